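#' Prioritize GWAS variants through the targetome cascade
#'
#' Runs the four-step prioritization on in-memory inputs:
#' 1. keep GWAS hits with `p < gwas_p_threshold`;
#' 2. expand the surviving index variants to LD proxies in the panel
#'    (`r2 >= r2_threshold`, within `proxy_window_bp`);
#' 3. intersect the candidate set with flank-extended miRNA binding sites;
#' 4. keep interactions whose target gene sits in an inflammatory pathway.
#' A run manifest records the record count entering and leaving each stage
#' (monotone non-increasing over the variant filters), input digests, the
#' configuration snapshot and package version.
#'
#' @param gwas GWAS hit tibble (see [read_gwas_hits()]).
#' @param panel A [haplotype_panel()].
#' @param sites Binding-site tibble (see [read_sites()]).
#' @param pathways Pathway tibble (see [read_pathways()]).
#' @param config A [pipeline_config()].
#' @return List of class `mirtld_prioritization`: `interactions` (final
#'   annotated interaction table), `candidates` (proxy map), `manifest`.
#' @export
prioritize_variants <- function(gwas, panel, sites, pathways,
                                config = pipeline_config()) {
  hits <- filter(as_tibble(gwas), .data$p_value < config$gwas_p_threshold)
  proxies <- proxy_expand(unique(hits$variant_id), panel, config)
  cand_ids <- unique(proxies$proxy_id)
  candidates <- panel$variants[panel$variants$id %in% cand_ids, , drop = FALSE]
  interactions <- intersect_variants(candidates, sites, config)
  final <- filter_by_pathways(interactions, pathways, inflammatory_only = TRUE)
  manifest <- list(
    config = unclass(config),
    version = as.character(utils::packageVersion("mirtld")),
    seed = config$rng_seed,
    counts = list(
      gwas_hits_in = nrow(gwas),
      index_pass_p = length(unique(hits$variant_id)),
      index_in_panel = length(unique(proxies$index_id)),
      index_skipped = length(attr(proxies, "skipped")),
      candidate_variants = length(cand_ids),
      variants_in_targetome = length(unique(interactions$id)),
      variants_after_pathway_filter = length(unique(final$id)),
      interactions_in_targetome = nrow(interactions),
      interactions_final = nrow(final)
    ),
    notes = if (nrow(final) == 0) "pipeline completed with empty output"
            else character()
  )
  structure(list(interactions = final, candidates = proxies,
                 manifest = manifest),
            class = "mirtld_prioritization")
}

#' @export
print.mirtld_prioritization <- function(x, ...) {
  cat("<targetome prioritization>\n")
  cnt <- x$manifest$counts
  for (k in names(cnt)) cat(sprintf("  %-32s %d\n", k, cnt[[k]]))
  invisible(x)
}

file_digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run prioritization from files and write outputs
#'
#' File-level wrapper over [prioritize_variants()]: reads the four inputs,
#' writes the interaction TSV, the proxy map TSV and a YAML run manifest
#' (including md5 digests of the inputs) into `out_dir`.
#'
#' @param gwas_path,panel_path,sites_path,pathways_path Input files.
#' @param out_dir Output directory (created if absent).
#' @param config A [pipeline_config()].
#' @return The `mirtld_prioritization` object, invisibly.
#' @export
cmd_prioritize <- function(gwas_path, panel_path, sites_path, pathways_path,
                           out_dir, config = pipeline_config()) {
  res <- prioritize_variants(
    gwas = read_gwas_hits(gwas_path),
    panel = read_haplotype_panel(panel_path),
    sites = read_sites(sites_path),
    pathways = read_pathways(pathways_path),
    config = config
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res$manifest$input_digests <- file_digests(
    c(gwas_path, panel_path, sites_path, pathways_path))
  readr::write_tsv(res$interactions, file.path(out_dir, "interactions.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$candidates, file.path(out_dir, "proxy_map.tsv"),
                   progress = FALSE)
  yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(res)
}

#' Run the association suite from files and write report tables
#'
#' Reads genotypes and samples, runs [run_association_suite()],
#' [hwe_controls()] (already part of the suite), pairwise LD summaries and
#' the cumulative genotype/haplotype tables for every variant pair, and
#' writes them as TSVs into `out_dir`.
#'
#' @param genotypes_path Genotype VCF or TSV.
#' @param samples_path Sample table TSV.
#' @param out_dir Output directory.
#' @param contrasts Contrast list, default [default_contrasts()].
#' @param config A [pipeline_config()].
#' @return List with the suite, LD table and cumulative objects, invisibly.
#' @export
cmd_associate <- function(genotypes_path, samples_path, out_dir,
                          contrasts = default_contrasts(),
                          config = pipeline_config()) {
  geno <- read_genotypes(genotypes_path)
  samples <- read_samples(samples_path)
  suite <- run_association_suite(geno, samples, contrasts, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(suite$results, file.path(out_dir, "association.tsv"),
                   progress = FALSE)
  readr::write_tsv(suite$hwe, file.path(out_dir, "hwe.tsv"), progress = FALSE)
  lds <- purrr::map_dfr(
    utils::combn(geno$variants$id, 2, simplify = FALSE),
    function(pr) {
      res <- tryCatch(ld_from_unphased(geno, pr[1], pr[2]),
                      error = function(e) tibble())
      res
    })
  if (nrow(lds) > 0) {
    readr::write_tsv(lds, file.path(out_dir, "ld_unphased.tsv"),
                     progress = FALSE)
  }
  cumulative <- list()
  if (nrow(geno$variants) >= 2) {
    groups <- split(samples$sample_id, samples$status)
    pairs <- utils::combn(geno$variants$id, 2, simplify = FALSE)
    cumulative <- purrr::map(pairs, function(pr) {
      tryCatch(cumulative_genotypes(geno, pr[1], pr[2], groups),
               error = function(e) NULL)
    })
    cum_freq <- purrr::map_dfr(purrr::compact(cumulative), function(cg) {
      mutate(cg$frequencies, pair = paste0(cg$id1, "/", cg$id2), .before = 1)
    })
    if (nrow(cum_freq) > 0) {
      readr::write_tsv(cum_freq, file.path(out_dir, "cumulative.tsv"),
                       progress = FALSE)
    }
  }
  invisible(list(suite = suite, ld = lds, cumulative = cumulative))
}

#' Write a full synthetic input set to disk
#'
#' Generates panel, cohort and targetome from a [simulation_spec()] and
#' writes them in the standard formats consumed by the readers (phased
#' panel VCF, genotype TSV, sample TSV, site BED, pathway and GWAS TSVs)
#' plus a `truth.json` with the planted ground-truth labels and parameters.
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Output directory (created if absent).
#' @param config A [pipeline_config()] used for the targetome truth labels.
#' @return Named list of file paths, invisibly.
#' @export
simulate_inputs <- function(spec, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(spec)
  cohort <- simulate_cohort(spec, panel)
  tgt <- simulate_targetome(spec, panel, config)
  paths <- list(
    panel = file.path(out_dir, "panel.vcf"),
    genotypes = file.path(out_dir, "genotypes.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    sites = file.path(out_dir, "sites.bed"),
    pathways = file.path(out_dir, "pathways.tsv"),
    gwas = file.path(out_dir, "gwas.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_vcf(panel, paths$panel)
  write_genotypes(cohort$genotypes, paths$genotypes)
  readr::write_tsv(cohort$samples, paths$samples, progress = FALSE)
  write_sites(tgt$sites, paths$sites)
  write_pathways(tgt$pathways, paths$pathways)
  write_gwas_hits(tgt$gwas, paths$gwas)
  jsonlite::write_json(
    list(targetome = tgt$truth,
         cohort = list(intercept = cohort$truth$intercept,
                       case_fraction = cohort$truth$case_fraction,
                       covariate_coefs = as.list(cohort$truth$covariate_coefs),
                       effect_spec = cohort$truth$effect_spec)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
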