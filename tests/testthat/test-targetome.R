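toy_sites <- function(n, chrom = "1") {
  set.seed(n)
  start <- sample.int(5000, n)
  tibble::tibble(
    mirna = sprintf("miR-%d", seq_len(n)), gene = sample(c("LAMC1", "GNB3", "OTHER"), n, TRUE),
    chrom = chrom, start = as.integer(start), end = as.integer(start + sample(6:9, n, TRUE)),
    strand = sample(c("+", "-"), n, TRUE), source = "targetscan"
  )
}

test_that("site extension adds flanks half-open and clamps at zero", {
  s <- tibble::tibble(mirna = "m", gene = "g", chrom = "1", start = 100L,
                      end = 107L, strand = "+", source = "other")
  ext <- extend_site(s, 25)
  expect_equal(c(ext$ext_start, ext$ext_end), c(75L, 132L))
  near0 <- extend_site(dplyr::mutate(s, start = 10L, end = 20L), 25)
  expect_equal(c(near0$ext_start, near0$ext_end), c(0L, 45L))
  ident <- extend_site(s, 0)
  expect_equal(c(ident$ext_start, ident$ext_end), c(100L, 107L))
  expect_error(extend_site(s, -1), ">= 0")
})

test_that("the ±flank boundary is inclusive at exactly flank bp", {
  s <- tibble::tibble(mirna = "m", gene = "g", chrom = "1", start = 1000L,
                      end = 1007L, strand = "+", source = "other")
  v <- toy_variants(4, pos = c(975L, 974L, 1031L, 1032L))
  out <- intersect_variants(v, s, pipeline_config(flank_nt = 25))
  expect_setequal(out$id, c("v001", "v003"))
  expect_true(all(out$placement == "flank"))
  expect_equal(out$distance_to_site[out$id == "v001"], -25L)
  expect_equal(out$distance_to_site[out$id == "v003"], 25L)
})

test_that("in-site vs flank placement follows the half-open site interval", {
  s <- tibble::tibble(mirna = "m", gene = "g", chrom = "1", start = 1000L,
                      end = 1007L, strand = "+", source = "other")
  v <- toy_variants(3, pos = c(1000L, 1006L, 1007L))
  out <- intersect_variants(v, s, pipeline_config(flank_nt = 25))
  expect_equal(out$placement, c("in_site", "in_site", "flank"))
  expect_equal(out$distance_to_site, c(0L, 0L, 1L))
})

test_that("intersection equals the brute-force double loop on random fixtures", {
  set.seed(606)
  variants <- toy_variants(300, pos = sample.int(6000, 300))
  sites <- toy_sites(40)
  got <- intersect_variants(variants, sites, pipeline_config(flank_nt = 25))
  want <- oracle_intersect(variants, sites, 25)
  got_key <- sort(paste(got$id, got$mirna, got$site_start, got$placement))
  want_key <- sort(paste(want$id, want$mirna, want$site_start, want$placement))
  expect_equal(got_key, want_key)
})

test_that("growing the flank never loses in-site hits or promotes flanks", {
  set.seed(42)
  variants <- toy_variants(100, pos = sample.int(3000, 100))
  sites <- toy_sites(15)
  small <- intersect_variants(variants, sites, pipeline_config(flank_nt = 10))
  big <- intersect_variants(variants, sites, pipeline_config(flank_nt = 40))
  key <- function(d) paste(d$id, d$mirna, d$site_start)
  in_small <- key(dplyr::filter(small, placement == "in_site"))
  in_big <- key(dplyr::filter(big, placement == "in_site"))
  expect_true(all(in_small %in% in_big))
  expect_setequal(in_small, in_big) # in-site set independent of flank
  flank_small <- key(dplyr::filter(small, placement == "flank"))
  expect_false(any(flank_small %in% in_big))
})

test_that("pathway filtering keeps inflammatory genes and annotates them", {
  interactions <- tibble::tibble(
    mirna = "m", gene = c("LAMC1", "GNB3", "XYZ"), id = c("r1", "r2", "r3"),
    chrom = "1", pos = 1:3, placement = "in_site", distance_to_site = 0L,
    site_start = 1L, site_end = 8L, strand = "+", source = "other")
  pathways <- tibble::tibble(
    pathway = c("Inflammatory Response Pathway", "ERK Signaling SuperPath",
                "PI3K/Akt Signaling"),
    source = c("WikiPathways", "PathCards", "KEGG"),
    gene = c("LAMC1", "GNB3", "LAMC1"),
    inflammatory = TRUE)
  out <- filter_by_pathways(interactions, pathways)
  expect_setequal(out$gene, c("LAMC1", "GNB3"))
  # two pathways -> one interaction row, two annotations
  expect_equal(sum(out$gene == "LAMC1"), 1)
  expect_match(out$pathways[out$gene == "LAMC1"], "Inflammatory Response")
  expect_match(out$pathways[out$gene == "LAMC1"], "PI3K/Akt")
  expect_warning(empty <- filter_by_pathways(interactions, pathways[0, ]),
                 "Empty pathway list")
  expect_equal(nrow(empty), 0)
})

test_that("interaction summaries count in-site and flank per gene, order-free", {
  set.seed(2)
  inter <- tibble::tibble(
    gene = c(rep("LAMC1", 27), rep("GNB3", 9)),
    placement = c(rep("in_site", 11), rep("flank", 16), rep("flank", 9)))
  out <- summarize_interactions(inter)
  expect_equal(out$n_in_site[out$gene == "LAMC1"], 11L)
  expect_equal(out$n_flank[out$gene == "LAMC1"], 16L)
  expect_equal(out$n_flank[out$gene == "GNB3"], 9L)
  expect_equal(out$n_in_site[out$gene == "GNB3"], 0L)
  shuffled <- inter[sample(nrow(inter)), ]
  expect_equal(summarize_interactions(shuffled), out)
  expect_equal(nrow(summarize_interactions(inter[0, ])), 0)
})
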