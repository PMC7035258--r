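test_that("classification follows the five-type precedence on a toy genome", {
  # chr1: g1..g10; chr2: h1..h10. Hand-worked expectations:
  #  - g1/g2 adjacent homologs            -> tandem
  #  - g4/g9 with 4 intervening genes     -> proximal
  #  - g3/h10 cross-chromosome pair       -> dispersed
  #  - g5..g8 + g10 diagonal onto h1..h5  -> wgd (both sides)
  #  - h6..h9 hitless                     -> singleton
  genes <- small_genome_tibble(
    c(sprintf("g%d", 1:10), sprintf("h%d", 1:10)),
    rep(c("chr1", "chr2"), each = 10), rep(as.integer(1:10 * 100), 2))
  pair <- function(a, b) tibble::tibble(
    query_id = a, subject_id = b, pct_identity = 80, aln_len = 300L,
    mismatches = 0L, gapopens = 0L, qstart = 1L, qend = 300L,
    sstart = 1L, send = 300L, evalue = 1e-20, bitscore = 400)
  hits <- dplyr::bind_rows(
    pair("g1", "g2"), pair("g4", "g9"), pair("g3", "h10"),
    pair("g5", "h1"), pair("g6", "h2"), pair("g7", "h3"),
    pair("g8", "h4"), pair("g10", "h5"))
  anchors <- anchors_from_hits(hits, genes, exclude_tandem_adjacent = FALSE)
  chain_an <- anchors_from_hits(hits, genes)
  blocks <- find_collinear_blocks(chain_an, genes,
                                  collinearity_params(n_permutations = 200))
  expect_equal(nrow(blocks$blocks), 1)
  expect_lt(blocks$blocks$p_value, 0.05)
  types <- classify_duplicates(genes, anchors, blocks)
  expected <- c(g1 = "tandem", g2 = "tandem", g3 = "dispersed",
                g4 = "proximal", g5 = "wgd", g6 = "wgd", g7 = "wgd",
                g8 = "wgd", g9 = "proximal", g10 = "wgd",
                h1 = "wgd", h2 = "wgd", h3 = "wgd", h4 = "wgd", h5 = "wgd",
                h6 = "singleton", h7 = "singleton", h8 = "singleton",
                h9 = "singleton", h10 = "dispersed")
  got <- setNames(types$dup_type, types$gene_id)
  expect_equal(got[names(expected)], expected)
})

test_that("precedence puts wgd above an adjacent homolog", {
  genes <- small_genome_tibble(
    c(sprintf("g%d", 1:6), sprintf("h%d", 1:5)),
    rep(c("chr1", "chr2"), c(6, 5)),
    c(as.integer(1:6 * 100), as.integer(1:5 * 100)))
  pair <- function(a, b) tibble::tibble(
    query_id = a, subject_id = b, pct_identity = 80, aln_len = 300L,
    mismatches = 0L, gapopens = 0L, qstart = 1L, qend = 300L,
    sstart = 1L, send = 300L, evalue = 1e-20, bitscore = 400)
  hits <- dplyr::bind_rows(
    pair("g1", "h1"), pair("g2", "h2"), pair("g3", "h3"),
    pair("g4", "h4"), pair("g5", "h5"), pair("g5", "g6"))
  anchors <- anchors_from_hits(hits, genes, exclude_tandem_adjacent = FALSE)
  blocks <- find_collinear_blocks(anchors_from_hits(hits, genes), genes,
                                  collinearity_params(n_permutations = 200))
  types <- classify_duplicates(genes, anchors, blocks)
  got <- setNames(types$dup_type, types$gene_id)
  expect_equal(got[["g5"]], "wgd")     # in block, despite adjacent g6
  expect_equal(got[["g6"]], "tandem")
})

test_that("classification errors when anchors reference unknown genes", {
  genes <- small_genome_tibble(c("g1", "g2"), "chr1", c(100L, 200L))
  anchors <- tibble::tibble(gene_a = "g1", gene_b = "gX", chrom_a = "chr1",
                            chrom_b = "chr1", rank_a = 0L, rank_b = 5L)
  blocks <- chain_anchors(anchors[0, ])
  expect_error(classify_duplicates(genes, anchors, blocks), "absent")
})

test_that("every gene receives exactly one type", {
  sim <- simulate_genome(sim_params(n_genes = 150, n_chroms = 2, seed = 21),
                         default_events())
  hits <- filter_anchors(emit_similarity_table(sim, seed = 1))
  anchors <- anchors_from_hits(hits, sim$genes,
                               exclude_tandem_adjacent = FALSE)
  blocks <- find_collinear_blocks(anchors_from_hits(hits, sim$genes),
                                  sim$genes,
                                  collinearity_params(n_permutations = 100))
  types <- classify_duplicates(sim$genes, anchors, blocks)
  expect_equal(sort(types$gene_id), sort(sim$genes$gene_id))
  expect_false(anyNA(types$dup_type))
  expect_true(all(types$dup_type %in%
                    c("singleton", "dispersed", "proximal", "tandem", "wgd")))
})

test_that("type summaries reproduce published-style percentages", {
  counts <- c(singleton = 5, dispersed = 42, proximal = 3, tandem = 17,
              wgd = 353)
  type_map <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:420),
    dup_type = rep(names(counts), counts))
  s <- summarize_dup_types(type_map)
  expect_equal(s$n, unname(counts[s$dup_type]))
  expect_equal(s$percent[match(c("singleton", "dispersed", "proximal",
                                 "tandem", "wgd"), s$dup_type)],
               c(1.19, 10.00, 0.71, 4.05, 84.05))
  expect_equal(sum(s$n), 420)
  expect_lt(abs(sum(s$percent) - 100), 0.05)
})

test_that("summary contracts hold for degenerate universes", {
  one <- tibble::tibble(gene_id = "g1", dup_type = "singleton")
  s <- summarize_dup_types(one)
  expect_equal(s$percent[s$dup_type == "singleton"], 100)
  expect_error(summarize_dup_types(one, character(0)), "non-empty")
  expect_error(summarize_dup_types(one, c("g1", "g2")), "cover")
})
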