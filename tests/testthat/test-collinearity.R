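mk_anchors <- function(ra, rb, chrom_a = "c1", chrom_b = "c2") {
  tibble::tibble(gene_a = sprintf("a%d", seq_along(ra)),
                 gene_b = sprintf("b%d", seq_along(ra)),
                 chrom_a = chrom_a, chrom_b = chrom_b,
                 rank_a = as.integer(ra), rank_b = as.integer(rb))
}

test_that("a perfect diagonal chains into one same-orientation block", {
  blocks <- chain_anchors(mk_anchors(0:4, 0:4))
  expect_equal(nrow(blocks$blocks), 1)
  expect_equal(blocks$blocks$orientation, "same")
  expect_equal(blocks$blocks$n_anchors, 5L)
  expect_equal(blocks$anchors$rank_a, 0:4)
})

test_that("the 50-gene gap constraint splits distant anchors", {
  blocks <- chain_anchors(mk_anchors(c(0, 52), c(0, 52)),
                          collinearity_params(min_anchors = 2))
  expect_equal(nrow(blocks$blocks), 0)
  # at gap exactly 50 intervening genes the pair chains
  ok <- chain_anchors(mk_anchors(c(0, 51), c(0, 51)),
                      collinearity_params(min_anchors = 2))
  expect_equal(nrow(ok$blocks), 1)
})

test_that("an anti-diagonal chains into one reverse-orientation block", {
  blocks <- chain_anchors(mk_anchors(0:4, 9:5))
  expect_equal(nrow(blocks$blocks), 1)
  expect_equal(blocks$blocks$orientation, "reverse")
  expect_equal(blocks$anchors$rank_b, 9:5)
})

test_that("chaining equals the exhaustive oracle on random instances", {
  for (s in 1:60) {
    inst <- random_anchor_instance(s)
    an <- mk_anchors(inst$ra, inst$rb)
    got <- chain_anchors(an, collinearity_params(max_gap = inst$max_gap,
                                                 min_anchors = inst$min_anchors))
    exp <- oracle_chain_blocks(inst$ra, inst$rb, inst$max_gap,
                               inst$min_anchors)
    expect_equal(nrow(got$blocks), length(exp), info = paste("seed", s))
    for (i in seq_along(exp)) {
      gi <- got$anchors[got$anchors$block_id == got$blocks$block_id[i], ]
      expect_equal(gi$rank_a, inst$ra[exp[[i]]$anchor_idx],
                   info = paste("seed", s, "block", i))
      expect_equal(gi$rank_b, inst$rb[exp[[i]]$anchor_idx],
                   info = paste("seed", s, "block", i))
      expect_equal(got$blocks$orientation[i], exp[[i]]$orientation,
                   info = paste("seed", s, "block", i))
    }
  }
})

test_that("blocks depend only on ranks, not gene labels", {
  an1 <- mk_anchors(c(0, 1, 2, 3, 4, 8), c(0, 1, 2, 3, 4, 9))
  an2 <- an1
  an2$gene_a <- sprintf("X%d", 6:1)
  an2$gene_b <- sprintf("Y%d", 6:1)
  b1 <- chain_anchors(an1)
  b2 <- chain_anchors(an2)
  expect_equal(b1$anchors[c("rank_a", "rank_b")],
               b2$anchors[c("rank_a", "rank_b")])
  expect_equal(b1$blocks$score, b2$blocks$score)
})

test_that("permutation p-values respect the add-one estimator bounds", {
  params <- collinearity_params(n_permutations = 200, seed = 3)
  # 20-anchor perfect diagonal among 20 anchors on a 500x500 grid: no random
  # redraw chains 20, so p attains its lower bound
  p <- block_pvalue(20, 20, 500, 500, params)
  expect_equal(p, 1 / 201)
  # score 1 is always reachable: p attains its upper bound
  expect_equal(block_pvalue(1, 20, 500, 500, params), 1)
  # a block scoring the typical best random chain sits mid-distribution
  null <- withr::with_seed(11,
    polyret:::perm_null_scores_cpp(50, 100, 100, 50, 500))
  p_mid <- block_pvalue(round(median(null)), 50, 100, 100,
                        collinearity_params(n_permutations = 500, seed = 12))
  expect_gt(p_mid, 0.2)
  expect_lt(p_mid, 0.9)
  expect_error(block_pvalue(5, 10, 0, 100, params), "positive")
})

test_that("colinear gene sets union significant blocks only", {
  an <- mk_anchors(0:4, 0:4)
  blocks <- chain_anchors(an)
  blocks$blocks$p_value <- 0.2
  expect_equal(colinear_gene_set(blocks), character(0))
  blocks$blocks$p_value <- 0.001
  cs <- colinear_gene_set(blocks)
  expect_equal(length(cs), 10)  # 5 genes per side
  expect_setequal(cs, c(sprintf("a%d", 1:5), sprintf("b%d", 1:5)))
})

test_that("hit classes rank best, second and other deterministically", {
  hits <- tibble::tibble(
    query_id = c("q", "q", "q", "q"),
    subject_id = c("s1", "s2", "s3", "q"),
    pct_identity = 80, aln_len = 300L, mismatches = 0L, gapopens = 0L,
    qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
    evalue = c(1e-30, 1e-20, 1e-10, 0), bitscore = c(500, 400, 300, 999))
  cls <- rank_hit_classes(hits)
  expect_equal(cls$hit_class[match(c("s1", "s2", "s3"), cls$subject_id)],
               c("best", "second", "other"))
  expect_false("q" %in% cls$subject_id)
  # equal E-values broken by bitscore
  hits$evalue <- c(1e-20, 1e-20, 1e-10, 0)
  cls2 <- rank_hit_classes(hits)
  expect_equal(cls2$hit_class[cls2$subject_id == "s1"], "best")
  expect_equal(cls2$hit_class[cls2$subject_id == "s2"], "second")
})

test_that("self-comparison anchors drop the tandem-adjacent diagonal", {
  genes <- small_genome_tibble(sprintf("g%d", 1:6), "chr1",
                               as.integer(1:6 * 100))
  hits <- tibble::tibble(
    query_id = c("g1", "g2", "g1"), subject_id = c("g2", "g1", "g4"),
    pct_identity = 80, aln_len = 300L, mismatches = 0L, gapopens = 0L,
    qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
    evalue = 1e-20, bitscore = 400)
  an <- anchors_from_hits(hits, genes)
  expect_equal(nrow(an), 1)  # only the g1-g4 pair survives
  all_an <- anchors_from_hits(hits, genes, exclude_tandem_adjacent = FALSE)
  expect_equal(nrow(all_an), 2)
  expect_error(anchors_from_hits(
    dplyr::mutate(hits, subject_id = c("g2", "g1", "missing")), genes),
    "absent")
})

test_that("whole-genome block finding recovers a duplicated chromosome", {
  # chr2 is a shuffled-free copy of chr1: one clean block spanning it
  genes <- small_genome_tibble(
    c(sprintf("a%d", 1:8), sprintf("b%d", 1:8)),
    rep(c("chr1", "chr2"), each = 8), rep(as.integer(1:8 * 100), 2))
  hits <- tibble::tibble(
    query_id = sprintf("a%d", 1:8), subject_id = sprintf("b%d", 1:8),
    pct_identity = 80, aln_len = 300L, mismatches = 0L, gapopens = 0L,
    qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
    evalue = 1e-20, bitscore = 400)
  an <- anchors_from_hits(hits, genes)
  blocks <- find_collinear_blocks(an, genes,
                                  collinearity_params(n_permutations = 200))
  expect_equal(nrow(blocks$blocks), 1)
  expect_equal(blocks$blocks$n_anchors, 8L)
  expect_lt(blocks$blocks$p_value, 0.05)
})
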