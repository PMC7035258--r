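mk_block <- function(ra, rb, ks, p = 0.001, chrom_a = "c1", chrom_b = "c2") {
  an <- tibble::tibble(gene_a = sprintf("a%d", seq_along(ra)),
                       gene_b = sprintf("b%d", seq_along(ra)),
                       chrom_a = chrom_a, chrom_b = chrom_b,
                       rank_a = as.integer(ra), rank_b = as.integer(rb))
  blocks <- chain_anchors(an)
  blocks$blocks$p_value <- p
  list(blocks = blocks,
       pair_ks = tibble::tibble(gene_a = an$gene_a, gene_b = an$gene_b,
                                ks = ks))
}

test_that("window construction enforces ordering and non-overlap", {
  expect_error(event_windows("a", 0.5, 0.2), "ks_min < ks_max")
  expect_error(event_windows(c("a", "b"), c(0, 0.4), c(0.5, 1)), "overlap")
  w <- event_windows(c("b", "a"), c(0.5, 0), c(1.2, 0.5))
  expect_equal(w$name, c("a", "b"))  # sorted by ks_min
})

test_that("blocks are labelled by the window containing their median Ks", {
  b <- mk_block(0:4, 0:4, ks = rep(0.30, 5))
  w <- event_windows(c("alpha", "beta"), c(0, 0.2), c(0.2, 0.5))
  labelled <- assign_block_events(b$blocks, b$pair_ks, w)
  expect_equal(labelled$blocks$event, "beta")

  # median outside all windows -> unassigned
  b2 <- mk_block(0:4, 0:4, ks = rep(3.0, 5))
  labelled2 <- assign_block_events(b2$blocks, b2$pair_ks, w)
  expect_true(is.na(labelled2$blocks$event))

  # half-open boundary: ks exactly at ks_max of alpha falls into beta
  b3 <- mk_block(0:4, 0:4, ks = rep(0.2, 5))
  labelled3 <- assign_block_events(b3$blocks, b3$pair_ks, w)
  expect_equal(labelled3$blocks$event, "beta")
})

test_that("a missing anchor Ks is an error naming the pair", {
  b <- mk_block(0:4, 0:4, ks = rep(0.3, 5))
  expect_error(assign_block_events(b$blocks, b$pair_ks[-2, ],
                                   default_event_windows()),
               "a2")
})

test_that("genes reduplicated in a younger event are recounted in both", {
  # two significant blocks sharing gene a1: one alpha-aged, one theta-aged
  an <- tibble::tibble(
    gene_a = c(sprintf("a%d", 1:5), sprintf("a%d", c(1, 6:9))),
    gene_b = c(sprintf("b%d", 1:5), sprintf("c%d", 1:5)),
    chrom_a = "c1",
    chrom_b = rep(c("c2", "c3"), each = 5),
    rank_a = c(0:4, 0L, 10:13), rank_b = c(0:4, 0:4))
  blocks <- list(
    blocks = tibble::tibble(
      block_id = 1:2, chrom_a = "c1", chrom_b = c("c2", "c3"),
      orientation = "same", n_anchors = 5L, score = 5L, total_gap = 0,
      p_value = 0.001, event = NA_character_),
    anchors = dplyr::mutate(an, block_id = rep(1:2, each = 5),
                            .before = 1))
  class(blocks) <- "polyret_blocks"
  pair_ks <- tibble::tibble(gene_a = an$gene_a, gene_b = an$gene_b,
                            ks = rep(c(0.2, 1.6), each = 5))
  w <- event_windows(c("alpha", "theta"), c(0, 1.2), c(0.5, 2.5))
  labelled <- assign_block_events(blocks, pair_ks, w)
  ev <- gene_event_participation(labelled)
  a1 <- ev$gene_events$event[ev$gene_events$gene_id == "a1"]
  expect_setequal(a1, c("alpha", "theta"))
  expect_equal(ev$event_counts$n[ev$event_counts$event == "alpha"], 10)
  expect_equal(ev$event_counts$n[ev$event_counts$event == "theta"], 10)
  # Venn partition sums to the number of event-assigned genes
  expect_equal(sum(ev$venn$n), length(unique(ev$gene_events$gene_id)))
  expect_equal(ev$venn$n[ev$venn$event_set == "alpha,theta"], 1)
})

test_that("event percentages use the half-up two-decimal convention", {
  expect_equal(format_percent(229, 420), "54.52")
  expect_equal(format_percent(132, 420), "31.43")
  expect_equal(format_percent(228, 420), "54.29")
})

test_that("simulated block labels recover the generating events", {
  sim <- simulate_genome(sim_params(n_genes = 500, n_chroms = 2,
                                    tandem_rate = 0, proximal_rate = 0,
                                    dispersed_rate = 0, seed = 31),
                         default_events())
  hits <- filter_anchors(emit_similarity_table(sim, seed = 1))
  an <- anchors_from_hits(hits, sim$genes)
  blocks <- find_collinear_blocks(an, sim$genes,
                                  collinearity_params(n_permutations = 100))
  blocks <- assign_block_events(blocks, sim$pairs, default_event_windows())
  # true event of a block = majority event of its anchor pairs
  truth_ev <- blocks$anchors |>
    dplyr::inner_join(sim$pairs, by = c("gene_a", "gene_b")) |>
    dplyr::group_by(block_id) |>
    dplyr::summarise(true_event = names(sort(table(event), decreasing = TRUE))[1])
  cmp <- dplyr::inner_join(blocks$blocks, truth_ev, by = "block_id") |>
    dplyr::filter(!is.na(p_value), p_value < 0.05)
  expect_gt(nrow(cmp), 10)
  expect_gte(mean(cmp$event == cmp$true_event, na.rm = TRUE), 0.9)
})

test_that("the Ks valley suggester finds the gap between two modes", {
  withr::with_seed(8, {
    ks <- c(rnorm(300, 0.2, 0.05), rnorm(300, 1.0, 0.1))
  })
  w <- suggest_ks_windows(ks, names = c("young", "old"))
  expect_equal(nrow(w), 2)
  cut <- w$ks_max[1]
  expect_gt(cut, 0.35)
  expect_lt(cut, 0.85)
})
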