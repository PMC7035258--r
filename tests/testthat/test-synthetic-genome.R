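test_that("no events and zero rates yield an unduplicated genome", {
  p <- sim_params(n_genes = 40, n_chroms = 2, tandem_rate = 0,
                  proximal_rate = 0, dispersed_rate = 0, seed = 1)
  sim <- simulate_genome(p, events = list())
  expect_equal(nrow(sim$genes), 40)
  expect_true(all(sim$truth$dup_type_truth == "singleton"))
  expect_equal(nrow(sim$pairs), 0)
})

test_that("a WGT with full retention triples every gene", {
  p <- sim_params(n_genes = 30, n_chroms = 2, tandem_rate = 0,
                  proximal_rate = 0, dispersed_rate = 0, seed = 2)
  ev <- list(event_spec("theta", 3L, 0.5, 1.0, 1.0))
  sim <- simulate_genome(p, ev)
  expect_equal(nrow(sim$genes), 90)
  copies <- table(sim$truth$anc_id)
  expect_true(all(copies == 3))
  expect_true(all(sim$truth$dup_type_truth == "wgd"))
  # 3 copies per gene -> 3 pairs per ancestral gene
  expect_equal(nrow(sim$pairs), 90)
})

test_that("the simulation is deterministic in its seed", {
  p <- sim_params(n_genes = 60, n_chroms = 3, inversion_count = 5, seed = 9)
  s1 <- simulate_genome(p, default_events())
  s2 <- simulate_genome(p, default_events())
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$pairs, s2$pairs)
})

test_that("event and parameter validation rejects bad input", {
  expect_error(event_spec("x", 4L, 1, 0.5, 0.5), "multiplicity")
  expect_error(event_spec("x", 2L, 1, 1.5, 0.5), "probability")
  # ages must strictly decrease oldest -> youngest
  ev <- list(event_spec("old", 2L, 0.5, 0.5, 0.5),
             event_spec("young", 2L, 0.8, 0.5, 0.5))
  expect_error(simulate_genome(sim_params(n_genes = 10, seed = 1), ev),
               "decreasing")
  expect_error(sim_params(n_genes = 2, n_chroms = 5), "n_genes")
  expect_error(sim_params(tandem_rate = 0.6, proximal_rate = 0.6),
               "sum to at most 1")
})

test_that("gene-count bookkeeping is exact", {
  p <- sim_params(n_genes = 200, n_chroms = 3, seed = 4)
  sim <- simulate_genome(p, default_events())
  expect_equal(nrow(sim$genes), nrow(sim$truth))
  expect_equal(sum(sim$truth$origin_event == "ancestral"), 200)
  expect_equal(anyDuplicated(sim$genes$gene_id), 0)
  # ranks are a permutation of 0..n-1 per chromosome
  by_chr <- split(sim$genes$rank, sim$genes$chromosome)
  expect_true(all(vapply(by_chr, function(r) {
    identical(sort(r), seq_along(r) - 1L)
  }, TRUE)))
})

test_that("Ks values cluster at their event ages", {
  p <- sim_params(n_genes = 400, n_chroms = 2, ks_noise_sd = 0.05,
                  tandem_rate = 0, proximal_rate = 0, dispersed_rate = 0,
                  seed = 7)
  sim <- simulate_genome(p, default_events())
  ages <- c(gamma = 1.6, beta = 0.8, alpha = 0.2)
  wgd <- sim$pairs[sim$pairs$mode == "wgd", ]
  nearest <- names(ages)[apply(abs(outer(wgd$ks, ages, "-")), 1, which.min)]
  expect_gte(mean(nearest == wgd$event), 0.9)
})

test_that("similarity identity decays with pair age and self-hits rank first", {
  p <- sim_params(n_genes = 150, n_chroms = 2, tandem_rate = 0,
                  proximal_rate = 0, dispersed_rate = 0, seed = 5)
  sim <- simulate_genome(p, default_events())
  hits <- emit_similarity_table(sim, identity_noise = 0, seed = 1)
  wgd <- dplyr::inner_join(
    hits, sim$pairs,
    by = c(query_id = "gene_a", subject_id = "gene_b"))
  young <- wgd$pct_identity[wgd$event == "alpha"]
  old <- wgd$pct_identity[wgd$event == "gamma"]
  expect_gt(min(young), max(old))
  # every gene's first-ranked hit is itself
  firsts <- hits |> dplyr::group_by(query_id) |> dplyr::slice_head(n = 1)
  expect_true(all(firsts$query_id == firsts$subject_id))
  expect_true(all(firsts$evalue == 0))
  # E-value monotone decreasing in identity
  nonself <- hits[hits$query_id != hits$subject_id, ]
  ord <- order(nonself$pct_identity)
  expect_true(all(diff(nonself$evalue[ord]) <= 0))
})

test_that("no duplication means self-hits only", {
  p <- sim_params(n_genes = 25, n_chroms = 1, tandem_rate = 0,
                  proximal_rate = 0, dispersed_rate = 0, seed = 3)
  sim <- simulate_genome(p, events = list())
  hits <- emit_similarity_table(sim, seed = 1)
  expect_equal(nrow(hits), 25)
  expect_true(all(hits$query_id == hits$subject_id))
})

test_that("the synthetic reference network is deterministic and sized sanely", {
  p <- sim_params(n_genes = 400, n_chroms = 2, focal_fraction = 0.3, seed = 6)
  sim <- simulate_genome(p, events = list())
  expect_equal(nrow(emit_reference_network(sim$truth, 0, seed = 1)), 0)
  e1 <- emit_reference_network(sim$truth, 4, seed = 5)
  e2 <- emit_reference_network(sim$truth, 4, seed = 5)
  expect_identical(e1, e2)
  n_focal <- length(unique(sim$truth$anc_id[sim$truth$class_tag == "focal"]))
  expect_gt(n_focal, 50)
  expect_true(nrow(e1) > 1.5 * n_focal && nrow(e1) < 2.5 * n_focal)
  expect_true(all(e1$from != e1$to))
  expect_error(emit_reference_network(sim$truth, n_focal + 5, seed = 1),
               "mean_degree")
})
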