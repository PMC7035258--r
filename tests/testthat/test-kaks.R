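test_that("site counts match codon-level enumeration", {
  expect_equal(ng86_sites("ATG"), c(S_sites = 0, N_sites = 3))
  expect_equal(ng86_sites("TTT"), c(S_sites = 1 / 3, N_sites = 8 / 3))
  # S + N = 3 x codon count for random stop-free sequences
  withr::with_seed(3, {
    for (i in 1:5) {
      s <- random_codons(20)
      st <- ng86_sites(s)
      expect_equal(unname(st[1] + st[2]), 60)
      expect_equal(unname(st), unname(oracle_sites(s)), tolerance = 1e-12)
    }
  })
  expect_error(ng86_sites("ATGTAA"), "Stop codon at codon index 2")
  expect_error(ng86_sites("ATGN"), "multiple of 3")
})

test_that("pairwise differences average over mutational pathways", {
  expect_equal(ng86_differences("TTT", "TTT"), c(sd = 0, nd = 0))
  expect_equal(ng86_differences("TTT", "TTC"), c(sd = 1, nd = 0))
  expect_equal(ng86_differences("TTT", "TTA"), c(sd = 0, nd = 1))
  # TTT -> GTA via TTT>GTT>GTA (0 syn) or TTT>TTA>GTA (Leu>Leu step? no:
  # TTA is Leu, TTT is Phe -> nonsyn; TTA>GTA Leu>Val nonsyn). Both paths
  # classified below by the independent oracle.
  got <- ng86_differences("TTT", "GTA")
  expect_equal(got, oracle_diffs("TTT", "GTA"), tolerance = 1e-12)
  expect_equal(unname(got[1] + got[2]), 2)
  # three-position difference conserves total changes
  got3 <- ng86_differences("AAA", "GGG")
  expect_equal(unname(got3[1] + got3[2]), 3)
  expect_equal(got3, oracle_diffs("AAA", "GGG"), tolerance = 1e-12)
})

test_that("Jukes-Cantor correction behaves at its boundaries", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.3), 0.3831, tolerance = 1e-4)
  expect_error(jukes_cantor(0.75), "saturates")
  expect_error(jukes_cantor(-0.1), "non-negative")
})

test_that("pair-level composition handles degenerate alignments", {
  s <- random_codons(20)
  same <- kaks_pair(s, s)
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  expect_true(is.na(same$omega))
  expect_false(same$positive_selection)

  # a single synonymous change: Ka = 0, omega = 0
  a <- paste0("TTT", strrep("GGG", 19))
  b <- paste0("TTC", strrep("GGG", 19))
  r <- kaks_pair(a, b)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  expect_equal(r$omega, 0)

  # gapped codon columns are dropped pairwise
  ga <- paste0("TTT", "A-G", strrep("GGG", 4))
  gb <- paste0("TTC", "ATG", strrep("GGG", 4))
  rg <- kaks_pair(ga, gb)
  expect_equal(rg$n_codons, 5L)
  expect_error(kaks_pair("---", "ATG"), "No ungapped")
  expect_error(kaks_pair("ATG", "ATGATG"), "equal length")
})

test_that("kaks_pair is symmetric and matches the brute-force oracle", {
  withr::with_seed(41, {
    for (i in 1:20) {
      a <- random_codons(30)
      b <- mutate_codons(a, sample(3:12, 1))
      r_ab <- kaks_pair(a, b)
      r_ba <- kaks_pair(b, a)
      expect_equal(as.data.frame(r_ab), as.data.frame(r_ba),
                   tolerance = 1e-12)
      o <- oracle_kaks(a, b)
      expect_equal(r_ab$S_sites, o$S, tolerance = 1e-10)
      expect_equal(r_ab$Sd, o$Sd, tolerance = 1e-10)
      expect_equal(r_ab$Nd, o$Nd, tolerance = 1e-10)
      expect_equal(r_ab$Ks, o$Ks, tolerance = 1e-10)
      expect_equal(r_ab$Ka, o$Ka, tolerance = 1e-10)
    }
  })
})

test_that("distances grow with divergence under neutral mutation", {
  withr::with_seed(47, {
    a <- random_codons(60)
    b1 <- mutate_codons(a, 4)
    b2 <- mutate_codons(b1, 8)
    b3 <- mutate_codons(b2, 12)
    d <- vapply(list(b1, b2, b3), function(b) {
      r <- kaks_pair(a, b)
      r$Ka * r$N_sites + r$Ks * r$S_sites
    }, 0)
    expect_true(all(diff(d) > 0))
  })
})

test_that("batch mode and FASTA input work end to end", {
  withr::with_seed(53, {
    seqs <- c(g1 = random_codons(25))
    seqs["g2"] <- mutate_codons(seqs[["g1"]], 5)
    seqs["g3"] <- mutate_codons(seqs[["g1"]], 10)
  })
  pairs <- tibble::tibble(gene_a = c("g1", "g1"), gene_b = c("g2", "g3"))
  batch <- kaks_batch(pairs, seqs)
  expect_equal(nrow(batch), 2)
  expect_equal(batch$gene_b, c("g2", "g3"))
  single <- kaks_pair(seqs[["g1"]], seqs[["g2"]])
  expect_equal(batch$Ks[1], single$Ks)
  expect_error(kaks_batch(tibble::tibble(gene_a = "g1", gene_b = "gX"), seqs),
               "No sequence")

  fa <- withr::local_tempfile()
  writeLines(c(">g1", seqs[["g1"]], ">g2", seqs[["g2"]]), fa)
  aln <- read_codon_alignment(fa)
  expect_equal(unname(aln), unname(seqs[c("g1", "g2")]))
  writeLines(c(">g1", seqs[["g1"]]), fa)
  expect_error(read_codon_alignment(fa), "exactly 2")
})
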