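#' Collinearity detection parameters
#'
#' @param max_gap Maximum intervening gene ranks allowed between adjacent
#'   chain anchors, on each genome. Default 50.
#' @param min_anchors Minimum anchors per reported block. Default 5.
#' @param p_max Block significance threshold. Default 0.05.
#' @param n_permutations Permutation count for the block null distribution.
#' @param seed Seed for the permutation null.
#' @return A list of class `polyret_collinearity_params`.
#' @export
collinearity_params <- function(max_gap = 50, min_anchors = 5, p_max = 0.05,
                                n_permutations = 1000, seed = 1L) {
  max_gap <- check_count(max_gap, "max_gap")
  min_anchors <- check_count(min_anchors, "min_anchors", min = 2)
  if (!is.numeric(p_max) || p_max <= 0 || p_max > 1)
    abort("`p_max` must be in (0, 1].")
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1)
  structure(list(max_gap = max_gap, min_anchors = min_anchors, p_max = p_max,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "polyret_collinearity_params")
}

new_blocks <- function(blocks, anchors) {
  structure(list(blocks = blocks, anchors = anchors),
            class = "polyret_blocks")
}

#' @export
print.polyret_blocks <- function(x, ...) {
  nsig <- sum(!is.na(x$blocks$p_value) & x$blocks$p_value < 0.05)
  cat(sprintf("<polyret_blocks> %d blocks (%d with p < 0.05), %d anchors\n",
              nrow(x$blocks), nsig, nrow(x$anchors)))
  invisible(x)
}

#' @export
tidy.polyret_blocks <- function(x, ...) x$blocks

#' @export
glance.polyret_blocks <- function(x, ...) {
  tibble(n_blocks = nrow(x$blocks),
         n_significant = sum(!is.na(x$blocks$p_value) & x$blocks$p_value < 0.05),
         n_anchors = nrow(x$anchors),
         median_block_size = if (nrow(x$blocks)) median(x$blocks$n_anchors) else NA_real_)
}

#' Build anchor pairs from filtered similarity hits and gene positions
#'
#' Joins the two sides of each hit to their chromosome and gene-order rank.
#' For a self-genome comparison (one position table), pairs are canonicalised
#' so each unordered pair appears once, self-pairs are dropped, and
#' tandem-adjacent pairs on the same chromosome (rank distance <= 1) are
#' excluded so the main diagonal cannot masquerade as a block.
#'
#' @param hits Similarity tibble, typically from [filter_anchors()].
#' @param genes Gene position tibble (query side).
#' @param genes_b Optional subject-side position tibble for a two-genome
#'   comparison; when `NULL` the comparison is within `genes`.
#' @param exclude_tandem_adjacent Drop same-chromosome pairs at rank distance
#'   <= 1 in a self-comparison. Keep the default for chaining; set `FALSE`
#'   when the anchors feed [classify_duplicates()], which needs tandem pairs.
#' @return An anchor tibble: `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `rank_a`, `rank_b`, deduplicated.
#' @export
anchors_from_hits <- function(hits, genes, genes_b = NULL,
                              exclude_tandem_adjacent = TRUE) {
  self_cmp <- is.null(genes_b)
  if (self_cmp) genes_b <- genes
  missing_a <- setdiff(unique(hits$query_id), genes$gene_id)
  missing_b <- setdiff(unique(hits$subject_id), genes_b$gene_id)
  if (length(missing_a) > 0 || length(missing_b) > 0)
    abort(sprintf("Gene(s) referenced by hits but absent from position table: %s",
                  paste(head(c(missing_a, missing_b), 3), collapse = ", ")))
  pos_a <- genes |> select(gene_a = "gene_id", chrom_a = "chromosome",
                           rank_a = "rank")
  pos_b <- genes_b |> select(gene_b = "gene_id", chrom_b = "chromosome",
                             rank_b = "rank")
  an <- hits |>
    select(gene_a = "query_id", gene_b = "subject_id") |>
    filter(.data$gene_a != .data$gene_b) |>
    inner_join(pos_a, by = "gene_a") |>
    inner_join(pos_b, by = "gene_b")
  if (self_cmp) {
    an <- an |>
      mutate(swap = .data$gene_a > .data$gene_b,
             ga = ifelse(.data$swap, .data$gene_b, .data$gene_a),
             gb = ifelse(.data$swap, .data$gene_a, .data$gene_b),
             ca = ifelse(.data$swap, .data$chrom_b, .data$chrom_a),
             cb = ifelse(.data$swap, .data$chrom_a, .data$chrom_b),
             ra = ifelse(.data$swap, .data$rank_b, .data$rank_a),
             rb = ifelse(.data$swap, .data$rank_a, .data$rank_b)) |>
      select(gene_a = "ga", gene_b = "gb", chrom_a = "ca", chrom_b = "cb",
             rank_a = "ra", rank_b = "rb")
    if (exclude_tandem_adjacent) {
      an <- an |>
        filter(!(.data$chrom_a == .data$chrom_b &
                   abs(.data$rank_a - .data$rank_b) <= 1))
    }
    # put each pair on a canonical chromosome-pair orientation
    sw <- an$chrom_a > an$chrom_b |
      (an$chrom_a == an$chrom_b & an$rank_a > an$rank_b)
    an[sw, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")] <-
      an[sw, c("gene_b", "gene_a", "chrom_b", "chrom_a", "rank_b", "rank_a")]
  }
  an |>
    distinct() |>
    arrange(.data$chrom_a, .data$chrom_b, .data$rank_a, .data$rank_b,
            .data$gene_a, .data$gene_b)
}

#' Chain anchors into collinear blocks on one chromosome pair
#'
#' Greedy best-chain-first extraction: the maximum-score chain under the gap
#' constraint is found by dynamic programming (score = anchor count; ties by
#' smaller total gap, then by lexicographically smaller
#' `(rank_a, rank_b)` anchor sequence, which puts the smallest starting rank
#' first; same orientation before reverse), its anchors are removed, and the
#' search repeats until no chain reaches `min_anchors`. Both orientations are
#' searched; blocks never share anchors.
#'
#' @param anchors Anchor tibble for a single chromosome pair (deduplicated).
#' @param params A [collinearity_params()] object.
#' @return A `polyret_blocks` object with `p_value` and `event` unset (`NA`);
#'   see [find_collinear_blocks()] for the scored pipeline version.
#' @export
chain_anchors <- function(anchors, params = collinearity_params()) {
  stopifnot(inherits(params, "polyret_collinearity_params"))
  if (nrow(anchors) > 0 &&
      nrow(distinct(anchors[, c("chrom_a", "chrom_b")])) > 1)
    abort("`chain_anchors()` expects anchors from a single chromosome pair; use find_collinear_blocks() for whole genomes.")
  anchors <- distinct(anchors)
  res <- chain_anchors_cpp(anchors$rank_a, anchors$rank_b,
                           params$max_gap, params$min_anchors)
  blocks_from_chains(res, anchors)
}

blocks_from_chains <- function(chains, anchors, block_id_offset = 0L) {
  empty_b <- tibble(block_id = integer(), chrom_a = character(),
                    chrom_b = character(), orientation = character(),
                    n_anchors = integer(), score = integer(),
                    total_gap = double(), p_value = double(),
                    event = character())
  empty_a <- tibble(block_id = integer(), gene_a = character(),
                    gene_b = character(), rank_a = integer(),
                    rank_b = integer())
  if (length(chains) == 0) return(new_blocks(empty_b, empty_a))
  b <- list(); a <- list()
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    idx <- ch$anchor_idx
    id <- block_id_offset + i
    b[[i]] <- tibble(block_id = id,
                     chrom_a = anchors$chrom_a[idx[1]],
                     chrom_b = anchors$chrom_b[idx[1]],
                     orientation = ch$orientation,
                     n_anchors = length(idx), score = ch$score,
                     total_gap = ch$total_gap,
                     p_value = NA_real_, event = NA_character_)
    a[[i]] <- tibble(block_id = id,
                     gene_a = anchors$gene_a[idx],
                     gene_b = anchors$gene_b[idx],
                     rank_a = anchors$rank_a[idx],
                     rank_b = anchors$rank_b[idx])
  }
  new_blocks(bind_rows(b), bind_rows(a))
}

#' Permutation p-value for a collinear block
#'
#' The null redraws the observed number of anchors uniformly on the
#' `len_a` x `len_b` gene-rank grid of the chromosome pair and records the
#' best chain score under the same gap constraint. The add-one estimator
#' `p = (1 + #{null best >= score}) / (1 + n_permutations)` is returned, so p
#' is always in `[1/(n_permutations + 1), 1]`. Deterministic per
#' `params$seed`.
#'
#' @param score Observed chain score (anchor count) of the block.
#' @param n_anchors Total anchors observed on the chromosome pair.
#' @param len_a,len_b Gene counts of the two chromosomes.
#' @param params A [collinearity_params()] object.
#' @return The permutation p-value.
#' @export
block_pvalue <- function(score, n_anchors, len_a, len_b,
                         params = collinearity_params()) {
  if (len_a <= 0 || len_b <= 0) abort("`len_a` and `len_b` must be positive.")
  null <- withr::with_seed(params$seed,
    perm_null_scores_cpp(n_anchors, len_a, len_b, params$max_gap,
                         params$n_permutations))
  (1 + sum(null >= score)) / (1 + params$n_permutations)
}

#' Detect significant collinear blocks across all chromosome pairs
#'
#' Runs [chain_anchors()] on every chromosome pair present in `anchors` and
#' attaches permutation p-values. The null distribution is computed once per
#' (chromosome pair, anchor count) and shared by all blocks of that pair.
#'
#' @param anchors Anchor tibble from [anchors_from_hits()] (whole genome).
#' @param genes Gene position tibble (query side); supplies chromosome
#'   lengths for the permutation grid.
#' @param params A [collinearity_params()] object.
#' @param genes_b Optional subject-side position tibble.
#' @return A `polyret_blocks` object; blocks are ordered by chromosome pair
#'   and extraction order, `block_id` is unique across the genome.
#' @export
find_collinear_blocks <- function(anchors, genes,
                                  params = collinearity_params(),
                                  genes_b = NULL) {
  stopifnot(inherits(params, "polyret_collinearity_params"))
  if (is.null(genes_b)) genes_b <- genes
  chrom_len_a <- table(genes$chromosome)
  chrom_len_b <- table(genes_b$chromosome)
  pairs <- anchors |>
    distinct(.data$chrom_a, .data$chrom_b) |>
    arrange(.data$chrom_a, .data$chrom_b)
  out <- list()
  withr::with_seed(params$seed, {
    for (i in seq_len(nrow(pairs))) {
      ca <- pairs$chrom_a[i]; cb <- pairs$chrom_b[i]
      an <- anchors |> filter(.data$chrom_a == ca, .data$chrom_b == cb)
      chains <- chain_anchors_cpp(an$rank_a, an$rank_b,
                                  params$max_gap, params$min_anchors)
      if (length(chains) == 0) next
      blk <- blocks_from_chains(chains, an)
      null <- perm_null_scores_cpp(nrow(an), as.integer(chrom_len_a[[ca]]),
                                   as.integer(chrom_len_b[[cb]]),
                                   params$max_gap, params$n_permutations)
      blk$blocks$p_value <- vapply(blk$blocks$score, function(s) {
        (1 + sum(null >= s)) / (1 + params$n_permutations)
      }, 0)
      out[[length(out) + 1]] <- blk
    }
  })
  if (length(out) == 0) return(blocks_from_chains(list(), anchors))
  # re-number blocks sequentially across the genome
  offset <- 0L
  blocks_l <- list(); anch_l <- list()
  for (piece in out) {
    nb <- nrow(piece$blocks)
    pb <- piece$blocks; pa <- piece$anchors
    pb$block_id <- pb$block_id + offset
    pa$block_id <- pa$block_id + offset
    blocks_l[[length(blocks_l) + 1]] <- pb
    anch_l[[length(anch_l) + 1]] <- pa
    offset <- offset + nb
  }
  new_blocks(bind_rows(blocks_l), bind_rows(anch_l))
}

#' Genes contained in at least one significant block
#'
#' @param blocks A `polyret_blocks` object with p-values.
#' @param p_max Significance threshold (exclusive). Default 0.05.
#' @return Sorted character vector of gene IDs (union over both block sides;
#'   each gene counted once).
#' @export
colinear_gene_set <- function(blocks, p_max = 0.05) {
  stopifnot(inherits(blocks, "polyret_blocks"))
  sig <- blocks$blocks$block_id[!is.na(blocks$blocks$p_value) &
                                  blocks$blocks$p_value < p_max]
  a <- blocks$anchors[blocks$anchors$block_id %in% sig, ]
  sort(unique(c(a$gene_a, a$gene_b)))
}

#' Label each hit best / second / other per query
#'
#' Non-self hits of each query are ranked by (E-value ascending, bitscore
#' descending, subject ID); rank 1 is `best`, rank 2 `second`, the rest
#' `other` — the labelling used for homology dot plots.
#'
#' @param hits Similarity tibble.
#' @return Tibble `query_id`, `subject_id`, `hit_class`.
#' @export
rank_hit_classes <- function(hits) {
  rank_hits(hits) |>
    group_by(.data$query_id) |>
    mutate(hit_class = dplyr::case_when(
      row_number() == 1 ~ "best",
      row_number() == 2 ~ "second",
      TRUE ~ "other")) |>
    ungroup() |>
    select("query_id", "subject_id", "hit_class")
}
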