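#' Duplicate classifier window parameters
#'
#' @param tandem_max_gap Maximum intervening genes for a tandem call
#'   (default 0, i.e. adjacent ranks).
#' @param proximal_max_gap Maximum intervening genes for a proximal call
#'   (default 10). Must exceed `tandem_max_gap`.
#' @return A list of class `polyret_classifier_params`.
#' @export
classifier_params <- function(tandem_max_gap = 0, proximal_max_gap = 10) {
  tandem_max_gap <- check_count(tandem_max_gap, "tandem_max_gap")
  proximal_max_gap <- check_count(proximal_max_gap, "proximal_max_gap")
  if (tandem_max_gap >= proximal_max_gap)
    abort("`tandem_max_gap` must be smaller than `proximal_max_gap`.")
  structure(list(tandem_max_gap = tandem_max_gap,
                 proximal_max_gap = proximal_max_gap),
            class = "polyret_classifier_params")
}

dup_type_levels <- c("singleton", "dispersed", "proximal", "tandem", "wgd")

#' Classify every gene into one of five duplication types
#'
#' Assigns each gene in `genes` exactly one type under the precedence
#' wgd > tandem > proximal > dispersed > singleton:
#' a gene in any significant collinear block is `wgd`; otherwise `tandem` if
#' it has a same-chromosome homolog within `tandem_max_gap` intervening genes;
#' otherwise `proximal` within `proximal_max_gap`; otherwise `dispersed` if it
#' has any homolog at all; otherwise `singleton`. "Homolog" means a partner in
#' the anchor-filtered hit set (loose E-value bound), not the stricter family
#' thresholds — classification is genome-wide.
#'
#' @param genes Gene position tibble (the classification universe).
#' @param anchors Anchor tibble from [anchors_from_hits()] after
#'   [filter_anchors()].
#' @param blocks A scored `polyret_blocks` object.
#' @param params A [classifier_params()] object.
#' @param p_max Block significance threshold used for the wgd call.
#' @return Tibble `gene_id`, `dup_type` covering every gene in `genes`.
#' @export
classify_duplicates <- function(genes, anchors, blocks,
                                params = classifier_params(), p_max = 0.05) {
  stopifnot(inherits(params, "polyret_classifier_params"))
  universe <- genes$gene_id
  missing <- setdiff(unique(c(anchors$gene_a, anchors$gene_b)), universe)
  if (length(missing) > 0)
    abort(sprintf("Gene(s) referenced by anchors but absent from position table: %s",
                  paste(head(missing, 3), collapse = ", ")))
  wgd_set <- colinear_gene_set(blocks, p_max)

  # intervening genes between the two sides of each same-chromosome pair
  same_chrom <- anchors |>
    filter(.data$chrom_a == .data$chrom_b) |>
    mutate(intervening = abs(.data$rank_a - .data$rank_b) - 1L)
  window_set <- function(gap) {
    w <- same_chrom |> filter(.data$intervening <= gap)
    unique(c(w$gene_a, w$gene_b))
  }
  tandem_set <- window_set(params$tandem_max_gap)
  proximal_set <- window_set(params$proximal_max_gap)
  homolog_set <- unique(c(anchors$gene_a, anchors$gene_b))

  tibble(gene_id = universe) |>
    mutate(dup_type = dplyr::case_when(
      .data$gene_id %in% wgd_set ~ "wgd",
      .data$gene_id %in% tandem_set ~ "tandem",
      .data$gene_id %in% proximal_set ~ "proximal",
      .data$gene_id %in% homolog_set ~ "dispersed",
      TRUE ~ "singleton"))
}

#' Summarise duplication-type counts and percentages
#'
#' @param type_map Tibble `gene_id`, `dup_type` from [classify_duplicates()].
#' @param universe Optional character vector restricting the summary (e.g. a
#'   focal family); defaults to all genes in `type_map`. Must be covered by
#'   `type_map` and non-empty.
#' @return Tibble `dup_type`, `n`, `percent` (percent rounded half-up to two
#'   decimals; one row per type in the order singleton, dispersed, proximal,
#'   tandem, wgd; counts sum to the universe size).
#' @export
summarize_dup_types <- function(type_map, universe = NULL) {
  if (is.null(universe)) universe <- type_map$gene_id
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  missing <- setdiff(universe, type_map$gene_id)
  if (length(missing) > 0)
    abort(sprintf("`type_map` does not cover the universe (e.g. %s).",
                  missing[1]))
  sub <- type_map |> filter(.data$gene_id %in% universe)
  counts <- table(factor(sub$dup_type, levels = dup_type_levels))
  tibble(dup_type = dup_type_levels,
         n = as.integer(counts),
         percent = round_half_up(100 * as.integer(counts) / length(universe), 2))
}
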