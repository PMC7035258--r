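#' Family identification thresholds
#'
#' The strict-inequality thresholds used for focal-family membership:
#' E-value < `evalue_max` and percent identity > `identity_min`.
#'
#' @param evalue_max Maximum E-value (exclusive). Default `1e-10`.
#' @param identity_min Minimum percent identity (exclusive). Default 60.
#' @return A list of class `polyret_family_thresholds`.
#' @export
family_thresholds <- function(evalue_max = 1e-10, identity_min = 60) {
  if (!is.numeric(evalue_max) || evalue_max <= 0)
    abort("`evalue_max` must be > 0.")
  if (!is.numeric(identity_min) || identity_min < 0 || identity_min > 100)
    abort("`identity_min` must be in [0, 100].")
  structure(list(evalue_max = evalue_max, identity_min = identity_min),
            class = "polyret_family_thresholds")
}

# Deterministic hit ranking: best first. Ties on E-value are broken by higher
# bitscore, then lexicographic subject ID.
rank_hits <- function(hits) {
  hits |>
    filter(.data$query_id != .data$subject_id) |>
    arrange(.data$query_id, .data$evalue, dplyr::desc(.data$bitscore),
            .data$subject_id)
}

#' Build a focal-family library from seed genes and cross-species hits
#'
#' For each seed gene with at least one cross-species hit passing the E-value
#' bound, its single top-ranked subject (lowest E-value, ties by highest
#' bitscore then lexicographic subject ID) is added to the library, which then
#' consists of the seed IDs plus these top hits.
#'
#' @param seed_ids Character vector of curated seed gene IDs.
#' @param cross_species_hits Similarity tibble whose queries are seed genes.
#' @param evalue_max E-value bound applied to candidate hits (exclusive).
#' @return A list of class `polyret_family_library` with elements `seed_ids`
#'   and `augmented_ids` (`seed_ids` is always a subset of `augmented_ids`).
#' @export
build_family_library <- function(seed_ids, cross_species_hits,
                                 evalue_max = 1e-10) {
  seed_ids <- sort(unique(seed_ids))
  top <- cross_species_hits |>
    filter(.data$query_id %in% seed_ids, .data$evalue < evalue_max) |>
    rank_hits() |>
    group_by(.data$query_id) |>
    slice_head(n = 1) |>
    ungroup() |>
    pull("subject_id")
  structure(list(seed_ids = seed_ids,
                 augmented_ids = sort(unique(c(seed_ids, top)))),
            class = "polyret_family_library")
}

#' Identify family members in a target genome
#'
#' A subject gene is a family member iff some hit from a library gene passes
#' both strict thresholds (E-value < `evalue_max` and identity >
#' `identity_min`). Self-hits are ignored. Loosening either threshold can
#' only add members, never remove them.
#'
#' @param library A [build_family_library()] object.
#' @param hits Similarity tibble with library genes as queries.
#' @param thresholds A [family_thresholds()] object.
#' @return Sorted character vector of member gene IDs.
#' @export
identify_family_members <- function(library, hits,
                                    thresholds = family_thresholds()) {
  stopifnot(inherits(library, "polyret_family_library"),
            inherits(thresholds, "polyret_family_thresholds"))
  hits |>
    filter(.data$query_id %in% library$augmented_ids,
           .data$query_id != .data$subject_id,
           .data$evalue < thresholds$evalue_max,
           .data$pct_identity > thresholds$identity_min) |>
    pull("subject_id") |>
    unique() |>
    sort()
}

#' Filter similarity hits down to potential collinearity anchors
#'
#' Keeps, per query, at most `top_k` non-self hits with E-value below
#' `evalue_max`, ranked by (E-value ascending, bitscore descending, subject ID
#' lexicographic). The loose E-value bound accommodates the high divergence of
#' duplicates born at ancient polyploidy events.
#'
#' @param hits Similarity tibble.
#' @param evalue_max E-value bound (exclusive). Default `1e-5`.
#' @param top_k Maximum matches retained per query. Default 5.
#' @return Filtered similarity tibble.
#' @export
filter_anchors <- function(hits, evalue_max = 1e-5, top_k = 5) {
  hits |>
    filter(.data$evalue < evalue_max) |>
    rank_hits() |>
    group_by(.data$query_id) |>
    slice_head(n = top_k) |>
    ungroup()
}

#' Reciprocal-best-hit orthologs and co-ortholog expansion
#'
#' `(a, b)` is an RBH ortholog pair iff `b` is `a`'s best A-to-B hit and `a`
#' is `b`'s best B-to-A hit (ties broken as in [filter_anchors()]). The
#' co-ortholog map additionally links each A-gene to every B-gene whose
#' bitscore is within `co_ortholog_ratio` of its best hit's bitscore, giving
#' the many-to-many map needed to project interaction networks onto genomes
#' that kept several duplicate copies.
#'
#' @param hits_ab Similarity tibble, genome A queries vs genome B subjects.
#' @param hits_ba Similarity tibble, genome B queries vs genome A subjects.
#' @param co_ortholog_ratio Bitscore ratio window for co-orthologs.
#' @return A list of class `polyret_orthologs` with tibbles `rbh`
#'   (`gene_a`, `gene_b`) and `co_orthologs` (`gene_a`, `gene_b`; many-to-many,
#'   built from the A-to-B direction).
#' @export
rbh_orthologs <- function(hits_ab, hits_ba, co_ortholog_ratio = 0.9) {
  best_of <- function(hits) {
    rank_hits(hits) |>
      group_by(.data$query_id) |>
      slice_head(n = 1) |>
      ungroup() |>
      select(query_id = "query_id", best_subject = "subject_id")
  }
  empty <- tibble(gene_a = character(), gene_b = character())
  if (nrow(hits_ab) == 0 || nrow(hits_ba) == 0) {
    return(structure(list(rbh = empty, co_orthologs = empty),
                     class = "polyret_orthologs"))
  }
  best_ab <- best_of(hits_ab)
  best_ba <- best_of(hits_ba)
  rbh <- best_ab |>
    inner_join(rename(best_ba, back = "best_subject"),
               by = c(best_subject = "query_id")) |>
    filter(.data$query_id == .data$back) |>
    select(gene_a = "query_id", gene_b = "best_subject") |>
    arrange(.data$gene_a)
  co <- rank_hits(hits_ab) |>
    group_by(.data$query_id) |>
    filter(.data$bitscore >= co_ortholog_ratio * max(.data$bitscore)) |>
    ungroup() |>
    select(gene_a = "query_id", gene_b = "subject_id") |>
    distinct() |>
    arrange(.data$gene_a, .data$gene_b)
  structure(list(rbh = rbh, co_orthologs = co), class = "polyret_orthologs")
}

#' @export
print.polyret_orthologs <- function(x, ...) {
  cat(sprintf("<polyret_orthologs> %d RBH pairs, %d co-ortholog links\n",
              nrow(x$rbh), nrow(x$co_orthologs)))
  invisible(x)
}
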