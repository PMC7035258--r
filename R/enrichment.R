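#' Enrichment test parameters
#'
#' @param alpha Significance level for the increase/decrease call.
#' @param background_mode `"all_genes"` compares the focal class against the
#'   whole-genome row (the layout of the published collinearity tables);
#'   `"non_focal"` uses the complement, avoiding the slight inflation from
#'   comparing overlapping sets.
#' @param yates Apply the Yates continuity correction (default off; counts in
#'   scope are large).
#' @return A list of class `polyret_enrichment_params`.
#' @export
enrichment_params <- function(alpha = 0.05,
                              background_mode = c("all_genes", "non_focal"),
                              yates = FALSE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    abort("`alpha` must be in (0, 1).")
  background_mode <- match.arg(background_mode)
  structure(list(alpha = alpha, background_mode = background_mode,
                 yates = isTRUE(yates)),
            class = "polyret_enrichment_params")
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' @param a,b Focal-class counts: in-category and not-in-category.
#' @param c,d Background counts: in-category and not-in-category.
#' @param yates Apply the Yates continuity correction.
#' @return A list with `chi2` (Pearson statistic, 1 df) and `p` (upper-tail
#'   probability). A zero row or column marginal is an error: the test is
#'   undefined there.
#' @examples
#' chisq_2x2(10, 10, 5, 15)
#' @export
chisq_2x2 <- function(a, b, c, d, yates = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) abort("Counts must be non-negative.")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    abort("Chi-squared test undefined: zero row or column marginal.")
  ht <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(chi2 = unname(ht$statistic), p = ht$p.value)
}

#' Collinearity enrichment of a focal gene class
#'
#' Builds the 2x2 table (focal colinear / focal non-colinear vs background
#' colinear / background non-colinear), runs the chi-squared test and calls
#' the status: `I` (significant increase of the focal colinear proportion
#' over the background), `D` (significant decrease), or `U` (no change).
#'
#' @param focal_set Character vector of focal gene IDs (subset of `universe`,
#'   non-empty).
#' @param colinear_set Character vector of colinear gene IDs.
#' @param universe Character vector of all genes.
#' @param params A [enrichment_params()] object.
#' @return An object of class `polyret_enrichment`; see
#'   [tidy.polyret_enrichment()].
#' @export
enrichment_row <- function(focal_set, colinear_set, universe,
                           params = enrichment_params()) {
  stopifnot(inherits(params, "polyret_enrichment_params"))
  focal_set <- unique(focal_set)
  universe <- unique(universe)
  if (length(focal_set) == 0) abort("`focal_set` must be non-empty.")
  if (length(setdiff(focal_set, universe)) > 0)
    abort("`focal_set` must be a subset of `universe`.")
  colinear_set <- intersect(unique(colinear_set), universe)
  bg <- if (params$background_mode == "all_genes") universe
        else setdiff(universe, focal_set)
  a <- length(intersect(focal_set, colinear_set))
  b <- length(focal_set) - a
  cc <- length(intersect(bg, colinear_set))
  dd <- length(bg) - cc
  ct <- chisq_2x2(a, b, cc, dd, yates = params$yates)
  prop_f <- a / (a + b)
  prop_b <- cc / (cc + dd)
  status <- if (ct$p < params$alpha) {
    if (prop_f > prop_b) "I" else "D"
  } else "U"
  structure(list(a = a, b = b, c = cc, d = dd,
                 focal_percent = round_half_up(100 * prop_f, 2),
                 background_percent = round_half_up(100 * prop_b, 2),
                 chi2 = ct$chi2, p = ct$p, status = status,
                 params = params),
            class = "polyret_enrichment")
}

#' @export
print.polyret_enrichment <- function(x, ...) {
  cat(sprintf("<polyret_enrichment> focal %d/%d (%s%%) vs background %d/%d (%s%%): chi2 = %.4g, p = %.3g, status %s\n",
              x$a, x$a + x$b, format(x$focal_percent),
              x$c, x$c + x$d, format(x$background_percent),
              x$chi2, x$p, x$status))
  invisible(x)
}

#' Tidy an enrichment result
#'
#' @param x A `polyret_enrichment` object.
#' @param ... Unused.
#' @return One-row tibble with the 2x2 counts, the colinear percentages, the
#'   chi-squared statistic, the p-value and the I/U/D status.
#' @export
tidy.polyret_enrichment <- function(x, ...) {
  tibble(focal_colinear = x$a, focal_total = x$a + x$b,
         focal_percent = x$focal_percent,
         background_colinear = x$c, background_total = x$c + x$d,
         background_percent = x$background_percent,
         chi2 = x$chi2, p_value = x$p, status = x$status)
}

#' @export
glance.polyret_enrichment <- function(x, ...) {
  tibble(chi2 = x$chi2, df = 1L, p_value = x$p, status = x$status,
         background_mode = x$params$background_mode,
         alpha = x$params$alpha)
}

#' Per-duplication-type enrichment of a focal class
#'
#' One 2x2 test per duplication type (focal vs background, in-type vs
#' not-in-type). Degenerate tables (a zero marginal, e.g. when every gene is
#' of one type) are skipped with status `U`, `NA` statistics and a warning.
#'
#' @param type_map Tibble `gene_id`, `dup_type` covering `universe`.
#' @param focal_set Character vector of focal gene IDs.
#' @param universe Character vector of all genes.
#' @param params A [enrichment_params()] object.
#' @return Tibble with one row per duplication type: counts, percentages,
#'   `chi2`, `p_value`, `status`.
#' @export
type_enrichment_table <- function(type_map, focal_set, universe,
                                  params = enrichment_params()) {
  stopifnot(inherits(params, "polyret_enrichment_params"))
  missing <- setdiff(universe, type_map$gene_id)
  if (length(missing) > 0)
    abort(sprintf("`type_map` does not cover the universe (e.g. %s).", missing[1]))
  focal_set <- intersect(unique(focal_set), universe)
  bg <- if (params$background_mode == "all_genes") universe
        else setdiff(universe, focal_set)
  rows <- lapply(dup_type_levels, function(tp) {
    in_type <- type_map$gene_id[type_map$dup_type == tp]
    a <- length(intersect(focal_set, in_type))
    b <- length(focal_set) - a
    cc <- length(intersect(bg, in_type))
    dd <- length(bg) - cc
    res <- tryCatch(chisq_2x2(a, b, cc, dd, yates = params$yates),
                    error = function(e) NULL)
    if (is.null(res)) {
      warn(sprintf("Degenerate 2x2 for type '%s'; status set to U.", tp))
      chi2 <- NA_real_; p <- NA_real_; status <- "U"
    } else {
      chi2 <- res$chi2; p <- res$p
      status <- if (p < params$alpha) {
        if (a / (a + b) > cc / (cc + dd)) "I" else "D"
      } else "U"
    }
    tibble(dup_type = tp, focal_n = a, focal_total = a + b,
           focal_percent = round_half_up(100 * a / (a + b), 2),
           background_n = cc, background_total = cc + dd,
           background_percent = round_half_up(100 * cc / (cc + dd), 2),
           chi2 = chi2, p_value = p, status = status)
  })
  bind_rows(rows)
}
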