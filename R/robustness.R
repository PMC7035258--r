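#' Robustness protocol parameters
#'
#' The published protocol removes fixed numbers (5, 10) and fixed percentages
#' (5%, 10%, 20%, 50%) of nodes, each repeated 100 times.
#'
#' @param removal_counts Integer vector of absolute node counts to remove.
#' @param removal_fractions Numeric vector of node fractions in (0, 1).
#' @param reps Repetitions per scheme.
#' @param seed Seed for the random removals.
#' @return A list of class `polyret_robustness_params`.
#' @export
robustness_params <- function(removal_counts = c(5L, 10L),
                              removal_fractions = c(0.05, 0.10, 0.20, 0.50),
                              reps = 100, seed = 1L) {
  if (length(removal_counts) > 0 && any(removal_counts < 1))
    abort("`removal_counts` must be >= 1.")
  if (length(removal_fractions) > 0 &&
      any(removal_fractions <= 0 | removal_fractions >= 1))
    abort("`removal_fractions` must be in (0, 1).")
  reps <- check_count(reps, "reps", min = 1)
  structure(list(removal_counts = as.integer(removal_counts),
                 removal_fractions = removal_fractions,
                 reps = reps, seed = as.integer(seed)),
            class = "polyret_robustness_params")
}

#' Robustness after removing an explicit node set
#'
#' `R = C / (N - Nr)` where `N` is the initial node count, `Nr` the number of
#' removed nodes and `C` the size of the largest linked group (connected
#' component) of what remains.
#'
#' @param net An [igraph::graph].
#' @param removed Character vector of node names to remove (a subset of the
#'   nodes, not all of them).
#' @return The robustness value `R` in (0, 1].
#' @export
robustness_after_removal <- function(net, removed) {
  nodes <- igraph::V(net)$name
  removed <- unique(removed)
  if (length(setdiff(removed, nodes)) > 0)
    abort("`removed` contains nodes not present in the network.")
  if (length(removed) >= length(nodes))
    abort("Cannot remove all nodes of the network.")
  sub <- igraph::delete_vertices(net, removed)
  comp <- igraph::components(sub)
  max(comp$csize) / (length(nodes) - length(removed))
}

resolve_nr <- function(N, nr = NULL, fraction = NULL) {
  if (is.null(nr) == is.null(fraction))
    abort("Supply exactly one of `nr` and `fraction`.")
  if (is.null(nr)) nr <- floor(fraction * N + 0.5)  # round half-up
  min(max(as.integer(nr), 1L), N - 1L)
}

#' Mean robustness under repeated random node removal
#'
#' Draws `reps` uniform samples of `Nr` distinct nodes, removes each and
#' averages `R = C / (N - Nr)`. Fractions resolve to
#' `Nr = round-half-up(f * N)`, clamped to `[1, N - 1]`. Deterministic per
#' seed.
#'
#' @param net An [igraph::graph] with at least 2 nodes.
#' @param nr Number of nodes to remove (give this or `fraction`).
#' @param fraction Fraction of nodes to remove.
#' @param reps Repetitions.
#' @param seed Integer seed.
#' @return Mean `R` over the repetitions.
#' @export
robustness_R <- function(net, nr = NULL, fraction = NULL, reps = 100,
                         seed = 1L) {
  N <- igraph::vcount(net)
  if (N <= 1) abort("Network must have more than one node.")
  nr <- resolve_nr(N, nr, fraction)
  nodes <- igraph::V(net)$name
  withr::with_seed(as.integer(seed), {
    mean(vapply(seq_len(reps), function(i) {
      robustness_after_removal(net, resample(nodes, nr))
    }, 0))
  })
}

#' Robustness profile over the full removal protocol
#'
#' One row per removal scheme in protocol order (absolute counts first, then
#' fractions). Schemes whose `Nr` would reach the node count are reported as
#' not applicable (`NA`).
#'
#' @param net An [igraph::graph].
#' @param params A [robustness_params()] object.
#' @param name Network label for the report.
#' @return Tibble of class `polyret_robustness`: `network`, `N`, `scheme`,
#'   `Nr`, `mean_R`.
#' @export
robustness_profile <- function(net, params = robustness_params(),
                               name = "network") {
  stopifnot(inherits(params, "polyret_robustness_params"))
  N <- igraph::vcount(net)
  schemes <- c(as.character(params$removal_counts),
               sprintf("%g%%", 100 * params$removal_fractions))
  nr_raw <- c(params$removal_counts,
              floor(params$removal_fractions * N + 0.5))
  rows <- lapply(seq_along(schemes), function(i) {
    nr <- nr_raw[i]
    applicable <- N > 1 && nr < N
    if (!applicable) {
      return(tibble(network = name, N = N, scheme = schemes[i],
                    Nr = NA_integer_, mean_R = NA_real_))
    }
    nr <- min(max(as.integer(nr), 1L), N - 1L)
    tibble(network = name, N = N, scheme = schemes[i], Nr = nr,
           mean_R = robustness_R(net, nr = nr, reps = params$reps,
                                 seed = derive_seed(params$seed, i)))
  })
  out <- bind_rows(rows)
  class(out) <- c("polyret_robustness", class(out))
  out
}

#' Format robustness profiles as a wide report table
#'
#' @param profiles A `polyret_robustness` tibble (possibly several networks
#'   row-bound).
#' @return A wide tibble: one row per network, `N`, then one 3-decimal
#'   `mean_R` column per scheme in protocol order (`NA` cells printed as
#'   `"NA"`).
#' @export
format_robustness_profile <- function(profiles) {
  scheme_order <- unique(profiles$scheme)
  profiles |>
    mutate(cell = ifelse(is.na(.data$mean_R), "NA",
                         sprintf("%.3f", .data$mean_R)),
           scheme = factor(.data$scheme, levels = scheme_order)) |>
    select("network", "N", "scheme", "cell") |>
    tidyr::pivot_wider(names_from = "scheme", values_from = "cell")
}
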