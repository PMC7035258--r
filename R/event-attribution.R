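#' Ks windows for paleopolyploidy event attribution
#'
#' Each window is a half-open Ks interval `[ks_min, ks_max)` carrying an event
#' name. Windows must not overlap. A block is attributed to the window that
#' contains the median Ks of its anchor pairs.
#'
#' @param name Character vector of event names.
#' @param ks_min,ks_max Numeric vectors of window bounds (`ks_min` inclusive,
#'   `ks_max` exclusive).
#' @return A tibble of class `polyret_event_windows`, sorted by `ks_min`.
#' @export
event_windows <- function(name, ks_min, ks_max) {
  if (length(name) != length(ks_min) || length(name) != length(ks_max))
    abort("`name`, `ks_min` and `ks_max` must have equal lengths.")
  if (any(ks_min >= ks_max)) abort("Each window needs `ks_min < ks_max`.")
  w <- tibble(name = as.character(name), ks_min = as.numeric(ks_min),
              ks_max = as.numeric(ks_max)) |>
    arrange(.data$ks_min)
  if (nrow(w) > 1 && any(w$ks_max[-nrow(w)] > w$ks_min[-1]))
    abort("Ks windows must not overlap.")
  class(w) <- c("polyret_event_windows", class(w))
  w
}

#' Default Ks windows matching [default_events()]
#'
#' alpha `[0, 0.5)`, beta `[0.5, 1.2)`, gamma `[1.2, 2.5)` — midpoints between
#' the default event ages 0.2, 0.8 and 1.6.
#'
#' @return A `polyret_event_windows` tibble.
#' @export
default_event_windows <- function() {
  event_windows(c("alpha", "beta", "gamma"),
                c(0, 0.5, 1.2), c(0.5, 1.2, 2.5))
}

window_of <- function(ks, windows) {
  out <- rep(NA_character_, length(ks))
  for (i in seq_len(nrow(windows))) {
    hit <- !is.na(ks) & ks >= windows$ks_min[i] & ks < windows$ks_max[i]
    out[hit] <- windows$name[i]
  }
  out
}

#' Attribute collinear blocks to polyploidy events by median anchor Ks
#'
#' The label of a block is the Ks window containing the median Ks of its
#' anchor pairs; a median falling outside every window leaves the block
#' unassigned (`NA`). Every anchor pair must have a Ks value.
#'
#' @param blocks A `polyret_blocks` object.
#' @param pair_ks Tibble `gene_a`, `gene_b`, `ks` (unordered pairs).
#' @param windows A [event_windows()] tibble.
#' @return The `polyret_blocks` object with `event` filled in.
#' @export
assign_block_events <- function(blocks, pair_ks,
                                windows = default_event_windows()) {
  stopifnot(inherits(blocks, "polyret_blocks"),
            inherits(windows, "polyret_event_windows"))
  if (nrow(blocks$anchors) == 0) return(blocks)
  ks_lookup <- bind_rows(
    pair_ks |> select("gene_a", "gene_b", "ks"),
    pair_ks |> select(gene_a = "gene_b", gene_b = "gene_a", "ks")) |>
    distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE)
  an <- blocks$anchors |>
    left_join(ks_lookup, by = c("gene_a", "gene_b"))
  if (anyNA(an$ks)) {
    i <- which(is.na(an$ks))[1]
    abort(sprintf("No Ks value for anchor pair %s / %s.",
                  an$gene_a[i], an$gene_b[i]))
  }
  med <- an |>
    group_by(.data$block_id) |>
    summarise(median_ks = median(.data$ks), .groups = "drop") |>
    mutate(event = window_of(.data$median_ks, windows))
  blocks$blocks <- blocks$blocks |>
    select(-"event") |>
    left_join(med |> select("block_id", "event"), by = "block_id")
  blocks
}

#' Per-gene event participation with the recounting rule
#'
#' A gene participates in every event whose labelled significant blocks
#' contain it; genes duplicated again in a younger event are therefore
#' recounted in both the older and the younger event's totals. Also returns
#' the Venn-style partition of genes by their exact event set.
#'
#' @param blocks A labelled, scored `polyret_blocks` object (see
#'   [assign_block_events()]).
#' @param universe Optional character vector (e.g. a focal family); when
#'   given, participation is restricted to it and percentages are reported
#'   over its size.
#' @param p_max Block significance threshold.
#' @return A list of class `polyret_events` with tibbles
#'   \describe{
#'     \item{gene_events}{`gene_id`, `event` (one row per gene-event link)}
#'     \item{event_counts}{`event`, `n` and, when `universe` is given,
#'       `percent` (half-up, 2 decimals)}
#'     \item{venn}{`event_set` (comma-joined, sorted), `n` — a partition of
#'       the event-assigned genes}
#'   }
#' @export
gene_event_participation <- function(blocks, universe = NULL, p_max = 0.05) {
  stopifnot(inherits(blocks, "polyret_blocks"))
  sig <- blocks$blocks |>
    filter(!is.na(.data$p_value), .data$p_value < p_max,
           !is.na(.data$event))
  gene_events <- blocks$anchors |>
    semi_join(sig, by = "block_id") |>
    inner_join(sig |> select("block_id", "event"), by = "block_id")
  gene_events <- bind_rows(
    gene_events |> select(gene_id = "gene_a", "event"),
    gene_events |> select(gene_id = "gene_b", "event")) |>
    distinct() |>
    arrange(.data$gene_id, .data$event)
  if (!is.null(universe))
    gene_events <- gene_events |> filter(.data$gene_id %in% universe)
  event_counts <- gene_events |>
    count(.data$event, name = "n") |>
    arrange(.data$event)
  if (!is.null(universe)) {
    event_counts <- event_counts |>
      mutate(percent = round_half_up(100 * .data$n / length(universe), 2))
  }
  venn <- gene_events |>
    group_by(.data$gene_id) |>
    summarise(event_set = paste(sort(unique(.data$event)), collapse = ","),
              .groups = "drop") |>
    count(.data$event_set, name = "n") |>
    arrange(.data$event_set)
  structure(list(gene_events = gene_events, event_counts = event_counts,
                 venn = venn),
            class = "polyret_events")
}

#' @export
print.polyret_events <- function(x, ...) {
  cat("<polyret_events>\n")
  print(x$event_counts)
  invisible(x)
}

#' Suggest Ks windows from the valleys of a Ks distribution
#'
#' Fits a kernel density to the Ks values, finds local maxima (modes) and the
#' minima (valleys) between them, and proposes one half-open window per mode
#' bounded by the neighbouring valleys. A diagnostic helper only: it is never
#' applied automatically, because silent misattribution is worse than asking
#' the analyst to confirm window bounds.
#'
#' @param ks Numeric vector of Ks values.
#' @param names Optional event names, youngest window first; defaults to
#'   `"event1"`, `"event2"`, ...
#' @param bw Kernel bandwidth passed to [stats::density()].
#' @return A [event_windows()] tibble.
#' @export
suggest_ks_windows <- function(ks, names = NULL, bw = "SJ") {
  ks <- ks[!is.na(ks)]
  if (length(ks) < 10) abort("Need at least 10 Ks values to suggest windows.")
  d <- density(ks, bw = bw, from = 0)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  if (length(is_max) == 0) is_max <- which.max(y)
  cuts <- numeric(0)
  if (length(is_max) > 1) {
    for (i in seq_len(length(is_max) - 1)) {
      seg <- is_max[i]:is_max[i + 1]
      cuts <- c(cuts, d$x[seg[which.min(y[seg])]])
    }
  }
  lo <- c(0, cuts)
  hi <- c(cuts, max(ks) * 1.05)
  if (is.null(names)) names <- sprintf("event%d", seq_along(lo))
  event_windows(names, lo, hi)
}
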