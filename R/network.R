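#' Project a reference interaction network through an ortholog map
#'
#' The "equivalent replacement" rule: for every reference edge `(a, b)`, an
#' edge `(x, y)` exists in the projected network iff `x` is an ortholog of
#' `a`, `y` an ortholog of `b`, and `x != y`. With a many-to-many
#' (co-ortholog) map the projection expands combinatorially, which is how
#' duplicate-rich genomes grow larger networks. Edges are undirected,
#' deduplicated, with no self-loops; nodes are the genes incident to at least
#' one edge.
#'
#' @param reference_edges Tibble `from`, `to` over reference gene IDs.
#' @param ortholog_map Tibble `gene_a` (reference ID), `gene_b` (target ID);
#'   many-to-many allowed (e.g. `rbh_orthologs()$co_orthologs`).
#' @param target_universe Optional character vector; map targets outside it
#'   are dropped.
#' @param annotations Optional tibble `gene_id`, plus any of `focal`
#'   (logical) and `event_set` (comma-joined string), copied onto the nodes.
#' @return An undirected simple [igraph::graph] with vertex attributes from
#'   `annotations` where supplied.
#' @export
project_network <- function(reference_edges, ortholog_map,
                            target_universe = NULL, annotations = NULL) {
  map <- ortholog_map |> distinct(.data$gene_a, .data$gene_b)
  if (!is.null(target_universe))
    map <- map |> filter(.data$gene_b %in% target_universe)
  edges <- reference_edges |>
    select("from", "to") |>
    inner_join(map, by = c(from = "gene_a"), relationship = "many-to-many") |>
    rename(x = "gene_b") |>
    inner_join(map, by = c(to = "gene_a"), relationship = "many-to-many") |>
    rename(y = "gene_b") |>
    filter(.data$x != .data$y) |>
    mutate(lo = pmin(.data$x, .data$y), hi = pmax(.data$x, .data$y)) |>
    distinct(.data$lo, .data$hi)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(annotations) && igraph::vcount(g) > 0) {
    idx <- match(igraph::V(g)$name, annotations$gene_id)
    if ("focal" %in% names(annotations))
      g <- igraph::set_vertex_attr(g, "focal", value = annotations$focal[idx])
    if ("event_set" %in% names(annotations))
      g <- igraph::set_vertex_attr(g, "event_set",
                                   value = annotations$event_set[idx])
  }
  g
}

#' Basic statistics of an interaction network
#'
#' @param net An [igraph::graph].
#' @return One-row tibble: `n_nodes`, `n_edges`, `max_degree`,
#'   `max_degree_node`, `edge_node_ratio` (edges / nodes, 0 for an empty
#'   network, reported to 2 decimals).
#' @export
network_stats <- function(net) {
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  if (n == 0) {
    return(tibble(n_nodes = 0L, n_edges = 0L, max_degree = 0L,
                  max_degree_node = NA_character_, edge_node_ratio = 0))
  }
  deg <- igraph::degree(net)
  i <- order(-deg, names(deg))[1]
  tibble(n_nodes = n, n_edges = e,
         max_degree = as.integer(deg[i]),
         max_degree_node = names(deg)[i],
         edge_node_ratio = round_half_up(e / n, 2))
}

#' Partition network nodes by their exact polyploidy-event set
#'
#' Counts, for every region of the event Venn diagram, the nodes whose
#' annotated event set is exactly that combination. The counts over all
#' regions partition the event-annotated nodes.
#'
#' @param net An [igraph::graph] whose vertices carry an `event_set`
#'   attribute (comma-joined, as written by [project_network()]), or a tibble
#'   `gene_id`, `event` as in `gene_event_participation()$gene_events`.
#' @return Tibble `event_set`, `n`, sorted by `event_set`.
#' @export
event_specific_nodes <- function(net) {
  if (inherits(net, "igraph")) {
    es <- igraph::vertex_attr(net, "event_set")
    if (is.null(es)) abort("Network vertices carry no `event_set` attribute.")
    sets <- es[!is.na(es) & nzchar(es)]
    sets <- vapply(strsplit(sets, ",", fixed = TRUE),
                   function(x) paste(sort(x), collapse = ","), "")
  } else {
    sets <- net |>
      group_by(.data$gene_id) |>
      summarise(s = paste(sort(unique(.data$event)), collapse = ","),
                .groups = "drop") |>
      pull("s")
  }
  if (length(sets) == 0) return(tibble(event_set = character(), n = integer()))
  tb <- table(sets)
  tibble(event_set = names(tb), n = as.integer(tb)) |>
    arrange(.data$event_set)
}
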