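#' Assemble a pipeline configuration
#'
#' Exactly one of `simulation` and `inputs` must be supplied: a run either
#' simulates a genome with known truth or ingests real tables.
#'
#' @param simulation List with elements `params` ([sim_params()]) and
#'   optionally `events` (list of [event_spec()]; defaults to
#'   [default_events()]) and `mean_degree` for the synthetic reference
#'   network.
#' @param inputs List of file paths: `gene_positions`, `similarity`,
#'   `seed_family`, and optionally `reference_network`, `ortholog_map`
#'   (two-column TSVs) and `pair_ks` (three-column TSV gene_a, gene_b, ks).
#' @param collinearity A [collinearity_params()] object.
#' @param family A [family_thresholds()] object.
#' @param classifier A [classifier_params()] object.
#' @param enrichment A [enrichment_params()] object.
#' @param robustness A [robustness_params()] object.
#' @param windows A [event_windows()] tibble.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Optional directory for intermediate and report files.
#' @return A list of class `polyret_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            collinearity = collinearity_params(),
                            family = family_thresholds(),
                            classifier = classifier_params(),
                            enrichment = enrichment_params(),
                            robustness = robustness_params(),
                            windows = default_event_windows(),
                            seed = 1L, out_dir = NULL) {
  if (is.null(simulation) == is.null(inputs))
    abort("Supply exactly one of `simulation` and `inputs`.")
  if (!is.null(inputs)) {
    required <- c("gene_positions", "similarity", "seed_family")
    miss <- setdiff(required, names(inputs))
    if (length(miss) > 0)
      abort(sprintf("Missing input path(s): %s", paste(miss, collapse = ", ")))
    for (p in unlist(inputs)) {
      if (!file.exists(p)) abort(sprintf("Input file does not exist: %s", p))
    }
  }
  if (!is.null(simulation)) {
    if (is.null(simulation$params) ||
        !inherits(simulation$params, "polyret_sim_params"))
      abort("`simulation$params` must be a sim_params() object.")
    simulation$events <- simulation$events %||% default_events()
    simulation$mean_degree <- simulation$mean_degree %||% 4
  }
  structure(list(simulation = simulation, inputs = inputs,
                 collinearity = collinearity, family = family,
                 classifier = classifier, enrichment = enrichment,
                 robustness = robustness, windows = windows,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "polyret_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level sections mirror [pipeline_config()] arguments;
#' parameter sections are flat `key: value` maps, `simulation/events` a list
#' of (name, multiplicity, age_ks, retention_background, retention_focal)
#' maps, `windows` a list of (name, ks_min, ks_max) maps.
#'
#' @param path YAML file path.
#' @return A `polyret_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simulation <- NULL
  if (!is.null(y$simulation)) {
    sp <- y$simulation$params %||% list()
    simulation <- list(
      params = do.call(sim_params, sp),
      events = if (!is.null(y$simulation$events)) {
        lapply(y$simulation$events, function(e) do.call(event_spec, e))
      },
      mean_degree = y$simulation$mean_degree)
  }
  windows <- if (!is.null(y$windows)) {
    event_windows(vapply(y$windows, `[[`, "", "name"),
                  vapply(y$windows, function(w) as.numeric(w$ks_min), 0),
                  vapply(y$windows, function(w) as.numeric(w$ks_max), 0))
  } else default_event_windows()
  build <- function(ctor, section) {
    if (is.null(y[[section]])) return(ctor())
    do.call(ctor, y[[section]])
  }
  pipeline_config(
    simulation = simulation, inputs = y$inputs,
    collinearity = build(collinearity_params, "collinearity"),
    family = build(family_thresholds, "family"),
    classifier = build(classifier_params, "classifier"),
    enrichment = build(enrichment_params, "enrichment"),
    robustness = build(robustness_params, "robustness"),
    windows = windows,
    seed = y$seed %||% 1L, out_dir = y$out_dir)
}

#' Run the full retention-analysis pipeline
#'
#' Stages, in order: simulate or ingest; focal-family identification; anchor
#' filtering; collinear block detection with permutation significance;
#' five-way duplicate classification; Ks-window event attribution with the
#' recounting rule; chi-squared enrichment (collinearity status and per
#' duplication type); ortholog projection of the reference interaction
#' network; robustness profiling. Ka/Ks screening runs separately on codon
#' alignments via [kaks_batch()]. Every stage draws its randomness from a
#' seed derived from the master seed, so identical configurations yield
#' identical reports; when `out_dir` is set, every intermediate table is
#' written there.
#'
#' @param config A `polyret_config` object.
#' @return A list of class `polyret_report`: `genes`, `focal_set`,
#'   `colinear_set`, `blocks`, `dup_types`, `dup_summary`,
#'   `focal_dup_summary`, `events`, `enrichment` (tidied row),
#'   `type_enrichment`, `network` (igraph or NULL), `network_stats`,
#'   `robustness`, `truth` (simulation mode only), `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "polyret_config"))
  seed <- config$seed
  sim_mode <- !is.null(config$simulation)

  # -- stage 1: simulate or ingest ---------------------------------------
  truth <- NULL; pair_ks <- NULL; reference_edges <- NULL; orth_map <- NULL
  if (sim_mode) {
    sp <- config$simulation$params
    sp$seed <- derive_seed(seed, 1)
    sim <- simulate_genome(sp, config$simulation$events)
    genes <- sim$genes
    truth <- sim$truth
    hits <- emit_similarity_table(sim, seed = derive_seed(seed, 2))
    pair_ks <- sim$pairs |> select("gene_a", "gene_b", "ks")
    reference_edges <- emit_reference_network(
      truth, config$simulation$mean_degree, seed = derive_seed(seed, 3))
    orth_map <- truth |>
      filter(.data$class_tag == "focal") |>
      select(gene_a = "anc_id", gene_b = "gene_id")
    seed_ids <- truth$gene_id[truth$class_tag == "focal" &
                                truth$origin_event == "ancestral"]
  } else {
    genes <- read_gene_positions(config$inputs$gene_positions)
    hits <- read_similarity_table(config$inputs$similarity)
    seed_ids <- read_gene_list(config$inputs$seed_family)
    if (!is.null(config$inputs$reference_network))
      reference_edges <- read_edge_list(config$inputs$reference_network)
    if (!is.null(config$inputs$ortholog_map)) {
      om <- read_edge_list(config$inputs$ortholog_map)
      orth_map <- om |> select(gene_a = "from", gene_b = "to")
    }
    if (!is.null(config$inputs$pair_ks)) {
      pk <- read.table(config$inputs$pair_ks, sep = "\t",
                       col.names = c("gene_a", "gene_b", "ks"))
      pair_ks <- as_tibble(pk)
    }
  }

  # -- stage 2: focal family ---------------------------------------------
  library <- build_family_library(seed_ids, hits,
                                  evalue_max = config$family$evalue_max)
  members <- identify_family_members(library, hits, config$family)
  focal_set <- sort(unique(c(
    intersect(library$augmented_ids, genes$gene_id), members)))

  # -- stage 3-4: anchors and blocks -------------------------------------
  anchor_hits <- filter_anchors(hits)
  anchors <- anchors_from_hits(anchor_hits, genes)
  cparams <- config$collinearity
  cparams$seed <- derive_seed(seed, 4)
  blocks <- find_collinear_blocks(anchors, genes, cparams)
  colinear <- colinear_gene_set(blocks, cparams$p_max)

  # -- stage 5: duplicate classification ---------------------------------
  # tandem-adjacent pairs are excluded from chaining but are exactly what
  # the tandem/proximal windows need, so rebuild anchors without the filter
  class_anchors <- anchors_from_hits(anchor_hits, genes,
                                     exclude_tandem_adjacent = FALSE)
  dup_types <- classify_duplicates(genes, class_anchors, blocks,
                                   config$classifier, cparams$p_max)
  dup_summary <- summarize_dup_types(dup_types)
  focal_dup_summary <- if (length(focal_set) > 0)
    summarize_dup_types(dup_types, focal_set) else NULL

  # -- stage 6: event attribution ----------------------------------------
  events <- NULL
  if (!is.null(pair_ks)) {
    blocks <- assign_block_events(blocks, pair_ks, config$windows)
    events <- gene_event_participation(blocks, universe = focal_set,
                                       p_max = cparams$p_max)
  }

  # -- stage 7: enrichment -----------------------------------------------
  enr <- enrichment_row(focal_set, colinear, genes$gene_id,
                        config$enrichment)
  type_enr <- type_enrichment_table(dup_types, focal_set, genes$gene_id,
                                    config$enrichment)

  # -- stage 8-9: network projection and robustness ----------------------
  network <- NULL; net_stats <- NULL; robustness <- NULL
  if (!is.null(reference_edges) && !is.null(orth_map) &&
      nrow(reference_edges) > 0) {
    ann <- tibble(gene_id = genes$gene_id,
                  focal = genes$gene_id %in% focal_set)
    if (!is.null(events)) {
      es <- events$gene_events |>
        group_by(.data$gene_id) |>
        summarise(event_set = paste(sort(unique(.data$event)),
                                    collapse = ","), .groups = "drop")
      ann <- ann |> left_join(es, by = "gene_id")
    }
    network <- project_network(reference_edges, orth_map,
                               target_universe = genes$gene_id,
                               annotations = ann)
    net_stats <- network_stats(network)
    if (igraph::vcount(network) > 1) {
      rparams <- config$robustness
      rparams$seed <- derive_seed(seed, 5)
      robustness <- robustness_profile(network, rparams, name = "projected")
    }
  }

  report <- structure(list(
    genes = genes, focal_set = focal_set, colinear_set = colinear,
    blocks = blocks, dup_types = dup_types, dup_summary = dup_summary,
    focal_dup_summary = focal_dup_summary, events = events,
    enrichment = tidy(enr), type_enrichment = type_enr,
    network = network, network_stats = net_stats, robustness = robustness,
    truth = truth,
    provenance = list(seed = seed, config_hash = rlang::hash(config),
                      package_version = as.character(utils::packageVersion("polyret")))),
    class = "polyret_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(as.data.frame(df), file.path(out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_gene_positions(report$genes, file.path(out_dir, "gene_positions.tsv"))
  write_gene_list(report$focal_set, file.path(out_dir, "focal_family.txt"))
  write_block_report(report$blocks, file.path(out_dir, "blocks.txt"))
  tsv(report$dup_types, "dup_types.tsv")
  tsv(report$dup_summary, "dup_summary.tsv")
  tsv(report$enrichment, "enrichment.tsv")
  tsv(report$type_enrichment, "type_enrichment.tsv")
  if (!is.null(report$events)) {
    tsv(report$events$event_counts, "event_counts.tsv")
    tsv(report$events$venn, "event_venn.tsv")
  }
  if (!is.null(report$network_stats)) tsv(report$network_stats, "network_stats.tsv")
  if (!is.null(report$network))
    write_edge_list(setNames(as_tibble(igraph::as_edgelist(report$network)),
                             c("from", "to")),
                    file.path(out_dir, "network_edges.tsv"))
  if (!is.null(report$robustness))
    tsv(format_robustness_profile(report$robustness), "robustness.tsv")
  yaml::write_yaml(report$provenance, file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}

#' @export
print.polyret_report <- function(x, ...) {
  cat("<polyret_report>\n")
  cat(sprintf("  genes: %d | focal family: %d | colinear: %d\n",
              nrow(x$genes), length(x$focal_set), length(x$colinear_set)))
  cat(sprintf("  blocks: %d (%d significant)\n", nrow(x$blocks$blocks),
              sum(!is.na(x$blocks$blocks$p_value) &
                    x$blocks$blocks$p_value < 0.05)))
  cat(sprintf("  enrichment: chi2 = %.4g, p = %.3g, status %s\n",
              x$enrichment$chi2, x$enrichment$p_value, x$enrichment$status))
  if (!is.null(x$network_stats))
    cat(sprintf("  network: %d nodes, %d edges (ratio %.2f)\n",
                x$network_stats$n_nodes, x$network_stats$n_edges,
                x$network_stats$edge_node_ratio))
  invisible(x)
}
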