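#' Specify a polyploidization event
#'
#' An event multiplies every chromosome of the genome: multiplicity 2 is a
#' whole-genome duplication (tetraploidy, WGD), multiplicity 3 a triplication
#' (hexaploidy, WGT). Duplicate pairs born at the event carry a synonymous
#' distance (Ks) centred on `age_ks`, so older events produce more diverged
#' pairs. Surviving duplicate copies are retained with class-dependent
#' probabilities, which is the mechanism that generates retention bias of a
#' focal gene class.
#'
#' @param name Event label (e.g. `"gamma"`, `"beta"`, `"alpha"`, `"theta"`).
#' @param multiplicity 2 (WGD) or 3 (WGT).
#' @param age_ks Mean Ks of duplicate pairs born at this event.
#' @param retention_background Probability in `[0, 1]` that a duplicate copy
#'   of a background gene survives.
#' @param retention_focal Same for focal-class genes.
#' @return A list of class `polyret_event`.
#' @export
event_spec <- function(name, multiplicity, age_ks,
                       retention_background, retention_focal) {
  if (!multiplicity %in% c(2L, 3L))
    abort("`multiplicity` must be 2 (WGD) or 3 (WGT).")
  if (!is.numeric(age_ks) || age_ks < 0)
    abort("`age_ks` must be a non-negative number.")
  check_prob(retention_background, "retention_background")
  check_prob(retention_focal, "retention_focal")
  structure(list(name = as.character(name),
                 multiplicity = as.integer(multiplicity),
                 age_ks = as.numeric(age_ks),
                 retention_background = retention_background,
                 retention_focal = retention_focal),
            class = "polyret_event")
}

#' Default recursive polyploidy history
#'
#' Three events in temporal order: an old hexaploidy ("gamma", Ks 1.6), then
#' two tetraploidies ("beta", Ks 0.8; "alpha", Ks 0.2), echoing the recursive
#' history of Brassicaceae-like genomes. Retention defaults give the focal
#' class a 0.8 vs 0.4 survival advantage, the biased-retention regime the
#' simulator is meant to emulate.
#'
#' @param retention_background,retention_focal Retention probabilities applied
#'   to every event.
#' @return List of [event_spec()] objects ordered oldest to youngest.
#' @export
default_events <- function(retention_background = 0.4, retention_focal = 0.8) {
  list(
    event_spec("gamma", 3L, 1.6, retention_background, retention_focal),
    event_spec("beta",  2L, 0.8, retention_background, retention_focal),
    event_spec("alpha", 2L, 0.2, retention_background, retention_focal))
}

#' Simulation parameters
#'
#' @param n_genes Ancestral gene count.
#' @param n_chroms Ancestral chromosome count.
#' @param focal_fraction Fraction of ancestral genes tagged focal.
#' @param tandem_rate,proximal_rate,dispersed_rate Per-gene probabilities of
#'   the single-gene duplication modes (applied once, after all polyploidy
#'   events). Their sum must not exceed 1.
#' @param inversion_count Number of random segment inversions applied after
#'   all duplications (collinearity erosion).
#' @param ks_noise_sd Standard deviation of per-pair Ks noise.
#' @param sgd_ks Mean Ks of single-gene duplicate pairs (tandem, proximal,
#'   dispersed); these are young copies, so the default is small.
#' @param seed Integer seed fixing all randomness of the simulation.
#' @return A list of class `polyret_sim_params`.
#' @export
sim_params <- function(n_genes = 2000, n_chroms = 5, focal_fraction = 0.3,
                       tandem_rate = 0.02, proximal_rate = 0.01,
                       dispersed_rate = 0.03, inversion_count = 0,
                       ks_noise_sd = 0.05, sgd_ks = 0.1, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  n_chroms <- check_count(n_chroms, "n_chroms", min = 1)
  if (n_genes < n_chroms) abort("`n_genes` must be >= `n_chroms`.")
  check_prob(focal_fraction, "focal_fraction")
  check_prob(tandem_rate, "tandem_rate")
  check_prob(proximal_rate, "proximal_rate")
  check_prob(dispersed_rate, "dispersed_rate")
  if (tandem_rate + proximal_rate + dispersed_rate > 1)
    abort("Single-gene duplication rates must sum to at most 1.")
  inversion_count <- check_count(inversion_count, "inversion_count")
  if (!is.numeric(ks_noise_sd) || ks_noise_sd < 0)
    abort("`ks_noise_sd` must be non-negative.")
  structure(list(n_genes = n_genes, n_chroms = n_chroms,
                 focal_fraction = focal_fraction, tandem_rate = tandem_rate,
                 proximal_rate = proximal_rate, dispersed_rate = dispersed_rate,
                 inversion_count = inversion_count, ks_noise_sd = ks_noise_sd,
                 sgd_ks = sgd_ks, seed = as.integer(seed)),
            class = "polyret_sim_params")
}

validate_events <- function(events) {
  if (length(events) == 0) return(invisible(events))
  ok <- vapply(events, inherits, TRUE, "polyret_event")
  if (!all(ok)) abort("`events` must be a list of event_spec() objects.")
  ages <- vapply(events, `[[`, 0, "age_ks")
  if (length(ages) > 1 && any(diff(ages) >= 0))
    abort("Event ages must be strictly decreasing from oldest to youngest.")
  invisible(events)
}

#' Simulate a polyploid genome with known duplication history
#'
#' Applies the polyploidy events oldest-to-youngest to an ancestral genome.
#' Each event appends whole chromosome copies (multiplicity - 1 new copies per
#' chromosome), preserving within-copy gene order exactly as paleo-blocks do;
#' each new duplicate copy then survives with the event's class-dependent
#' retention probability (the pre-event copy always survives, so no gene goes
#' extinct). Single-gene duplications (tandem at the adjacent rank, proximal
#' at 2-10 intervening genes, dispersed on another chromosome) are applied
#' once after all events, and `inversion_count` random segment inversions
#' (length 2-25 genes) erode collinearity last. Every surviving homologous
#' pair carries a latent Ks drawn from Normal(age of its divergence event,
#' `ks_noise_sd`), truncated at 0.
#'
#' @param params A [sim_params()] object.
#' @param events List of [event_spec()] objects ordered oldest to youngest
#'   (strictly decreasing `age_ks`).
#' @return A list of class `polyret_sim` with elements
#'   \describe{
#'     \item{genes}{tibble: `gene_id`, `chromosome`, `start`, `end`, `strand`,
#'       `rank`, `class_tag`}
#'     \item{truth}{tibble: `gene_id`, `anc_id`, `class_tag`,
#'       `dup_type_truth`, `origin_event`}
#'     \item{pairs}{tibble of surviving homologous pairs: `gene_a`, `gene_b`,
#'       `event`, `mode`, `ks`}
#'   }
#' @examples
#' sim <- simulate_genome(sim_params(n_genes = 50, n_chroms = 2, seed = 7),
#'                        default_events())
#' head(sim$truth)
#' @export
simulate_genome <- function(params, events = default_events()) {
  stopifnot(inherits(params, "polyret_sim_params"))
  validate_events(events)
  withr::with_seed(params$seed, simulate_genome_impl(params, events))
}

simulate_genome_impl <- function(params, events) {
  n <- params$n_genes
  n_events <- length(events)

  # Per-copy state, grown as events fire. `branch` holds one integer per
  # processed event: 0 = stayed on the pre-event copy, k >= 1 = k-th new copy.
  # Two copies of the same ancestral gene diverged at the first event where
  # their branch vectors differ.
  anc <- seq_len(n)
  focal_anc <- runif(n) < params$focal_fraction
  copy_anc <- anc
  copy_origin <- rep("ancestral", n)
  copy_branch <- matrix(integer(0), nrow = n, ncol = 0)

  # Chromosomes: list of integer vectors of copy indices in gene order.
  sizes <- diff(floor(seq(0, n, length.out = params$n_chroms + 1)))
  chrom_names <- sprintf("chr%02d", seq_len(params$n_chroms))
  chroms <- split(seq_len(n), rep(seq_len(params$n_chroms), times = sizes))
  names(chroms) <- chrom_names

  for (ei in seq_along(events)) {
    ev <- events[[ei]]
    copy_branch <- cbind(copy_branch, rep(0L, nrow(copy_branch)))
    old_chroms <- chroms
    for (k in seq_len(ev$multiplicity - 1L)) {
      for (cn in names(old_chroms)) {
        src <- old_chroms[[cn]]
        if (length(src) == 0) next
        keep_p <- ifelse(focal_anc[copy_anc[src]],
                         ev$retention_focal, ev$retention_background)
        survives <- runif(length(src)) < keep_p
        if (!any(survives)) next
        src <- src[survives]
        new_idx <- nrow(copy_branch) + seq_along(src)
        copy_anc <- c(copy_anc, copy_anc[src])
        copy_origin <- c(copy_origin, rep(ev$name, length(src)))
        nb <- copy_branch[src, , drop = FALSE]
        nb[, ei] <- k
        copy_branch <- rbind(copy_branch, nb)
        chroms[[sprintf("%s_%s%d", cn, ev$name, k)]] <- new_idx
      }
    }
  }

  # Event-born homologous pairs: all surviving copy pairs per ancestral gene,
  # dated by the first event at which their lineages split.
  event_names <- vapply(events, `[[`, "", "name")
  event_ages <- vapply(events, `[[`, 0, "age_ks")
  pair_a <- integer(0); pair_b <- integer(0); pair_ev <- integer(0)
  by_anc <- split(seq_along(copy_anc), copy_anc)
  for (g in by_anc) {
    if (length(g) < 2) next
    cmb <- utils::combn(g, 2)
    for (j in seq_len(ncol(cmb))) {
      u <- cmb[1, j]; v <- cmb[2, j]
      d <- which(copy_branch[u, ] != copy_branch[v, ])[1]
      pair_a <- c(pair_a, u); pair_b <- c(pair_b, v); pair_ev <- c(pair_ev, d)
    }
  }

  # Single-gene duplications on a snapshot of the post-event genome.
  sgd_src <- integer(0); sgd_new <- integer(0); sgd_mode <- character(0)
  n_copies <- length(copy_anc)
  t_r <- params$tandem_rate; p_r <- params$proximal_rate
  d_r <- params$dispersed_rate
  if (t_r + p_r + d_r > 0) {
    u <- runif(n_copies)
    mode <- ifelse(u < t_r, "tandem",
                   ifelse(u < t_r + p_r, "proximal",
                          ifelse(u < t_r + p_r + d_r, "dispersed", "none")))
    for (src in which(mode != "none")) {
      cn <- which(vapply(chroms, function(v) src %in% v, TRUE))[1]
      pos <- match(src, chroms[[cn]])
      new_idx <- length(copy_anc) + 1L
      copy_anc <- c(copy_anc, copy_anc[src])
      copy_origin <- c(copy_origin, mode[src])
      m <- mode[src]
      if (m == "tandem") {
        chroms[[cn]] <- append(chroms[[cn]], new_idx, after = pos)
      } else if (m == "proximal") {
        gap <- sample(2:10, 1)
        at <- min(pos + gap, length(chroms[[cn]]))
        chroms[[cn]] <- append(chroms[[cn]], new_idx, after = at)
      } else {
        others <- setdiff(seq_along(chroms), cn)
        target <- if (length(others) > 0) resample(others, 1) else cn
        at <- resample(0:length(chroms[[target]]), 1)
        chroms[[target]] <- append(chroms[[target]], new_idx, after = at)
      }
      sgd_src <- c(sgd_src, src); sgd_new <- c(sgd_new, new_idx)
      sgd_mode <- c(sgd_mode, m)
    }
  }

  # Collinearity erosion: random segment inversions (2-25 genes).
  strand_flip <- rep(FALSE, length(copy_anc))
  if (params$inversion_count > 0) {
    eligible <- function() which(lengths(chroms) >= 2)
    for (i in seq_len(params$inversion_count)) {
      el <- eligible()
      cn <- resample(el, 1)
      len_c <- length(chroms[[cn]])
      seg_len <- resample(2:min(25, len_c), 1)
      s <- resample(seq_len(len_c - seg_len + 1), 1)
      idx <- s:(s + seg_len - 1)
      seg <- chroms[[cn]][idx]
      chroms[[cn]][idx] <- rev(seg)
      strand_flip[seg] <- !strand_flip[seg]
    }
  }

  # Gene IDs: the ancestral copy keeps the base ID, later copies get a
  # per-ancestral-gene counter suffix.
  gene_id <- character(length(copy_anc))
  for (g in split(seq_along(copy_anc), copy_anc)) {
    base <- sprintf("G%05d", copy_anc[g[1]])
    gene_id[g[1]] <- base
    if (length(g) > 1)
      gene_id[g[-1]] <- sprintf("%s.%d", base, seq_len(length(g) - 1) + 1L)
  }

  # Ks per pair: truncated normal at the divergence event's age.
  draw_ks <- function(mu, m) pmax(0, rnorm(m, mu, params$ks_noise_sd))
  pairs <- tibble(
    gene_a = gene_id[pair_a], gene_b = gene_id[pair_b],
    event = event_names[pair_ev], mode = "wgd",
    ks = draw_ks(event_ages[pair_ev], length(pair_a)))
  if (length(sgd_src) > 0) {
    pairs <- bind_rows(pairs, tibble(
      gene_a = gene_id[sgd_src], gene_b = gene_id[sgd_new],
      event = sgd_mode, mode = sgd_mode,
      ks = draw_ks(params$sgd_ks, length(sgd_src))))
  }

  # Position table.
  ord <- order(names(chroms))
  glist <- lapply(names(chroms)[ord], function(cn) {
    ids <- chroms[[cn]]
    if (length(ids) == 0) return(NULL)
    r <- seq_along(ids) - 1L
    tibble(gene_id = gene_id[ids], chromosome = cn,
           start = r * 1000L + 1L, end = r * 1000L + 600L,
           strand = ifelse(strand_flip[ids], "-", "+"),
           rank = r,
           class_tag = ifelse(focal_anc[copy_anc[ids]], "focal", "background"))
  })
  genes <- bind_rows(glist)

  # Truth: duplication-type precedence wgd > tandem > proximal > dispersed.
  dup_type <- rep("singleton", length(copy_anc))
  for (m in c("dispersed", "proximal", "tandem")) {
    in_m <- sgd_mode == m
    dup_type[c(sgd_src[in_m], sgd_new[in_m])] <- m
  }
  dup_type[c(pair_a, pair_b)] <- "wgd"
  truth <- tibble(
    gene_id = gene_id,
    anc_id = sprintf("G%05d", copy_anc),
    class_tag = ifelse(focal_anc[copy_anc], "focal", "background"),
    dup_type_truth = dup_type,
    origin_event = copy_origin) |>
    arrange(.data$gene_id)

  structure(list(genes = genes, truth = truth, pairs = pairs,
                 params = params, events = events),
            class = "polyret_sim")
}

#' @export
print.polyret_sim <- function(x, ...) {
  cat(sprintf("<polyret_sim> %d genes on %d chromosomes (%d ancestral), %d homologous pairs\n",
              nrow(x$genes), length(unique(x$genes$chromosome)),
              x$params$n_genes, nrow(x$pairs)))
  invisible(x)
}

#' Emit a simulated all-vs-all similarity table
#'
#' Stands in for an all-vs-all protein search on the simulated genome. Every
#' surviving homologous pair appears in both query/subject orientations with
#' percent identity `100 * exp(-decay_k * Ks)` plus bounded uniform noise,
#' so identity decreases monotonically with pair age; E-values decrease
#' monotonically with identity (`10^(-1.8 * identity)`). A self-hit
#' (identity 100, E-value 0) is emitted per gene and ranks first.
#'
#' @param sim A `polyret_sim` object from [simulate_genome()].
#' @param decay_k Identity decay rate per Ks unit.
#' @param identity_noise Half-width of the bounded uniform identity noise
#'   (percentage points).
#' @param aln_len Nominal alignment length reported for every hit.
#' @param seed Seed for the identity noise.
#' @return A similarity tibble in the layout of [read_similarity_table()],
#'   ordered per query by increasing E-value.
#' @export
emit_similarity_table <- function(sim, decay_k = 0.3, identity_noise = 0.5,
                                  aln_len = 300L, seed = 1L) {
  stopifnot(inherits(sim, "polyret_sim"))
  withr::with_seed(as.integer(seed), {
    p <- sim$pairs
    ident <- 100 * exp(-decay_k * p$ks)
    if (identity_noise > 0 && nrow(p) > 0)
      ident <- ident + runif(nrow(p), -identity_noise, identity_noise)
    ident <- pmin(pmax(ident, 0.1), 99.9)
    half <- tibble(query_id = p$gene_a, subject_id = p$gene_b,
                   pct_identity = ident)
    both <- bind_rows(half,
                      tibble(query_id = p$gene_b, subject_id = p$gene_a,
                             pct_identity = ident))
    selfh <- tibble(query_id = sim$genes$gene_id,
                    subject_id = sim$genes$gene_id,
                    pct_identity = 100)
    out <- bind_rows(selfh, both) |>
      mutate(aln_len = as.integer(aln_len),
             mismatches = as.integer(round(aln_len * (1 - .data$pct_identity / 100))),
             gapopens = 0L,
             qstart = 1L, qend = as.integer(aln_len),
             sstart = 1L, send = as.integer(aln_len),
             evalue = ifelse(.data$pct_identity >= 100, 0,
                             10^(-1.8 * .data$pct_identity)),
             bitscore = round(2 * aln_len * .data$pct_identity / 100, 1)) |>
      arrange(.data$query_id, .data$evalue, dplyr::desc(.data$bitscore),
              .data$subject_id)
    out[, similarity_cols]
  })
}

#' Emit a synthetic reference interaction network over ancestral focal genes
#'
#' A preferential-attachment (Barabasi-Albert) graph over the ancestral focal
#' gene IDs, standing in for a curated interaction database of the reference
#' species. Undirected, simple, no self-loops, deterministic per seed.
#'
#' @param truth Truth tibble from [simulate_genome()].
#' @param mean_degree Target mean degree (edges emitted ~ `mean_degree/2`
#'   per node); 0 gives an empty edge list.
#' @param seed Integer seed.
#' @return An edge tibble with columns `from`, `to`.
#' @export
emit_reference_network <- function(truth, mean_degree = 4, seed = 1L) {
  nodes <- sort(unique(truth$anc_id[truth$class_tag == "focal"]))
  if (length(nodes) == 0 || mean_degree == 0)
    return(tibble(from = character(), to = character()))
  if (mean_degree > length(nodes) - 1)
    abort("`mean_degree` cannot exceed node count - 1.")
  m <- max(1L, as.integer(round(mean_degree / 2)))
  withr::with_seed(as.integer(seed), {
    g <- igraph::sample_pa(length(nodes), m = m, directed = FALSE)
    perm <- sample(nodes)
    el <- igraph::as_edgelist(g)
    tibble(from = perm[as.integer(el[, 1])],
           to = perm[as.integer(el[, 2])]) |>
      filter(.data$from != .data$to) |>
      distinct()
  })
}
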