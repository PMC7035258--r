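# Independent brute-force oracles. These deliberately share no code with the
# package implementation: chains are found by subset enumeration, genetic-code
# lookups come from a hard-coded translation string, and connected components
# use a hand-rolled BFS.

# ---- chaining oracle ---------------------------------------------------

# Compare two candidate chains under the documented total order:
# score desc, total gap asc, lexicographic (rank_a, rank_b) sequence asc,
# same orientation before reverse. Returns TRUE if a beats b.
oracle_chain_better <- function(a, b) {
  if (a$len != b$len) return(a$len > b$len)
  if (a$gap != b$gap) return(a$gap < b$gap)
  sa <- as.vector(rbind(a$seq_ra, a$seq_rb))
  sb <- as.vector(rbind(b$seq_ra, b$seq_rb))
  for (k in seq_len(min(length(sa), length(sb)))) {
    if (sa[k] != sb[k]) return(sa[k] < sb[k])
  }
  a$orient < b$orient  # 0 = same first
}

# Best valid chain among all subsets of the active anchors (exhaustive).
oracle_best_chain <- function(ra, rb, active, max_gap) {
  idx <- which(active)
  n <- length(idx)
  best <- NULL
  for (mask in seq_len(2^n - 1)) {
    sel <- idx[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
    if (!is.null(best) && length(sel) < best$len) next
    for (orient in c(0L, 1L)) {
      o <- order(ra[sel], if (orient == 0L) rb[sel] else -rb[sel])
      s <- sel[o]
      if (length(s) > 1) {
        dra <- diff(ra[s])
        drb <- if (orient == 0L) diff(rb[s]) else -diff(rb[s])
        if (any(dra <= 0) || any(drb <= 0)) next
        if (any(dra - 1 > max_gap) || any(drb - 1 > max_gap)) next
        gap <- sum(dra - 1) + sum(drb - 1)
      } else {
        if (orient == 1L) next  # 1-anchor chains count as same orientation
        gap <- 0
      }
      cand <- list(len = length(s), gap = gap, orient = orient,
                   seq_ra = ra[s], seq_rb = rb[s], sel = s)
      if (is.null(best) || oracle_chain_better(cand, best)) best <- cand
    }
  }
  best
}

# Greedy best-chain-first extraction by exhaustive search; returns a list of
# blocks in extraction order, each with orientation / indices / score / gap.
oracle_chain_blocks <- function(ra, rb, max_gap, min_anchors) {
  active <- rep(TRUE, length(ra))
  out <- list()
  while (sum(active) >= min_anchors) {
    best <- oracle_best_chain(ra, rb, active, max_gap)
    if (is.null(best) || best$len < min_anchors) break
    out[[length(out) + 1]] <- list(
      orientation = if (best$orient == 0L) "same" else "reverse",
      anchor_idx = best$sel, score = best$len, total_gap = best$gap)
    active[best$sel] <- FALSE
  }
  out
}

# ---- NG86 oracle -------------------------------------------------------

# Standard genetic code from the classic 64-character translation string,
# positions indexed in T, C, A, G order.
oracle_translate <- local({
  aas <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  b <- c(T = 0L, C = 1L, A = 2L, G = 3L)
  function(codon) {
    v <- b[strsplit(codon, "")[[1]]]
    aas[v[1] * 16 + v[2] * 4 + v[3] + 1]
  }
})

oracle_sites <- function(seq) {
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  S <- 0
  for (cd in codons) {
    aa <- oracle_translate(cd)
    cv <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (alt in setdiff(c("T", "C", "A", "G"), cv[pos])) {
        mv <- cv; mv[pos] <- alt
        if (oracle_translate(paste(mv, collapse = "")) == aa) S <- S + 1 / 3
      }
    }
  }
  c(S = S, N = 3 * length(codons) - S)
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (r in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], r)
  }
  out
}

oracle_diffs <- function(ca, cb) {
  if (ca == cb) return(c(sd = 0, nd = 0))
  va <- strsplit(ca, "")[[1]]; vb <- strsplit(cb, "")[[1]]
  pos <- which(va != vb)
  paths <- list()
  for (ord in oracle_perms(pos)) {
    cur <- va; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      prev_aa <- oracle_translate(paste(cur, collapse = ""))
      cur[p] <- vb[p]
      new_aa <- oracle_translate(paste(cur, collapse = ""))
      if (new_aa == "*") blocked <- TRUE
      if (new_aa == prev_aa && new_aa != "*") sd <- sd + 1 else nd <- nd + 1
    }
    paths[[length(paths) + 1]] <- list(sd = sd, nd = nd, blocked = blocked)
  }
  ok <- Filter(function(p) !p$blocked, paths)
  if (length(ok) == 0) ok <- paths
  c(sd = mean(vapply(ok, `[[`, 0, "sd")),
    nd = mean(vapply(ok, `[[`, 0, "nd")))
}

oracle_kaks <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  sa <- oracle_sites(seq_a); sb <- oracle_sites(seq_b)
  S <- (sa[["S"]] + sb[["S"]]) / 2
  N <- (sa[["N"]] + sb[["N"]]) / 2
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    d <- oracle_diffs(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) -(3 / 4) * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

# Random codon sequence free of stop codons.
random_codons <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                  collapse = "")
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  paste(codons, collapse = "")
}

# Mutate a stop-free codon sequence, keeping it stop-free.
mutate_codons <- function(seq, n_mut) {
  stops <- c("TAA", "TAG", "TGA")
  v <- strsplit(seq, "")[[1]]
  for (i in seq_len(n_mut)) {
    repeat {
      p <- sample(length(v), 1)
      old <- v[p]
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      cd_start <- 3 * ((p - 1) %/% 3) + 1
      cd <- paste(v[cd_start:(cd_start + 2)], collapse = "")
      if (!cd %in% stops) break
      v[p] <- old
    }
  }
  paste(v, collapse = "")
}

# ---- robustness oracle -------------------------------------------------

# Largest connected component size by BFS over an edge list (matrix of node
# names), counting isolated members of `nodes` as singleton components.
oracle_lcc <- function(nodes, edges) {
  if (length(nodes) == 0) return(0L)
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      if (a %in% nodes && b %in% nodes) {
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
      }
    }
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  best <- 0L
  for (s in nodes) {
    if (seen[[s]]) next
    queue <- s; seen[[s]] <- TRUE; size <- 0L
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]; size <- size + 1L
      for (nb in adj[[cur]]) {
        if (!seen[[nb]]) { seen[[nb]] <- TRUE; queue <- c(queue, nb) }
      }
    }
    best <- max(best, size)
  }
  best
}

# Exact distribution of R over all removals of `nr` nodes.
oracle_robustness_exact <- function(nodes, edges, nr) {
  combs <- utils::combn(nodes, nr)
  vapply(seq_len(ncol(combs)), function(i) {
    keep <- setdiff(nodes, combs[, i])
    oracle_lcc(keep, edges) / length(keep)
  }, 0)
}

# ---- misc helpers ------------------------------------------------------

random_anchor_instance <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(2:12, 1)
    grid <- sample(6:18, 1)
    pts <- unique(data.frame(ra = sample(0:(grid - 1), n, replace = TRUE),
                             rb = sample(0:(grid - 1), n, replace = TRUE)))
    list(ra = pts$ra, rb = pts$rb,
         max_gap = sample(c(1L, 2L, 3L, 50L), 1),
         min_anchors = sample(2:3, 1))
  })
}

small_genome_tibble <- function(ids, chroms, starts, strand = "+") {
  tibble::tibble(gene_id = ids, chromosome = chroms, start = starts,
                 end = starts + 99L, strand = strand) |>
    polyret:::assign_ranks()
}
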