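## Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
##
## Sites: each codon position contributes the fraction of its three possible
## single-nucleotide changes that are synonymous to S and the complement to N
## (changes creating a stop codon count as nonsynonymous), so S + N = 3 per
## codon. Differences: codon pairs differing at 2 or 3 positions average the
## synonymous/nonsynonymous step counts over all minimal mutational pathways;
## pathways passing through a stop codon are excluded and the remainder
## reweighted equally (if every pathway is blocked, all are used, with steps
## into stops counted nonsynonymous).

.kaks_env <- new.env(parent = emptyenv())

bases <- c("A", "C", "G", "T")

codon_table <- function() {
  if (!is.null(.kaks_env$tab)) return(.kaks_env$tab)
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aa <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]])
  }, "")
  tab <- list(aa = setNames(aa, codons))
  # per-codon synonymous site count (sum over the 3 positions of the
  # synonymous fraction among the 3 alternative bases)
  syn_sites <- vapply(codons, function(cd) {
    if (tab$aa[[cd]] == "*") return(NA_real_)
    s <- 0
    cv <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(bases, cv[pos])) {
        alt <- cv; alt[pos] <- b
        altc <- paste(alt, collapse = "")
        if (tab$aa[[altc]] == tab$aa[[cd]]) s <- s + 1 / 3
      }
    }
    s
  }, 0)
  tab$syn_sites <- syn_sites
  .kaks_env$tab <- tab
  tab
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3 != 0) abort("Sequence length must be a multiple of 3.")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' @param seq A coding nucleotide sequence (length a multiple of 3, no stop
#'   codons).
#' @return Named numeric vector `c(S_sites =, N_sites =)`; the two always sum
#'   to 3 x codon count.
#' @examples
#' ng86_sites("ATG")  # S = 0, N = 3
#' ng86_sites("TTT")  # S = 1/3, N = 8/3
#' @export
ng86_sites <- function(seq) {
  tab <- codon_table()
  codons <- split_codons(seq)
  bad <- which(!codons %in% names(tab$aa))
  if (length(bad) > 0)
    abort(sprintf("Codon %d ('%s') contains a non-ACGT character.",
                  bad[1], codons[bad[1]]))
  stops <- which(tab$aa[codons] == "*")
  if (length(stops) > 0)
    abort(sprintf("Stop codon at codon index %d ('%s').",
                  stops[1], codons[stops[1]]))
  S <- sum(tab$syn_sites[codons])
  c(S_sites = S, N_sites = 3 * length(codons) - S)
}

# All minimal mutational pathways between two codons, as lists of
# intermediate codons (excluding the endpoints).
codon_paths <- function(codon_a, codon_b) {
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  lapply(perms(diff_pos), function(ord) {
    cur <- strsplit(codon_a, "")[[1]]
    tgt <- strsplit(codon_b, "")[[1]]
    steps <- character(0)
    for (p in ord) {
      cur[p] <- tgt[p]
      steps <- c(steps, paste(cur, collapse = ""))
    }
    steps  # last element is codon_b itself
  })
}

#' Nei-Gojobori synonymous and nonsynonymous differences between two codons
#'
#' @param codon_a,codon_b Ungapped, non-stop codons.
#' @return Named numeric vector `c(sd =, nd =)`; `sd + nd` equals the number
#'   of differing positions.
#' @examples
#' ng86_differences("TTT", "TTC")  # one synonymous change
#' ng86_differences("TTT", "GTA")  # averaged over 2 pathways
#' @export
ng86_differences <- function(codon_a, codon_b) {
  tab <- codon_table()
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  paths <- codon_paths(codon_a, codon_b)
  classify_path <- function(steps) {
    cur <- codon_a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (nxt in steps) {
      if (tab$aa[[nxt]] == "*") blocked <- TRUE
      if (tab$aa[[nxt]] == tab$aa[[cur]] && tab$aa[[nxt]] != "*") {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  res <- lapply(paths, classify_path)
  ok <- !vapply(res, `[[`, TRUE, "blocked")
  if (any(ok)) res <- res[ok]
  c(sd = mean(vapply(res, `[[`, 0, "sd")),
    nd = mean(vapply(res, `[[`, 0, "nd")))
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * ln(1 - 4p/3)` for an observed proportion of differences
#' `p < 0.75`.
#'
#' @param p Proportion of observed differences per site.
#' @return The corrected distance.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0)) abort("`p` must be non-negative.")
  if (any(p >= 0.75))
    abort("Jukes-Cantor correction saturates at p >= 0.75.")
  -(3 / 4) * log(1 - 4 * p / 3)
}

#' Ka/Ks for one aligned codon pair (Nei-Gojobori 1986)
#'
#' Drops codon columns containing a gap in either sequence, averages the
#' site counts of the two sequences, sums the pathway-averaged differences
#' per codon, converts to proportions and applies the Jukes-Cantor
#' correction. `omega = Ka/Ks`; when `Ks = 0` omega is undefined and reported
#' as `NA` (not infinity). `positive_selection` is `TRUE` iff both distances
#' are defined and omega > 1.
#'
#' @param seq_a,seq_b Aligned nucleotide strings over `A`,`C`,`G`,`T`,`-` of
#'   equal length (a multiple of 3).
#' @return One-row tibble of class `polyret_kaks`: `n_codons`, `S_sites`,
#'   `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `omega`,
#'   `positive_selection`.
#' @export
kaks_pair <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    abort("Aligned sequences must have equal length.")
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  gapped <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
  ca <- ca[!gapped]; cb <- cb[!gapped]
  if (length(ca) == 0) abort("No ungapped codon columns to compare.")
  sites_a <- ng86_sites(paste(ca, collapse = ""))
  sites_b <- ng86_sites(paste(cb, collapse = ""))
  S <- (sites_a[["S_sites"]] + sites_b[["S_sites"]]) / 2
  N <- (sites_a[["N_sites"]] + sites_b[["N_sites"]]) / 2
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    d <- ng86_differences(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  omega <- if (Ks > 0) Ka / Ks else NA_real_
  out <- tibble(n_codons = length(ca), S_sites = S, N_sites = N,
                Sd = Sd, Nd = Nd, pS = pS, pN = pN, Ks = Ks, Ka = Ka,
                omega = omega,
                positive_selection = !is.na(omega) && omega > 1)
  class(out) <- c("polyret_kaks", class(out))
  out
}

#' Batch Ka/Ks over a list of gene pairs
#'
#' @param pairs Tibble `gene_a`, `gene_b`.
#' @param sequences Named character vector of aligned coding sequences (the
#'   two members of each pair must be mutually aligned).
#' @return Tibble with `gene_a`, `gene_b` and the [kaks_pair()] columns.
#' @export
kaks_batch <- function(pairs, sequences) {
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(sequences))
  if (length(missing) > 0)
    abort(sprintf("No sequence for gene(s): %s",
                  paste(head(missing, 3), collapse = ", ")))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    res <- kaks_pair(sequences[[pairs$gene_a[i]]],
                     sequences[[pairs$gene_b[i]]])
    dplyr::bind_cols(tibble(gene_a = pairs$gene_a[i],
                            gene_b = pairs$gene_b[i]), res)
  })
  bind_rows(rows)
}

#' Read a pairwise FASTA codon alignment
#'
#' @param path FASTA file with exactly two aligned records.
#' @return Named character vector of length 2.
#' @export
read_codon_alignment <- function(path) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  if (length(fa) != 2)
    abort(sprintf("Expected exactly 2 FASTA records, found %d.", length(fa)))
  setNames(toupper(vapply(fa, as.character, "")), names(fa))
}
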