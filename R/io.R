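#' Read a gene position table
#'
#' Reads a tab-separated table with columns chromosome, gene_id, start, end,
#' strand (1-based inclusive coordinates, GFF convention). Lines starting with
#' `#` are skipped. Gene order ranks are computed per chromosome from `start`,
#' ties broken by lexicographic `gene_id`; ranks are 0-based in memory.
#'
#' @param path Path to the file.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `rank`, sorted by (chromosome, start).
#' @export
read_gene_positions <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(gene_id = character(), chromosome = character(),
                  start = integer(), end = integer(), strand = character(),
                  rank = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5)) {
    abort(sprintf("Malformed gene position line %d: expected >= 5 tab-separated columns, got %d.",
                  lineno[which(nf < 5)[1]], nf[which(nf < 5)[1]]))
  }
  chromosome <- vapply(fields, `[[`, "", 1)
  gene_id <- vapply(fields, `[[`, "", 2)
  start_c <- vapply(fields, `[[`, "", 3)
  end_c <- vapply(fields, `[[`, "", 4)
  strand <- vapply(fields, `[[`, "", 5)
  start <- suppressWarnings(as.integer(start_c))
  end <- suppressWarnings(as.integer(end_c))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    abort(sprintf("Malformed gene position line %d: non-integer start/end.", lineno[bad[1]]))
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0)
    abort(sprintf("Malformed gene position line %d: strand must be '+' or '-'.", lineno[bad[1]]))
  bad <- which(start > end)
  if (length(bad) > 0)
    abort(sprintf("Malformed gene position line %d: start > end.", lineno[bad[1]]))
  if (anyDuplicated(gene_id))
    abort(sprintf("Duplicate gene_id in %s: %s", path,
                  gene_id[duplicated(gene_id)][1]))
  tibble(gene_id = gene_id, chromosome = chromosome,
         start = start, end = end, strand = strand) |>
    assign_ranks()
}

# Rank genes 0..n-1 within each chromosome by start, ties by gene_id.
assign_ranks <- function(genes) {
  genes |>
    arrange(.data$chromosome, .data$start, .data$gene_id) |>
    group_by(.data$chromosome) |>
    mutate(rank = row_number() - 1L) |>
    ungroup()
}

#' Write a gene position table
#'
#' @param genes Tibble as returned by [read_gene_positions()] or
#'   [simulate_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_positions <- function(genes, path) {
  df <- genes[, c("chromosome", "gene_id", "start", "end", "strand")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

similarity_cols <- c("query_id", "subject_id", "pct_identity", "aln_len",
                     "mismatches", "gapopens", "qstart", "qend", "sstart",
                     "send", "evalue", "bitscore")

#' Read an all-vs-all similarity table (12-column tabular BLAST dialect)
#'
#' Accepts the tabular "outfmt 6" layout: query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' E-value, bitscore. Scientific notation with ASCII `e`/`E` is accepted.
#' Lines starting with `#` are skipped. Malformed lines raise an error naming
#' the line number.
#'
#' @param path Path to the file.
#' @return A tibble with columns `query_id`, `subject_id`, `pct_identity`,
#'   `aln_len`, `mismatches`, `gapopens`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`.
#' @export
read_similarity_table <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- tibble(query_id = character(), subject_id = character(),
                  pct_identity = double(), aln_len = integer(),
                  mismatches = integer(), gapopens = integer(),
                  qstart = integer(), qend = integer(), sstart = integer(),
                  send = integer(), evalue = double(), bitscore = double())
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    i <- which(nf != 12)[1]
    abort(sprintf("Malformed similarity line %d: expected 12 tab-separated columns, got %d.",
                  lineno[i], nf[i]))
  }
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  num <- function(col, name, integer = FALSE) {
    x <- suppressWarnings(as.numeric(m[, col]))
    bad <- which(is.na(x))
    if (length(bad) > 0)
      abort(sprintf("Malformed similarity line %d: non-numeric %s.",
                    lineno[bad[1]], name))
    if (integer) as.integer(x) else x
  }
  out <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = num(3, "pct_identity"),
    aln_len = num(4, "aln_len", TRUE), mismatches = num(5, "mismatches", TRUE),
    gapopens = num(6, "gapopens", TRUE), qstart = num(7, "qstart", TRUE),
    qend = num(8, "qend", TRUE), sstart = num(9, "sstart", TRUE),
    send = num(10, "send", TRUE),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"))
  if (any(out$evalue < 0))
    abort("Malformed similarity table: negative evalue.")
  if (any(out$pct_identity < 0 | out$pct_identity > 100))
    abort("Malformed similarity table: pct_identity outside [0, 100].")
  out
}

#' Write a similarity table in the 12-column tabular dialect
#'
#' @param hits Tibble with the columns of [read_similarity_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(hits, path) {
  df <- as.data.frame(hits[, similarity_cols])
  df$evalue <- format_evalue(df$evalue)
  df$pct_identity <- sprintf("%.2f", df$pct_identity)
  df$bitscore <- sprintf("%.1f", df$bitscore)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_evalue <- function(x) {
  ifelse(x == 0, "0.0", sprintf("%.2e", x))
}

#' Read / write a plain gene-ID list (one ID per line)
#'
#' @param path File path.
#' @return `read_gene_list()` returns a character vector;
#'   `write_gene_list()` returns `path` invisibly.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- x[!startsWith(x, "#") & nzchar(x)]
  x
}

#' @rdname read_gene_list
#' @param ids Character vector of gene IDs.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read / write a two-column tab-separated edge list
#'
#' @param path File path.
#' @return `read_edge_list()` returns a tibble with columns `from`, `to`;
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(tibble(from = character(), to = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2)) {
    i <- which(nf != 2)[1]
    abort(sprintf("Malformed edge list line %d: expected 2 tab-separated columns.",
                  lineno[i]))
  }
  tibble(from = vapply(fields, `[[`, "", 1), to = vapply(fields, `[[`, "", 2))
}

#' @rdname read_edge_list
#' @param edges Tibble with columns `from`, `to`.
#' @export
write_edge_list <- function(edges, path) {
  write.table(as.data.frame(edges[, c("from", "to")]), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a collinear block report
#'
#' The report starts with a single `#`-prefixed column header. Each block then
#' contributes one `>`-prefixed header line (block id, chromosome pair,
#' orientation, anchor count, score, p-value with at least 3 significant
#' digits, event label or `.`), followed by one tab-separated anchor pair per
#' line (gene_a, gene_b, rank_a, rank_b). The reader reconstructs the block
#' object exactly.
#'
#' @param blocks A `polyret_blocks` object (see [find_collinear_blocks()]).
#' @param path File path.
#' @return `write_block_report()` returns `path` invisibly;
#'   `read_block_report()` returns a `polyret_blocks` object.
#' @export
write_block_report <- function(blocks, path) {
  stopifnot(inherits(blocks, "polyret_blocks"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#block_id\tchrom_a\tchrom_b\torientation\tn_anchors\tscore\tp_value\tevent", con)
  b <- blocks$blocks
  a <- blocks$anchors
  if (nrow(b) > 0) {
    for (i in seq_len(nrow(b))) {
      writeLines(sprintf(">%d\t%s\t%s\t%s\t%d\t%d\t%s\t%s",
                         b$block_id[i], b$chrom_a[i], b$chrom_b[i],
                         b$orientation[i], b$n_anchors[i], b$score[i],
                         ifelse(is.na(b$p_value[i]), "NA",
                                sprintf("%.6g", b$p_value[i])),
                         ifelse(is.na(b$event[i]), ".", b$event[i])), con)
      ai <- a[a$block_id == b$block_id[i], ]
      writeLines(sprintf("%s\t%s\t%d\t%d", ai$gene_a, ai$gene_b,
                         ai$rank_a, ai$rank_b), con)
    }
  }
  invisible(path)
}

#' @rdname write_block_report
#' @export
read_block_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  blocks <- list()
  anchors <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      f <- strsplit(substring(ln, 2), "\t", fixed = TRUE)[[1]]
      if (length(f) != 8) abort("Malformed block header in block report.")
      cur <- as.integer(f[1])
      blocks[[length(blocks) + 1]] <- tibble(
        block_id = cur, chrom_a = f[2], chrom_b = f[3], orientation = f[4],
        n_anchors = as.integer(f[5]), score = as.integer(f[6]),
        p_value = suppressWarnings(as.numeric(f[7])),
        event = if (f[8] == ".") NA_character_ else f[8])
    } else {
      if (is.null(cur)) abort("Anchor line before any block header in block report.")
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 4) abort("Malformed anchor line in block report.")
      anchors[[length(anchors) + 1]] <- tibble(
        block_id = cur, gene_a = f[1], gene_b = f[2],
        rank_a = as.integer(f[3]), rank_b = as.integer(f[4]))
    }
  }
  empty_b <- tibble(block_id = integer(), chrom_a = character(),
                    chrom_b = character(), orientation = character(),
                    n_anchors = integer(), score = integer(),
                    p_value = double(), event = character())
  empty_a <- tibble(block_id = integer(), gene_a = character(),
                    gene_b = character(), rank_a = integer(),
                    rank_b = integer())
  new_blocks(
    blocks = if (length(blocks)) bind_rows(blocks) else empty_b,
    anchors = if (length(anchors)) bind_rows(anchors) else empty_a)
}
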