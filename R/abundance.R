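#' Count peptides in a parsed round
#'
#' Tallies translated peptides over `status == "pass"` records only; the
#' resulting table is the per-round abundance used by every downstream
#' normalization and ranking step.
#'
#' @param parsed A data.frame from [parse_reads()] / [qc_run()], or a
#'   character vector of peptides (already filtered).
#' @param round_label Label for the round, e.g. `"pan0"`.
#' @return An `abundance_table`: data.frame with columns `peptide` and
#'   `count` sorted by decreasing count (ties lexicographic), and
#'   attributes `round_label` and `total_passed`.
#' @export
count_peptides <- function(parsed, round_label) {
  peps <- if (is.data.frame(parsed)) {
    parsed$peptide[parsed$status == "pass"]
  } else {
    as.character(parsed)
  }
  if (length(peps) == 0L) {
    tab <- data.frame(peptide = character(), count = integer(),
                      stringsAsFactors = FALSE)
  } else {
    t <- table(peps)
    tab <- data.frame(peptide = names(t), count = as.integer(t),
                      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$count, tab$peptide), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab, round_label = as.character(round_label),
            total_passed = sum(tab$count),
            class = c("abundance_table", "data.frame"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table [", attr(x, "round_label"), "]: ",
      nrow(x), " unique peptides, ", attr(x, "total_passed"),
      " passing reads\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Total passing reads behind an abundance table
#' @param table An `abundance_table`.
#' @return Integer count.
#' @export
total_passed <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  attr(table, "total_passed")
}

#' Round label of an abundance table
#' @param table An `abundance_table`.
#' @return Character label.
#' @export
round_label <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  attr(table, "round_label")
}

.check_total <- function(table) {
  if (total_passed(table) == 0L)
    stop("normalization undefined: table has no passing reads",
         call. = FALSE)
}

#' Copies per million reads
#'
#' `count / total_passed * 1e6` for each requested peptide; peptides
#' absent from the table have 0 copies. With `peptides = NULL` the full
#' named CPM vector over the table is returned.
#'
#' @param table An `abundance_table`.
#' @param peptides Character vector of peptides, or `NULL` for all.
#' @return Named numeric vector of CPM values.
#' @export
cpm <- function(table, peptides = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  .check_total(table)
  all_cpm <- table$count / total_passed(table) * 1e6
  names(all_cpm) <- table$peptide
  if (is.null(peptides)) return(all_cpm)
  out <- all_cpm[peptides]
  out[is.na(out)] <- 0
  names(out) <- peptides
  out
}

#' Percent abundance
#'
#' `count / total_passed * 100`; absent peptides are 0%.
#'
#' @inheritParams cpm
#' @return Named numeric vector of percentages.
#' @export
percent <- function(table, peptides = NULL) {
  cpm(table, peptides) / 1e4
}

#' Sequence-redundancy distribution
#'
#' Bins every unique peptide by the decade of its CPM value — the
#' redundancy classes of a redundancy plot. Bins are half-open
#' `[low, high)` with the top bin closed at 1e6, so a boundary value
#' falls in the higher bin.
#'
#' @param table An `abundance_table`.
#' @param edges Numeric vector of bin boundaries in CPM (default decade
#'   edges `1, 10, ..., 1e6`).
#' @return A `redundancy_bins` data.frame with columns `bin_low_cpm`,
#'   `bin_high_cpm`, `unique_sequences`, `read_fraction`.
#' @export
redundancy_bins <- function(table, edges = 10^(0:6)) {
  stopifnot(inherits(table, "abundance_table"))
  .check_total(table)
  edges <- sort(unique(edges))
  v <- cpm(table)
  if (any(v < edges[1L] | v > edges[length(edges)]))
    stop("observed CPM outside the bin range", call. = FALSE)
  # [low, high) everywhere, top bin closed: right-open cut
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  uniq <- tabulate(bin, nbins = nb)
  frac <- vapply(seq_len(nb),
                 function(b) sum(table$count[bin == b]), numeric(1)) /
    total_passed(table)
  structure(
    data.frame(bin_low_cpm = edges[-length(edges)],
               bin_high_cpm = edges[-1L],
               unique_sequences = uniq,
               read_fraction = frac),
    class = c("redundancy_bins", "data.frame")
  )
}

#' Merge abundance tables of the same round
#'
#' Key-wise sum of counts; equivalent to counting the concatenated
#' parsed streams.
#'
#' @param x,y `abundance_table`s.
#' @return An `abundance_table` labelled as `x`.
#' @export
merge_abundance <- function(x, y) {
  stopifnot(inherits(x, "abundance_table"), inherits(y, "abundance_table"))
  peps <- c(rep(x$peptide, x$count), rep(y$peptide, y$count))
  count_peptides(peps, round_label(x))
}

#' Write an abundance table (and optionally its redundancy bins) as TSV
#'
#' @param table An `abundance_table`.
#' @param path Destination TSV (columns peptide, count, cpm, percent,
#'   rank).
#' @param redundancy_path Optional destination for the redundancy TSV.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(table, path, redundancy_path = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(peptide = table$peptide, count = table$count,
                   cpm = unname(cpm(table)),
                   percent = unname(percent(table)),
                   rank = unname(rank_by_abundance(table)[table$peptide]))
  .write_tsv(df, path,
             meta = c(paste0("round_label=", round_label(table)),
                      paste0("total_passed=", total_passed(table))))
  if (!is.null(redundancy_path))
    .write_tsv(as.data.frame(redundancy_bins(table)), redundancy_path,
               meta = paste0("round_label=", round_label(table)))
  invisible(path)
}

#' Read an abundance TSV written by [write_abundance_tsv()]
#'
#' @param path TSV path.
#' @return An `abundance_table`.
#' @export
read_abundance_tsv <- function(path) {
  head <- readLines(path, n = 10L)
  lab <- sub("^# round_label=", "", grep("^# round_label=", head, value = TRUE))
  df <- .read_tsv(path)
  tab <- data.frame(peptide = as.character(df$peptide),
                    count = as.integer(df$count), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$peptide), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, round_label = if (length(lab)) lab[1L] else NA_character_,
            total_passed = sum(tab$count),
            class = c("abundance_table", "data.frame"))
}
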