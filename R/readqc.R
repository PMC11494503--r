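#' Locate the intein anchors in amplicon reads
#'
#' Finds the upstream (C-intein) and downstream (N-intein) anchor in each
#' read, allowing up to `max_anchor_mismatch` substitutions per anchor
#' (no indels). The leftmost upstream occurrence is taken, then the
#' nearest downstream occurrence starting after the upstream anchor ends;
#' the enclosed span is the candidate extein. Coordinates are 1-based and
#' inclusive, the R/Bioconductor convention.
#'
#' @param reads A `DNAStringSet` or character vector of read sequences.
#' @param design A [siclopps_design()].
#' @return A data.frame with one row per read: `extein_start`,
#'   `extein_end` (1-based inclusive bounds of the enclosed span, `NA` on
#'   failure) and `found` (logical). A span of width 0 has
#'   `extein_end == extein_start - 1`.
#' @export
locate_anchors <- function(reads, design) {
  stopifnot(inherits(design, "siclopps_design"))
  ch <- if (is.character(reads)) toupper(reads) else as.character(reads)
  n <- length(ch)
  if (n == 0L)
    return(data.frame(extein_start = integer(), extein_end = integer(),
                      found = logical()))
  if (any(!nzchar(ch)))
    stop("read sequences must be nonempty", call. = FALSE)
  up <- design$upstream_anchor
  dn <- design$downstream_anchor
  mm <- design$max_anchor_mismatch

  if (mm == 0L) {
    up_start <- regexpr(up, ch, fixed = TRUE)
    up_start[up_start < 0L] <- NA_integer_
    cut <- up_start + nchar(up)  # first base after the upstream anchor
    tail_seq <- substr(ch, cut, nchar(ch))
    rel <- regexpr(dn, tail_seq, fixed = TRUE)
    rel[rel < 0L] <- NA_integer_
    dn_start <- cut + rel - 1L
  } else {
    x <- if (is.character(reads)) Biostrings::DNAStringSet(ch) else reads
    up_start <- .first_start(Biostrings::vmatchPattern(up, x,
                                                       max.mismatch = mm))
    cut <- up_start + nchar(up)
    dn_start <- .first_start_at_or_after(
      Biostrings::vmatchPattern(dn, x, max.mismatch = mm), cut, n)
  }
  found <- !is.na(up_start) & !is.na(dn_start)
  data.frame(
    extein_start = ifelse(found, cut, NA_integer_),
    extein_end = ifelse(found, dn_start - 1L, NA_integer_),
    found = found
  )
}

# leftmost match start per read from an MIndex, NA where absent
.first_start <- function(m) {
  s <- Biostrings::startIndex(m)
  len <- lengths(s)
  out <- rep(NA_integer_, length(s))
  hit <- len > 0L
  out[hit] <- vapply(s[hit], `[[`, integer(1), 1L)
  out
}

# leftmost match start >= cut[i] per read (matches are in increasing order)
.first_start_at_or_after <- function(m, cut, n) {
  s <- Biostrings::startIndex(m)
  idx <- rep(seq_len(n), lengths(s))
  st <- unlist(s, use.names = FALSE)
  if (is.null(st)) return(rep(NA_integer_, n))
  keep <- !is.na(cut[idx]) & st >= cut[idx]
  idx <- idx[keep]; st <- st[keep]
  first <- !duplicated(idx)
  out <- rep(NA_integer_, n)
  out[idx[first]] <- st[first]
  out
}

#' Parse amplicon reads into extein records
#'
#' Composes anchor location, extein length check, base-ambiguity check
#' and translation. Each read receives the first failing status in the
#' fixed order `no_anchor`, `bad_length`, `ambiguous_base`,
#' `bad_first_residue`, `stop_codon`; reads passing all checks have
#' status `pass` and a translated peptide. The randomized tag preceding
#' the upstream anchor is recorded as `n6_tag` (possibly shorter than
#' `n6_length` when the read starts mid-tag; truncated to the adjacent
#' `n6_length` bases otherwise).
#'
#' @inheritParams locate_anchors
#' @param ids Optional character vector of read identifiers (recycled
#'   from `names(reads)` or generated as `read1..readN`).
#' @param stop_policy Passed to [translate_extein_detail()].
#' @return A data.frame with columns `read_id`, `n6_tag`, `extein_dna`,
#'   `peptide`, `status`, `non_nns`.
#' @export
parse_reads <- function(reads, design, ids = NULL,
                        stop_policy = c("reject",
                                        "translate_amber_as_stop")) {
  stopifnot(inherits(design, "siclopps_design"))
  stop_policy <- match.arg(stop_policy)
  ch <- if (is.character(reads)) toupper(reads) else as.character(reads)
  n <- length(ch)
  if (is.null(ids)) {
    ids <- if (!is.null(names(ch)) && all(nzchar(names(ch)))) names(ch)
           else paste0("read", seq_len(n))
  }
  if (n == 0L)
    return(data.frame(read_id = character(), n6_tag = character(),
                      extein_dna = character(), peptide = character(),
                      status = character(), non_nns = logical(),
                      stringsAsFactors = FALSE))

  loc <- locate_anchors(ch, design)
  status <- rep("no_anchor", n)
  extein <- rep(NA_character_, n)
  n6_tag <- rep(NA_character_, n)
  peptide <- rep(NA_character_, n)
  non_nns <- rep(FALSE, n)

  f <- loc$found
  if (any(f)) {
    extein[f] <- substr(ch[f], loc$extein_start[f], loc$extein_end[f])
    up_start <- loc$extein_start[f] - nchar(design$upstream_anchor)
    tag_from <- pmax(1L, up_start - design$n6_length)
    n6_tag[f] <- substr(ch[f], tag_from, up_start - 1L)
    elen <- extein_length(design)
    ok_len <- nchar(extein) == elen & f
    status[f & !ok_len] <- "bad_length"
    if (any(ok_len)) {
      ext <- gsub("[^ACGT]", "N", extein[ok_len])
      det <- translate_extein_detail(ext, design, stop_policy)
      status[ok_len] <- det$status
      peptide[ok_len] <- det$peptide
      non_nns[ok_len] <- det$non_nns
    }
  }
  data.frame(read_id = ids, n6_tag = n6_tag, extein_dna = extein,
             peptide = peptide, status = status, non_nns = non_nns,
             stringsAsFactors = FALSE)
}

.qc_statuses <- c("pass", "no_anchor", "bad_length", "ambiguous_base",
                  "bad_first_residue", "stop_codon")

#' Summarize parsed reads into a QC report
#'
#' @param parsed A data.frame from [parse_reads()].
#' @return A `qc_report`: list with `total_reads`, `counts` (named
#'   integer over all status categories, summing to `total_reads`) and
#'   `pass_fraction`.
#' @export
qc_report <- function(parsed) {
  counts <- vapply(.qc_statuses,
                   function(s) sum(parsed$status == s), integer(1))
  total <- nrow(parsed)
  structure(
    list(total_reads = total, counts = counts,
         pass_fraction = if (total > 0L) counts[["pass"]] / total else NA_real_),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SICLOPPS read QC report\n")
  cat("  total reads:", x$total_reads, "\n")
  for (s in names(x$counts)) cat(sprintf("  %-18s %d\n", s, x$counts[[s]]))
  cat(sprintf("  pass fraction: %.4f\n", x$pass_fraction))
  invisible(x)
}

#' Run QC on a FASTQ/FASTA file or an in-memory read set
#'
#' Reads the input (FASTQ or FASTA, optionally gzipped; format inferred
#' from the extension, `.fq`/`.fastq` meaning FASTQ), parses every read
#' and tallies the QC report. Base qualities are not used for filtering:
#' validity is defined purely by sequence identity to the design.
#'
#' @param input File path, `DNAStringSet`, or character vector of reads.
#' @param design A [siclopps_design()].
#' @inheritParams parse_reads
#' @return A list of class `qc_result` with elements `parsed` (the
#'   per-read data.frame) and `report` (a [qc_report()]).
#' @export
qc_run <- function(input, design,
                   stop_policy = c("reject", "translate_amber_as_stop")) {
  stop_policy <- match.arg(stop_policy)
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", input, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(input, format = fmt)
    # FASTQ ids may carry a description after a space; keep the id token
    names(reads) <- sub("\\s.*$", "", names(reads))
    parsed <- parse_reads(reads, design, stop_policy = stop_policy)
  } else {
    parsed <- parse_reads(input, design, stop_policy = stop_policy)
  }
  structure(list(parsed = parsed, report = qc_report(parsed)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

# TSV writer shared by all modules: '#' metadata lines, one header line.
.write_tsv <- function(df, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write parsed reads and the QC report as TSV
#'
#' @param qc A `qc_result` from [qc_run()].
#' @param parsed_path Destination TSV for per-read records.
#' @param report_path Optional destination TSV for the category counts.
#' @return `parsed_path`, invisibly.
#' @export
write_qc_tsv <- function(qc, parsed_path, report_path = NULL) {
  stopifnot(inherits(qc, "qc_result"))
  cols <- c("read_id", "status", "peptide", "extein_dna", "n6_tag",
            "non_nns")
  .write_tsv(qc$parsed[, cols], parsed_path,
             meta = paste0("sicloppsr parsed reads; total=",
                           qc$report$total_reads))
  if (!is.null(report_path)) {
    rep_df <- data.frame(status = names(qc$report$counts),
                         reads = as.integer(qc$report$counts))
    .write_tsv(rep_df, report_path,
               meta = sprintf("sicloppsr qc report; pass_fraction=%.6f",
                              qc$report$pass_fraction))
  }
  invisible(parsed_path)
}
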