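#' Assemble abundance tables into a biopanning series
#'
#' @param tables A list of `abundance_table`s, naive library first
#'   (round 0), in panning order.
#' @return A `round_series` (the validated list).
#' @export
round_series <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("a round series needs at least 2 rounds", call. = FALSE)
  ok <- vapply(tables, inherits, logical(1), "abundance_table")
  if (!all(ok)) stop("all elements must be abundance tables", call. = FALSE)
  labs <- vapply(tables, round_label, character(1))
  if (anyDuplicated(labs)) stop("round labels must be unique", call. = FALSE)
  names(tables) <- labs
  structure(tables, class = c("round_series", "list"))
}

.series_table <- function(series, round) {
  if (is.character(round)) {
    if (!round %in% names(series))
      stop("unknown round label: ", round, call. = FALSE)
    series[[round]]
  } else {
    if (round < 1L || round > length(series))
      stop("round index out of range: ", round, call. = FALSE)
    series[[round]]
  }
}

#' Default pseudo-CPM for fold-enrichment ratios
#'
#' The CPM contributed by a single read in the shallower of the two
#' rounds, `1e6 / min(total_passed)`. Adding it to numerator and
#' denominator keeps every fold finite and scales with sequencing depth.
#'
#' @param series A [round_series()].
#' @param from_round,to_round Round labels or indices.
#' @return A single pseudo-CPM value.
#' @export
default_pseudo_cpm <- function(series, from_round, to_round) {
  t1 <- total_passed(.series_table(series, from_round))
  t2 <- total_passed(.series_table(series, to_round))
  1e6 / min(t1, t2)
}

#' Fold enrichment of a peptide between two rounds
#'
#' `(cpm_to + pseudo_cpm) / (cpm_from + pseudo_cpm)`. With
#' `pseudo_cpm = 0` and the peptide absent from the source round the
#' ratio is `Inf`; the default pseudo count (see [default_pseudo_cpm()])
#' keeps all folds finite.
#'
#' @param series A [round_series()].
#' @param peptides Character vector of peptides.
#' @param from_round,to_round Round labels or indices, `from` before
#'   `to`.
#' @param pseudo_cpm Non-negative pseudo count in CPM units; `NULL`
#'   (default) uses [default_pseudo_cpm()].
#' @return Named numeric vector of fold enrichments.
#' @export
fold_enrichment <- function(series, peptides, from_round, to_round,
                            pseudo_cpm = NULL) {
  stopifnot(inherits(series, "round_series"))
  if (is.null(pseudo_cpm))
    pseudo_cpm <- default_pseudo_cpm(series, from_round, to_round)
  if (pseudo_cpm < 0) stop("pseudo_cpm must be >= 0", call. = FALSE)
  c_from <- cpm(.series_table(series, from_round), peptides)
  c_to <- cpm(.series_table(series, to_round), peptides)
  (c_to + pseudo_cpm) / (c_from + pseudo_cpm)
}

#' Classify enriched sequences
#'
#' A peptide is enriched when its raw copy number in the final round is
#' at least `min_count` and its CPM in the final round exceeds its CPM in
#' every predecessor round considered (the two rounds immediately before
#' it, i.e. pans 0 and 1 for a 2-round screen).
#'
#' @param series A [round_series()] with at least 3 rounds (naive + 2
#'   pans, or a final round with two predecessors).
#' @param min_count Minimum raw copy number in the final round
#'   (default 10).
#' @return Character vector of enriched peptides (sorted).
#' @export
classify_enriched <- function(series, min_count = 10L) {
  stopifnot(inherits(series, "round_series"))
  k <- length(series)
  if (k < 3L)
    stop("classification needs a final round with >= 2 predecessors",
         call. = FALSE)
  final <- series[[k]]
  cand <- final$peptide[final$count >= min_count]
  if (length(cand) == 0L) return(character())
  cf <- cpm(final, cand)
  c1 <- cpm(series[[k - 1L]], cand)
  c0 <- cpm(series[[k - 2L]], cand)
  sort(cand[cf > c1 & cf > c0])
}

#' Rank peptides by abundance
#'
#' Rank 1 is the most abundant peptide; ties are broken lexicographically
#' so ranks are a reproducible permutation of `1..n` (no dense/shared
#' ranks).
#'
#' @param table An `abundance_table`.
#' @return Named integer vector mapping peptide to rank.
#' @export
rank_by_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(table) == 0L) stop("cannot rank an empty table", call. = FALSE)
  o <- order(-table$count, table$peptide)
  r <- integer(nrow(table))
  r[o] <- seq_len(nrow(table))
  names(r) <- table$peptide
  r
}

#' Adjusted inverse enrichment score
#'
#' The composite hit score
#' `enr_i_adj = rank2 + w02 * enr02 + w12 * enr12`
#' combining the final-round abundance rank with weighted enrichment
#' terms from the naive library (`enr02`) and the previous round
#' (`enr12`) to the final round. Lower is better; sorting ascending
#' yields the overall rank.
#'
#' @param rank2 Integer rank(s) by final-round abundance (1 = most
#'   abundant).
#' @param enr02,enr12 Non-negative finite enrichment terms.
#' @param w02,w12 Weights (defaults 1e-4 and 1e-2).
#' @return Numeric score(s).
#' @examples
#' adjusted_inverse_enrichment(1, 10000, 50)  # 2.5
#' @export
adjusted_inverse_enrichment <- function(rank2, enr02, enr12,
                                        w02 = 1e-4, w12 = 1e-2) {
  if (any(rank2 < 1)) stop("rank2 must be >= 1", call. = FALSE)
  if (any(!is.finite(enr02)) || any(!is.finite(enr12)) ||
      any(enr02 < 0) || any(enr12 < 0))
    stop("enrichment terms must be finite and >= 0 ",
         "(use a pseudo count to cap infinite folds)", call. = FALSE)
  rank2 + w02 * enr02 + w12 * enr12
}

#' Score and rerank peptides across a biopanning series
#'
#' Builds the full cross-round record for every peptide observed in the
#' final round: per-round CPM, pairwise fold enrichments, the
#' final-round rank, the adjusted inverse enrichment score and the
#' overall rank obtained by sorting scores ascending (ties broken by
#' final-round rank, then peptide). Peptides absent from the final round
#' are never ranked.
#'
#' @param series A [round_series()] with >= 3 rounds.
#' @param min_count Passed to [classify_enriched()] for the `enriched`
#'   flag.
#' @param w02,w12 Score weights, see [adjusted_inverse_enrichment()].
#' @param pseudo_cpm Pseudo count for folds; `NULL` for the depth-aware
#'   default.
#' @param enr_interpretation How the score's enrichment terms are taken
#'   from the fold enrichments: `"fold"` (literal; large enrichment adds
#'   to the score) or `"inverse_fold"` (reciprocal; large enrichment
#'   improves the score). Both readings of the composite score are
#'   supported because its additive form rewards low values while its
#'   terms are conventionally reported as folds.
#' @return An `enrichment_table` data.frame sorted by `overall_rank`
#'   with columns `peptide`, one `cpm_<label>` per round,
#'   `raw_count_final`, `fold_01`, `fold_12`, `fold_02` (for a 3-round
#'   series), `rank2`, `enr02`, `enr12`, `enr_i_adj`, `overall_rank`,
#'   `enriched`.
#' @export
enrichment_table <- function(series, min_count = 10L,
                             w02 = 1e-4, w12 = 1e-2,
                             pseudo_cpm = NULL,
                             enr_interpretation = c("fold", "inverse_fold")) {
  stopifnot(inherits(series, "round_series"))
  enr_interpretation <- match.arg(enr_interpretation)
  k <- length(series)
  if (k < 3L)
    stop("enrichment ranking needs >= 3 rounds", call. = FALSE)
  final <- series[[k]]
  peps <- final$peptide
  if (length(peps) == 0L) stop("final round is empty", call. = FALSE)

  out <- data.frame(peptide = peps, stringsAsFactors = FALSE)
  for (i in seq_len(k))
    out[[paste0("cpm_", names(series)[i])]] <- unname(cpm(series[[i]], peps))
  out$raw_count_final <- final$count

  pairs <- rbind(cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L),
                 if (k >= 3L) c(1L, k))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    out[[sprintf("fold_%d%d", i - 1L, j - 1L)]] <-
      unname(fold_enrichment(series, peps, i, j, pseudo_cpm))
  }

  out$rank2 <- unname(rank_by_abundance(final)[peps])
  f02 <- unname(fold_enrichment(series, peps, 1L, k, pseudo_cpm))
  f12 <- unname(fold_enrichment(series, peps, k - 1L, k, pseudo_cpm))
  if (enr_interpretation == "inverse_fold") {
    f02 <- 1 / f02
    f12 <- 1 / f12
  }
  out$enr02 <- f02
  out$enr12 <- f12
  out$enr_i_adj <- adjusted_inverse_enrichment(out$rank2, f02, f12,
                                               w02 = w02, w12 = w12)
  out <- rank_overall(out)
  out$enriched <- out$peptide %in% classify_enriched(series, min_count)
  structure(out, round_labels = names(series), w02 = w02, w12 = w12,
            enr_interpretation = enr_interpretation,
            class = c("enrichment_table", "data.frame"))
}

#' Assign the overall rank by ascending score
#'
#' Reorders scored records lowest to highest `enr_i_adj` (ties broken by
#' `rank2`, then peptide) and assigns `overall_rank = 1..n`.
#'
#' @param records A data.frame with columns `peptide`, `rank2`,
#'   `enr_i_adj`.
#' @return The reordered data.frame with an `overall_rank` column.
#' @export
rank_overall <- function(records) {
  need <- c("peptide", "rank2", "enr_i_adj")
  if (!all(need %in% names(records)))
    stop("records must carry columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(records$enr_i_adj)))
    stop("all records must be scored with finite enr_i_adj", call. = FALSE)
  o <- order(records$enr_i_adj, records$rank2, records$peptide)
  records <- records[o, , drop = FALSE]
  records$overall_rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}

#' Write an enrichment table as TSV
#'
#' @param etab An `enrichment_table`.
#' @param path Destination TSV.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(etab, path) {
  stopifnot(inherits(etab, "enrichment_table"))
  .write_tsv(as.data.frame(etab), path,
             meta = c(paste0("rounds=", paste(attr(etab, "round_labels"),
                                              collapse = ",")),
                      sprintf("w02=%g w12=%g interpretation=%s",
                              attr(etab, "w02"), attr(etab, "w12"),
                              attr(etab, "enr_interpretation"))))
  invisible(path)
}
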