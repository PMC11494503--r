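#' Run the full screening-analysis pipeline
#'
#' Orchestrates qc -> count -> enrich -> motifs over per-round FASTQ
#' files: per round, a parsed-read TSV, QC report, abundance and
#' redundancy TSVs; across rounds, the enrichment table with the overall
#' reranking; and for the top `top_n` peptides by overall rank, a
#' homology-neighbor table, motif counts, a logo matrix and a one-hot
#' cluster tree in Newick format. Inputs are validated before any output
#' is written, and the composition equals running each stage by hand on
#' the same inputs (no hidden state).
#'
#' @param fastq Character vector of per-round FASTQ/FASTA paths, naive
#'   round first.
#' @param labels Round labels, same length as `fastq` (default
#'   `pan0..panK`).
#' @param design A [siclopps_design()]; default [default_design()].
#' @param out_dir Output directory, created if missing.
#' @param min_count,w02,w12,pseudo_cpm,enr_interpretation Passed to
#'   [enrichment_table()].
#' @param motif_patterns Character vector of motif pattern strings to
#'   count among the enriched set (default the screen's consensus
#'   queries `CRX(L/V)XL` and `CRX(L/V/F/Y)XL`).
#' @param top_n Number of top-ranked peptides for the motif/cluster
#'   stage (default 100).
#' @param neighbor_threshold Homology threshold for the neighbor table
#'   (default 0.8).
#' @param linkage Linkage for the cluster tree (default `"average"`).
#' @param stop_policy Passed to [qc_run()].
#' @return Invisibly, a list with the per-stage objects (`qc`,
#'   `tables`, `series`, `enrichment`, `neighbors`, `motif_counts`,
#'   `logo`, `tree`) and `paths` (every file written).
#' @export
run_pipeline <- function(fastq, labels = NULL,
                         design = default_design(),
                         out_dir = "siclopps_out",
                         min_count = 10L, w02 = 1e-4, w12 = 1e-2,
                         pseudo_cpm = NULL,
                         enr_interpretation = c("fold", "inverse_fold"),
                         motif_patterns = c("CRX(L/V)XL", "CRX(L/V/F/Y)XL"),
                         top_n = 100L,
                         neighbor_threshold = 0.8,
                         linkage = c("average", "complete", "ward"),
                         stop_policy = c("reject",
                                         "translate_amber_as_stop")) {
  enr_interpretation <- match.arg(enr_interpretation)
  linkage <- match.arg(linkage)
  stop_policy <- match.arg(stop_policy)
  if (is.null(labels)) labels <- paste0("pan", seq_along(fastq) - 1L)
  if (length(labels) != length(fastq) || anyDuplicated(labels))
    stop("labels must be unique and match the FASTQ files", call. = FALSE)
  missing <- fastq[!file.exists(fastq)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  paths <- list()
  qc <- tables <- vector("list", length(fastq))
  names(qc) <- names(tables) <- labels
  for (i in seq_along(fastq)) {
    qc[[i]] <- qc_run(fastq[i], design, stop_policy = stop_policy)
    p_parsed <- file.path(out_dir, paste0("parsed_", labels[i], ".tsv"))
    p_report <- file.path(out_dir, paste0("qc_", labels[i], ".tsv"))
    write_qc_tsv(qc[[i]], p_parsed, p_report)
    tables[[i]] <- count_peptides(qc[[i]]$parsed, labels[i])
    p_ab <- file.path(out_dir, paste0("abundance_", labels[i], ".tsv"))
    p_red <- file.path(out_dir, paste0("redundancy_", labels[i], ".tsv"))
    write_abundance_tsv(tables[[i]], p_ab, p_red)
    paths[[labels[i]]] <- c(parsed = p_parsed, qc = p_report,
                            abundance = p_ab, redundancy = p_red)
  }

  series <- round_series(tables)
  etab <- enrichment_table(series, min_count = min_count,
                           w02 = w02, w12 = w12, pseudo_cpm = pseudo_cpm,
                           enr_interpretation = enr_interpretation)
  p_enr <- file.path(out_dir, "enrichment.tsv")
  write_enrichment_tsv(etab, p_enr)
  paths$enrichment <- p_enr

  top <- utils::head(etab$peptide, top_n)
  enriched <- etab$peptide[etab$enriched]
  nb_pool <- if (length(enriched) >= 2L) enriched else etab$peptide
  neighbors <- neighbor_table(top, nb_pool, threshold = neighbor_threshold)
  p_nb <- file.path(out_dir, "neighbors_top.tsv")
  .write_tsv(neighbors, p_nb,
             meta = sprintf("homology neighbors; threshold=%g pool=%d",
                            neighbor_threshold, length(nb_pool)))
  paths$neighbors <- p_nb

  mc <- data.frame(
    pattern = motif_patterns,
    unique_matches = vapply(motif_patterns,
                            function(p) motif_count(nb_pool, p), integer(1)),
    stringsAsFactors = FALSE
  )
  p_mc <- file.path(out_dir, "motif_counts.tsv")
  .write_tsv(mc, p_mc, meta = sprintf("motif counts over %d peptides",
                                      length(nb_pool)))
  paths$motif_counts <- p_mc

  logo <- logo_matrix(top)
  p_logo <- file.path(out_dir, "logo_top.tsv")
  .write_tsv(data.frame(position = rownames(logo), logo,
                        check.names = FALSE), p_logo,
             meta = sprintf("position frequency matrix of top %d peptides",
                            length(top)))
  paths$logo <- p_logo

  tree <- NULL
  if (length(unique(top)) >= 2L) {
    tree <- hcluster(top, linkage = linkage)
    p_tree <- file.path(out_dir, "tree_top.nwk")
    write_tree_newick(tree, p_tree)
    paths$tree <- p_tree
  }

  invisible(list(qc = qc, tables = tables, series = series,
                 enrichment = etab, neighbors = neighbors,
                 motif_counts = mc, logo = logo, tree = tree,
                 paths = paths))
}
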