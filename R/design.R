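#' SICLOPPS library design
#'
#' Describes the architecture of a SICLOPPS amplicon read: a short
#' randomized tag (N6), the 3' end of the C-intein coding sequence
#' (upstream anchor), the extein coding region (one fixed Cys codon
#' followed by `n_variable` degenerate codons), and the 5' start of the
#' N-intein coding sequence (downstream anchor). The parser and the read
#' simulator share this object so that simulated reads are parseable by
#' construction.
#'
#' @param upstream_anchor DNA string; fixed sequence immediately
#'   preceding the extein (C-intein side).
#' @param downstream_anchor DNA string; fixed sequence immediately
#'   following the extein (N-intein side).
#' @param n6_length Integer, length in bases of the randomized tag at the
#'   read start (diversity insert for cluster calling). Default 6.
#' @param fixed_first_codons Character vector of codons accepted for the
#'   invariant first cysteine. Default `c("TGT", "TGC")`.
#' @param n_variable Integer, number of degenerate codons after the fixed
#'   Cys. Default 5 (a CX5 library).
#' @param variable_codon_scheme Degenerate codon scheme for the variable
#'   positions. Only `"NNS"` is supported.
#' @param max_anchor_mismatch Integer, substitution budget allowed when
#'   locating each anchor in a read. Default 1.
#'
#' @return An object of class `siclopps_design`.
#' @examples
#' d <- siclopps_design("GGTTCTCATAACGCTCGCGAT", "TGCTTAAGTACCGGTGAAGCT")
#' extein_length(d)        # 18 bases
#' library_diversity(d)    # 3.2e6 distinct peptides
#' @export
siclopps_design <- function(upstream_anchor,
                            downstream_anchor,
                            n6_length = 6L,
                            fixed_first_codons = c("TGT", "TGC"),
                            n_variable = 5L,
                            variable_codon_scheme = "NNS",
                            max_anchor_mismatch = 1L) {
  upstream_anchor <- toupper(as.character(upstream_anchor))
  downstream_anchor <- toupper(as.character(downstream_anchor))
  .check_dna <- function(x, what) {
    if (length(x) != 1L || is.na(x) || nchar(x) == 0L)
      stop(what, " must be a single nonempty DNA string", call. = FALSE)
    if (grepl("[^ACGT]", x))
      stop(what, " contains characters outside {A,C,G,T}", call. = FALSE)
  }
  .check_dna(upstream_anchor, "upstream_anchor")
  .check_dna(downstream_anchor, "downstream_anchor")
  if (identical(upstream_anchor, downstream_anchor))
    stop("upstream and downstream anchors must differ", call. = FALSE)
  fixed_first_codons <- toupper(fixed_first_codons)
  if (!all(nchar(fixed_first_codons) == 3L) ||
      any(grepl("[^ACGT]", fixed_first_codons)))
    stop("fixed_first_codons must be DNA triplets", call. = FALSE)
  n6_length <- as.integer(n6_length)
  n_variable <- as.integer(n_variable)
  max_anchor_mismatch <- as.integer(max_anchor_mismatch)
  if (n6_length < 0L) stop("n6_length must be >= 0", call. = FALSE)
  if (n_variable < 1L) stop("n_variable must be >= 1", call. = FALSE)
  shorter <- min(nchar(upstream_anchor), nchar(downstream_anchor))
  if (max_anchor_mismatch < 0L || max_anchor_mismatch >= shorter)
    stop("max_anchor_mismatch must be in [0, length of shorter anchor)",
         call. = FALSE)
  structure(
    list(
      upstream_anchor = upstream_anchor,
      downstream_anchor = downstream_anchor,
      n6_length = n6_length,
      fixed_first_codons = fixed_first_codons,
      n_variable = n_variable,
      variable_codon_scheme = variable_codon_scheme,
      max_anchor_mismatch = max_anchor_mismatch
    ),
    class = "siclopps_design"
  )
}

#' @export
print.siclopps_design <- function(x, ...) {
  cat("SICLOPPS library design\n")
  cat("  read layout : [N", x$n6_length, "][", x$upstream_anchor,
      "][extein ", extein_length(x), " nt][", x$downstream_anchor, "]\n",
      sep = "")
  cat("  extein      : ", paste(x$fixed_first_codons, collapse = "/"),
      " + ", x$n_variable, "x ", x$variable_codon_scheme, " codons\n",
      sep = "")
  cat("  anchor mismatch budget:", x$max_anchor_mismatch, "\n")
  invisible(x)
}

#' Extein length in bases
#'
#' @param design A [siclopps_design()].
#' @return Integer: `3 * (1 + n_variable)` (18 at CX5 defaults).
#' @export
extein_length <- function(design) {
  stopifnot(inherits(design, "siclopps_design"))
  3L * (1L + design$n_variable)
}

#' Peptide length encoded by a design
#' @param design A [siclopps_design()].
#' @return Integer: `1 + n_variable`.
#' @export
peptide_length <- function(design) {
  stopifnot(inherits(design, "siclopps_design"))
  1L + design$n_variable
}

#' The NNS codon set
#'
#' NNS codons have any base at positions 1-2 and G or C at position 3.
#' The 32-member set encodes all 20 canonical amino acids; it retains the
#' amber stop (TAG) but excludes ochre (TAA) and opal (TGA).
#'
#' @return Character vector of 32 codons.
#' @examples
#' length(nns_codons())      # 32
#' "TAG" %in% nns_codons()   # TRUE  (amber survives the S constraint)
#' "TAA" %in% nns_codons()   # FALSE
#' @export
nns_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(as.vector(outer(b, b, paste0)), c("G", "C"), paste0))
}

# codon -> amino acid table under the standard genetic code ("*" = stop)
.codon_table <- function() Biostrings::GENETIC_CODE

#' Translate an extein coding sequence
#'
#' Translates the cropped extein DNA under the standard genetic code and
#' applies the library's validity rules: the first codon must encode the
#' invariant Cys, no base may be ambiguous, and (under
#' `stop_policy = "reject"`) no variable codon may be a stop. Reads
#' failing any rule translate to `NA`; the reason is available from
#' [translate_extein_detail()].
#'
#' @param extein_dna Character vector of extein sequences, each of length
#'   `3 * (1 + n_variable)` over `{A,C,G,T,N}`.
#' @param design A [siclopps_design()].
#' @param stop_policy `"reject"` (default): any stop codon in a variable
#'   position invalidates the read. `"translate_amber_as_stop"`: stops are
#'   rendered as `"*"` in the peptide (for amber-suppressor hosts one can
#'   then handle `*` downstream).
#' @return Character vector of peptides, `NA` where rejected. A sequence
#'   whose length is not `3 * (1 + n_variable)` is a structural error and
#'   raises a condition rather than returning `NA`.
#' @examples
#' d <- siclopps_design("GGTTCTCATAACGCTCGCGAT", "TGCTTAAGTACCGGTGAAGCT")
#' translate_extein("TGTGCGGCGGCGGCGGCG", d)  # "CAAAAA"
#' translate_extein("TGTCTGCTGTTTGTGTAT", d)  # "CLLFVY"
#' translate_extein("TGTCTGCTGTTTGTGTAG", d)  # NA (amber in variable codon)
#' @export
translate_extein <- function(extein_dna, design,
                             stop_policy = c("reject",
                                             "translate_amber_as_stop")) {
  res <- translate_extein_detail(extein_dna, design, stop_policy)
  res$peptide
}

#' Translate exteins with per-read QC detail
#'
#' Vectorized workhorse behind [translate_extein()] and the read parser.
#'
#' @inheritParams translate_extein
#' @return A data.frame with columns `peptide` (NA where invalid),
#'   `status` (one of `pass`, `ambiguous_base`, `bad_first_residue`,
#'   `stop_codon`) and `non_nns` (logical: some variable codon has A/T at
#'   its third base — flagged, not rejected).
#' @export
translate_extein_detail <- function(extein_dna, design,
                                    stop_policy = c("reject",
                                                    "translate_amber_as_stop")) {
  stopifnot(inherits(design, "siclopps_design"))
  stop_policy <- match.arg(stop_policy)
  extein_dna <- toupper(as.character(extein_dna))
  elen <- extein_length(design)
  n <- length(extein_dna)
  if (n == 0L)
    return(data.frame(peptide = character(), status = character(),
                      non_nns = logical(), stringsAsFactors = FALSE))
  bad_len <- nchar(extein_dna) != elen
  if (any(bad_len))
    stop("extein length must be ", elen, " bases (multiple of 3); ",
         "offending index: ", which(bad_len)[1L], call. = FALSE)
  if (any(grepl("[^ACGTN]", extein_dna)))
    stop("extein sequences may contain only A, C, G, T or N", call. = FALSE)

  np <- peptide_length(design)
  gc <- .codon_table()
  codons <- matrix("", nrow = n, ncol = np)
  for (j in seq_len(np)) {
    codons[, j] <- substr(extein_dna, 3L * j - 2L, 3L * j)
  }
  aa <- matrix(gc[codons], nrow = n, ncol = np)  # NA for codons with N

  ambiguous <- rowSums(is.na(aa)) > 0L
  first_ok <- codons[, 1L] %in% design$fixed_first_codons
  var_aa <- aa[, -1L, drop = FALSE]
  has_stop <- rowSums(var_aa == "*", na.rm = TRUE) > 0L
  third <- substr(as.vector(codons[, -1L, drop = FALSE]), 3L, 3L)
  non_nns <- rowSums(matrix(third %in% c("A", "T"), nrow = n)) > 0L

  status <- rep("pass", n)
  if (stop_policy == "reject") status[has_stop] <- "stop_codon"
  status[!first_ok] <- "bad_first_residue"
  status[ambiguous] <- "ambiguous_base"

  peptide <- rep(NA_character_, n)
  ok <- status == "pass"
  if (any(ok)) {
    pep <- aa[ok, , drop = FALSE]
    peptide[ok] <- apply(pep, 1L, paste0, collapse = "")
  }
  data.frame(peptide = peptide, status = status, non_nns = non_nns,
             stringsAsFactors = FALSE)
}

#' Theoretical peptide diversity of the library
#'
#' Under the NNS scheme every variable position encodes all 20 canonical
#' amino acids, so a design with one fixed residue and `n_variable`
#' randomized residues spans `20^n_variable` distinct peptides —
#' 3,200,000 for the CX5 default.
#'
#' @param design A [siclopps_design()].
#' @return Number of distinct peptides.
#' @export
library_diversity <- function(design) {
  stopifnot(inherits(design, "siclopps_design"))
  if (!identical(design$variable_codon_scheme, "NNS"))
    stop("unsupported codon scheme: ", design$variable_codon_scheme,
         call. = FALSE)
  20^design$n_variable
}

#' Read a library design from a YAML config file
#'
#' Keys mirror the arguments of [siclopps_design()]; missing keys take
#' the defaults. The packaged CX5 design with synthetic anchors is at
#' `system.file("extdata", "cx5_design.yml", package = "sicloppsr")`.
#'
#' @param path Path to a YAML file.
#' @return A [siclopps_design()].
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(siclopps_design))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown design keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(siclopps_design, cfg)
}

#' The packaged default CX5 design
#'
#' Synthetic intein anchors are shipped for testing and simulation; real
#' datasets require the anchors of the actual SICLOPPS construct.
#'
#' @return A [siclopps_design()].
#' @export
default_design <- function() {
  read_design(system.file("extdata", "cx5_design.yml",
                          package = "sicloppsr", mustWork = TRUE))
}
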