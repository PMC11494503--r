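# Shared fixtures: a small CX5 design with synthetic anchors and read
# constructors used across the suite.

test_design <- function(max_anchor_mismatch = 1L) {
  siclopps_design(
    upstream_anchor = "GGTTCTCATAACGCTCGCGAT",
    downstream_anchor = "TGCTTAAGTACCGGTGAAGCT",
    max_anchor_mismatch = max_anchor_mismatch
  )
}

# assemble a well-formed read around a given extein
make_read <- function(extein, design = test_design(), n6 = "ACGTAC") {
  paste0(n6, design$upstream_anchor, extein, design$downstream_anchor)
}

# one valid NNS encoding per peptide, first codon TGT; deterministic
# (always the alphabetically first NNS codon per residue)
encode_peptide <- function(peptide) {
  gc <- Biostrings::GENETIC_CODE
  nns <- nns_codons()
  nns <- sort(nns[gc[nns] != "*"])
  first <- vapply(split(nns, gc[nns]), `[[`, character(1), 1L)
  res <- strsplit(peptide, "")[[1]][-1]
  paste0("TGT", paste0(first[res], collapse = ""))
}

# abundance table built directly from a named count vector
make_table <- function(counts, label) {
  count_peptides(rep(names(counts), counts), label)
}

random_peptides <- function(n, len = 6L) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    paste0("C", paste0(sample(aa, len - 1L, replace = TRUE), collapse = ""))
  }, character(1))
}

# brute-force greedy agglomeration oracle: cluster-to-cluster distances
# are recomputed from the leaf-pair distance matrix at every step (no
# Lance-Williams updates), with the same documented tie-break (smallest
# minimal-leaf-index pair). Returns hclust-style merge and height.
oracle_agglomerate <- function(dmat, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))      # leaf index sets, in creation order
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- Inf; bi <- bj <- NA; bkey <- c(Inf, Inf)
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        pair_d <- dmat[clusters[[i]], clusters[[j]], drop = FALSE]
        dd <- if (linkage == "average") mean(pair_d) else max(pair_d)
        key_new <- c(min(clusters[[i]]), min(clusters[[j]]))
        if (dd < best ||
            (dd == best &&
             (key_new[1] < bkey[1] ||
              (key_new[1] == bkey[1] && key_new[2] < bkey[2])))) {
          best <- dd; bi <- i; bj <- j; bkey <- key_new
        }
      }
    }
    merge[step, ] <- c(ids[[bi]], ids[[bj]])
    height[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    ids[[bi]] <- step
    clusters[[bj]] <- NULL
    ids <- ids[-bj]
  }
  list(merge = merge, height = height)
}
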