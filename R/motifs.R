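#' Variable-position identity between two peptides
#'
#' Fraction of matching residues among the variable positions, excluding
#' the first `n_fixed` residues (the invariant Cys of a CX5 library
#' carries no information and is excluded by default). Two hexapeptides
#' differing at exactly one of the five variable positions share 0.8
#' identity — the "4 out of 5 overlap" homology threshold.
#'
#' @param p1,p2 Peptides of equal length.
#' @param n_fixed Number of leading fixed residues to exclude
#'   (default 1).
#' @return Fraction in `[0, 1]`; symmetric in its arguments.
#' @examples
#' variable_identity("CRTYIL", "CRVYIL")  # 0.8
#' @export
variable_identity <- function(p1, p2, n_fixed = 1L) {
  if (nchar(p1) != nchar(p2))
    stop("peptides must have equal length", call. = FALSE)
  if (nchar(p1) <= n_fixed)
    stop("no variable positions to compare", call. = FALSE)
  a <- strsplit(p1, "")[[1]][-seq_len(n_fixed)]
  b <- strsplit(p2, "")[[1]][-seq_len(n_fixed)]
  mean(a == b)
}

#' Homology neighborhood of a peptide
#'
#' All pool members (other than the query itself) sharing at least
#' `threshold` variable-position identity with the query — at the 0.8
#' default, hexapeptides matching at >= 4 of 5 variable positions.
#'
#' @param peptide Query peptide.
#' @param pool Character vector of peptides, same length as the query.
#' @param threshold Identity threshold in `[0, 1]` (default 0.8).
#' @param n_fixed Leading fixed residues excluded from identity.
#' @return Character vector of neighbors (sorted, unique).
#' @export
homology_neighbors <- function(peptide, pool, threshold = 0.8,
                               n_fixed = 1L) {
  pool <- unique(as.character(pool))
  pool <- setdiff(pool, peptide)
  if (length(pool) == 0L) return(character())
  id <- vapply(pool, variable_identity, numeric(1), p1 = peptide,
               n_fixed = n_fixed)
  sort(pool[id >= threshold])
}

#' Tabulate homology neighbor counts over a pool
#'
#' For each query peptide, the number (and identity) of pool members
#' within the homology threshold — the per-hit "related sequences"
#' statistic.
#'
#' @param queries Character vector of query peptides.
#' @inheritParams homology_neighbors
#' @return A data.frame with columns `peptide`, `n_neighbors`,
#'   `neighbors` (comma-separated).
#' @export
neighbor_table <- function(queries, pool, threshold = 0.8, n_fixed = 1L) {
  rows <- lapply(queries, function(q) {
    nb <- homology_neighbors(q, pool, threshold, n_fixed)
    data.frame(peptide = q, n_neighbors = length(nb),
               neighbors = paste(nb, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Parse a motif pattern string
#'
#' Accepts both bracket notation (`"CRX[LVFY]XL"`) and the slash
#' notation common in screening papers (`"CRX(L/V/F/Y)XL"`). `X` is a
#' wildcard over all 20 canonical amino acids; a bare letter fixes the
#' position; a group allows any of its members.
#'
#' @param pattern Pattern string.
#' @return A `motif_pattern`: list of per-position allowed-residue sets.
#' @examples
#' p <- motif_pattern("CRX(L/V)XL")
#' motif_match(c("CRTLIL", "CAAAAA"), p)  # TRUE FALSE
#' @export
motif_pattern <- function(pattern) {
  if (inherits(pattern, "motif_pattern")) return(pattern)
  s <- gsub("\\s", "", toupper(pattern))
  sets <- list()
  i <- 1L
  while (i <= nchar(s)) {
    ch <- substr(s, i, i)
    if (ch %in% c("[", "(")) {
      close <- if (ch == "[") "]" else ")"
      j <- regexpr(close, substr(s, i + 1L, nchar(s)), fixed = TRUE)
      if (j < 0L) stop("unclosed group in pattern: ", pattern, call. = FALSE)
      grp <- substr(s, i + 1L, i + j - 1L)
      grp <- strsplit(gsub("/", "", grp), "")[[1]]
      if (!length(grp) || !all(grp %in% .AA20))
        stop("invalid group in pattern: ", pattern, call. = FALSE)
      sets[[length(sets) + 1L]] <- unique(grp)
      i <- i + j + 1L
    } else if (ch == "X") {
      sets[[length(sets) + 1L]] <- .AA20
      i <- i + 1L
    } else if (ch %in% .AA20) {
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in pattern: ", pattern,
           call. = FALSE)
    }
  }
  structure(sets, pattern = pattern, class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("Motif pattern:", attr(x, "pattern"), "(", length(x), "positions )\n")
  invisible(x)
}

#' Match peptides against a motif pattern
#'
#' @param peptides Character vector of peptides whose length equals the
#'   pattern length.
#' @param pattern A [motif_pattern()] or pattern string.
#' @return Logical vector: `TRUE` where every residue lies in its
#'   position's allowed set.
#' @export
motif_match <- function(peptides, pattern) {
  pattern <- motif_pattern(pattern)
  L <- length(pattern)
  if (length(peptides) == 0L) return(logical())
  if (any(nchar(peptides) != L))
    stop("peptide length does not match pattern length ", L, call. = FALSE)
  ok <- rep(TRUE, length(peptides))
  for (j in seq_len(L)) {
    ok <- ok & substr(peptides, j, j) %in% pattern[[j]]
  }
  ok
}

#' Count unique pool members matching a motif
#'
#' @param pool Character vector of peptides.
#' @inheritParams motif_match
#' @return Integer count of unique matching peptides.
#' @export
motif_count <- function(pool, pattern) {
  pool <- unique(as.character(pool))
  if (length(pool) == 0L) return(0L)
  sum(motif_match(pool, pattern))
}

#' Position frequency matrix for a sequence logo
#'
#' @param sequences Nonempty character vector of equal-length peptides.
#' @return A `positions x 20` matrix of residue frequencies; every row
#'   sums to 1.
#' @export
logo_matrix <- function(sequences) {
  sequences <- as.character(sequences)
  if (length(sequences) == 0L)
    stop("logo_matrix needs at least one sequence", call. = FALSE)
  L <- unique(nchar(sequences))
  if (length(L) != 1L)
    stop("sequences must have equal length", call. = FALSE)
  m <- matrix(0, nrow = L, ncol = length(.AA20),
              dimnames = list(paste0("pos", seq_len(L)), .AA20))
  for (j in seq_len(L)) {
    t <- table(factor(substr(sequences, j, j), levels = .AA20))
    m[j, ] <- as.numeric(t) / length(sequences)
  }
  m
}

#' One-hot encode peptides
#'
#' Each variable position becomes a 20-length indicator block (alphabet
#' order ACDEFGHIKLMNPQRSTVWY); the leading fixed residue is excluded by
#' default since it is invariant across a CX5 library. A hexapeptide
#' maps to a 100-bit vector with exactly 5 ones.
#'
#' @param peptides Character vector of peptides.
#' @param n_fixed Leading residues to exclude (default 1; 0 to encode
#'   the full sequence).
#' @return A binary matrix, one row per peptide, `20 * n_encoded`
#'   columns.
#' @export
onehot <- function(peptides, n_fixed = 1L) {
  peptides <- as.character(peptides)
  L <- unique(nchar(peptides))
  if (length(L) != 1L)
    stop("peptides must have equal length", call. = FALSE)
  pos <- seq.int(n_fixed + 1L, L)
  m <- matrix(0L, nrow = length(peptides), ncol = 20L * length(pos))
  colnames(m) <- as.vector(outer(.AA20, pos,
                                 function(a, p) paste0("p", p, "_", a)))
  for (k in seq_along(pos)) {
    res <- substr(peptides, pos[k], pos[k])
    idx <- match(res, .AA20)
    if (anyNA(idx))
      stop("non-canonical residue in peptide: ",
           peptides[which(is.na(idx))[1L]], call. = FALSE)
    m[cbind(seq_along(peptides), (k - 1L) * 20L + idx)] <- 1L
  }
  rownames(m) <- peptides
  m
}

#' Pairwise peptide distances
#'
#' `hamming_onehot`: Hamming distance between one-hot encodings (twice
#' the number of mismatching variable positions). `euclid_onehot`: the
#' Euclidean counterpart (`sqrt` of the Hamming distance on binary
#' vectors). `blosum62`: score-derived distance
#' `sum over variable positions of (S(x,x) + S(y,y))/2 - S(x,y)` with S
#' the BLOSUM62 substitution matrix; zero on identical peptides,
#' symmetric, larger for substitutions between dissimilar residues.
#'
#' @param peptides Character vector of equal-length peptides.
#' @param metric One of `"hamming_onehot"`, `"euclid_onehot"`,
#'   `"blosum62"`.
#' @param n_fixed Leading fixed residues excluded from all metrics.
#' @return A `dist` object over the peptides.
#' @export
peptide_dist <- function(peptides,
                         metric = c("hamming_onehot", "euclid_onehot",
                                    "blosum62"),
                         n_fixed = 1L) {
  metric <- match.arg(metric)
  peptides <- as.character(peptides)
  if (metric %in% c("hamming_onehot", "euclid_onehot")) {
    oh <- onehot(peptides, n_fixed = n_fixed)
    d <- stats::dist(oh, method = "manhattan")  # = Hamming on binaries
    if (metric == "euclid_onehot") d <- sqrt(d)
  } else {
    S <- .blosum62()
    L <- unique(nchar(peptides))
    if (length(L) != 1L)
      stop("peptides must have equal length", call. = FALSE)
    pos <- seq.int(n_fixed + 1L, L)
    n <- length(peptides)
    res <- matrix(unlist(lapply(pos, function(p) substr(peptides, p, p))),
                  nrow = n)
    if (!all(res %in% .AA20))
      stop("non-canonical residue: BLOSUM62 distances are defined over ",
           "the 20-letter alphabet", call. = FALSE)
    dm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        x <- res[i, ]; y <- res[j, ]
        dm[i, j] <- sum((S[cbind(x, x)] + S[cbind(y, y)]) / 2 -
                          S[cbind(x, y)])
      }
    }
    d <- stats::as.dist(dm)
  }
  attr(d, "Labels") <- peptides
  d
}

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Deterministic agglomerative clustering of peptides
#'
#' Builds a binary merge tree over peptides by agglomerative clustering
#' on one-hot (or BLOSUM62) distances. Unlike generic implementations,
#' the merge order under tied distances is fully specified: among
#' equal-distance pairs the pair whose member clusters contain the
#' smallest original indices merges first, so the tree is reproducible
#' across platforms.
#'
#' @param peptides Character vector (>= 2, duplicates allowed; each
#'   occurrence is a leaf).
#' @param linkage `"average"` (default), `"complete"` or `"ward"`
#'   (Ward's minimum-variance update on squared distances).
#' @param metric Passed to [peptide_dist()].
#' @param n_fixed Leading fixed residues excluded from distances.
#' @return An object of classes `peptide_hclust` and `hclust` (usable
#'   with [stats::cutree()], [ape::as.phylo()], `plot()`).
#' @export
hcluster <- function(peptides,
                     linkage = c("average", "complete", "ward"),
                     metric = c("hamming_onehot", "euclid_onehot",
                                "blosum62"),
                     n_fixed = 1L) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  peptides <- as.character(peptides)
  if (length(peptides) < 2L)
    stop("clustering needs at least 2 peptides", call. = FALSE)
  d <- peptide_dist(peptides, metric = metric, n_fixed = n_fixed)
  .agglomerate(d, linkage = linkage, labels = peptides)
}

#' BLOSUM62 distance tree of peptides
#'
#' Convenience wrapper: [hcluster()] with the BLOSUM62 score-derived
#' distance, the substitution-aware analogue of the one-hot tree used
#' for relating closely homologous hits.
#'
#' @inheritParams hcluster
#' @return A `peptide_hclust` tree.
#' @export
blosum_tree <- function(peptides,
                        linkage = c("average", "complete", "ward"),
                        n_fixed = 1L) {
  hcluster(peptides, linkage = match.arg(linkage), metric = "blosum62",
           n_fixed = n_fixed)
}

# Agglomerative clustering with an explicit tie-break: among pairs at
# the minimal distance, merge the one with the smallest (i, j) cluster
# indices in creation order. Cluster-to-cluster distances follow the
# Lance-Williams updates for average / complete / ward linkage.
.agglomerate <- function(d, linkage, labels) {
  n <- attr(d, "Size")
  dm <- as.matrix(d)
  diag(dm) <- Inf
  if (linkage == "ward") dm <- dm^2
  size <- rep(1L, n)
  id <- -seq_len(n)              # hclust convention: negatives = leaves
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    sub <- dm[active, active, drop = FALSE]
    best <- min(sub)
    w <- which(sub == best, arr.ind = TRUE)
    w <- w[w[, 1L] < w[, 2L], , drop = FALSE]
    w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE]  # smallest-index pair
    i <- active[w[1L, 1L]]
    j <- active[w[1L, 2L]]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- if (linkage == "ward") sqrt(best) else best

    others <- setdiff(active, c(i, j))
    ni <- size[i]; nj <- size[j]
    for (k in others) {
      dm[i, k] <- dm[k, i] <- switch(
        linkage,
        average = (ni * dm[i, k] + nj * dm[j, k]) / (ni + nj),
        complete = max(dm[i, k], dm[j, k]),
        ward = {
          nk <- size[k]
          ((ni + nk) * dm[i, k] + (nj + nk) * dm[j, k] -
             nk * dm[i, j]) / (ni + nj + nk)
        }
      )
    }
    size[i] <- ni + nj
    id[i] <- step
    active <- setdiff(active, j)
  }

  structure(
    list(merge = merge, height = height,
         order = .leaf_order(merge, n),
         labels = labels, method = linkage,
         dist.method = "peptide", call = match.call()),
    class = c("peptide_hclust", "hclust")
  )
}

# left-to-right leaf order by recursive traversal of the merge matrix
.leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}

#' Cut a cluster tree into k flat groups
#'
#' Removes the `k - 1` highest merges, yielding exactly `k` groups.
#'
#' @param tree A tree from [hcluster()] / [blosum_tree()].
#' @param k Number of groups, `1 <= k <=` leaf count.
#' @return Integer vector of group memberships named by peptide.
#' @export
flat_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]", call. = FALSE)
  stats::cutree(tree, k = k)
}

#' Export a cluster tree in Newick format
#'
#' Branch lengths are derived from merge heights (via
#' [ape::as.phylo()]), so any tree viewer can render the dendrogram,
#' including circular layouts.
#'
#' @param tree A tree from [hcluster()] / [blosum_tree()].
#' @param path Destination file; `NULL` returns the Newick string.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_tree_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  # as.phylo requires unique labels; disambiguate duplicates
  t2 <- tree
  t2$labels <- make.unique(t2$labels, sep = "_dup")
  phy <- ape::as.phylo(t2)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
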