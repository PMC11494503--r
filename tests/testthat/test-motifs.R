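test_that("variable-position identity excludes the fixed Cys", {
  expect_equal(variable_identity("CRTYIL", "CRVYIL"), 0.8)
  expect_equal(variable_identity("CRTYIL", "CRTYIL"), 1.0)
  expect_equal(variable_identity("CAAAAA", "CLLFVY"), 0.0)
  expect_equal(variable_identity("CRTYIL", "CRVYIL"),
               variable_identity("CRVYIL", "CRTYIL"))
  expect_error(variable_identity("CRTYIL", "CRTY"), "equal length")
})

test_that("homology neighborhoods honor the 4-of-5 threshold and symmetry", {
  expect_setequal(
    homology_neighbors("CRTYIL", c("CRVYIL", "CRTYIV", "CAAAAA")),
    c("CRVYIL", "CRTYIV"))
  expect_equal(homology_neighbors("CRTYIL", character()), character())
  expect_false("CRTYIL" %in%
                 homology_neighbors("CRTYIL", c("CRTYIL", "CRVYIL")))

  # symmetry as a relation over random pools
  set.seed(13)
  pool <- unique(random_peptides(40))
  for (p in pool[1:10]) {
    for (q in homology_neighbors(p, pool)) {
      expect_true(p %in% homology_neighbors(q, pool))
    }
  }

  nb <- neighbor_table(c("CRTYIL", "CAAAAA"),
                       c("CRTYIL", "CRVYIL", "CRTYIV", "CAAAAA"))
  expect_equal(nb$n_neighbors, c(2L, 0L))
})

test_that("motif patterns parse both bracket and slash notation", {
  p1 <- motif_pattern("CRX[LVFY]XL")
  p2 <- motif_pattern("CRX(L/V/F/Y)XL")
  expect_length(p1, 6L)
  expect_equal(unclass(p1)[4], unclass(p2)[4])
  expect_setequal(p1[[4]], c("L", "V", "F", "Y"))
  expect_length(p1[[3]], 20L)
  expect_error(motif_pattern("CRX[LV"), "unclosed")
  expect_error(motif_pattern("CR1XXL"), "unexpected")
})

test_that("motif matching and counting follow per-position set membership", {
  pat <- "CRX[LVFY]XL"
  expect_true(motif_match("CRTYIL", pat))
  expect_true(motif_match("CRLYVL", pat))
  expect_false(motif_match("CAAAAA", pat))
  expect_error(motif_match("CRTY", pat), "length")
  expect_equal(motif_count(c("CRTYIL", "CRLYVL", "CAAAAA"), pat), 2L)
  expect_equal(motif_count(character(), pat), 0L)
  # an all-wildcard pattern matches the whole pool (duplicates collapse)
  pool <- c(random_peptides(25), "CRTYIL", "CRTYIL")
  expect_equal(motif_count(pool, "XXXXXX"), length(unique(pool)))
})

test_that("logo matrices are position frequency tables", {
  m <- logo_matrix(c("CRTYIL", "CRVYIL"))
  expect_equal(dim(m), c(6L, 20L))
  expect_equal(m["pos2", "R"], 1.0)
  expect_equal(m["pos3", "T"], 0.5)
  expect_equal(m["pos3", "V"], 0.5)
  expect_equal(unname(rowSums(m)), rep(1, 6))
  expect_error(logo_matrix(character()), "at least one")

  # a pool matching a fixed-position pattern concentrates that row
  pool <- c("CRTYIL", "CRLYVL", "CRIFIL")
  lm <- logo_matrix(pool[motif_match(pool, "CRXXXL")])
  expect_equal(lm["pos2", "R"], 1.0)
  expect_equal(lm["pos6", "L"], 1.0)
})

test_that("one-hot encoding is a 20-per-position indicator over variable sites", {
  oh <- onehot(c("CRTYIL", "CRVYIL"))
  expect_equal(ncol(oh), 100L)
  expect_equal(unname(rowSums(oh)), c(5, 5))
  expect_equal(sum(oh[1, ] != oh[2, ]), 2L)     # one position, two bits
  expect_equal(sum(abs(onehot("CAAAAA") - onehot("CAAAAA"))), 0)
  expect_error(onehot("CRTYIB"), "non-canonical")

  d <- peptide_dist(c("CRTYIL", "CRVYIL", "CAAAAA"))
  expect_equal(as.vector(d), c(2, 10, 10))
})

test_that("clustering merges identical leaves first and preserves leaf count", {
  tr <- hcluster(c("CRTYIL", "CRTYIL", "CAAAAA"))
  expect_s3_class(tr, "hclust")
  expect_length(tr$labels, 3L)
  expect_equal(sort(tr$merge[1, ]), c(-2L, -1L))  # the duplicate pair
  expect_equal(tr$height[1], 0)
  expect_true(all(diff(tr$height) >= 0))

  g <- flat_clusters(tr, 2L)
  expect_equal(g[[1]], g[[2]])
  expect_length(unique(flat_clusters(tr, 1L)), 1L)
  expect_length(unique(flat_clusters(tr, 3L)), 3L)
  expect_error(flat_clusters(tr, 4L), "k must be")
})

test_that("agglomeration matches a brute-force greedy oracle over random draws", {
  set.seed(99)
  for (rep in 1:100) {
    peps <- random_peptides(5)
    linkage <- if (rep %% 2 == 0) "average" else "complete"
    tr <- hcluster(peps, linkage = linkage)
    dmat <- as.matrix(peptide_dist(peps))
    orc <- oracle_agglomerate(dmat, linkage)
    expect_identical(tr$merge, orc$merge)
    expect_equal(tr$height, orc$height)
  }
})

test_that("one-hot clustering is invariant under alphabet permutation", {
  set.seed(17)
  peps <- unique(random_peptides(12))
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  # a bijection on the alphabet that keeps the fixed residue fixed
  rest <- setdiff(aa, "C")
  perm <- setNames(c("C", sample(rest)), c("C", rest))
  permute <- function(p) paste0(perm[strsplit(p, "")[[1]]], collapse = "")
  t1 <- hcluster(peps)
  t2 <- hcluster(vapply(peps, permute, character(1)))
  expect_identical(t1$merge, t2$merge)
  expect_equal(t1$height, t2$height)
})

test_that("BLOSUM62 distances are zero on identity, symmetric, and match hand lookup", {
  d <- as.matrix(peptide_dist(c("CRTYIL", "CRTYIL"), metric = "blosum62"))
  expect_equal(d[1, 2], 0)
  dm <- as.matrix(peptide_dist(c("CRTYIL", "CRVYIL", "CWWWWW"),
                               metric = "blosum62"))
  expect_equal(dm, t(dm))
  # independent lookup: the pair differs only at T vs V
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62
  expected <- (S["T", "T"] + S["V", "V"]) / 2 - S["T", "V"]
  expect_equal(dm["CRTYIL", "CRVYIL"], expected)
  expect_error(peptide_dist(c("CRTYIB", "CAAAAA"), metric = "blosum62"),
               "non-canonical|BLOSUM62")

  tr <- blosum_tree(c("CRTYIL", "CRVYIL", "CWWWWW", "CAAAAA"))
  expect_length(tr$labels, 4L)
  expect_equal(sort(tr$merge[1, ]), c(-2L, -1L))  # most similar pair first
})

test_that("trees export to Newick with heights as branch lengths", {
  peps <- c("CRTYIL", "CRVYIL", "CAAAAA", "CWWWWW")
  tr <- hcluster(peps)
  nwk <- write_tree_newick(tr)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "CRTYIL")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, peps)
  path <- tempfile(fileext = ".nwk")
  write_tree_newick(tr, path)
  expect_true(file.size(path) > 0)
  # duplicate leaves are disambiguated, not dropped
  nw2 <- write_tree_newick(hcluster(c("CRTYIL", "CRTYIL", "CAAAAA")))
  expect_length(ape::read.tree(text = nw2)$tip.label, 3L)
  unlink(path)
})
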