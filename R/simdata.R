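#' Simulation configuration for library construction and biopanning
#'
#' Parameters of the ground-truth generator: a naive plasmid pool of
#' `n_unique_members` random peptides plus a spike-in control at a fixed
#' fraction, iterated through fitness-weighted selection bottlenecks, and
#' sequenced with independent per-base substitution errors. All
#' randomness flows from `seed`.
#'
#' @param n_unique_members Number of distinct library peptides in the
#'   naive pool (default 1e4).
#' @param spike_peptide Internal-standard peptide (default `"CAAAAA"`),
#'   present at `spike_fraction` of the naive pool.
#' @param spike_fraction Fraction of the naive pool held by the spike
#'   (default 0.08, an 8% spike).
#' @param reads_per_round Reads emitted per sequenced round
#'   (default 1e5).
#' @param n_rounds Number of sequenced rounds including the naive
#'   library (default 3: pan0, pan1, pan2).
#' @param fitness Named numeric vector of survival weights per peptide,
#'   or `NULL` to plant `n_hits` peptides at `hit_weight` and leave the
#'   rest (including the spike) neutral at 1.
#' @param n_hits,hit_weight Used when `fitness` is `NULL` (defaults 20
#'   and 5): the planted high-fitness peptides emulating true inhibitors
#'   whose hosts outgrow the rest under selection.
#' @param bottleneck_size Colonies surviving each selection round
#'   (default 1e5).
#' @param base_error_rate Per-base substitution probability at
#'   sequencing (default 0).
#' @param seed Integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_unique_members = 10000L,
                       spike_peptide = "CAAAAA",
                       spike_fraction = 0.08,
                       reads_per_round = 100000L,
                       n_rounds = 3L,
                       fitness = NULL,
                       n_hits = 20L,
                       hit_weight = 5,
                       bottleneck_size = 100000L,
                       base_error_rate = 0,
                       seed = 1L) {
  if (spike_fraction < 0 || spike_fraction >= 1)
    stop("spike_fraction must be in [0, 1)", call. = FALSE)
  if (reads_per_round <= 0) stop("reads_per_round must be > 0", call. = FALSE)
  if (!is.null(fitness)) {
    if (is.null(names(fitness)) || any(!is.finite(fitness)) ||
        any(fitness < 0))
      stop("fitness must be a named vector of finite weights >= 0",
           call. = FALSE)
  }
  if (base_error_rate < 0 || base_error_rate > 1)
    stop("base_error_rate must be a probability", call. = FALSE)
  structure(
    list(n_unique_members = as.integer(n_unique_members),
         spike_peptide = toupper(spike_peptide),
         spike_fraction = spike_fraction,
         reads_per_round = as.integer(reads_per_round),
         n_rounds = as.integer(n_rounds),
         fitness = fitness,
         n_hits = as.integer(n_hits),
         hit_weight = hit_weight,
         bottleneck_size = as.integer(bottleneck_size),
         base_error_rate = base_error_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# decode peptide index (1..20^k) into k residues over the AA alphabet
.decode_peptides <- function(idx, k) {
  m <- matrix("", nrow = length(idx), ncol = k)
  r <- idx - 1L
  for (j in seq_len(k)) {
    m[, j] <- .AA20[r %% 20L + 1L]
    r <- r %/% 20L
  }
  apply(m, 1L, paste0, collapse = "")
}

# one NNS encoding per peptide: fixed first codon + a random non-stop
# NNS codon per variable residue
.encode_peptides <- function(peptides, design) {
  gc <- .codon_table()
  nns <- nns_codons()
  nns <- nns[gc[nns] != "*"]          # amber excluded from encodings
  by_aa <- split(nns, gc[nns])
  np <- peptide_length(design)
  n <- length(peptides)
  out <- rep(design$fixed_first_codons[1L], n)
  for (j in 2:np) {
    res <- substr(peptides, j, j)
    codon <- vapply(by_aa[res], function(cs) cs[sample.int(length(cs), 1L)],
                    character(1))
    out <- paste0(out, codon)
  }
  out
}

#' Build the naive plasmid pool
#'
#' Samples `n_unique_members` distinct peptides uniformly from the
#' design's peptide space, assigns each one a valid NNS DNA encoding,
#' places the spike-in at exactly `spike_fraction`, and distributes the
#' remaining mass over members by a symmetric Dirichlet (the
#' plasmid-prep abundance noise of a real library).
#'
#' @param config A [sim_config()].
#' @param design A [siclopps_design()].
#' @param concentration Dirichlet concentration for member frequencies
#'   (default 1).
#' @return A `sim_pool`: data.frame with columns `peptide`, `extein_dna`,
#'   `freq` (summing to 1) and `is_spike`.
#' @export
make_naive_pool <- function(config, design, concentration = 1) {
  stopifnot(inherits(config, "sim_config"),
            inherits(design, "siclopps_design"))
  if (config$n_unique_members > library_diversity(design))
    stop("n_unique_members exceeds library diversity", call. = FALSE)
  set.seed(config$seed)
  k <- design$n_variable
  first_aa <- unname(.codon_table()[design$fixed_first_codons[1L]])
  # sample distinct members, avoiding the spike peptide itself
  m <- min(config$n_unique_members + 1L, 20^k)
  idx <- sample.int(20^k, m)
  peps <- paste0(first_aa, .decode_peptides(idx, k))
  peps <- setdiff(peps, config$spike_peptide)
  if (length(peps) < config$n_unique_members)
    stop("peptide space too small for the requested pool", call. = FALSE)
  peps <- peps[seq_len(config$n_unique_members)]
  w <- stats::rgamma(length(peps), shape = concentration)
  freq <- w / sum(w) * (1 - config$spike_fraction)
  pool <- data.frame(
    peptide = c(config$spike_peptide, peps),
    freq = c(config$spike_fraction, freq),
    is_spike = c(TRUE, rep(FALSE, length(peps))),
    stringsAsFactors = FALSE
  )
  pool$extein_dna <- .encode_peptides(pool$peptide, design)
  structure(pool[, c("peptide", "extein_dna", "freq", "is_spike")],
            class = c("sim_pool", "data.frame"))
}

#' Default planted-hit fitness map for a pool
#'
#' Neutral weight 1 everywhere except `n_hits` randomly chosen
#' non-spike members at `hit_weight` — the simulated true inhibitors.
#'
#' @param pool A `sim_pool`.
#' @param n_hits,hit_weight Number and weight of planted hits.
#' @param seed Integer seed for the hit draw.
#' @return Named numeric vector of weights over the pool's peptides.
#' @export
planted_fitness <- function(pool, n_hits = 20L, hit_weight = 5,
                            seed = 1L) {
  stopifnot(inherits(pool, "sim_pool"))
  set.seed(seed)
  w <- rep(1, nrow(pool))
  names(w) <- pool$peptide
  members <- which(!pool$is_spike)
  hits <- sample(members, min(n_hits, length(members)))
  w[hits] <- hit_weight
  w
}

#' One round of fitness-weighted selection
#'
#' Draws `bottleneck_size` surviving colonies by multinomial sampling
#' with probability proportional to `frequency x fitness`, then
#' renormalizes. Peptides missing from the draw are lost from the pool,
#' emulating the plate bottleneck; peptides missing from the fitness map
#' are treated as neutral (weight 1).
#'
#' @param pool A `sim_pool`.
#' @param config A [sim_config()] (supplies `bottleneck_size` and, if
#'   set, `fitness`).
#' @param fitness Optional named weight vector overriding
#'   `config$fitness`.
#' @param seed Integer seed for this round's draw.
#' @return The post-selection `sim_pool`.
#' @export
biopan_round <- function(pool, config, fitness = NULL, seed = config$seed) {
  stopifnot(inherits(pool, "sim_pool"), inherits(config, "sim_config"))
  w <- fitness %||% config$fitness
  if (is.null(w)) w <- planted_fitness(pool, config$n_hits,
                                       config$hit_weight, config$seed)
  wv <- w[pool$peptide]
  wv[is.na(wv)] <- 1
  p <- pool$freq * wv
  if (sum(p) <= 0) stop("total selection weight is zero", call. = FALSE)
  set.seed(seed)
  draw <- as.vector(stats::rmultinom(1L, config$bottleneck_size, p))
  keep <- draw > 0L
  out <- pool[keep, , drop = FALSE]
  out$freq <- draw[keep] / sum(draw[keep])
  rownames(out) <- NULL
  structure(out, class = c("sim_pool", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit sequencing reads from a pool
#'
#' Each read is `random N6 tag + upstream anchor + member extein DNA +
#' downstream anchor`, with the member drawn multinomially from the pool
#' frequencies and independent per-base substitution errors applied at
#' `base_error_rate`. Qualities are uniform Phred 40. A companion TSV of
#' each read's true peptide supports exact round-trip validation.
#'
#' @param pool A `sim_pool`.
#' @param design A [siclopps_design()].
#' @param n_reads Number of reads.
#' @param base_error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param path FASTQ destination (`.gz` suffix compresses); `NULL`
#'   returns the reads without writing.
#' @param truth_path Optional TSV destination for `read_id`, `peptide`.
#' @param id_prefix Prefix for read identifiers.
#' @return Invisibly, a data.frame with `read_id`, `sequence`,
#'   `peptide` (the ground truth).
#' @export
emit_fastq <- function(pool, design, n_reads,
                       base_error_rate = 0, seed = 1L,
                       path = NULL, truth_path = NULL,
                       id_prefix = "read") {
  stopifnot(inherits(pool, "sim_pool"), inherits(design, "siclopps_design"))
  set.seed(seed)
  n_reads <- as.integer(n_reads)
  draw <- as.vector(stats::rmultinom(1L, n_reads, pool$freq))
  member <- sample(rep.int(seq_len(nrow(pool)), draw))  # shuffle reads
  n6 <- if (design$n6_length > 0L) {
    apply(matrix(sample(c("A", "C", "G", "T"),
                        design$n6_length * n_reads, replace = TRUE),
                 nrow = design$n6_length), 2L, paste0, collapse = "")
  } else rep("", n_reads)
  seqs <- paste0(n6, design$upstream_anchor, pool$extein_dna[member],
                 design$downstream_anchor)
  if (base_error_rate > 0) {
    L <- nchar(seqs[1L])
    n_err <- stats::rbinom(1L, n_reads * L, base_error_rate)
    if (n_err > 0L) {
      at <- sample.int(n_reads * L, n_err)
      rd <- (at - 1L) %/% L + 1L
      ps <- (at - 1L) %% L + 1L
      old <- substr(seqs[rd], ps, ps)
      new <- vapply(old, function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                    b), 1L), character(1))
      for (e in seq_len(n_err)) {
        substr(seqs[rd[e]], ps[e], ps[e]) <- new[e]
      }
    }
  }
  ids <- sprintf("%s%07d", id_prefix, seq_len(n_reads))
  truth <- data.frame(read_id = ids, sequence = seqs,
                      peptide = pool$peptide[member],
                      stringsAsFactors = FALSE)
  if (!is.null(path)) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::PhredQuality(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = grepl("\\.gz$", path))
  }
  if (!is.null(truth_path))
    .write_tsv(truth[, c("read_id", "peptide")], truth_path,
               meta = "sicloppsr simulated ground truth")
  invisible(truth)
}

#' Simulate a full biopanning experiment
#'
#' Builds the naive pool, applies `n_rounds - 1` selection rounds, and
#' emits a FASTQ plus ground-truth TSV per round (pan0 = naive). Every
#' round's seed is derived deterministically from the master seed, so a
#' config reproduces its FASTQ files byte for byte.
#'
#' @param config A [sim_config()].
#' @param design A [siclopps_design()]; default [default_design()].
#' @param out_dir Output directory (created); `NULL` keeps everything
#'   in memory.
#' @return A list with `pools` (per-round `sim_pool`s), `truth`
#'   (per-round ground-truth data.frames), `fitness` (the weight map),
#'   `fastq` and `truth_tsv` (paths per round when `out_dir` is given),
#'   `labels`.
#' @export
simulate_biopanning <- function(config, design = default_design(),
                                out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pool <- make_naive_pool(config, design)
  fitness <- config$fitness %||%
    planted_fitness(pool, config$n_hits, config$hit_weight, config$seed)
  labels <- paste0("pan", seq_len(config$n_rounds) - 1L)
  pools <- vector("list", config$n_rounds)
  pools[[1L]] <- pool
  for (r in seq_len(config$n_rounds - 1L)) {
    pools[[r + 1L]] <- biopan_round(pools[[r]], config, fitness = fitness,
                                    seed = config$seed + 1000L * r)
  }
  names(pools) <- labels
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  fastq <- truth_tsv <- stats::setNames(character(config$n_rounds), labels)
  truth <- vector("list", config$n_rounds)
  for (r in seq_len(config$n_rounds)) {
    fq <- if (is.null(out_dir)) NULL
          else file.path(out_dir, paste0(labels[r], ".fastq"))
    tt <- if (is.null(out_dir)) NULL
          else file.path(out_dir, paste0("truth_", labels[r], ".tsv"))
    truth[[r]] <- emit_fastq(pools[[r]], design, config$reads_per_round,
                             base_error_rate = config$base_error_rate,
                             seed = config$seed + 1000L * (r - 1L) + 500L,
                             path = fq, truth_path = tt,
                             id_prefix = paste0(labels[r], "_"))
    if (!is.null(out_dir)) { fastq[r] <- fq; truth_tsv[r] <- tt }
  }
  names(truth) <- labels
  if (!is.null(out_dir)) {
    .write_tsv(data.frame(peptide = names(fitness),
                          weight = as.numeric(fitness)),
               file.path(out_dir, "fitness.tsv"),
               meta = "sicloppsr simulated fitness map")
  }
  list(pools = pools, truth = truth, fitness = fitness,
       fastq = if (is.null(out_dir)) NULL else fastq,
       truth_tsv = if (is.null(out_dir)) NULL else truth_tsv,
       labels = labels)
}
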