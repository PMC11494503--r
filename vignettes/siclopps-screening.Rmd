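---
title: "Decoding and ranking SICLOPPS biopanning screens"
author: "sicloppsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and ranking SICLOPPS biopanning screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicloppsr)
```

## The screening problem

SICLOPPS (split-intein circular ligation of peptides and proteins)
expresses plasmid-encoded head-to-tail cyclic peptides inside bacteria.
Coupled to a reverse two-hybrid selection, cells survive only when their
cyclic peptide disrupts a targeted protein–protein interaction, so
iterative rounds of selection ("biopanning") enrich active sequences.
Deep sequencing of the plasmid pool before and after each round turns
hit identification into a counting problem: which peptides rise in
abundance, and in what order should they be synthesized for validation?

`sicloppsr` implements the computational half of that workflow. A
typical library is CX5: an invariant N-terminal cysteine followed by
five fully randomized residues, encoded by NNS codons (any base at
positions 1–2, G or C at position 3). NNS covers all 20 amino acids
while excluding the ochre and opal stops; the amber stop (TAG) survives
the S constraint and is handled explicitly. A CX5 library spans
$20^5 = 3.2\times10^6$ peptides.

## Read architecture and quality control

Each amplicon read is laid out as

```
[N6 tag][C-intein anchor][extein: Cys codon + 5 NNS codons][N-intein anchor]
```

The six randomized bases at the start increase base diversity for
cluster calling on the flow cell; the fixed intein-coding sequences
flanking the 18-base extein are the parser's anchors. `locate_anchors()`
finds the leftmost upstream-anchor occurrence and the nearest
downstream occurrence after it, allowing a configurable number of
substitutions per anchor (default 1, no indels — anchors are short fixed
regions and indel sequencing errors simply route a read to the
`no_anchor`/`bad_length` bins, which is acceptable at amplicon error
rates). Only the forward strand is searched: sequencing starts on the
forward strand immediately after the adapter, so reverse-complement
reads do not occur in well-formed runs.

`parse_reads()` then applies a fixed cascade of checks, recording the
**first** failure so that category counts are reproducible:

1. `no_anchor` — either anchor missing;
2. `bad_length` — enclosed span is not $3(1 + n_\mathrm{var})$ bases;
3. `ambiguous_base` — an N (or other non-ACGT symbol) inside the extein;
4. `bad_first_residue` — first codon is not an accepted Cys codon
   (TGT or TGC by default; the template codon is configurable);
5. `stop_codon` — a stop in a variable codon.

Two policy decisions are exposed because the underlying biology is
host-dependent. Amber codons are rejected by default (`stop_policy =
"reject"`): we count peptides, and a TAG-carrying member yields no
full-length peptide in a non-suppressor host. In a *supE* host that
reads through amber, `translate_amber_as_stop` keeps the read and marks
the position with `*`. Second, a variable codon with A or T at its
third base violates the NNS design but is most often a sequencing error
sitting on a genuine library member, so such reads are translated and
flagged `non_nns` rather than discarded. Base qualities are not used
for filtering: validity is defined by sequence identity to the design,
and the anchor/translation cascade is already a strong error filter.

## Abundance, normalization and redundancy

`count_peptides()` tallies peptides over `status == "pass"` reads only;
all normalizations are relative to passing reads, since those are the
sequences actually analyzed. Two derived views are provided: copies per
million reads (CPM, `count / total × 10^6`) and percent. The
sequence-redundancy distribution (`redundancy_bins()`) assigns each
unique peptide to the decade bin of its CPM value — bins are half-open
$[low, high)$ with the top bin closed at $10^6$, so a peptide at
exactly 1000 CPM belongs to the 1k–10k class. In a naive library
nearly all mass sits in the 1–10 CPM classes; selection shifts it
upward, and the spike-in control (below) is the only high-abundance
member before panning.

## The spike-in control

The library is doped with a plasmid encoding *cyclo*-AAAAA at 8% of
total plasmids. Because the spike confers no survival advantage, its
trajectory is a built-in selection meter: enrichment of genuine hits
must come at the spike's expense, so a falling spike percentage is
direct evidence that panning worked. The simulator reproduces this
design, and the test suite checks both the naive-library recovery of
the configured fraction and the expected depletion under selection.

## Enrichment classification and reranking

With abundance tables for the naive library (pan 0) and two panning
rounds (pan 1, pan 2), a sequence is classified **enriched** when its
raw copy number in the final round is at least 10 and its CPM in the
final round exceeds its CPM in both predecessors. The copy-number floor
suppresses Poisson noise at the bottom of the table; the CPM comparison
makes the rule invariant to sequencing depth.

Hits are ordered by the adjusted inverse enrichment score

$$\mathit{enr}_{i\text{-}adj} = \mathit{rank}_2
  + 0.0001\cdot \mathit{enr}_{02} + 0.01\cdot \mathit{enr}_{12},$$

where $\mathit{rank}_2$ is the abundance rank after the second round
(1 = most abundant) and $\mathit{enr}_{02}$, $\mathit{enr}_{12}$ are
the enrichment terms from pan 0 and pan 1 to pan 2. Sorting ascending
gives the overall rank: the score is dominated by the final-round rank,
with the enrichment terms acting as small tie-breakers that promote
late risers. Two readings of the enrichment terms are supported via
`enr_interpretation` because the score's name and its arithmetic pull
in opposite directions: taken literally as fold enrichments (the
default, matching how the terms are reported), a *larger* enrichment
slightly *worsens* this lower-is-better score; taken as inverse folds,
it improves it. The default follows the printed arithmetic; both modes
are first-class and the choice is recorded in the output metadata.

Three numerical conventions matter for reproducibility. Ranking ties
are broken lexicographically by peptide, so ranks are always a
permutation of $1..n$. Fold enrichments use a pseudo-count equal to the
CPM of a single read in the shallower round ($10^6/\text{total}$),
keeping every fold finite and depth-aware; a sequence absent from the
final round is never ranked. And `rank2` is computed on raw final-round
counts (identical ordering to CPM at fixed depth).

## Motif analytics

Hexapeptides are too short for general motif-discovery tools, which on
6-mers tend to return either one diffuse cluster or many overlaid ones.
The package instead implements the direct searches that work at this
length:

* **Homology neighborhoods** — `homology_neighbors()` returns all
  sequences sharing at least 80% variable-position identity with a
  query (4 of 5 positions for CX5). The fixed cysteine is excluded from
  identity: it carries no information in a CX5 library. Identity is
  positional, not rotational — the intein fixes the cyclization point,
  so reads are registered and rotational matching would conflate
  distinct encodings.
* **Wildcard motif queries** — patterns such as `CRX(L/V)XL` or
  `CRX[LVFY]XL` (both notations accepted) are matched per position;
  `motif_count()` reports unique matches in a pool.
* **Logos** — `logo_matrix()` returns the position × residue frequency
  matrix behind a sequence logo.
* **Clustering** — `hcluster()` agglomerates one-hot encoded peptides
  (a 20-bit indicator block per variable position; two peptides
  differing at $k$ positions are $2k$ apart in Hamming distance).
  The agglomeration is written in-package so the merge order under tied
  distances is fully specified: among equal-distance pairs, the pair
  whose clusters contain the smallest original indices merges first.
  Ties are pervasive with integer-valued distances on short peptides,
  and determinism across platforms was judged more valuable than any
  aesthetic ordering. Average linkage is the default; complete and Ward
  are available, and no claim is made that one of them is canonical for
  this data — all outputs are regenerable under any supported linkage.
  `blosum_tree()` swaps in the substitution-aware distance
  $d(x,y) = \sum_\text{pos} \tfrac{S(x,x)+S(y,y)}{2} - S(x,y)$ with
  $S$ = BLOSUM62, which is zero on identity and symmetric. Trees export
  to Newick (`write_tree_newick()`), so circular dendrograms can be
  drawn by any viewer; no plotting is built in.

## The simulator

`simulate_biopanning()` generates the full ground-truth substrate the
tests run on: a naive pool of distinct random peptides with a symmetric
Dirichlet abundance profile (concentration 1 — the heavy-tailed
plasmid-prep noise of a freshly cloned library), the spike-in at its
exact fraction, and per-round selection modeled as a single
weighted-multinomial bottleneck with probabilities proportional to
frequency × fitness. This deliberately collapses the growth dynamics of
colonies on a plate into relative survival weights at the sequenced
endpoint; the reduction has closed-form expectations (a weight-2
peptide starting at parity with a weight-1 peptide is expected at 2/3
after one round), which is what makes the selection model testable.
Reads are emitted with a random N6 tag, the design's anchors, one fixed
NNS encoding per peptide, and independent per-base substitution errors.

Default study conditions: 10^4 unique members, 8% spike, 3 sequenced
rounds, 10^5 reads and 10^5 surviving colonies per round, 20 planted
hits at fitness 5 against a neutral background, error rate 0. The
planted-hit fraction and weight are chosen to mirror a screen where a
small set of genuine inhibitors dominates after two rounds; bottleneck
and read depth are large enough that drift does not swamp selection.
Simplifications to keep in mind when interpreting green tests: one DNA
encoding per peptide (synonymous diversity is orthogonal to every
peptide-level property tested), substitution-only sequencing error
(indels only exercise the `no_anchor`/`bad_length` paths, covered by
direct construction), no PCR amplification bias, and uniform Phred
qualities. Passing tests therefore demonstrate correctness of the
decoding/ranking machinery under a faithful selection model — not
robustness to every artifact of a real sequencing run.

All randomness flows from one master seed; per-round seeds are derived
deterministically from it, so a configuration reproduces its FASTQ
files byte for byte.

## Problem sizes used in validation

The shipped validation suite exercises the pipeline at the scales where
its statistical claims are sharp but a laptop run stays comfortable:
spike-in recovery uses 10^6 error-free reads over 10^4 members (3
binomial standard errors ≈ 0.08 percentage points); end-to-end hit
recovery uses 20 planted hits among 10^4 members at 10^5 reads per
round; oracle cross-checks run counting on 10^4 reads and clustering on
100 random 5-peptide draws against brute-force reimplementations.

## Known limitations

* Anchors ship as synthetic placeholders; real datasets need the actual
  intein-flanking sequences of the construct in a design YAML.
* No paired-end merging or demultiplexing: inputs are per-round,
  demultiplexed single-read FASTQs.
* No statistical significance testing of enrichment — the
  classification is a deterministic rule, and uncertainty enters only
  through the copy-number floor.
* Ring sizes other than one fixed residue plus `n_variable` randomized
  residues are not supported.

## A minimal run

```{r, eval = FALSE}
library(sicloppsr)
cfg <- sim_config(seed = 1L)                  # study-condition defaults
sim <- simulate_biopanning(cfg, out_dir = "sim")
res <- run_pipeline(sim$fastq, out_dir = "results")
head(res$enrichment)
```
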