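# sicloppsr

Decoding and ranking of NGS-based SICLOPPS cyclic-peptide screens.

SICLOPPS (split-intein circular ligation of peptides and proteins)
libraries express plasmid-encoded cyclic peptides — typically CX5: an
invariant cysteine plus five NNS-randomized residues, 20^5 = 3.2 million
peptides — inside bacteria coupled to a life/death selection. Iterative
rounds of selection (biopanning) enrich peptides that disrupt the
targeted protein–protein interaction, and deep sequencing of the plasmid
pool before and after each round turns hit calling into a counting
problem. `sicloppsr` is for screeners who have per-round amplicon FASTQ
files and need ranked, motif-annotated hit lists.

The package covers the full computational workflow:

* **Read QC** — locate the fixed intein-coding anchors flanking the
  extein (substitution-tolerant, leftmost match), crop, validate
  (anchor / length / ambiguity / first-residue / stop cascade) and
  translate each read.
* **Abundance** — peptide counts, copies per million (CPM), percent,
  and the decade-binned sequence-redundancy distribution.
* **Enrichment** — a sequence is *enriched* when its final-round copy
  number is ≥ 10 and its CPM exceeds both predecessor rounds. Hits are
  reranked by the adjusted inverse enrichment score

  `enr_i_adj = rank_2 + 0.0001 * enr_02 + 0.01 * enr_12`

  (final-round rank plus weighted cross-round enrichment terms, sorted
  lowest-to-highest; an 8% *cyclo*-AAAAA spike-in serves as the
  neutral internal standard whose depletion tracks selection).
* **Motifs** — 4-of-5 variable-position homology neighborhoods,
  wildcard motif queries (`CRX(L/V/F/Y)XL` or `CRX[LVFY]XL` notation),
  logo frequency matrices, deterministic agglomerative clustering of
  one-hot encoded peptides, BLOSUM62 distance trees, Newick export.
* **Simulation** — a seeded generator of naive pools, spike-ins,
  fitness-weighted selection bottlenecks and FASTQ reads, providing
  ground truth for every pipeline property.

## Worked example

Simulate a small 3-round screen (500 library members, 10 planted
high-fitness peptides, 5,000 reads/round) and rank hits:

```r
library(sicloppsr)
d   <- default_design()
cfg <- sim_config(n_unique_members = 500L, reads_per_round = 5000L,
                  bottleneck_size = 20000L, n_hits = 10L, seed = 42L)
sim  <- simulate_biopanning(cfg, d, out_dir = "sim")
tabs <- lapply(sim$labels, function(l)
  count_peptides(qc_run(sim$fastq[[l]], d)$parsed, l))
et   <- enrichment_table(round_series(tabs))
head(as.data.frame(et)[, c("peptide", "cpm_pan0", "cpm_pan2", "rank2",
                           "enr_i_adj", "overall_rank", "enriched")])
```

```
  peptide cpm_pan0 cpm_pan2 rank2 enr_i_adj overall_rank enriched
1  CEIVEP     3200    61000     1  1.034703            1     TRUE
2  CMNKMR     3200    54800     2  2.036874            2     TRUE
3  CAAAAA    70800    52800     3  3.007237            3    FALSE
4  CVVVCL     1400    43800     4  4.040681            4     TRUE
5  CDDKFS     2800    43200     5  5.040901            5     TRUE
6  CLIGFM     3200    40400     6  6.033936            6     TRUE
```

Reading the output: `rank2` is the abundance rank after the final
round; `enr_i_adj` adds the (weighted) fold-enrichment terms, and
sorting it ascending gives `overall_rank`. The planted high-fitness
peptides surface at the top and are flagged `enriched`; the CAAAAA
spike-in is still abundant (it started at 8% ≈ 80,000 CPM) but is
falling and is correctly *not* classified as enriched. Motif analytics
then operate on the ranked list, e.g.
`homology_neighbors("CRTYIL", et$peptide)` or
`write_tree_newick(hcluster(head(et$peptide, 100)), "top100.nwk")`.

The same stages are available as subcommands of a thin CLI:

```sh
Rscript inst/cli/siclopps.R simulate --out-dir sim --seed 1
Rscript inst/cli/siclopps.R run --in sim/pan0.fastq,sim/pan1.fastq,sim/pan2.fastq \
    --out-dir results
```

Real datasets need the actual intein anchor sequences of the construct:
copy `inst/extdata/cx5_design.yml` (which ships synthetic placeholder
anchors) and edit it, then pass `--design` / `read_design()`.

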