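# cesponge

Competing endogenous RNA (ceRNA) network inference from back-splice
junctions, for transcriptomics researchers studying how circRNAs and
lncRNAs sponge miRNAs across a staged bulk RNA-seq design — the motivating
system is brown-adipose-tissue whitening across four growth stages (D0,
D15, D85, Y2; three replicates each).

The package implements the full inference chain as tested, reusable R
functions, exercised end to end on a synthetic data generator with a
ground-truth manifest:

* **BSJ circRNA calling** — reads failing exact linear mapping have their
  20 nt terminal anchors remapped; reversed anchor order plus exact
  extension to a unique breakpoint with the canonical splice signal
  (genomic `AG` before the circ start, `GT` after its end, strand-
  normalized) calls a junction. Credible circRNAs need ≥ 2 unique BSJ reads
  in at least one sample *and* recovery in both the whole-transcriptome and
  circRNA-seq library arms, merged on exact coordinates.
* **Junction-spanning MRE discovery** — the last 100 nt and first 100 nt of
  the spliced circRNA are linked into a BSJ pseudo-sequence; miRNA seed
  sites (positions 2–8, Watson–Crick, T≡U) strictly straddling the junction
  with no site on the linear sequence are interactions that exist only in
  the circular form.
* **Expression-gated triple networks** — a predicted pair becomes an edge
  only if Spearman rho < −0.6 with p < 0.05 across the 12 samples; miRNAs
  bound by both a ceRNA and an mRNA define (ceRNA, miRNA, mRNA) axes, and
  the circRNA- and lncRNA-centred networks are compared by shared miRNAs.
* **Supporting statistics** — a simplified negative-binomial Wald test
  (median-of-ratios normalization; decision rule p < 0.05, |log2FC| > 1),
  stage-selective k-means clustering (k = 7) on z-scored stage means,
  small-RNA adapter trimming (18–30 nt inserts) and exact-match miRNA
  counting, Smith–Waterman conservation screening (identity ≥ 70 %,
  coverage ≥ 100 nt, total identity ≥ 75 %), EASE-penalised hypergeometric
  enrichment, and 2^−ΔΔCt relative quantification.

## Worked example

The numbered scripts under `analysis/` run the whole study; stage 1
simulates, stages 2–6 analyse only what earlier stages wrote to `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detect_circrnas.R
```

```
whole-tx junctions: 50  circRNA-seq junctions: 50  credible: 50
recall vs manifest: 1.000  precision: 1.000
```

All 50 implanted circRNAs are recovered at exact coordinates from the read
data alone, and nothing else is called. Continuing,

```sh
Rscript analysis/04_target_sites.R
Rscript analysis/05_cerna_networks.R
```

```
junction-spanning sites: 11  junction-only circRNA-miRNA pairs: 10
junction-only pairs vs manifest: recall 1.000, precision 1.000
edges passing the correlation gate: miRNA-mRNA 13 , lncRNA-miRNA 17 , circRNA-miRNA 7
triple axes: circRNA network 6 , lncRNA network 16
miRNA overlap: 4 shared; 36.4% of the lncRNA network's miRNAs
```

The 10 junction-only pairs are exactly the implanted split-seed MREs (plus
any chance straddles the generator recorded); the correlation gate then
thins the sequence-predicted pairs to the anti-correlated sponge axes. The
same chain is available programmatically:

```r
library(cesponge)
res <- run_pipeline(pipeline_config(), out_dir = "results/run")
nrow(res$credible)        # 50 credible circRNAs
res$novel_junction_pairs  # junction-only circRNA-miRNA interactions
```

Every file `run_pipeline()` writes is listed with its MD5 checksum and the
full parameter set in `provenance.tsv`; identical configurations reproduce
byte-identical output trees.

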