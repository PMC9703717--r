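---
title: "Inferring circRNA- and lncRNA-centred ceRNA networks from back-splice junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring circRNA- and lncRNA-centred ceRNA networks from back-splice junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Circular RNAs (circRNAs) and long non-coding RNAs can act as competing
endogenous RNAs (ceRNAs): by carrying miRNA response elements (MREs) they
sequester shared miRNAs and thereby de-repress the miRNAs' mRNA targets.
`cesponge` implements, as one tested pipeline, the chain of inferences used
to reconstruct such networks from a staged bulk RNA-seq design — here a
brown-adipose-tissue whitening time course with four stages (D0, D15, D85,
Y2 — days and years of age) and three replicates per stage:

1. **circRNA discovery.** A circRNA is identified by its back-splice
   junction (BSJ): a read that crosses the junction carries the downstream
   donor sequence *before* the upstream acceptor sequence. For every read
   that fails exact linear mapping, the first and last 20 nt (anchors) are
   remapped; if both anchors map uniquely to one chromosome and strand in
   reversed genomic order, the anchors are extended towards the read middle
   without mismatch. A candidate is emitted only when exactly one breakpoint
   is consistent with the canonical splice signal — genomic `AG` immediately
   5' of the circRNA start and `GT` immediately 3' of its end, reverse-
   complemented on the minus strand.
2. **Credibility filters.** A junction must be supported by at least two
   *unique* BSJ reads (distinct read sequences) in at least one sample, and
   must be recovered independently in both library arms — the per-sample
   whole-transcriptome libraries and the RNase-R-enriched circRNA-seq
   library. Only the exact (chromosome, start, end, strand) coordinates
   merge; junctions one nucleotide apart are distinct circRNAs.
3. **Junction-spanning MREs.** Circularization creates sequence that does
   not exist in any linear transcript. The last 100 nt and first 100 nt of
   the spliced circRNA are linked into a *BSJ pseudo-sequence*; target sites
   strictly straddling the junction, for miRNAs with no site anywhere on the
   linear spliced sequence, are *junction-only* interactions that exist only
   in the circular form.
4. **Expression gates.** A sequence-predicted (ceRNA, miRNA) or
   (miRNA, mRNA) pair becomes a network edge only when the two profiles are
   anti-correlated across the 12 samples: Spearman rho < −0.6 with
   p < 0.05 (both strict). miRNAs with gated edges to both a ceRNA and an
   mRNA define the (ceRNA, miRNA, mRNA) regulatory axes of the triple
   networks; the circRNA- and lncRNA-centred networks are compared by their
   shared miRNA complement.
5. **Context.** Differential expression between stage pairs (p < 0.05 and
   |log2FC| > 1), stage-selective k-means clustering (k = 7) of DE
   features, a cross-species conservation screen (per-alignment identity
   ≥ 70 %, union query coverage ≥ 100 nt, total identity ≥ 75 %), and
   EASE-penalised hypergeometric term enrichment (p < 0.05).

Every step is driven by the numbered scripts under `analysis/` and by
`run_pipeline()`, and every step is validated against a synthetic dataset
with a complete ground-truth manifest.

## The synthetic study and what it does (not) emulate

`generate_dataset(simulation_config())` builds a self-contained study:

* a 2 × 60 kb random genome carrying 60 multi-exon genes (2–4 exons of
  200–400 nt, introns 100–250 nt, random strand);
* 50 circRNAs, each circularizing 1–3 consecutive transcript-order exons of
  its own host gene, with `AG`/`GT` flanks written into the genome
  (strand-aware). The transcript-last exon is never circularized — it hosts
  the 150 nt 3'UTR used for mRNA target implants;
* 24 mature miRNAs (22 nt) with distinct seeds. Each miRNA's seed
  complement is implanted once into a 3'UTR and once into a lncRNA; a
  configurable fraction of circRNAs (default 0.2) receives a seed
  complement *split across the BSJ* (3' part at the spliced-sequence end,
  5' part at its start), and chance linear occurrences of that seed are
  mutated away so the junction-only property holds by construction. Further
  circRNAs receive body sites > 100 nt from either end;
* per-sample whole-transcriptome reads (150 nt): linear transcript windows
  plus 10 distinct BSJ-straddling reads per circRNA per sample (junction
  offsets sampled without replacement, ≥ 21 nt on each side); a pooled
  circRNA-seq read set; and small-RNA reads (50 nt) built as mature miRNA +
  3' adapter, replicated to match the miRNA count matrix exactly;
* negative-binomial count matrices (Var = mu + a·mu², default a = 0.05,
  log-normal(0, 0.1) library-size factors) over seven stage archetypes —
  four single-stage-selective patterns, two ramps, one mid-peak. Half of
  the miRNAs carry a designed stage response drawn from the *graded*
  archetypes (ramps, mid-peak) and their targets carry the mirrored
  profile; the other half of every feature class is flat.

Two design points deserve emphasis because they are statistical, not
cosmetic. First, the flat features are what make median-of-ratios
normalization identifiable: with every feature stage-responsive the median
ratio tracks the stage signal instead of the library depth. Second,
designed sponge miRNAs avoid the single-stage archetypes: a 3-high /
9-exchangeable profile against its mirror has an expected Spearman rho of
only about −0.55 across 12 samples — below the −0.6 gate *by construction*,
independent of counting noise — whereas ramp and mid-peak mirrors reach
−0.94 and −0.76.

What the generator deliberately does **not** emulate: sequencing errors and
quality variation (reads are error-free by default; a uniform substitution
rate is available), multi-mapping ambiguity on a realistic repeat-rich
genome, rolling-circle multimers and intron-retaining circRNA isoforms,
fragment-length and GC biases, and genome-scale sequence composition.
Passing tests therefore demonstrate that the *algorithms* implement their
stated rules exactly and recover a clean, fully specified truth; they do
not certify recall on real libraries, where alignment heuristics and noise
models dominate.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| anchor length | 20 | nt | terminal-anchor remapping length; unique in a 120 kb random genome with overwhelming probability |
| min unique BSJ reads | 2 | reads | credibility filter; "unique" means distinct read sequences |
| max circRNA span | 50 | kb | guards against chimeric anchor pairs |
| trim policy | 18–30 nt, overlap ≥ 3, 0 errors | nt | small-RNA insert selection around the 22 nt miRNA mode |
| seed span | miRNA positions 2–8 | — | 7mer-m8 Watson–Crick seed anchoring |
| site scores | +5 match, +1 G:U (outside seed), −3 mismatch | — | permissive, fully specified stand-in for heuristic aligners; `min_total_score = 0` makes a seed match sufficient |
| junction window | 100 + 100 | nt | BSJ pseudo-sequence; windows overlap (never truncate) for spliced lengths < 200 nt |
| correlation gate | rho < −0.6, p < 0.05 | — | strict inequalities, two-sided t approximation on n = 12 |
| DE rule | p < 0.05 and abs(log2FC) > 1 | — | raw p, pseudo-count 0.5 in the fold change |
| k-means | k = 7, 50 restarts, margin 0.5 | z-units | stage-selective clustering of z-scored stage means |
| conservation | ≥ 0.70 / ≥ 0.75 / ≥ 100 | identity, identity, nt | per-alignment identity, union-coverage total identity, covered length |

## Numerical choices

* **Wald reference distribution.** The simplified DESeq2-like test
  (median-of-ratios normalization, method-of-moments NB dispersion floored
  at 1e−8, delta-method standard error of the log2 fold change) refers the
  Wald statistic to a **t distribution with nA + nB − 2 degrees of
  freedom**. With n = 3 per group a standard-normal reference is seriously
  anti-conservative (empirical type-I error ≈ 0.12 at nominal 0.05 over
  20,000 null NB features, mu = 100, dispersion = 0.1); the t reference
  restores calibration (≈ 0.048) at negligible cost in power (≥ 0.97 for a
  4-fold change at mu = 100). This is the usual small-sample correction and
  is the package's own choice; numerical agreement with DESeq2 is neither
  claimed nor sought — only the decision rule is preserved.
* **Spearman p-values** use the t approximation with n − 2 df (standard at
  n = 12). Against an exact permutation null (1e5 permutations) at
  rho = −0.699, n = 12, the approximation is accurate to ~2.5e−3
  (0.0114 vs 0.0139); the acceptance test bounds the discrepancy at 0.005.
  Ties get average ranks; zero-variance profiles are undefined and the pair
  is skipped and counted rather than coerced.
* **Breakpoint ties.** If more than one breakpoint along a read is
  consistent with exact anchor extension and the GT/AG signal
  (microhomology), the read is discarded and logged — conservative, and
  the reason the caller can claim exact coordinates. The implanted flanks
  themselves exclude ±1 nt shifts, since a shifted acceptor would need `A`
  where the implanted `G` sits.
* **k-means initialization.** Base R provides Hartigan–Wong with random
  starts, not k-means++; the package uses `stats::kmeans` with 50 random
  restarts under a caller-supplied seed. Same-seed runs are bit-stable and
  the archetype benchmark is recovered with adjusted Rand index 1.0 across
  seeds, which is the property that matters.
* **Degenerate inputs.** Pseudo-sequences are defined down to spliced
  length 2 (the windows then overlap and duplicate sites are deduplicated
  by circular coordinate); `aggregate_candidates` and the network builders
  return typed empty tables rather than failing on empty input; readers
  reject rather than coerce malformed records, naming the offender.

## Open design choices and their resolution

* The credibility merge in the source procedure used a second external
  caller on the circRNA-seq arm. Re-implementing that caller is out of
  scope here; the pipeline preserves the dual-evidence *structure* by
  running the same anchor caller independently on the circRNA-seq read set.
* "Unique BSJ reads" is operationalised as distinct read sequences —
  a desk-scale proxy for distinct fragments that needs no alignment
  positions.
* The two conservation identity thresholds are read as *per-alignment*
  identity (≥ 70 %) versus *union-coverage* identity (≥ 75 %, summed
  identical positions over the union of covered query intervals) — the only
  reading in which both numbers constrain the call. The filter is monotone:
  alignments below 70 % identity are ignored, so adding evidence can never
  revoke a conserved call.
* The DE threshold uses the raw p-value at 0.05 (the stated rule);
  Benjamini–Hochberg adjusted values are emitted alongside for users who
  prefer them.
* The correlation test is two-sided by default, with a one-sided (negative)
  alternative available.
* Multi-mapping small-RNA reads are counted fractionally (1/n), keeping
  column sums interpretable.

## Problem sizes

The shipped configuration — 120 kb genome, 60 genes, 50 circRNAs, 24
miRNAs, 30 lncRNAs, 12 whole-transcriptome samples of ~900 reads plus 500
BSJ reads each — was chosen so that a full simulate-to-enrichment run
completes in well under a minute and the entire test suite, including two
end-to-end determinism runs and a 20-seed axis-recovery study, in a few
minutes, while every rule in the pipeline still has non-trivial positive
and negative instances (multi-exon and minus-strand circRNAs, overlapping
pseudo-sequence windows, junction-only and body MREs, flat and graded
expression archetypes).

## Known limitations

* The caller requires both read arms to be genomically contiguous; BSJ
  reads whose arm crosses an additional linear splice junction are dropped
  (logged), which on annotation-rich real data would need the spliced-
  alignment machinery this package intentionally avoids.
* Exact matching only: any sequencing error in an anchor or extension loses
  the read (robustness under the optional error mode degrades gracefully
  but recall is no longer 1.0).
* The target model is seed-anchored and ungapped, with no thermodynamic
  term; it is a discovery-logic stand-in, not a reimplementation of any
  specific prediction tool.
* The NB test has no shrinkage, outlier handling, or independent filtering;
  with more than a handful of replicates a dedicated DE package is the
  right tool.
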