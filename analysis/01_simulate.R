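#!/usr/bin/env Rscript

## Stage 1: simulate the synthetic study.
##
## Emulates the 4-stage (D0, D15, D85, Y2) x 3-replicate design: a small
## two-chromosome genome with 60 multi-exon genes, 50 implanted circRNAs
## with AG...GT genomic splice flanks, 24 miRNAs whose seed complements are
## implanted into 3'UTRs, lncRNAs, circRNA bodies and across back-splice
## junctions, whole-transcriptome + circRNA-seq + small-RNA read sets, and
## negative-binomial count matrices with designed stage-selective profiles.
## Everything implanted is recorded in the ground-truth manifest.

library(cesponge)

seed <- 1L
out <- "results/data"

cfg <- simulation_config(seed = seed)
ds <- generate_dataset(cfg)
write_dataset(ds, out)

cat("synthetic dataset written to", out, "\n")
cat("  genome:", length(ds$genome), "chromosomes,",
    sum(nchar(ds$genome)), "nt\n")
cat("  genes:", nrow(ds$genes), " circRNAs:", nrow(ds$manifest$circ_truth),
    " miRNAs:", length(ds$mirna), " lncRNAs:", length(ds$lncrna), "\n")
cat("  implanted MREs:", nrow(ds$manifest$mre_truth),
    "(", sum(ds$manifest$mre_truth$target_class == "circ_junction"),
    "junction-spanning )\n")
cat("  junction-only circRNA-miRNA pairs in truth:",
    nrow(ds$manifest$novel_junction_pairs), "\n")
cat("  samples:", paste(ds$sample_info$sample_id, collapse = " "), "\n")
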