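#!/usr/bin/env Rscript

## Stage 3: small-RNA processing and differential expression.
##
## Small-RNA reads are adapter-trimmed (3' adapter, zero mismatches, >= 3 nt
## overlap, 18-30 nt inserts kept) and counted against the mature miRNA set
## by exact match under T/U equivalence. Each feature class is then tested
## between every pair of stages with the simplified NB Wald test; features
## with p < 0.05 and |log2FC| > 1 are called differentially expressed.

library(cesponge)

data_dir <- "results/data"
res_dir <- "results"

samples <- read.delim(file.path(data_dir, "manifest", "samples.tsv"))
mature <- read_fasta(file.path(data_dir, "mirna.fa"))

mirna_counts <- vapply(samples$sample_id, function(s) {
  reads <- read_fastq(file.path(data_dir, "reads", paste0("smallrna_", s, ".fastq")))
  trimmed <- trim_small_rna(reads, trim_policy())
  count_mirna(trimmed, mature)
}, numeric(length(mature)))
storage.mode(mirna_counts) <- "integer"
write_counts(mirna_counts, file.path(res_dir, "mirna_counts_from_reads.tsv"))
cat("miRNA counts from reads:", nrow(mirna_counts), "miRNAs x",
    ncol(mirna_counts), "samples\n")

counts <- list(
  mirna = mirna_counts,
  mrna = read_counts(file.path(data_dir, "counts_mrna.tsv")),
  lncrna = read_counts(file.path(data_dir, "counts_lncrna.tsv")),
  circ = read_counts(file.path(data_dir, "counts_circ.tsv")))

stages <- samples$stage[match(colnames(counts$mirna), samples$sample_id)]
cmp <- combn(unique(stages), 2)
de <- list()
for (cl in names(counts)) {
  for (j in seq_len(ncol(cmp))) {
    ga <- samples$sample_id[samples$stage == cmp[1, j]]
    gb <- samples$sample_id[samples$stage == cmp[2, j]]
    d <- nb_wald_de(counts[[cl]], ga, gb)
    d$class <- cl; d$group_a <- cmp[1, j]; d$group_b <- cmp[2, j]
    de[[paste(cl, j)]] <- d
    cat(sprintf("  %-6s %s vs %s: %d up, %d down\n", cl, cmp[2, j], cmp[1, j],
                sum(d$significant & d$log2fc > 0),
                sum(d$significant & d$log2fc < 0)))
  }
}
de <- do.call(rbind, de)
rownames(de) <- NULL
write_network_tsv(de, file.path(res_dir, "differential_expression.tsv"))
cat("DE features (any comparison):",
    length(unique(de$feature_id[de$significant])), "\n")
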