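#!/usr/bin/env Rscript

## Stage 2: back-splice junction detection and credibility filtering.
##
## Reads that fail exact linear mapping have their 20 nt terminal anchors
## remapped; a reversed anchor order with a unique, GT/AG-consistent
## breakpoint calls a junction. Candidates need >= 2 unique BSJ reads in at
## least one sample, and only junctions seen in both the whole-transcriptome
## and the circRNA-seq arm are kept as credible circRNAs.

library(cesponge)

data_dir <- "results/data"
res_dir <- "results"

genome <- as.list(read_fasta(file.path(data_dir, "genome.fa")))
annotation <- read_gtf(file.path(data_dir, "annotation.gtf"))
samples <- read.delim(file.path(data_dir, "manifest", "samples.tsv"))

index <- build_index(genome, k = 20)

wt_cands <- data.table::rbindlist(lapply(samples$sample_id, function(s) {
  reads <- read_fastq(file.path(data_dir, "reads", paste0("wholetx_", s, ".fastq")))
  r <- call_bsj_readset(reads, index, genome, sample_id = s)
  cat(sprintf("  %s: %d reads, %d linear, %d BSJ\n", s,
              r$stats["n_reads"], r$stats["linear"], r$stats["bsj"]))
  r$candidates
}))
wt <- aggregate_candidates(wt_cands, min_unique = 2)

cs_reads <- read_fastq(file.path(data_dir, "reads", "circseq_pool.fastq"))
cs <- aggregate_candidates(
  call_bsj_readset(cs_reads, index, genome, sample_id = "pool")$candidates,
  min_unique = 2)

credible <- merge_dual_evidence(wt$junctions, cs$junctions)
cat("whole-tx junctions:", nrow(wt$junctions),
    " circRNA-seq junctions:", nrow(cs$junctions),
    " credible:", nrow(credible), "\n")

## spliced sequences of the credible circRNAs (annotation-aware); junctions
## that coincide with a manifest circRNA take its id, the rest keep their
## coordinate id
truth <- read.delim(file.path(data_dir, "manifest", "circ_truth.tsv"))
k <- function(d) paste(d$chrom, d$start, d$end, d$strand)
mapped <- truth$circ_id[match(k(credible), k(truth))]
credible$circ_id <- ifelse(is.na(mapped), credible$circ_id, mapped)
spliced <- vapply(seq_len(nrow(credible)), function(i) {
  spliced_sequence(as.list(credible[i, ]), annotation, genome)
}, character(1))
names(spliced) <- credible$circ_id

write_bed(data.frame(chrom = credible$chrom, start = credible$start,
                     end = credible$end, name = credible$circ_id,
                     score = rowSums(as.data.frame(credible)[, samples$sample_id]),
                     strand = credible$strand),
          file.path(res_dir, "circ_credible.bed"))
write_fasta(spliced, file.path(res_dir, "circ_credible.fa"))
write_network_tsv(as.data.frame(credible), file.path(res_dir, "circ_bsj_counts.tsv"))

## recovery against the simulation's ground truth
cat(sprintf("recall vs manifest: %.3f  precision: %.3f\n",
            mean(k(truth) %in% k(credible)), mean(k(credible) %in% k(truth))))
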