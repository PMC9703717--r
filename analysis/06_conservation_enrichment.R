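#!/usr/bin/env Rscript

## Stage 6: conservation screen and term enrichment.
##
## Network circRNAs are aligned (Smith-Waterman, both strands) against a
## synthetic cross-species reference database -- point-mutated copies of half
## the circRNAs plus unrelated decoys -- and called conserved under the
## three-threshold rule (per-alignment identity >= 70%, union coverage
## >= 100 nt, total identity >= 75%). Network mRNAs are tested for term
## enrichment with the EASE-penalised hypergeometric test against a
## synthetic term map that includes each miRNA's designed target set.

library(cesponge)

data_dir <- "results/data"
res_dir <- "results"
seed <- 1L

circ <- read_fasta(file.path(res_dir, "circ_credible.fa"))
axes_circ <- read_network_tsv(file.path(res_dir, "axes_circ.tsv"))
mre <- read.delim(file.path(data_dir, "manifest", "mre_truth.tsv"))
genes <- read_gtf(file.path(data_dir, "annotation.gtf"))
universe <- unique(genes$gene_id)

## synthetic reference database (deterministic under the seed)
set.seed(seed + 1000L)
ids <- names(circ)
mut <- function(s, rate = 0.08) {
  hit <- which(runif(nchar(s)) < rate)
  for (i in hit) substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                                  substr(s, i, i)), 1)
  s
}
refdb <- c(setNames(vapply(circ[seq_along(ids) %% 2 == 1], mut, character(1)),
                    paste0("ref_", ids[seq_along(ids) %% 2 == 1])),
           setNames(vapply(1:5, function(i) {
             paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
           }, character(1)), paste0("decoy", 1:5)))

screen_ids <- unique(axes_circ$cerna_id)
if (length(screen_ids) == 0) screen_ids <- names(circ)
screen_ids <- intersect(screen_ids, names(circ))
if (length(screen_ids) == 0) screen_ids <- names(circ)
cons <- conservation_screen(circ[screen_ids], refdb)
write_network_tsv(cons, file.path(res_dir, "conservation.tsv"))
cat("conserved circRNAs:", sum(cons$conserved), "of", nrow(cons), "screened\n")

## enrichment of the circRNA-network mRNAs
set.seed(seed + 2000L)
utr <- mre[mre$target_class == "utr3", ]
term_map <- split(utr$target_id, paste0("targets_of_", utr$mirna_id))
for (i in 1:8) {
  term_map[[sprintf("random_term_%02d", i)]] <- sample(universe, max(5, length(universe) %/% 6))
}
gene_set <- intersect(unique(axes_circ$mrna_id), universe)
enr <- ease_enrichment(gene_set, universe, term_map)
write_network_tsv(enr, file.path(res_dir, "enrichment.tsv"))
cat("enriched terms (p < 0.05):", sum(enr$significant), "of", nrow(enr), "\n")
print(head(enr[, c("term_id", "overlap", "term_size", "p")], 3), row.names = FALSE)
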