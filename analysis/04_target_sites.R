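#!/usr/bin/env Rscript

## Stage 4: miRNA target-site prediction.
##
## Seed-anchored (miRNA positions 2-8, Watson-Crick, T == U) site scanning
## on 3'UTRs and lncRNAs, plus the back-splice-junction analysis: the last
## 100 nt and first 100 nt of each credible circRNA are linked into a
## pseudo-sequence, sites strictly straddling the junction are kept, and
## pairs with a junction site but no site anywhere on the linear spliced
## sequence are reported as junction-only (novel) interactions.

library(cesponge)

data_dir <- "results/data"
res_dir <- "results"

mirnas <- read_fasta(file.path(data_dir, "mirna.fa"))
utr3 <- read_fasta(file.path(data_dir, "utr3.fa"))
lncrna <- read_fasta(file.path(data_dir, "lncrna.fa"))
circ <- read_fasta(file.path(res_dir, "circ_credible.fa"))

params <- score_params()
sites_utr <- predict_target_sites(mirnas, utr3, params)
sites_lnc <- predict_target_sites(mirnas, lncrna, params)
sites_circ <- predict_target_sites(mirnas, circ, params)
junc_sites <- predict_junction_sites(mirnas, circ, params)
novel <- novel_junction_pairs(mirnas, circ, params)

write_network_tsv(sites_utr, file.path(res_dir, "sites_utr3.tsv"))
write_network_tsv(sites_lnc, file.path(res_dir, "sites_lncrna.tsv"))
write_network_tsv(sites_circ, file.path(res_dir, "sites_circ_linear.tsv"))
write_network_tsv(junc_sites, file.path(res_dir, "sites_circ_junction.tsv"))
write_network_tsv(novel, file.path(res_dir, "novel_junction_pairs.tsv"))

cat("sites on 3'UTRs:", nrow(sites_utr),
    " on lncRNAs:", nrow(sites_lnc),
    " on circRNA linear sequences:", nrow(sites_circ), "\n")
cat("junction-spanning sites:", nrow(junc_sites),
    " junction-only circRNA-miRNA pairs:", nrow(novel), "\n")

truth <- read.delim(file.path(data_dir, "manifest", "novel_junction_pairs.tsv"))
cat(sprintf("junction-only pairs vs manifest: recall %.3f, precision %.3f\n",
            mean(paste(truth$circ_id, truth$mirna_id) %in%
                   paste(novel$circ_id, novel$mirna_id)),
            mean(paste(novel$circ_id, novel$mirna_id) %in%
                   paste(truth$circ_id, truth$mirna_id))))
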