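#!/usr/bin/env Rscript

## Stage 5: correlation-gated ceRNA networks and stage clustering.
##
## A sequence-predicted pair becomes a network edge only when its expression
## profiles are anti-correlated across the 12 samples (Spearman rho < -0.6,
## p < 0.05). miRNAs bound by both a ceRNA and an mRNA define the
## (ceRNA, miRNA, mRNA) regulatory axes of the circRNA- and lncRNA-centred
## triple networks, whose miRNA complements are then compared. DE features
## are k-means-clustered (k = 7) on z-scored stage means and clusters are
## labelled with the stage where their centroid peaks.

library(cesponge)

data_dir <- "results/data"
res_dir <- "results"
seed <- 1L

samples <- read.delim(file.path(data_dir, "manifest", "samples.tsv"))
stages <- samples$stage
counts <- list(
  mirna = read_counts(file.path(res_dir, "mirna_counts_from_reads.tsv")),
  mrna = read_counts(file.path(data_dir, "counts_mrna.tsv")),
  lncrna = read_counts(file.path(data_dir, "counts_lncrna.tsv")),
  circ = read_counts(file.path(data_dir, "counts_circ.tsv")))
profiles <- lapply(counts, function(m) t(t(m) / size_factors(m)))

## detected circRNAs are keyed by coordinates; map them to manifest ids so
## expression profiles (quantified per manifest feature) can be attached
truth <- read.delim(file.path(data_dir, "manifest", "circ_truth.tsv"))
bed <- read.delim(file.path(res_dir, "circ_credible.bed"), header = FALSE,
                  col.names = c("chrom", "start", "end", "name", "score", "strand"))
bed$feature <- truth$circ_id[match(paste(bed$chrom, bed$start, bed$end, bed$strand),
                                   paste(truth$chrom, truth$start, truth$end, truth$strand))]
id_map <- setNames(bed$feature, bed$name)

as_pairs <- function(sites, map = NULL) {
  src <- if (is.null(map)) sites$target_id else unname(map[sites$target_id])
  data.frame(source_id = src, mirna_id = sites$mirna_id)
}
sites_utr <- read_network_tsv(file.path(res_dir, "sites_utr3.tsv"))
sites_lnc <- read_network_tsv(file.path(res_dir, "sites_lncrna.tsv"))
sites_circ <- read_network_tsv(file.path(res_dir, "sites_circ_linear.tsv"))

edges_mrna <- corr_filter(as_pairs(sites_utr), profiles$mrna, profiles$mirna)
edges_lnc <- corr_filter(as_pairs(sites_lnc), profiles$lncrna, profiles$mirna)
edges_circ <- corr_filter(as_pairs(sites_circ, id_map), profiles$circ, profiles$mirna)
cat("edges passing the correlation gate: miRNA-mRNA", nrow(edges_mrna),
    ", lncRNA-miRNA", nrow(edges_lnc), ", circRNA-miRNA", nrow(edges_circ), "\n")

axes_circ <- assemble_triples(edges_circ, edges_mrna, "circRNA")
axes_lnc <- assemble_triples(edges_lnc, edges_mrna, "lncRNA")
overlap <- network_overlap(axes_circ, axes_lnc, "circRNA", "lncRNA")
cat("triple axes: circRNA network", nrow(axes_circ),
    ", lncRNA network", nrow(axes_lnc), "\n")
cat(sprintf("miRNA overlap: %d shared; %.1f%% of the lncRNA network's miRNAs\n",
            length(overlap$shared), 100 * overlap$fraction_b))

for (obj in list(list(edges_mrna, "edges_mirna_mrna.tsv"),
                 list(edges_lnc, "edges_lncrna_mirna.tsv"),
                 list(edges_circ, "edges_circ_mirna.tsv"),
                 list(axes_circ, "axes_circ.tsv"),
                 list(axes_lnc, "axes_lncrna.tsv"),
                 list(overlap$summary, "network_overlap.tsv"))) {
  write_network_tsv(obj[[1]], file.path(res_dir, obj[[2]]))
}
if (nrow(axes_circ)) write_graphml(axes_circ, file.path(res_dir, "axes_circ.graphml"))
if (nrow(axes_lnc)) write_graphml(axes_lnc, file.path(res_dir, "axes_lncrna.graphml"))

## stage-selective clustering of DE features
de <- read_network_tsv(file.path(res_dir, "differential_expression.tsv"))
for (cl in c("mirna", "circ")) {
  ids <- unique(de$feature_id[de$class == cl & de$significant])
  if (length(ids) <= 7) ids <- rownames(profiles[[cl]])
  kc <- kmeans_stage_clusters(profiles[[cl]][ids, ], stages, k = 7, seed = seed)
  tab <- data.frame(feature_id = names(kc$cluster), cluster = unname(kc$cluster),
                    selective_stage = kc$selective_stage[kc$cluster])
  write_network_tsv(tab, file.path(res_dir, paste0("clusters_", cl, ".tsv")))
  cat(cl, "clusters ->", paste(sprintf("%s:%s", seq_along(kc$selective_stage),
                                       kc$selective_stage), collapse = " "), "\n")
}
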