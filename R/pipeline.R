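#' Pipeline configuration
#'
#' Bundles the simulation settings and every analysis threshold used by
#' [run_pipeline()]. All thresholds are validated before any stage runs.
#'
#' @param sim a [simulation_config()].
#' @param anchor_len BSJ anchor length (nt, >= 12).
#' @param min_unique_reads unique-BSJ-read support filter (>= 1).
#' @param max_span maximal circRNA genomic span (nt).
#' @param alpha,lfc differential-expression decision thresholds
#'   (p < alpha and |log2FC| > lfc).
#' @param rho_max,p_max Spearman gates for ceRNA edges (rho_max must be
#'   negative: the gate selects anti-correlated pairs).
#' @param k_clusters,cluster_margin stage-clustering settings.
#' @param score a [score_params()] for target prediction.
#' @param min_identity,min_total_identity,min_cover conservation thresholds.
#' @param enrich_alpha enrichment significance threshold.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            anchor_len = 20L, min_unique_reads = 2L,
                            max_span = 50000L,
                            alpha = 0.05, lfc = 1,
                            rho_max = -0.6, p_max = 0.05,
                            k_clusters = 7L, cluster_margin = 0.5,
                            score = score_params(),
                            min_identity = 0.70, min_total_identity = 0.75,
                            min_cover = 100L, enrich_alpha = 0.05) {
  cfg <- list(sim = sim, anchor_len = as.integer(anchor_len),
              min_unique_reads = as.integer(min_unique_reads),
              max_span = as.integer(max_span), alpha = alpha, lfc = lfc,
              rho_max = rho_max, p_max = p_max,
              k_clusters = as.integer(k_clusters), cluster_margin = cluster_margin,
              score = score, min_identity = min_identity,
              min_total_identity = min_total_identity,
              min_cover = as.integer(min_cover), enrich_alpha = enrich_alpha)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
validate_pipeline_config <- function(cfg) {
  if (!inherits(cfg$sim, "simulation_config")) stop("cfg$sim must be a simulation_config")
  validate_simulation_config(cfg$sim)
  if (cfg$anchor_len < 12L) stop("anchor_len must be >= 12")
  if (cfg$min_unique_reads < 1L) stop("min_unique_reads must be >= 1")
  if (cfg$rho_max >= 0) {
    stop("rho_max must be negative: the correlation gate selects ",
         "anti-correlated ceRNA-miRNA pairs (got ", cfg$rho_max, ")")
  }
  for (nm in c("alpha", "p_max", "enrich_alpha")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1) stop(nm, " must be in (0, 1]")
  }
  if (cfg$lfc < 0) stop("lfc must be non-negative")
  if (cfg$k_clusters < 1L) stop("k_clusters must be >= 1")
  for (nm in c("min_identity", "min_total_identity")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must be in [0, 1]")
  }
  invisible(cfg)
}

## deterministic synthetic reference database for the conservation screen:
## point-mutated copies of half the circRNAs plus unrelated decoys
.synthetic_refdb <- function(circ_seqs, mut_rate = 0.08, n_decoys = 5L) {
  ids <- names(circ_seqs)
  conserved_ids <- ids[seq_along(ids) %% 2L == 1L]
  refs <- vapply(conserved_ids, function(cid) {
    s <- circ_seqs[[cid]]
    n <- nchar(s)
    hit <- which(stats::runif(n) < mut_rate)
    for (i in hit) {
      substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"), substr(s, i, i)), 1L)
    }
    s
  }, character(1))
  names(refs) <- paste0("ref_", conserved_ids)
  decoys <- stats::setNames(random_dna(n_decoys, 300L), paste0("decoy", seq_len(n_decoys)))
  c(refs, decoys)
}

## deterministic synthetic term map over the gene universe: one term per
## miRNA (its designed targets) plus random terms
.synthetic_term_map <- function(gene_ids, mre_truth, n_random = 8L) {
  utr <- mre_truth[mre_truth$target_class == "utr3", , drop = FALSE]
  tm <- split(utr$target_id, paste0("targets_of_", utr$mirna_id))
  for (i in seq_len(n_random)) {
    tm[[sprintf("random_term_%02d", i)]] <- sample(gene_ids, max(5L, length(gene_ids) %/% 6L))
  }
  tm
}

#' Run the full synthetic ceRNA-network pipeline
#'
#' Chains simulate -> BSJ detection (whole-transcriptome + circRNA-seq
#' arms) -> credibility merge -> small-RNA trimming/counting ->
#' differential expression -> target prediction (3'UTR, lncRNA, circRNA
#' pseudo-sequence) -> correlation-gated triple networks -> stage-selective
#' clustering -> conservation screen -> term enrichment. Every output file
#' is listed with its MD5 checksum, together with all parameters, in
#' `provenance.tsv`; reruns with an identical configuration are
#' byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all intermediate and final results.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir, quiet = FALSE) {
  validate_pipeline_config(cfg)
  say <- function(...) if (!quiet) message(...)
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(res_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  ## 1. simulate ---------------------------------------------------------------
  say("simulating dataset (seed ", cfg$sim$seed, ")")
  ds <- generate_dataset(cfg$sim)
  write_dataset(ds, file.path(out_dir, "data"))
  stages <- ds$sample_info$stage
  samples <- ds$sample_info$sample_id

  ## 2. BSJ detection, both library arms --------------------------------------
  say("detecting back-splice junctions")
  genome <- as.list(ds$genome)
  index <- build_index(genome, cfg$anchor_len)
  wt_cands <- data.table::rbindlist(lapply(samples, function(s) {
    call_bsj_readset(ds$read_sets$wholetx[[s]], index, genome, sample_id = s,
                     max_span = cfg$max_span)$candidates
  }))
  wt <- aggregate_candidates(wt_cands, cfg$min_unique_reads)
  cs_cands <- call_bsj_readset(ds$read_sets$circseq, index, genome,
                               sample_id = "pool", max_span = cfg$max_span)$candidates
  cs <- aggregate_candidates(cs_cands, cfg$min_unique_reads)
  credible <- merge_dual_evidence(wt$junctions, cs$junctions)
  say("  credible circRNAs: ", nrow(credible))

  ## map detected junctions to manifest ids (exact-coordinate match)
  truth <- ds$manifest$circ_truth
  key <- paste(truth$chrom, truth$start, truth$end, truth$strand)
  credible_ids <- truth$circ_id[match(
    paste(credible$chrom, credible$start, credible$end, credible$strand), key)]
  circ_spliced <- stats::setNames(vapply(seq_len(nrow(credible)), function(i) {
    spliced_sequence(as.list(credible[i, ]), ds$annotation, genome)
  }, character(1)), ifelse(is.na(credible_ids),
                           credible$circ_id, credible_ids))
  write_bed(data.frame(chrom = credible$chrom, start = credible$start,
                       end = credible$end, name = names(circ_spliced),
                       score = 0, strand = credible$strand),
            file.path(res_dir, "circ_credible.bed"))
  cnt_cols <- intersect(samples, names(credible))
  circ_bsj_counts <- as.data.frame(credible)[, c("circ_id", cnt_cols), drop = FALSE]
  tsv(circ_bsj_counts, "circ_bsj_read_counts.tsv")

  ## 3. small-RNA trimming and counting ----------------------------------------
  say("trimming and counting small-RNA reads")
  mirna_counts <- vapply(samples, function(s) {
    trimmed <- trim_small_rna(ds$read_sets$smallrna[[s]], trim_policy())
    count_mirna(trimmed, ds$mirna)
  }, numeric(length(ds$mirna)))
  mirna_counts <- round(mirna_counts)
  storage.mode(mirna_counts) <- "integer"
  write_counts(mirna_counts, file.path(res_dir, "mirna_counts_from_reads.tsv"))

  ## 4. differential expression -------------------------------------------------
  say("differential expression across stage pairs")
  counts <- ds$counts
  counts$mirna <- mirna_counts
  cmp <- utils::combn(unique(stages), 2L)
  de <- list()
  for (cl in names(counts)) {
    for (j in seq_len(ncol(cmp))) {
      ga <- samples[stages == cmp[1, j]]; gb <- samples[stages == cmp[2, j]]
      d <- nb_wald_de(counts[[cl]], ga, gb, alpha = cfg$alpha, lfc = cfg$lfc)
      d$class <- cl; d$group_a <- cmp[1, j]; d$group_b <- cmp[2, j]
      de[[paste(cl, j)]] <- d
    }
  }
  de <- do.call(rbind, de)
  rownames(de) <- NULL
  tsv(de, "differential_expression.tsv")

  ## normalized profiles for correlations and clustering
  norm_profiles <- lapply(counts, function(m) t(t(m) / size_factors(m)))

  ## 5. target prediction --------------------------------------------------------
  say("predicting miRNA target sites")
  sites_utr <- predict_target_sites(ds$mirna, ds$utr3, cfg$score)
  sites_lnc <- predict_target_sites(ds$mirna, ds$lncrna, cfg$score)
  sites_circ <- predict_target_sites(ds$mirna, circ_spliced, cfg$score)
  junc_pairs <- novel_junction_pairs(ds$mirna, circ_spliced, cfg$score)
  tsv(sites_utr, "sites_utr3.tsv"); tsv(sites_lnc, "sites_lncrna.tsv")
  tsv(sites_circ, "sites_circ_linear.tsv")
  tsv(junc_pairs, "novel_junction_pairs.tsv")

  ## 6. correlation-gated edges and triple networks ------------------------------
  say("assembling correlation-gated triple networks")
  as_pairs <- function(sites) data.frame(source_id = sites$target_id,
                                         mirna_id = sites$mirna_id,
                                         stringsAsFactors = FALSE)
  edges_mrna <- corr_filter(as_pairs(sites_utr), norm_profiles$mrna,
                            norm_profiles$mirna, cfg$rho_max, cfg$p_max)
  edges_lnc <- corr_filter(as_pairs(sites_lnc), norm_profiles$lncrna,
                           norm_profiles$mirna, cfg$rho_max, cfg$p_max)
  edges_circ <- corr_filter(as_pairs(sites_circ), norm_profiles$circ,
                            norm_profiles$mirna, cfg$rho_max, cfg$p_max)
  axes_circ <- assemble_triples(edges_circ, edges_mrna, "circRNA")
  axes_lnc <- assemble_triples(edges_lnc, edges_mrna, "lncRNA")
  overlap <- network_overlap(axes_circ, axes_lnc, "circRNA", "lncRNA")
  tsv(edges_mrna, "edges_mirna_mrna.tsv"); tsv(edges_lnc, "edges_lncrna_mirna.tsv")
  tsv(edges_circ, "edges_circ_mirna.tsv")
  tsv(axes_circ, "axes_circ.tsv"); tsv(axes_lnc, "axes_lncrna.tsv")
  if (nrow(axes_circ) > 0L) write_graphml(axes_circ, file.path(res_dir, "axes_circ.graphml"))
  if (nrow(axes_lnc) > 0L) write_graphml(axes_lnc, file.path(res_dir, "axes_lncrna.graphml"))
  tsv(overlap$summary, "network_overlap.tsv")

  ## 7. stage-selective clustering ------------------------------------------------
  say("stage-selective k-means clustering")
  ## cluster the differentially expressed features of a class (all features
  ## when too few are DE to fill k clusters)
  clusters <- lapply(c(mirna = "mirna", circ = "circ"), function(cl) {
    prof <- norm_profiles[[cl]]
    ids <- unique(de$feature_id[de$class == cl & de$significant])
    if (length(ids) <= cfg$k_clusters) ids <- rownames(prof)
    kmeans_stage_clusters(prof[ids, , drop = FALSE], stages,
                          k = cfg$k_clusters, seed = cfg$sim$seed,
                          margin = cfg$cluster_margin)
  })
  for (cl in names(clusters)) {
    kk <- clusters[[cl]]
    tsv(data.frame(feature_id = names(kk$cluster), cluster = unname(kk$cluster),
                   selective_stage = kk$selective_stage[kk$cluster]),
        paste0("clusters_", cl, ".tsv"))
  }

  ## 8. conservation screen ---------------------------------------------------------
  say("conservation screen")
  set.seed(cfg$sim$seed + 1000L)
  network_circs <- unique(axes_circ$cerna_id)
  refdb <- .synthetic_refdb(circ_spliced)
  screen_ids <- if (length(network_circs) > 0L) network_circs else names(circ_spliced)
  cons <- conservation_screen(circ_spliced[screen_ids], refdb,
                              min_identity = cfg$min_identity,
                              min_total_identity = cfg$min_total_identity,
                              min_cover = cfg$min_cover)
  tsv(cons, "conservation.tsv")

  ## 9. enrichment -------------------------------------------------------------------
  say("term enrichment of network mRNAs")
  set.seed(cfg$sim$seed + 2000L)
  term_map <- .synthetic_term_map(ds$genes$gene_id, ds$manifest$mre_truth)
  net_genes <- unique(axes_circ$mrna_id)
  enr <- if (length(net_genes) > 0L) {
    ease_enrichment(net_genes, ds$genes$gene_id, term_map, cfg$enrich_alpha)
  } else {
    ease_enrichment(character(0), ds$genes$gene_id, term_map, cfg$enrich_alpha)
  }
  tsv(enr, "enrichment.tsv")

  ## 10. provenance ---------------------------------------------------------------
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "provenance.tsv"]
  flat <- function(x) vapply(x, function(v) paste(format(v, digits = 15), collapse = ","),
                             character(1))
  prov <- rbind(
    data.frame(key = paste0("param.sim.", names(cfg$sim)), value = flat(cfg$sim)),
    data.frame(key = paste0("param.", setdiff(names(cfg), c("sim", "score"))),
               value = flat(cfg[setdiff(names(cfg), c("sim", "score"))])),
    data.frame(key = paste0("param.score.", names(cfg$score)), value = flat(cfg$score)),
    data.frame(key = paste0("md5.", sub(paste0("^", out_dir, "/?"), "", files)),
               value = unname(tools::md5sum(files))))
  utils::write.table(prov, file.path(out_dir, "provenance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  say("done: ", out_dir)

  invisible(list(dataset = ds, credible = credible, circ_spliced = circ_spliced,
                 mirna_counts = mirna_counts, de = de,
                 sites = list(utr3 = sites_utr, lncrna = sites_lnc, circ = sites_circ),
                 novel_junction_pairs = junc_pairs,
                 edges = list(mrna = edges_mrna, lncrna = edges_lnc, circ = edges_circ),
                 axes = list(circ = axes_circ, lncrna = axes_lnc),
                 overlap = overlap, clusters = clusters,
                 conservation = cons, enrichment = enr, out_dir = out_dir))
}
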