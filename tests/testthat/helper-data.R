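## Shared fixtures, built once per test run. The default synthetic dataset
## and its BSJ detection results are cached because several files (and the
## acceptance tests) exercise them.

.cache <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.cache$ds)) .cache$ds <- generate_dataset(simulation_config())
  .cache$ds
}

small_config <- function(seed = 5L) {
  simulation_config(seed = seed, n_genes = 20L, n_circ = 10L, n_mirna = 8L,
                    n_lncrna = 8L, bsj_coverage = 4L, linear_coverage = 0.5)
}

## full dual-library detection on the default dataset
default_detection <- function() {
  if (is.null(.cache$det)) {
    ds <- default_dataset()
    genome <- as.list(ds$genome)
    index <- build_index(genome)
    wt_cands <- data.table::rbindlist(lapply(ds$sample_info$sample_id, function(s) {
      call_bsj_readset(ds$read_sets$wholetx[[s]], index, genome, sample_id = s)$candidates
    }))
    cs_cands <- call_bsj_readset(ds$read_sets$circseq, index, genome,
                                 sample_id = "pool")$candidates
    wt <- aggregate_candidates(wt_cands)
    cs <- aggregate_candidates(cs_cands)
    .cache$det <- list(genome = genome, index = index, wt_cands = wt_cands,
                       wt = wt, cs = cs,
                       credible = merge_dual_evidence(wt$junctions, cs$junctions))
  }
  .cache$det
}

coord_key <- function(df) paste(df$chrom, df$start, df$end, df$strand)

## independent brute-force re-implementation of the credibility filters,
## used as the oracle for aggregate_candidates / merge_dual_evidence
brute_force_credible <- function(cand, min_unique = 2L, circseq_keys = NULL) {
  keys <- unique(coord_key(cand))
  kept <- character(0)
  for (k in keys) {
    rows <- cand[coord_key(cand) == k, , drop = FALSE]
    ok <- FALSE
    for (s in unique(rows$sample_id)) {
      if (length(unique(rows$read_seq[rows$sample_id == s])) >= min_unique) ok <- TRUE
    }
    if (ok && (is.null(circseq_keys) || k %in% circseq_keys)) kept <- c(kept, k)
  }
  sort(kept)
}

## exhaustive position-by-position seed-site scan (oracle for seed_sites)
brute_force_seed_scan <- function(mirna_seq, target) {
  mirna_seq <- as_rna(mirna_seq)
  target <- as_dna(target)
  seed_rc <- revcomp(as_dna(substr(mirna_seq, 2, 8)))
  hits <- integer(0)
  if (nchar(target) >= 7) {
    for (i in 0:(nchar(target) - 7)) {
      if (substr(target, i + 1, i + 7) == seed_rc) hits <- c(hits, i)
    }
  }
  hits
}

## textbook Smith-Waterman with linear gaps (oracle for local_align scores)
sw_score <- function(a, b, match = 1, mismatch = -2, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (a[i] == b[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + sc, H[i, j + 1] + gap, H[i + 1, j] + gap)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}
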