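test_that("infeasible configurations fail with the violated constraint", {
  expect_error(simulation_config(n_circ = 100, n_genes = 50), "n_circ")
  expect_error(simulation_config(nb_dispersion = 0), "dispersion")
  expect_error(simulation_config(reps_per_stage = 1), "reps_per_stage")
  expect_error(generate_dataset(simulation_config(n_genes = 200, n_circ = 10)),
               "do not fit")
})

test_that("identical seeds give byte-identical datasets on disk", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(small_config()), d1)
  write_dataset(generate_dataset(small_config()), d2)
  f <- list.files(d1, recursive = TRUE)
  expect_identical(f, list.files(d2, recursive = TRUE))
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
})

test_that("the manifest records exactly the configured circRNAs with AG/GT flanks", {
  ds <- default_dataset()
  tr <- ds$manifest$circ_truth
  expect_equal(nrow(tr), ds$config$n_circ)
  for (i in seq_len(nrow(tr))) {
    g <- ds$genome[[tr$chrom[i]]]
    up <- substr(g, tr$start[i] - 1, tr$start[i])      # [start-2, start)
    dn <- substr(g, tr$end[i] + 1, tr$end[i] + 2)      # [end, end+2)
    if (tr$strand[i] == "+") {
      expect_identical(c(up, dn), c("AG", "GT"))
    } else {
      expect_identical(c(revcomp(dn), revcomp(up)), c("AG", "GT"))
    }
    expect_equal(nchar(tr$spliced_sequence[i]), tr$spliced_length[i])
  }
})

test_that("junction MRE seeds are split across the BSJ and absent from the linear sequence", {
  ds <- default_dataset()
  mre <- ds$manifest$mre_truth
  junc <- mre[mre$target_class == "circ_junction", ]
  expect_gt(nrow(junc), 0)
  for (i in seq_len(nrow(junc))) {
    m <- junc$mirna_id[i]
    sq <- ds$circ_seqs[[junc$target_id[i]]]
    sc <- revcomp(as_dna(substr(ds$mirna[[m]], 2, 8)))
    ## independent substring-scan oracle: not in the linear sequence (hence
    ## in neither the head nor the tail window alone) ...
    expect_false(grepl(sc, sq, fixed = TRUE))
    ## ... but present straddling the junction of the pseudo-sequence
    ps <- bsj_pseudo_sequence(sq)
    hits <- gregexpr(sc, ps$pseudo, fixed = TRUE)[[1]]
    expect_true(any(hits != -1 & (hits - 1) < ps$junction_offset &
                      (hits - 1) + 7 > ps$junction_offset))
  }
  ## drawn junction-MRE count matches the configured fraction
  expect_equal(nrow(junc),
               round(ds$config$fraction_junction_only_mres * ds$config$n_circ))
})

test_that("implanted 3'UTR and lncRNA MREs are present in the emitted sequences", {
  ds <- default_dataset()
  mre <- ds$manifest$mre_truth
  for (cls in c("utr3", "lncrna")) {
    sub <- mre[mre$target_class == cls, ]
    seqs <- if (cls == "utr3") ds$utr3 else ds$lncrna
    for (i in seq_len(nrow(sub))) {
      sc <- revcomp(as_dna(substr(ds$mirna[[sub$mirna_id[i]]], 2, 8)))
      expect_identical(substr(seqs[[sub$target_id[i]]], sub$site_start[i] + 1,
                              sub$site_end[i]), sc)
    }
  }
})

test_that("BSJ reads are junction-straddling windows of the doubled sequence", {
  circ <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  reads <- simulate_bsj_reads(circ, 10, 150)
  doubled <- paste0(circ, circ)
  for (r in reads) {
    pos <- regexpr(r, doubled, fixed = TRUE)[1]
    expect_gt(pos, 0)
    ## window crosses offset 500 with >= 21 nt on each side
    expect_lte(pos - 1, 500 - 21)
    expect_gte(pos - 1 + 150, 500 + 21)
  }
  expect_identical(simulate_bsj_reads(circ, 0, 150), character(0))
  expect_error(simulate_bsj_reads(substr(circ, 1, 100), 5, 150), "rolling")
  expect_equal(nchar(simulate_bsj_reads(substr(circ, 1, 100), 5, 150,
                                        rolling = TRUE)), rep(150L, 5))
})

test_that("simulated counts approach the Poisson limit as dispersion vanishes", {
  design <- matrix(100, 1, 4, dimnames = list("f1", c("D0", "D15", "D85", "Y2")))
  set.seed(99)
  cnt <- simulate_counts(design[rep(1, 2500), , drop = FALSE],
                         rep(c("D0", "D15", "D85", "Y2"), each = 1),
                         dispersion = 1e-6, size_factors = rep(1, 4))
  draws <- as.vector(cnt)   # 10,000 draws at mean 100
  expect_lt(abs(var(draws) - 100) / 100, 0.05)
  expect_error(simulate_counts(design, "D0", dispersion = 0), "positive")
})

test_that("designed sponge pairs are strongly anti-correlated at low dispersion", {
  design_mi <- matrix(2^(7 + 2 * c(1, 2 / 3, 1 / 3, 0)), 1, 4,
                      dimnames = list("m", c("D0", "D15", "D85", "Y2")))
  design_tg <- matrix(2^(7 + 2 * c(0, 1 / 3, 2 / 3, 1)), 1, 4,
                      dimnames = list("t", c("D0", "D15", "D85", "Y2")))
  stages <- rep(c("D0", "D15", "D85", "Y2"), each = 3)
  set.seed(123)
  hits <- replicate(200, {
    a <- simulate_counts(design_mi, stages, 0.01, size_factors = rep(1, 12))
    b <- simulate_counts(design_tg, stages, 0.01, size_factors = rep(1, 12))
    spearman_cor(as.numeric(a), as.numeric(b))$rho < -0.6
  })
  expect_gte(mean(hits), 0.9)
})

test_that("an all-stage-equal design stays mostly below the DE thresholds", {
  set.seed(7)
  design <- matrix(150, 2000, 4,
                   dimnames = list(paste0("f", 1:2000), c("D0", "D15", "D85", "Y2")))
  stages <- rep(c("D0", "D15", "D85", "Y2"), each = 3)
  cnt <- simulate_counts(design, stages, 0.1, size_factors = rep(1, 12))
  colnames(cnt) <- paste0(stages, "_", 1:12)
  de <- nb_wald_de(cnt, colnames(cnt)[1:3], colnames(cnt)[4:6], sf = rep(1, 6))
  expect_lte(mean(de$significant), 0.10)
})
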