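test_that("a perfect duplex gives exactly one maximally scoring site", {
  mi <- "UGAGGUAGUAGGUUGUAUAGUU"   # 22 nt
  target <- revcomp(as_dna(mi))
  s <- seed_sites("m", mi, "t", target)
  expect_equal(nrow(s), 1)
  expect_equal(s$start, 0)
  expect_equal(s$end, 22)
  expect_equal(s$score, 22 * score_params()$match_score)
  expect_identical(s$pairing, strrep("M", 22))
  ## no seed complement -> no sites
  expect_equal(nrow(seed_sites("m", mi, "t", strrep("A", 100))), 0)
})

test_that("site sets match an exhaustive position-by-position scan", {
  set.seed(101)
  target <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  for (i in 1:20) {
    mi <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = "")
    hits <- brute_force_seed_scan(mi, target)
    s <- seed_sites(sprintf("m%d", i), mi, "t", target)
    ## every oracle hit is inside a reported site of that miRNA (overlap
    ## dedup may merge neighbours); every reported site covers an oracle hit
    for (h in hits) {
      expect_true(any(s$start <= h & s$end >= h + 7))
    }
    if (length(hits) == 0) expect_equal(nrow(s), 0)
    for (j in seq_len(nrow(s))) {
      expect_true(any(hits >= s$start[j] & hits + 7 <= s$end[j]))
    }
  }
})

test_that("G:U wobble is rewarded outside the seed and mismatches penalized", {
  mi <- paste0("A", "GGGGGGG", "AAAAAAAAAAAAAA")   # seed = GGGGGGG (pos 2-8)
  target_core <- "CCCCCCC"                          # perfect seed complement
  ## target position pairing miRNA pos 9 is the base just before the core;
  ## miRNA pos 9 is A: WC partner T, wobble impossible, G is a mismatch
  t_mm <- paste0(strrep("T", 13), "G", target_core, "TA")
  t_wc <- paste0(strrep("T", 13), "T", target_core, "TA")
  p <- score_params()
  s_mm <- seed_sites("m", mi, "t", t_mm, p)
  s_wc <- seed_sites("m", mi, "t", t_wc, p)
  expect_equal(s_wc$score - s_mm$score, p$match_score - p$mismatch_score)
  ## miRNA pos 1 = A vs target G would also mismatch; U-mirna/G-target wobbles
  mi_u <- paste0("A", "GGGGGGG", "U", strrep("A", 13))
  t_wob <- paste0(strrep("T", 12), "G", target_core, "TA")  # G pairs miRNA U
  s_wob <- seed_sites("m", mi_u, "t", t_wob, p)
  expect_true(grepl("W", s_wob$pairing))
})

test_that("the BSJ pseudo-sequence follows the min(100, L) window rule", {
  set.seed(102)
  circ318 <- paste(sample(c("A", "C", "G", "T"), 318, replace = TRUE), collapse = "")
  ps <- bsj_pseudo_sequence(circ318)
  expect_equal(nchar(ps$pseudo), 200)
  expect_equal(ps$junction_offset, 100)
  expect_identical(ps$pseudo, paste0(substr(circ318, 219, 318), substr(circ318, 1, 100)))
  ## L = 150 < 200: windows overlap by 50 nt, no truncation
  circ150 <- substr(circ318, 1, 150)
  ps150 <- bsj_pseudo_sequence(circ150)
  expect_equal(nchar(ps150$pseudo), 200)
  expect_equal(ps150$junction_offset, 100)
  ## degenerate 4-mer doubles itself
  ps4 <- bsj_pseudo_sequence("ACGT")
  expect_identical(ps4$pseudo, "ACGTACGT")
  expect_equal(ps4$junction_offset, 4)
})

test_that("the junction filter keeps strictly straddling sites only", {
  sites <- data.frame(mirna_id = "m", target_id = "c",
                      start = c(90L, 0L, 100L), end = c(112L, 22L, 122L),
                      score = 35, pairing = "x", stringsAsFactors = FALSE)
  kept <- junction_filter(sites, 100L)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, 90L)
  expect_true(all(kept$spans_junction))
})

test_that("junction-spanning sites vanish when rescanning the linear sequence", {
  ds <- default_dataset()
  junc <- predict_junction_sites(ds$mirna, ds$circ_seqs)
  for (i in seq_len(nrow(junc))) {
    sq <- ds$circ_seqs[[junc$target_id[i]]]
    sc <- revcomp(as_dna(substr(ds$mirna[[junc$mirna_id[i]]], 2, 8)))
    joff <- junc$junction_offset[i]
    L <- nchar(sq)
    ## map the pseudo-coordinate seed back to circular coordinates: the site
    ## exists only under circularization, so the seed must straddle position 0
    ps <- bsj_pseudo_sequence(sq)
    hits <- gregexpr(sc, ps$pseudo, fixed = TRUE)[[1]] - 1
    stray <- any(hits >= 0 & (hits + 7 <= joff | hits >= joff))
    if (!stray) expect_false(grepl(sc, sq, fixed = TRUE))
  }
  expect_gt(nrow(junc), 0)
})

test_that("junction-only pairs equal the manifest and respect the body-exclusion rule", {
  ds <- default_dataset()
  np <- novel_junction_pairs(ds$mirna, ds$circ_seqs)
  man <- ds$manifest$novel_junction_pairs
  man <- man[order(man$circ_id, man$mirna_id), ]
  expect_identical(paste(np$circ_id, np$mirna_id), paste(man$circ_id, man$mirna_id))
  ## constructed exclusion case: same seed at the junction AND in the body
  set.seed(103)
  mi <- "UGAGGUAGUAGGUUGUAUAGUU"
  sc <- revcomp(as_dna(substr(mi, 2, 8)))
  body <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  body <- gsub(sc, "AAAAAAA", body, fixed = TRUE)
  with_junc <- paste0(substr(sc, 4, 7), substr(body, 5, 296), substr(sc, 1, 3))
  with_both <- paste0(substr(with_junc, 1, 150), sc, substr(with_junc, 158, 296))
  mirnas <- c(m = mi)
  expect_equal(nrow(novel_junction_pairs(mirnas, c(c1 = with_junc))), 1)
  expect_equal(nrow(novel_junction_pairs(mirnas, c(c1 = with_both))), 0)
  expect_equal(nrow(novel_junction_pairs(mirnas, character(0))), 0)
})

test_that("pseudo-sequence sites equal doubled-sequence junction windows (L >= 200)", {
  ds <- default_dataset()
  circs <- ds$circ_seqs[nchar(ds$circ_seqs) >= 200]
  expect_gt(length(circs), 0)
  for (cid in names(circs)[1:min(10, length(circs))]) {
    sq <- circs[[cid]]; L <- nchar(sq)
    ps <- bsj_pseudo_sequence(sq)
    via_pseudo <- junction_filter(
      predict_target_sites(ds$mirna, stats::setNames(ps$pseudo, cid)),
      ps$junction_offset)
    doubled <- paste0(sq, sq)
    dsites <- predict_target_sites(ds$mirna, stats::setNames(doubled, cid))
    via_doubled <- dsites[dsites$start < L & dsites$end > L, , drop = FALSE]
    ## compare in junction-centred coordinates
    k1 <- sort(paste(via_pseudo$mirna_id, via_pseudo$start - ps$junction_offset,
                     via_pseudo$end - ps$junction_offset))
    k2 <- sort(paste(via_doubled$mirna_id, via_doubled$start - L,
                     via_doubled$end - L))
    expect_identical(k1, k2)
  }
})

test_that("implanted 3'UTR MRE pairs are all recovered and site sets ignore list order", {
  ds <- default_dataset()
  sites <- predict_target_sites(ds$mirna, ds$utr3)
  mre <- ds$manifest$mre_truth
  utr <- mre[mre$target_class == "utr3", ]
  for (i in seq_len(nrow(utr))) {
    expect_true(any(sites$mirna_id == utr$mirna_id[i] &
                      sites$target_id == utr$target_id[i]))
  }
  ## reordering targets leaves the site set unchanged
  sites_rev <- predict_target_sites(ds$mirna, rev(ds$utr3))
  key <- function(s) sort(paste(s$mirna_id, s$target_id, s$start, s$end, s$score))
  expect_identical(key(sites), key(sites_rev))
  expect_equal(nrow(predict_target_sites(character(0), ds$utr3)), 0)
})
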