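test_that("Spearman correlation reproduces its closed forms and cor.test", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3, 2.3, 8.4)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_equal(spearman_cor(x, x)$rho, 1)
  set.seed(111)
  y <- -x + rnorm(12)
  s <- spearman_cor(x, y)
  expect_equal(s$rho, unname(suppressWarnings(
    cor.test(x, y, method = "spearman")$estimate)))
  ## zero variance -> undefined, pair skipped
  expect_null(spearman_cor(x, rep(1, 12)))
  expect_error(spearman_cor(x[1:3], y[1:3]), "n >= 4")
})

test_that("the correlation gate applies strict thresholds", {
  ## ranks engineered so rho is exactly -0.6 (n = 4, sum d^2 = 16)
  prof_s <- matrix(c(1, 2, 3, 4), 1, dimnames = list("s", NULL))
  prof_m <- matrix(c(3, 4, 1, 2), 1, dimnames = list("m", NULL))
  pairs <- data.frame(source_id = "s", mirna_id = "m")
  expect_equal(spearman_cor(prof_s[1, ], prof_m[1, ])$rho, -0.6)
  expect_equal(nrow(corr_filter(pairs, prof_s, prof_m)), 0)   # strict <
  ## strongly anti-correlated pair is retained
  set.seed(112)
  ps <- matrix(1:12, 1, dimnames = list("s", NULL))
  pm <- matrix(12:1 + rnorm(12, 0, 0.1), 1, dimnames = list("m", NULL))
  e <- corr_filter(pairs, ps, pm)
  expect_equal(nrow(e), 1)
  expect_lt(e$rho, -0.9)
  ## missing profile is skipped, not an error
  e2 <- corr_filter(data.frame(source_id = "absent", mirna_id = "m"), ps, pm)
  expect_equal(nrow(e2), 0)
  expect_equal(attr(e2, "skipped"), 1)
})

test_that("gated edges equal a brute-force re-evaluation on random pairs", {
  set.seed(113)
  n <- 60
  src <- matrix(rnorm(n * 12), n, dimnames = list(paste0("s", 1:n), NULL))
  mir <- matrix(rnorm(n * 12), n, dimnames = list(paste0("m", 1:n), NULL))
  pairs <- data.frame(source_id = sample(rownames(src), 200, TRUE),
                      mirna_id = sample(rownames(mir), 200, TRUE))
  got <- corr_filter(pairs, src, mir)
  want <- character(0)
  for (i in seq_len(nrow(unique(pairs)))) {
    u <- unique(pairs)[i, ]
    r <- suppressWarnings(cor.test(src[u$source_id, ], mir[u$mirna_id, ],
                                   method = "spearman"))
    rho <- unname(r$estimate)
    tt <- rho * sqrt(10 / (1 - rho^2))
    p <- 2 * pt(-abs(tt), 10)
    if (rho < -0.6 && p < 0.05) want <- c(want, paste(u$source_id, u$mirna_id))
  }
  expect_setequal(paste(got$source_id, got$mirna_id), want)
})

test_that("triple-axis assembly enumerates all shared-miRNA combinations", {
  one <- assemble_triples(data.frame(source_id = "c1", mirna_id = "m1"),
                          data.frame(source_id = "g1", mirna_id = "m1"))
  expect_equal(nrow(one), 1)
  expect_identical(one$cerna_class, "circRNA")
  none <- assemble_triples(data.frame(source_id = "c1", mirna_id = "m1"),
                           data.frame(source_id = "g1", mirna_id = "m2"))
  expect_equal(nrow(none), 0)
  six <- assemble_triples(data.frame(source_id = c("c1", "c2"), mirna_id = "m1"),
                          data.frame(source_id = c("g1", "g2", "g3"), mirna_id = "m1"))
  expect_equal(nrow(six), 6)
})

test_that("axis counts satisfy the degree-product identity on random bipartite sets", {
  set.seed(121)
  for (rep in 1:5) {
    ce <- unique(data.frame(source_id = sample(paste0("c", 1:30), 300, TRUE),
                            mirna_id = sample(paste0("m", 1:15), 300, TRUE)))
    mr <- unique(data.frame(source_id = sample(paste0("g", 1:40), 300, TRUE),
                            mirna_id = sample(paste0("m", 1:15), 300, TRUE)))
    axes <- assemble_triples(ce, mr)
    ## nested-loop enumeration oracle
    n_oracle <- 0L
    for (m in paste0("m", 1:15)) {
      n_oracle <- n_oracle + sum(ce$mirna_id == m) * sum(mr$mirna_id == m)
    }
    expect_equal(nrow(axes), n_oracle)
    expect_false(any(duplicated(axes[, 1:3])))
  }
})

test_that("k-means recovers implanted archetypes and labels selective stages", {
  set.seed(131)
  ap <- simulate_archetype_profiles(10, 0.1)
  kc <- kmeans_stage_clusters(ap$profiles, ap$stages, k = 7, seed = 1)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(kc$cluster, ap$truth), 1)
  ## same seed is bit-stable; different seeds still recover the archetypes
  kc2 <- kmeans_stage_clusters(ap$profiles, ap$stages, k = 7, seed = 1)
  expect_identical(kc$cluster, kc2$cluster)
  kc3 <- kmeans_stage_clusters(ap$profiles, ap$stages, k = 7, seed = 99)
  expect_gte(mclust::adjustedRandIndex(kc$cluster, kc3$cluster), 0.95)
  ## the four single-stage archetypes map to selective-stage labels
  expect_true(all(c("D0", "D15", "D85", "Y2") %in% kc$selective_stage))
})

test_that("selective-stage labelling applies the argmax-with-margin rule", {
  ## build profiles whose stage means are exactly the centroid patterns
  set.seed(132)
  prof <- rbind(d0a = rep(c(2.0, -0.7, -0.6, -0.7), each = 3),
                d0b = rep(c(2.0, -0.7, -0.6, -0.7), each = 3),
                amba = rep(c(1.0, 0.9, -1.0, -0.9), each = 3),
                ambb = rep(c(1.0, 0.9, -1.0, -0.9), each = 3))
  prof <- prof + matrix(rnorm(48, 0, 1e-3), 4)
  rownames(prof) <- c("d0a", "d0b", "amba", "ambb")
  stages <- rep(c("D0", "D15", "D85", "Y2"), each = 3)
  kc <- kmeans_stage_clusters(prof, stages, k = 2, seed = 1)
  expect_identical(unname(kc$selective_stage[kc$cluster["d0a"]]), "D0")
  expect_identical(unname(kc$selective_stage[kc$cluster["amba"]]), "none")
  ## k = 1 puts everything in a single cluster
  k1 <- kmeans_stage_clusters(prof, stages, k = 1, seed = 1)
  expect_true(all(k1$cluster == 1))
  expect_error(kmeans_stage_clusters(prof, stages, k = 7, seed = 1), "fewer")
})

test_that("network overlap reports shared and specific miRNA sets", {
  ax <- function(m) data.frame(cerna_id = "c", mirna_id = m, mrna_id = "g",
                               cerna_class = "circRNA")
  ov <- network_overlap(ax(c("a", "b", "c")), ax(c("b", "c", "d")))
  expect_identical(ov$shared, c("b", "c"))
  expect_equal(ov$fraction_a, 2 / 3)
  expect_identical(ov$only_b, "d")
  same <- network_overlap(ax(c("a", "b")), ax(c("a", "b")))
  expect_equal(c(same$fraction_a, same$fraction_b), c(1, 1))
  disj <- network_overlap(ax("a"), ax("b"))
  expect_equal(disj$fraction_a, 0)
})

test_that("designed sponge axes are recovered through the correlation gates", {
  ## low-dispersion datasets across seeds: the gated edge sets must contain
  ## nearly all designed (ceRNA, miRNA, mRNA) axes
  recalls <- vapply(1:20, function(sd) {
    ds <- generate_dataset(simulation_config(seed = sd, nb_dispersion = 0.005),
                           reads = FALSE)
    ax <- ds$manifest$designed_axes
    np <- lapply(ds$counts, function(m) t(t(m) / size_factors(m)))
    ce_prof <- rbind(np$circ, np$lncrna)
    e_c <- corr_filter(data.frame(source_id = ax$cerna_id, mirna_id = ax$mirna_id),
                       ce_prof, np$mirna)
    e_m <- corr_filter(data.frame(source_id = ax$mrna_id, mirna_id = ax$mirna_id),
                       np$mrna, np$mirna)
    mean(paste(ax$cerna_id, ax$mirna_id) %in% paste(e_c$source_id, e_c$mirna_id) &
           paste(ax$mrna_id, ax$mirna_id) %in% paste(e_m$source_id, e_m$mirna_id))
  }, numeric(1))
  expect_gte(mean(recalls), 0.9)
})
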