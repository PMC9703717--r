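#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of average ranks (ties averaged); the
#' two-sided p-value uses the t approximation with n - 2 degrees of freedom,
#' standard at n = 12. A one-sided (negative) alternative is available.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param alternative "two.sided" (default) or "less".
#' @return list with `rho` and `p`; `NULL` if either vector has zero
#'   variance (the pair should be skipped).
#' @export
spearman_cor <- function(x, y, alternative = c("two.sided", "less")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (n != length(y) || n < 4L) stop("need equal-length vectors with n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (alternative == "two.sided") 2 * stats::pt(-abs(tstat), n - 2)
    else stats::pt(tstat, n - 2)
  }
  list(rho = rho, p = p)
}

#' Correlation-gate candidate ceRNA-miRNA (or miRNA-mRNA) pairs
#'
#' Keeps a sequence-predicted pair as a network edge only when the two
#' expression profiles are strongly anti-correlated: Spearman rho strictly
#' below `rho_max` and p strictly below `p_max` across the samples. Pairs
#' with a missing profile or zero variance are skipped and counted.
#'
#' @param pairs data.frame with columns `source_id`, `mirna_id` (one row per
#'   sequence-predicted pair).
#' @param source_profiles,mirna_profiles numeric matrices (features x
#'   samples, same sample order).
#' @param rho_max correlation threshold (default -0.6, strict `<`).
#' @param p_max p-value threshold (default 0.05, strict `<`).
#' @param alternative passed to [spearman_cor()].
#' @return data.frame of edges `source_id`, `mirna_id`, `rho`, `p`; skipped
#'   pair counts in attribute `"skipped"`.
#' @export
corr_filter <- function(pairs, source_profiles, mirna_profiles,
                        rho_max = -0.6, p_max = 0.05,
                        alternative = "two.sided") {
  pairs <- unique(pairs[, c("source_id", "mirna_id")])
  keep <- vector("list", nrow(pairs))
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    sid <- pairs$source_id[i]; mid <- pairs$mirna_id[i]
    if (!sid %in% rownames(source_profiles) || !mid %in% rownames(mirna_profiles)) {
      skipped <- skipped + 1L
      next
    }
    ct <- spearman_cor(source_profiles[sid, ], mirna_profiles[mid, ], alternative)
    if (is.null(ct)) {
      skipped <- skipped + 1L
      next
    }
    if (ct$rho < rho_max && ct$p < p_max) {
      keep[[i]] <- data.frame(source_id = sid, mirna_id = mid, rho = ct$rho,
                              p = ct$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, keep[!vapply(keep, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(source_id = character(0), mirna_id = character(0),
                      rho = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Assemble ceRNA-miRNA-mRNA triple axes
#'
#' One axis per (ceRNA, miRNA, mRNA) combination sharing a miRNA present on
#' both edge lists, so the axis count is `sum over m of
#' deg_ceRNA(m) * deg_mRNA(m)`.
#'
#' @param cerna_mirna_edges data.frame with `source_id`, `mirna_id`.
#' @param mirna_mrna_edges data.frame with `source_id` (mRNA), `mirna_id`.
#' @param cerna_class label for the ceRNA side ("circRNA" or "lncRNA").
#' @return data.frame of axes: `cerna_id`, `mirna_id`, `mrna_id`,
#'   `cerna_class`.
#' @export
assemble_triples <- function(cerna_mirna_edges, mirna_mrna_edges,
                             cerna_class = "circRNA") {
  ce <- unique(data.frame(cerna_id = cerna_mirna_edges$source_id,
                          mirna_id = cerna_mirna_edges$mirna_id,
                          stringsAsFactors = FALSE))
  mr <- unique(data.frame(mirna_id = mirna_mrna_edges$mirna_id,
                          mrna_id = mirna_mrna_edges$source_id,
                          stringsAsFactors = FALSE))
  axes <- merge(ce, mr, by = "mirna_id")
  if (nrow(axes) == 0L) {
    return(data.frame(cerna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), cerna_class = character(0),
                      stringsAsFactors = FALSE))
  }
  axes$cerna_class <- cerna_class
  axes <- axes[order(axes$cerna_id, axes$mirna_id, axes$mrna_id),
               c("cerna_id", "mirna_id", "mrna_id", "cerna_class")]
  rownames(axes) <- NULL
  axes
}

#' Stage-selective k-means clustering of expression profiles
#'
#' Features are summarized to per-stage means, z-scored per feature over the
#' stage means, and clustered by k-means (50 random restarts under a fixed
#' seed, Euclidean distance). A cluster is labelled selective for the stage
#' where its centroid peaks when the margin over the runner-up stage exceeds
#' `margin` z-units; several clusters may share a selective stage.
#'
#' @param profiles numeric matrix, features x samples.
#' @param stages stage label per sample column.
#' @param k number of clusters (default 7).
#' @param seed RNG seed for reproducible restarts.
#' @param nstart random restarts (default 50).
#' @param margin selectivity margin in z-units (default 0.5).
#' @return list with `cluster` (named integer per feature),
#'   `selective_stage` (per cluster), `centroids` (k x stages, z-scale),
#'   `dropped` (features with zero variance across stage means).
#' @export
kmeans_stage_clusters <- function(profiles, stages, k = 7L, seed = 1L,
                                  nstart = 50L, margin = 0.5) {
  stage_levels <- unique(stages)
  sm <- t(apply(profiles, 1, function(x) tapply(x, stages, mean)[stage_levels]))
  colnames(sm) <- stage_levels
  sds <- apply(sm, 1, stats::sd)
  dropped <- rownames(sm)[sds == 0]
  sm <- sm[sds > 0, , drop = FALSE]
  if (nrow(sm) < k) stop("fewer usable features (", nrow(sm), ") than clusters (", k, ")")
  z <- t(scale(t(sm)))
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100L)
  cent <- km$centers
  selective <- apply(cent, 1, function(v) {
    o <- order(v, decreasing = TRUE)
    if (v[o[1]] - v[o[2]] > margin) stage_levels[o[1]] else "none"
  })
  list(cluster = km$cluster, selective_stage = selective, centroids = cent,
       dropped = dropped)
}

#' Compare the miRNA complements of two triple networks
#'
#' Reports the shared miRNA set, the fraction of each network's miRNAs that
#' are shared, and the network-specific miRNA lists.
#'
#' @param axes_a,axes_b triple-axis data.frames ([assemble_triples()]).
#' @param label_a,label_b network labels for the report.
#' @return list with `shared`, `fraction_a`, `fraction_b`, `only_a`,
#'   `only_b`, and a one-row `summary` data.frame.
#' @export
network_overlap <- function(axes_a, axes_b, label_a = "A", label_b = "B") {
  ma <- unique(axes_a$mirna_id); mb <- unique(axes_b$mirna_id)
  shared <- intersect(ma, mb)
  list(shared = sort(shared),
       fraction_a = if (length(ma)) length(shared) / length(ma) else NA_real_,
       fraction_b = if (length(mb)) length(shared) / length(mb) else NA_real_,
       only_a = sort(setdiff(ma, mb)), only_b = sort(setdiff(mb, ma)),
       summary = data.frame(
         network_a = label_a, network_b = label_b,
         n_mirna_a = length(ma), n_mirna_b = length(mb),
         n_shared = length(shared),
         fraction_a = if (length(ma)) length(shared) / length(ma) else NA_real_,
         fraction_b = if (length(mb)) length(shared) / length(mb) else NA_real_,
         stringsAsFactors = FALSE))
}
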