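#' Small-RNA adapter trimming policy
#'
#' Mirrors the cutadapt-style call used for small-RNA libraries: 3' adapter
#' `AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC`, zero tolerated errors, minimum
#' adapter overlap 3 nt, and retained insert length between 18 and 30 nt.
#'
#' @param adapter 3' adapter sequence (DNA).
#' @param min_len,max_len retained read length bounds (nt).
#' @param min_overlap minimal matched adapter prefix at the read 3' end.
#' @return a `trim_policy` list.
#' @export
trim_policy <- function(adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                        min_len = 18L, max_len = 30L, min_overlap = 3L) {
  stopifnot(min_len <= max_len, min_overlap >= 1L)
  structure(list(adapter = as_dna(adapter), min_len = as.integer(min_len),
                 max_len = as.integer(max_len), min_overlap = as.integer(min_overlap)),
            class = "trim_policy")
}

## 0-based position of the leftmost adapter occurrence in one read; the
## adapter may run off the read 3' end (suffix overlap) as long as at least
## min_overlap bases match exactly; -1 when absent
.adapter_pos <- function(read, adapter, min_overlap) {
  n <- nchar(read); alen <- nchar(adapter)
  for (i in 0:(n - min_overlap)) {
    m <- min(alen, n - i)
    if (substr0(read, i, i + m) == substr(adapter, 1L, m)) return(i)
  }
  -1L
}

#' Trim 3' adapters from small-RNA reads and length-filter
#'
#' The adapter is removed at its leftmost exact occurrence (suffix overlaps
#' of at least `min_overlap` bases allowed, zero mismatches); reads are then
#' retained only if the trimmed length lies within `[min_len, max_len]`.
#' Rejections are counted, never errors.
#'
#' @param reads character vector of read sequences (or data.frame with `seq`).
#' @param policy a [trim_policy()].
#' @return character vector of retained trimmed reads, with a `"stats"`
#'   attribute (named counts: input, trimmed, too_short, too_long, retained).
#' @export
trim_small_rna <- function(reads, policy = trim_policy()) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  seqs <- as_dna(seqs)
  uniq <- unique(seqs)
  pos <- vapply(uniq, .adapter_pos, integer(1),
                adapter = policy$adapter, min_overlap = policy$min_overlap,
                USE.NAMES = FALSE)
  trimmed_u <- ifelse(pos >= 0L, substr(uniq, 1L, pos), uniq)
  map <- match(seqs, uniq)
  trimmed <- trimmed_u[map]
  len <- nchar(trimmed)
  keep <- len >= policy$min_len & len <= policy$max_len
  out <- trimmed[keep]
  attr(out, "stats") <- c(input = length(seqs),
                          trimmed = sum(pos[map] >= 0L),
                          too_short = sum(len < policy$min_len),
                          too_long = sum(len > policy$max_len),
                          retained = sum(keep))
  out
}

#' Count trimmed small-RNA reads against a mature miRNA set
#'
#' A read increments a miRNA when it equals the full-length mature sequence
#' under T/U equivalence (mature orientation only). Reads matching several
#' mature sequences are assigned fractionally (1/n to each).
#'
#' @param reads trimmed read sequences.
#' @param mature named character vector of mature miRNA sequences (RNA or
#'   DNA; ids must be unique).
#' @return named numeric vector of counts per miRNA id.
#' @export
count_mirna <- function(reads, mature) {
  if (anyDuplicated(names(mature))) {
    stop("duplicate mature miRNA id(s): ",
         paste(unique(names(mature)[duplicated(names(mature))]), collapse = ", "))
  }
  mat_dna <- as_dna(mature)
  reads <- as_dna(if (is.data.frame(reads)) reads$seq else reads)
  tab <- table(reads)
  counts <- stats::setNames(numeric(length(mature)), names(mature))
  groups <- split(names(mat_dna), unname(mat_dna))
  hit <- groups[names(tab)]
  for (i in seq_along(hit)) {
    ids <- hit[[i]]
    if (is.null(ids)) next
    counts[ids] <- counts[ids] + as.numeric(tab[i]) / length(ids)
  }
  counts
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over zero-free features of
#' the ratio between the sample's count and the feature's geometric mean
#' across samples; factors are rescaled to geometric mean 1.
#'
#' @param counts feature x sample count matrix.
#' @return named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  nz <- rowSums(counts == 0) == 0
  if (!any(nz)) {
    stop("no feature is zero-free across all samples; ",
         "median-of-ratios needs a pseudo-reference (filter or add features)")
  }
  logc <- log(counts[nz, , drop = FALSE])
  logref <- rowMeans(logc)
  sf <- apply(logc, 2, function(x) exp(stats::median(x - logref)))
  sf / exp(mean(log(sf)))
}

#' Simplified negative-binomial Wald test for differential expression
#'
#' A transparent DESeq2-like procedure preserving the decision rule
#' `p < alpha` and `|log2FC| > lfc`: counts are normalized by
#' median-of-ratios factors; `log2FC = log2((meanB + 0.5) / (meanA + 0.5))`;
#' a per-feature dispersion is estimated by the method of moments (floored)
#' and the Wald statistic `log2FC / SE` is referred to a t distribution with
#' `nA + nB - 2` degrees of freedom -- the usual small-sample correction,
#' without which the test is anti-conservative at n = 3 per group (empirical
#' type-I error ~0.12 at nominal 0.05 under a standard-normal reference).
#' Numerical agreement with DESeq2 is not claimed. Benjamini-Hochberg
#' adjusted p-values are also reported but do not enter the decision rule.
#'
#' @param counts feature x sample count matrix.
#' @param group_a,group_b column names (or indices) of the two groups, each
#'   with >= 2 samples.
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @param pseudo pseudo-count added to group means (default 0.5).
#' @param sf optional precomputed size factors for all columns of `counts`.
#' @return data.frame with `feature_id`, `baseMeanA`, `baseMeanB`, `log2fc`,
#'   `se`, `stat`, `pvalue`, `padj`, `significant`.
#' @export
nb_wald_de <- function(counts, group_a, group_b, alpha = 0.05, lfc = 1,
                       pseudo = 0.5, sf = NULL) {
  a <- counts[, group_a, drop = FALSE]
  b <- counts[, group_b, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) stop("each group needs >= 2 samples")
  if (any(colSums(a) == 0) || any(colSums(b) == 0)) {
    stop("a sample has an all-zero library; cannot normalize")
  }
  if (is.null(sf)) sf <- size_factors(cbind(a, b))
  norm <- t(t(cbind(a, b)) / sf)
  na <- ncol(a); nb <- ncol(b)
  xa <- norm[, seq_len(na), drop = FALSE]
  xb <- norm[, na + seq_len(nb), drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  ## method-of-moments NB dispersion, pooled across groups and floored
  disp_a <- (va - ma) / pmax(ma, 1e-8)^2
  disp_b <- (vb - mb) / pmax(mb, 1e-8)^2
  disp <- pmax((disp_a + disp_b) / 2, 1e-8)
  log2fc <- log2((mb + pseudo) / (ma + pseudo))
  ## delta method on log group means
  var_ma <- (ma + disp * ma^2) / na
  var_mb <- (mb + disp * mb^2) / nb
  se <- sqrt(var_ma / (ma + pseudo)^2 + var_mb / (mb + pseudo)^2) / log(2)
  se[se == 0] <- NA_real_
  stat <- log2fc / se
  pvalue <- 2 * stats::pt(-abs(stat), df = na + nb - 2L)
  pvalue[is.na(pvalue)] <- 1
  padj <- stats::p.adjust(pvalue, method = "BH")
  data.frame(feature_id = rownames(counts) %||% seq_len(nrow(counts)),
             baseMeanA = ma, baseMeanB = mb, log2fc = log2fc, se = se,
             stat = stat, pvalue = pvalue, padj = padj,
             significant = pvalue < alpha & abs(log2fc) > lfc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per replicate, `dCt = Cq_target - Cq_reference`; per group,
#' `ddCt = mean(dCt) - mean(dCt[calibrator])` and relative expression is
#' `2^-ddCt`, so the calibrator group is 1 by construction.
#'
#' @param cq_target,cq_reference numeric vectors of matched per-replicate Cq
#'   values (target gene and reference gene, e.g. U6).
#' @param groups group label per replicate.
#' @param calibrator calibrator group label.
#' @return named numeric vector of relative expression per group.
#' @export
delta_delta_ct <- function(cq_target, cq_reference, groups, calibrator) {
  if (length(cq_target) != length(cq_reference) || anyNA(cq_reference)) {
    stop("reference Cq values must be present for every replicate")
  }
  if (!calibrator %in% groups) stop("calibrator group not found: ", calibrator)
  dct <- cq_target - cq_reference
  mean_dct <- tapply(dct, groups, mean)
  ddct <- mean_dct - mean_dct[[calibrator]]
  stats::setNames(as.vector(2^(-ddct)), names(mean_dct))
}
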