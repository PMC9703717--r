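#' Scoring parameters for seed-anchored target prediction
#'
#' A fully specified stand-in for heuristic alignment-based MRE predictors:
#' sites are anchored by a perfect Watson-Crick match to the miRNA seed
#' (positions 2-8, 7mer-m8) and extended over the full miRNA span where the
#' target is long enough. G:U wobbles are rewarded only outside the seed.
#' The default `min_total_score = 0` makes a seed match sufficient.
#'
#' @param match_score,wobble_score,mismatch_score,gap_score per-position
#'   scores (must satisfy match > wobble > 0 > mismatch > gap).
#' @param min_total_score sites scoring below this are dropped.
#' @return a `score_params` list.
#' @export
score_params <- function(match_score = 5, wobble_score = 1,
                         mismatch_score = -3, gap_score = -8,
                         min_total_score = 0) {
  if (!(match_score > wobble_score && wobble_score > 0 &&
        0 > mismatch_score && mismatch_score > gap_score)) {
    stop("scores must satisfy match > wobble > 0 > mismatch > gap")
  }
  structure(list(match_score = match_score, wobble_score = wobble_score,
                 mismatch_score = mismatch_score, gap_score = gap_score,
                 min_total_score = min_total_score), class = "score_params")
}

## per-position pairing codes for miRNA base (RNA) vs target base (DNA/RNA),
## antiparallel: "M" Watson-Crick, "W" G:U wobble, "m" mismatch
.pair_code <- function(mi, tg) {
  tg <- chartr("U", "T", tg)
  wc <- (mi == "A" & tg == "T") | (mi == "U" & tg == "A") |
    (mi == "C" & tg == "G") | (mi == "G" & tg == "C")
  wob <- (mi == "G" & tg == "T") | (mi == "U" & tg == "G")
  ifelse(wc, "M", ifelse(wob, "W", "m"))
}

#' Predict seed-anchored miRNA sites on one target sequence
#'
#' One candidate site per occurrence of the reverse complement of miRNA
#' positions 2-8 (T and U equivalent). Each site is extended over the full
#' miRNA span where the target allows, scored per position (Watson-Crick
#' match, G:U wobble outside the seed, mismatch), and overlapping sites of
#' the same miRNA are deduplicated keeping the best score.
#'
#' @param mirna_id miRNA identifier.
#' @param mirna_seq mature miRNA sequence, 5'->3' (RNA, 18-30 nt).
#' @param target_id target identifier.
#' @param target target sequence (DNA or RNA).
#' @param params a [score_params()].
#' @return data.frame of sites: `mirna_id`, `target_id`, `start`, `end`
#'   (0-based half-open on the target), `score`, `pairing`.
#' @export
seed_sites <- function(mirna_id, mirna_seq, target_id, target,
                       params = score_params()) {
  mirna_seq <- as_rna(mirna_seq)
  nmi <- nchar(mirna_seq)
  if (nmi < 18L || nmi > 30L) stop("mature miRNA length must be 18-30 nt: ", mirna_id)
  target <- as_dna(target)
  Lt <- nchar(target)
  empty <- data.frame(mirna_id = character(0), target_id = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      pairing = character(0), stringsAsFactors = FALSE)
  if (Lt < 7L) return(empty)
  seed_rc <- revcomp(as_dna(substr(mirna_seq, 2L, 8L)))
  hits <- find_fixed(seed_rc, target)
  if (length(hits) == 0L) return(empty)
  mi_chars <- strsplit(mirna_seq, "")[[1]]
  tg_chars <- strsplit(target, "")[[1]]
  sites <- lapply(hits, function(i) {
    ## miRNA position m (1-based) pairs target position i + 8 - m (0-based)
    m_all <- seq_len(nmi)
    t_all <- i + 8L - m_all
    ok <- t_all >= 0L & t_all < Lt
    m <- m_all[ok]; tpos <- t_all[ok]
    code <- .pair_code(mi_chars[m], tg_chars[tpos + 1L])
    in_seed <- m >= 2L & m <= 8L
    score <- sum(ifelse(code == "M", params$match_score,
                        ifelse(code == "W" & !in_seed, params$wobble_score,
                               params$mismatch_score)))
    ## pairing string in miRNA 5'->3' order
    data.frame(mirna_id = mirna_id, target_id = target_id,
               start = min(tpos), end = max(tpos) + 1L, score = score,
               pairing = paste(code, collapse = ""), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, sites)
  out <- out[out$score >= params$min_total_score, , drop = FALSE]
  .dedup_overlaps(out)
}

## keep the best-scoring site among mutually overlapping same-miRNA sites
.dedup_overlaps <- function(sites) {
  if (nrow(sites) <= 1L) return(sites)
  sites <- sites[order(-sites$score, sites$start), , drop = FALSE]
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    prior <- which(keep)
    overlaps <- any(sites$start[prior] < sites$end[i] &
                      sites$start[i] < sites$end[prior])
    keep[i] <- !overlaps
  }
  out <- sites[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Predict miRNA sites over a set of target sequences
#'
#' Applies [seed_sites()] to every (miRNA, target) combination; for mRNAs
#' pass 3'UTR sequences only, so prediction is restricted to the 3'UTR
#' sequence space.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param targets named character vector of target sequences (e.g. 3'UTRs
#'   keyed by gene, or lncRNAs).
#' @param params a [score_params()].
#' @return data.frame of sites across all pairs.
#' @export
predict_target_sites <- function(mirnas, targets, params = score_params()) {
  out <- list()
  for (m in names(mirnas)) {
    for (tg in names(targets)) {
      s <- seed_sites(m, mirnas[[m]], tg, targets[[tg]], params)
      if (nrow(s) > 0L) out[[length(out) + 1L]] <- s
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      pairing = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build the back-splice-junction pseudo-sequence
#'
#' The last `min(100, L)` nt of the spliced circRNA joined to its first
#' `min(100, L)` nt: a linear window of the circular permutation centred on
#' the BSJ. For spliced lengths below 200 the two windows overlap rather
#' than truncate.
#'
#' @param circ_spliced spliced circRNA sequence (length >= 2).
#' @param flank window size on each side of the junction (default 100 nt).
#' @return list with `pseudo` (sequence) and `junction_offset` (0-based
#'   position of the junction inside `pseudo`, equal to `min(flank, L)`).
#' @export
bsj_pseudo_sequence <- function(circ_spliced, flank = 100L) {
  L <- nchar(circ_spliced)
  if (L < 2L) stop("spliced sequence must have length >= 2")
  w <- min(flank, L)
  list(pseudo = paste0(substring(circ_spliced, L - w + 1L, L),
                       substring(circ_spliced, 1L, w)),
       junction_offset = w)
}

#' Keep only junction-spanning sites on a pseudo-sequence
#'
#' A site spans the junction iff `start < junction_offset < end` (a site
#' starting exactly at the junction does not cross it). Retained sites are
#' flagged `spans_junction = TRUE`.
#'
#' @param sites data.frame of sites predicted on a pseudo-sequence.
#' @param junction_offset junction position from [bsj_pseudo_sequence()].
#' @return the junction-spanning subset with a `spans_junction` column.
#' @export
junction_filter <- function(sites, junction_offset) {
  out <- sites[sites$start < junction_offset & sites$end > junction_offset, ,
               drop = FALSE]
  if (nrow(out) > 0L) out$spans_junction <- TRUE else out$spans_junction <- logical(0)
  out
}

#' Predict junction sites for a set of circRNAs
#'
#' Runs seed prediction on each circRNA's BSJ pseudo-sequence and keeps the
#' junction-spanning sites; duplicate sites arising from overlapping head
#' and tail windows (spliced length < 2 x flank) are deduplicated by their
#' circular coordinate.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param circs named character vector of spliced circRNA sequences.
#' @param params a [score_params()].
#' @param flank junction window (default 100 nt).
#' @return data.frame of junction-spanning sites with pseudo-sequence
#'   coordinates and `junction_offset`.
#' @export
predict_junction_sites <- function(mirnas, circs, params = score_params(),
                                   flank = 100L) {
  out <- list()
  for (cid in names(circs)) {
    ps <- bsj_pseudo_sequence(circs[[cid]], flank)
    L <- nchar(circs[[cid]])
    sites <- predict_target_sites(mirnas, stats::setNames(ps$pseudo, cid), params)
    sites <- junction_filter(sites, ps$junction_offset)
    if (nrow(sites) == 0L) next
    ## circular start coordinate deduplicates head/tail window overlap copies
    circ_start <- (sites$start - ps$junction_offset) %% L
    dup <- duplicated(data.frame(sites$mirna_id, circ_start))
    sites <- sites[!dup, , drop = FALSE]
    sites$junction_offset <- ps$junction_offset
    out[[length(out) + 1L]] <- sites
  }
  if (length(out) == 0L) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      pairing = character(0), spans_junction = logical(0),
                      junction_offset = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Junction-only (novel) circRNA-miRNA pairs
#'
#' A pair is reported iff the miRNA has at least one junction-spanning site
#' on the circRNA's BSJ pseudo-sequence and no site anywhere on the full
#' spliced linear sequence -- the response element exists only under
#' circularization.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param circs named character vector of spliced circRNA sequences.
#' @param params a [score_params()].
#' @param flank junction window (default 100 nt).
#' @return data.frame with `circ_id`, `mirna_id`, sorted.
#' @export
novel_junction_pairs <- function(mirnas, circs, params = score_params(),
                                 flank = 100L) {
  junc <- predict_junction_sites(mirnas, circs, params, flank)
  linear <- predict_target_sites(mirnas, circs, params)
  jp <- unique(junc[, c("target_id", "mirna_id")])
  names(jp) <- c("circ_id", "mirna_id")
  if (nrow(jp) == 0L) return(jp)
  lin_key <- paste(linear$target_id, linear$mirna_id)
  jp <- jp[!(paste(jp$circ_id, jp$mirna_id) %in% lin_key), , drop = FALSE]
  jp <- jp[order(jp$circ_id, jp$mirna_id), , drop = FALSE]
  rownames(jp) <- NULL
  jp
}
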