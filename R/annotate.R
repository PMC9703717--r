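#' Best local alignment between two sequences
#'
#' Optimal Smith-Waterman local alignment under a simple linear-gap scoring
#' scheme (match +1, mismatch -2, gap -2 by default), computed with
#' Biostrings. Both the query and its reverse complement are aligned and
#' the better strand is reported, with the cover interval mapped back to
#' query coordinates.
#'
#' @param query,subject DNA sequences (character).
#' @param match,mismatch,gap per-position scores.
#' @return list: `score`, `aligned_length` (alignment columns incl. gaps),
#'   `identical_positions`, `identity`, `query_start`, `query_end` (0-based
#'   half-open on the original query), `strand`.
#' @export
local_align <- function(query, subject, match = 1, mismatch = -2, gap = -2) {
  if (!nzchar(query) || !nzchar(subject)) stop("sequences must be non-empty")
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                      mismatch = mismatch)
  aln_one <- function(q) {
    Biostrings::pairwiseAlignment(q, subject, type = "local",
                                  substitutionMatrix = sub_mat,
                                  gapOpening = 0, gapExtension = -gap)
  }
  q_fwd <- as_dna(query); q_rev <- revcomp(q_fwd)
  a_fwd <- aln_one(q_fwd); a_rev <- aln_one(q_rev)
  use_rev <- Biostrings::score(a_rev) > Biostrings::score(a_fwd)
  a <- if (use_rev) a_rev else a_fwd
  qlen <- nchar(q_fwd)
  p <- Biostrings::pattern(a)
  qs <- Biostrings::start(p) - 1L          # 0-based on the aligned strand
  qe <- Biostrings::end(p)
  if (use_rev) {
    tmp <- qs
    qs <- qlen - qe
    qe <- qlen - tmp
  }
  list(score = Biostrings::score(a),
       aligned_length = Biostrings::nchar(a),
       identical_positions = Biostrings::nmatch(a),
       identity = Biostrings::nmatch(a) / Biostrings::nchar(a),
       query_start = qs, query_end = qe,
       strand = if (use_rev) "-" else "+")
}

#' Conservation call for one query against a reference database
#'
#' A query is conserved iff some subject has kept alignments -- each with
#' per-alignment identity >= `min_identity` -- whose union covers at least
#' `min_cover` nt of the query and whose summed identical positions divided
#' by the covered length is >= `min_total_identity`. Mirrors the
#' three-threshold rule (mapping identity >= 70%, total identity >= 75%,
#' covered region >= 100 nt) used to map circRNA/lncRNA sequences across
#' species. Adding alignments can only ever add coverage, so the call is
#' monotone.
#'
#' @param alignments data.frame with one row per alignment of this query:
#'   `subject_id`, `identity`, `identical_positions`, `query_start`,
#'   `query_end`.
#' @param query_length query length (nt).
#' @param min_identity per-alignment identity threshold (default 0.70).
#' @param min_total_identity union-coverage identity threshold (default 0.75).
#' @param min_cover minimal covered query length in nt (default 100).
#' @return logical: conserved or not.
#' @export
conservation_filter <- function(alignments, query_length,
                                min_identity = 0.70,
                                min_total_identity = 0.75,
                                min_cover = 100L) {
  if (is.null(alignments) || nrow(alignments) == 0L) return(FALSE)
  kept <- alignments[alignments$identity >= min_identity, , drop = FALSE]
  if (nrow(kept) == 0L) return(FALSE)
  for (sid in unique(kept$subject_id)) {
    al <- kept[kept$subject_id == sid, , drop = FALSE]
    covered <- logical(query_length)
    for (i in seq_len(nrow(al))) {
      covered[seq(al$query_start[i] + 1L, al$query_end[i])] <- TRUE
    }
    cov_len <- sum(covered)
    if (cov_len >= min_cover &&
        sum(al$identical_positions) / cov_len >= min_total_identity) {
      return(TRUE)
    }
  }
  FALSE
}

#' Conservation screen of queries against a subject database
#'
#' Aligns every query to every subject with [local_align()] and applies
#' [conservation_filter()] per query.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param ... thresholds passed to [conservation_filter()].
#' @return data.frame with `query_id`, `conserved`, `best_subject`,
#'   `best_identity`.
#' @export
conservation_screen <- function(queries, subjects, ...) {
  out <- lapply(names(queries), function(qid) {
    q <- queries[[qid]]
    als <- do.call(rbind, lapply(names(subjects), function(sid) {
      a <- local_align(q, subjects[[sid]])
      data.frame(subject_id = sid, identity = a$identity,
                 identical_positions = a$identical_positions,
                 query_start = a$query_start, query_end = a$query_end,
                 stringsAsFactors = FALSE)
    }))
    best <- als[which.max(als$identical_positions), , drop = FALSE]
    data.frame(query_id = qid,
               conserved = conservation_filter(als, nchar(q), ...),
               best_subject = best$subject_id, best_identity = best$identity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' EASE-penalised hypergeometric term enrichment
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least `overlap - 1` annotated genes in the set (the conservative EASE
#' variant of Fisher's test: the observed overlap is reduced by one, floored
#' at zero, so singleton overlaps are never significant).
#'
#' @param gene_set character vector of genes of interest (subset of
#'   `universe`).
#' @param universe character vector of background genes.
#' @param term_map named list (term -> character vector of universe genes),
#'   or a two-column data.frame `term`, `gene`.
#' @param alpha significance threshold on the raw p (default 0.05).
#' @return data.frame: `term_id`, `overlap`, `set_size`, `term_size`,
#'   `universe_size`, `p`, `significant`, sorted by p.
#' @export
ease_enrichment <- function(gene_set, universe, term_map, alpha = 0.05) {
  if (!all(gene_set %in% universe)) {
    stop("gene_set contains genes outside the universe: ",
         paste(utils::head(setdiff(gene_set, universe), 3), collapse = ", "))
  }
  if (is.data.frame(term_map)) term_map <- split(term_map$gene, term_map$term)
  gene_set <- unique(gene_set); universe <- unique(universe)
  N <- length(universe); n <- length(gene_set)
  rows <- lapply(names(term_map), function(tid) {
    term_genes <- intersect(unique(term_map[[tid]]), universe)
    K <- length(term_genes)
    if (K == 0L) return(NULL)          # term absent from the universe
    ov <- length(intersect(term_genes, gene_set))
    k_pen <- max(ov - 1L, 0L)
    p <- if (k_pen == 0L) 1 else stats::phyper(k_pen - 1L, K, N - K, n,
                                               lower.tail = FALSE)
    data.frame(term_id = tid, overlap = ov, set_size = n, term_size = K,
               universe_size = N, p = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(term_id = character(0), overlap = integer(0),
                      set_size = integer(0), term_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  out[order(out$p, out$term_id), , drop = FALSE]
}
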