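#' Build an exact k-mer genome index
#'
#' Indexes every genomic k-mer on both strands: a lookup of a k-mer returns
#' all positions where it occurs on the forward strand (`+`) and all
#' positions where its reverse complement occurs (`-`). Backed by a keyed
#' data.table for O(log n) batch lookups.
#'
#' @param genome named character vector of chromosome sequences.
#' @param k anchor length in nt (default 20, >= 12).
#' @return a `genome_index` list with the lookup table, `k` and chromosome
#'   lengths.
#' @export
build_index <- function(genome, k = 20L) {
  if (k < 12L) stop("anchor length k must be >= 12")
  lens <- nchar(genome)
  if (k > min(lens)) {
    stop("k (", k, ") exceeds the shortest chromosome (", min(lens), " nt)")
  }
  tabs <- lapply(names(genome), function(chrom) {
    n <- lens[[chrom]]
    pos <- 0:(n - k)
    fwd <- substring(genome[[chrom]], pos + 1L, pos + k)
    data.table::data.table(
      kmer = c(fwd, revcomp(fwd)),
      chrom = chrom,
      pos = rep(pos, 2L),
      strand = rep(c("+", "-"), each = length(pos)))
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  structure(list(table = dt, k = as.integer(k), chrom_lengths = lens),
            class = "genome_index")
}

#' Look up k-mers in a genome index
#'
#' @param index a [build_index()] result.
#' @param kmers character vector of k-mers.
#' @return data.table with columns `kmer`, `chrom`, `pos` (0-based), `strand`;
#'   zero rows for absent k-mers.
#' @export
lookup_kmers <- function(index, kmers) {
  index$table[data.table::data.table(kmer = kmers), nomatch = NULL, on = "kmer"]
}

#' Extract terminal anchors from a read
#'
#' The head anchor is the first `anchor_len` nt, the tail anchor the last
#' `anchor_len` nt. Reads shorter than two anchors are not usable.
#'
#' @param read read sequence.
#' @param anchor_len anchor length (default 20 nt).
#' @return list with `head` and `tail`, or `NULL` for short reads.
#' @export
extract_anchors <- function(read, anchor_len = 20L) {
  n <- nchar(read)
  if (n < 2L * anchor_len) return(NULL)
  list(head = substr(read, 1L, anchor_len),
       tail = substr(read, n - anchor_len + 1L, n))
}

## length of the common prefix of two strings
.common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n)); bv <- utf8ToInt(substr(b, 1L, n))
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1] - 1L
}

## breakpoint search shared by detect_bsj; r is oriented so that it reads
## across the junction on the forward genome: [circ tail part][circ head part]
.find_breakpoints <- function(r, chrom_seq, p1, p2, k, strand) {
  L <- nchar(r)
  ## e1: maximal exact extension of the head anchor rightwards from p1
  g1 <- substr0(chrom_seq, p1, min(p1 + L, nchar(chrom_seq)))
  e1 <- .common_prefix(r, g1)
  ## e2: maximal exact extension of the tail anchor leftwards ending at p2+k
  g2 <- substr0(chrom_seq, max(0L, p2 + k - L), p2 + k)
  e2 <- .common_prefix(stringi::stri_reverse(r), stringi::stri_reverse(g2))
  lo <- max(k, L - e2); hi <- min(e1, L - k)
  if (lo > hi) return(integer(0))
  sig5 <- if (strand == "+") "AG" else "AC"   # genomic 2-mer before circ start
  sig3 <- if (strand == "+") "GT" else "CT"   # genomic 2-mer after circ end
  valid <- integer(0)
  for (b in lo:hi) {
    S <- p2 + k - (L - b); E <- p1 + b
    if (S < 2L || E + 2L > nchar(chrom_seq)) next
    if (substr0(chrom_seq, S - 2L, S) == sig5 &&
        substr0(chrom_seq, E, E + 2L) == sig3) {
      valid <- c(valid, b)
    }
  }
  valid
}

## single-hit-per-anchor lookup helper; hits is a data.table (possibly empty)
.unique_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) != 1L) NULL else hits
}

#' Detect a back-splice junction in one read
#'
#' find_circ-style anchor remapping: the read's two 20 nt terminal anchors
#' must each map uniquely to the same chromosome and strand with the head
#' anchor genomically downstream of the tail anchor (reversed order =
#' back-splice). The anchors are then extended towards the read middle
#' without mismatch; a candidate is emitted only if exactly one breakpoint
#' is consistent with the GT/AG splice signal (strand-normalized: genomic
#' `AG` immediately before the circ start and `GT` immediately after its
#' end). Multiple consistent breakpoints are ambiguous and discarded.
#'
#' @param read read sequence (assumed to have failed linear mapping).
#' @param index a [build_index()] result.
#' @param genome named character vector of chromosomes.
#' @param anchor_len anchor length; must equal `index$k`.
#' @param max_span maximal circRNA genomic span (default 50 kb).
#' @param hit_lookup optional prebuilt kmer->hits list (internal fast path).
#' @param details when `TRUE`, always return a list with `candidate` (the
#'   data.frame or `NULL`) and `reason` (why no candidate was emitted).
#' @return one-row data.frame (`chrom`, `start`, `end`, `strand`,
#'   `splice_signal`), or `NULL` when the read yields no candidate.
#' @export
detect_bsj <- function(read, index, genome, anchor_len = index$k,
                       max_span = 50000L, hit_lookup = NULL, details = FALSE) {
  fail <- function(reason) {
    if (details) list(candidate = NULL, reason = reason) else NULL
  }
  emit <- function(cand) {
    if (details) list(candidate = cand, reason = "ok") else cand
  }
  anc <- extract_anchors(read, anchor_len)
  if (is.null(anc)) return(fail("short_read"))
  get_hits <- function(kmer) {
    if (!is.null(hit_lookup)) hit_lookup[[kmer]] else lookup_kmers(index, kmer)
  }
  h1 <- .unique_hit(get_hits(anc$head))
  h2 <- .unique_hit(get_hits(anc$tail))
  if (is.null(h1) || is.null(h2)) return(fail("ambiguous_or_unmapped_anchor"))
  if (h1$chrom != h2$chrom || h1$strand != h2$strand) return(fail("anchor_pair_inconsistent"))
  strand <- h1$strand
  if (strand == "+") {
    r <- read; p1 <- h1$pos; p2 <- h2$pos
  } else {
    r <- revcomp(read); p1 <- h2$pos; p2 <- h1$pos
  }
  if (p1 <= p2) return(fail("forward_order_not_backsplice"))
  k <- anchor_len; L <- nchar(r)
  span <- p1 - p2 + L - k          # end - start, identical for every breakpoint
  if (span < 2L * k) return(fail("span_too_short"))
  if (span > max_span) return(fail("span_exceeds_max"))
  valid <- .find_breakpoints(r, genome[[h1$chrom]], p1, p2, k, strand)
  if (length(valid) == 0L) return(fail("no_gtag_breakpoint"))
  if (length(valid) > 1L) return(fail("ambiguous_breakpoint"))
  b <- valid[1]
  emit(data.frame(chrom = h1$chrom, start = p2 + k - (L - b), end = p1 + b,
                  strand = strand, splice_signal = "GT/AG", stringsAsFactors = FALSE))
}

## exact full-length linear mapping on either strand
.is_linear <- function(read, genome, hit_lookup, k) {
  for (o in c(read, revcomp(read))) {
    hits <- hit_lookup[[substr(o, 1L, k)]]
    if (is.null(hits)) next
    fwd <- hits[hits$strand == "+", , drop = FALSE]
    for (i in seq_len(nrow(fwd))) {
      if (substr0(genome[[fwd$chrom[i]]], fwd$pos[i],
                  fwd$pos[i] + nchar(o)) == o) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Call back-splice junctions over a read set
#'
#' Runs the linear-mapping pre-filter and [detect_bsj()] over every read,
#' using one batched index lookup for all anchors. Reads that map linearly
#' end-to-end are never BSJ candidates.
#'
#' @param reads data.frame with `id` and `seq` columns, or a character vector.
#' @param index,genome see [detect_bsj()].
#' @param sample_id label attached to emitted candidates.
#' @param anchor_len,max_span see [detect_bsj()].
#' @return list with `candidates` (data.table: `chrom`, `start`, `end`,
#'   `strand`, `splice_signal`, `read_seq`, `sample_id`) and `stats` (named
#'   counts of read fates).
#' @export
call_bsj_readset <- function(reads, index, genome, sample_id = "sample",
                             anchor_len = index$k, max_span = 50000L) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  k <- anchor_len
  long <- nchar(seqs) >= 2L * k
  stats <- c(n_reads = length(seqs), short_read = sum(!long))
  seqs_l <- seqs[long]
  rc <- revcomp(seqs_l)
  n <- length(seqs_l)
  anchors <- unique(c(substr(seqs_l, 1L, k), substring(seqs_l, nchar(seqs_l) - k + 1L),
                      substr(rc, 1L, k), substring(rc, nchar(rc) - k + 1L)))
  hitdt <- lookup_kmers(index, anchors)
  hit_lookup <- if (nrow(hitdt) > 0L) split(hitdt, by = "kmer") else list()
  out <- vector("list", n)
  reasons <- character(0)
  n_linear <- 0L
  for (i in seq_len(n)) {
    if (.is_linear(seqs_l[i], genome, hit_lookup, k)) {
      n_linear <- n_linear + 1L
      next
    }
    det <- detect_bsj(seqs_l[i], index, genome, k, max_span, hit_lookup,
                      details = TRUE)
    if (is.null(det$candidate)) {
      reasons <- c(reasons, det$reason)
    } else {
      cand <- det$candidate
      cand$read_seq <- seqs_l[i]
      cand$sample_id <- sample_id
      out[[i]] <- cand
    }
  }
  candidates <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  stats <- c(stats, linear = n_linear, bsj = nrow(candidates), table(reasons))
  list(candidates = candidates, stats = stats)
}

#' Apply the unique-read support filter to BSJ candidates
#'
#' A candidate junction survives if it is supported by at least
#' `min_unique` distinct read sequences in at least one sample; surviving
#' junctions are then quantified in every sample (zeros allowed). "Unique
#' BSJ reads" are distinct read sequences supporting the junction.
#'
#' @param candidates data.table from [call_bsj_readset()] (rows may pool
#'   several samples via `sample_id`).
#' @param min_unique minimal distinct-read support (default 2).
#' @return list with `junctions` (surviving coordinates + per-sample unique
#'   read counts, wide) and `support` (long per-sample counts for all
#'   candidates).
#' @export
aggregate_candidates <- function(candidates, min_unique = 2L) {
  cols <- c("chrom", "start", "end", "strand")
  if (nrow(candidates) == 0L) {
    empty <- data.table::data.table(chrom = character(0), start = integer(0),
                                    end = integer(0), strand = character(0))
    return(list(junctions = empty, support = empty))
  }
  dt <- data.table::as.data.table(candidates)
  support <- dt[, list(unique_reads = data.table::uniqueN(read_seq)),
                by = c(cols, "sample_id")]
  keep <- support[, list(max_support = max(unique_reads)), by = cols][max_support >= min_unique]
  if (nrow(keep) == 0L) {
    return(list(junctions = support[0L, cols, with = FALSE], support = support))
  }
  wide <- data.table::dcast(support[keep, on = cols],
                            chrom + start + end + strand ~ sample_id,
                            value.var = "unique_reads", fill = 0L)
  data.table::setorderv(wide, cols)
  list(junctions = wide, support = support)
}

#' Merge dual-library evidence into credible circRNAs
#'
#' A junction is credible only if its exact (chrom, start, end, strand)
#' occurs in both the whole-transcriptome-derived and the circRNA-seq-derived
#' junction sets; per-sample counts are carried from the whole-transcriptome
#' set.
#'
#' @param wholetx_junctions wide junction table ([aggregate_candidates()]
#'   `$junctions`) from the whole-transcriptome libraries.
#' @param circseq_junctions junction table from the circRNA-seq library.
#' @return data.table of credible circRNAs with per-sample counts and a
#'   `circ_id` of the form `chrom:start-end(strand)`.
#' @export
merge_dual_evidence <- function(wholetx_junctions, circseq_junctions) {
  cols <- c("chrom", "start", "end", "strand")
  wt <- data.table::as.data.table(wholetx_junctions)
  cs <- unique(data.table::as.data.table(circseq_junctions)[, cols, with = FALSE])
  credible <- wt[cs, on = cols, nomatch = NULL]
  data.table::setorderv(credible, cols)
  if (nrow(credible) > 0L) {
    credible[, circ_id := sprintf("%s:%d-%d(%s)", chrom, start, end, strand)]
    data.table::setcolorder(credible, c("circ_id", cols))
  } else {
    credible[, circ_id := character(0)]
  }
  credible[]
}

#' Assemble the spliced sequence of a circRNA
#'
#' Concatenates annotated exons lying inside the circularized span in
#' transcript order (reverse-complemented on the minus strand); when no exon
#' annotation overlaps the span, the genomic substring is used. Exons that
#' extend beyond the span boundaries are an error.
#'
#' @param circ list or one-row data.frame with `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param annotation feature data.frame as from [read_gtf()] (may be `NULL`).
#' @param genome named character vector of chromosomes.
#' @return spliced sequence (DNA alphabet, transcript orientation).
#' @export
spliced_sequence <- function(circ, annotation, genome) {
  chrom_seq <- genome[[circ$chrom]]
  if (is.null(chrom_seq)) stop("unknown chromosome: ", circ$chrom)
  if (!is.null(annotation)) {
    ex <- annotation[annotation$feature_type == "exon" &
                       annotation$chrom == circ$chrom &
                       annotation$strand == circ$strand &
                       annotation$end > circ$start & annotation$start < circ$end, ,
                     drop = FALSE]
  } else {
    ex <- NULL
  }
  if (!is.null(ex) && nrow(ex) > 0L) {
    if (any(ex$start < circ$start | ex$end > circ$end)) {
      stop("exon extends outside the circRNA span ", circ$chrom, ":",
           circ$start, "-", circ$end)
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    pieces <- substring(chrom_seq, ex$start + 1L, ex$end)
    if (circ$strand == "-") {
      paste(rev(revcomp(pieces)), collapse = "")
    } else {
      paste(pieces, collapse = "")
    }
  } else {
    s <- substr0(chrom_seq, circ$start, circ$end)
    if (circ$strand == "-") revcomp(s) else s
  }
}
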