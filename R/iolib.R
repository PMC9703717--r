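#' @title Readers and writers for pipeline file formats
#' @description
#' Strict readers/writers for FASTA, FASTQ, GTF, BED, TSV count tables and
#' network exports. All readers validate rather than coerce: malformed input
#' is rejected with a message naming the offending record. Every writer's
#' output is accepted by its reader with equality (round-trip guarantee).
#'
#' Internal coordinates are 0-based half-open everywhere in this package;
#' GTF I/O converts to/from the 1-based inclusive convention at the file
#' boundary, BED is written natively.
#' @name iolib
NULL

.valid_alphabet <- function(seqs, ids) {
  up <- toupper(seqs)
  bad_chr <- grepl("[^ACGTUN]", up)
  if (any(bad_chr)) {
    stop("invalid sequence alphabet in record(s): ",
         paste(ids[bad_chr], collapse = ", "))
  }
  mixed <- grepl("T", up) & grepl("U", up)
  if (any(mixed)) {
    stop("record(s) mix T and U: ", paste(ids[mixed], collapse = ", "))
  }
  up
}

#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector of uppercase sequences; names are record
#'   ids (first whitespace-separated token), descriptions are kept in the
#'   `"description"` attribute.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stop("empty sequence in record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  seqs <- .valid_alphabet(seqs, ids)
  names(seqs) <- ids
  attr(seqs, "description") <- stats::setNames(desc, ids)
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector (an optional `"description"` attribute
#'   is appended to headers).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  desc <- attr(seqs, "description")
  set <- Biostrings::BStringSet(unname(seqs))
  hdr <- names(seqs)
  if (!is.null(desc)) {
    d <- desc[names(seqs)]
    hdr <- ifelse(!is.na(d) & nzchar(d), paste(hdr, d), hdr)
  }
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read / write FASTQ
#'
#' Plain 4-line-per-record FASTQ (Phred+33). Returned as a data.frame with
#' columns `id`, `seq`, `qual`.
#' @param path file path.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("FASTQ file not a multiple of 4 lines: ", path)
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  ids <- lines[(idx - 1L) * 4L + 1L]
  if (!all(startsWith(ids, "@"))) stop("malformed FASTQ header line(s) in ", path)
  seqs <- toupper(lines[(idx - 1L) * 4L + 2L])
  qual <- lines[(idx - 1L) * 4L + 4L]
  if (any(nchar(seqs) != nchar(qual))) {
    bad <- which(nchar(seqs) != nchar(qual))[1]
    stop("sequence/quality length mismatch at record ", ids[bad])
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", ids)),
             seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`
#'   (constant "I" quality is filled in when absent).
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual %||% strrep("I", nchar(reads$seq))
  out <- character(4L * nrow(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$seq
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read / write gene annotation (GTF)
#'
#' Internally features are a data.frame with 0-based half-open `start`/`end`;
#' the GTF file is 1-based inclusive and conversion happens here.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `feature_type`, `start`, `end`,
#'   `strand`, `gene_id`, `transcript_id`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    feature_type = as.character(gr$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id %||% NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(df$start < 0L | df$end <= df$start)) stop("invalid feature coordinates in ", path)
  if (any(!df$strand %in% c("+", "-"))) stop("undefined strand in ", path)
  df
}

#' @rdname read_gtf
#' @param features data.frame as returned by [read_gtf()].
#' @export
write_gtf <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start + 1L, features$end),
    strand = features$strand
  )
  S4Vectors::mcols(gr)$source <- "cesponge"
  S4Vectors::mcols(gr)$type <- features$feature_type
  S4Vectors::mcols(gr)$gene_id <- features$gene_id
  S4Vectors::mcols(gr)$transcript_id <- features$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write intervals as BED (0-based half-open, native convention)
#'
#' @param df data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                   df$chrom, df$start, df$end, df$name, df$score, df$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV count table
#'
#' Rectangular TSV, first column = feature ids, remaining columns = samples.
#' Cells must be non-negative integers; violations are reported with the
#' feature and sample name.
#'
#' @param path file path.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("count table needs a feature column plus samples: ", path)
  feats <- as.character(tab[[1]])
  if (anyDuplicated(feats)) stop("duplicate feature id(s) in ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(apply(m, 2, as.numeric))
  num <- matrix(num, nrow = nrow(tab), dimnames = list(feats, colnames(m)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-integer or negative count at feature ", feats[bad[1, 1]],
         ", sample ", colnames(m)[bad[1, 2]])
  }
  storage.mode(num) <- "integer"
  num
}

#' @rdname read_counts
#' @param counts integer matrix (features x samples).
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ceRNA network edges / axes
#'
#' Edges and triple axes are written as TSV; `write_graphml()` additionally
#' exports the bipartite/triple graph for network tools.
#'
#' @param df data.frame of edges (`source_id`, `mirna_id`, ...) or axes
#'   (`cerna_id`, `mirna_id`, `mrna_id`, ...).
#' @param path output path.
#' @export
write_network_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_network_tsv
#' @param axes data.frame of triple axes with `cerna_id`, `mirna_id`,
#'   `mrna_id` and `cerna_class` columns.
#' @export
write_graphml <- function(axes, path) {
  edges <- unique(rbind(
    data.frame(from = axes$cerna_id, to = axes$mirna_id, stringsAsFactors = FALSE),
    data.frame(from = axes$mirna_id, to = axes$mrna_id, stringsAsFactors = FALSE)
  ))
  nodes <- data.frame(name = unique(c(axes$cerna_id, axes$mirna_id, axes$mrna_id)),
                      stringsAsFactors = FALSE)
  cls <- c(stats::setNames(axes$cerna_class, axes$cerna_id),
           stats::setNames(rep("miRNA", nrow(axes)), axes$mirna_id),
           stats::setNames(rep("mRNA", nrow(axes)), axes$mrna_id))
  nodes$class <- unname(cls[nodes$name])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
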