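test_that("the k-mer index finds exact hits on both strands and nothing else", {
  set.seed(21)
  genome <- list(chr1 = paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                              collapse = ""))
  idx <- build_index(genome, 20)
  kmer <- substr(genome$chr1, 101, 120)   # 0-based position 100
  h <- lookup_kmers(idx, kmer)
  expect_true(any(h$pos == 100 & h$strand == "+"))
  h_rc <- lookup_kmers(idx, revcomp(kmer))
  expect_true(any(h_rc$pos == 100 & h_rc$strand == "-"))
  ## random 20-mers absent from a 10 kb genome: verify against full-text scan
  set.seed(22)
  for (i in 1:20) {
    q <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    scan_hit <- grepl(q, genome$chr1, fixed = TRUE) ||
      grepl(revcomp(q), genome$chr1, fixed = TRUE)
    expect_equal(nrow(lookup_kmers(idx, q)) > 0, scan_hit)
  }
  expect_error(build_index(list(chr1 = "ACGTACGT"), 20), "shortest chromosome")
})

test_that("anchor extraction follows the 20 + 20 terminal rule", {
  r150 <- strrep("ACGT", 38)   # 152 nt
  r150 <- substr(r150, 1, 150)
  a <- extract_anchors(r150)
  expect_identical(a$head, substr(r150, 1, 20))
  expect_identical(a$tail, substr(r150, 131, 150))
  r40 <- substr(r150, 1, 40)
  a40 <- extract_anchors(r40)
  expect_identical(paste0(a40$head, a40$tail), r40)   # adjacent, non-overlapping
  expect_null(extract_anchors(substr(r150, 1, 39)))
})

test_that("manifest BSJ reads yield exact junction coordinates; linear reads never do", {
  ds <- default_dataset()
  det <- default_detection()
  tr <- ds$manifest$circ_truth
  set.seed(31)
  for (i in sample(nrow(tr), 8)) {
    reads <- simulate_bsj_reads(tr$spliced_sequence[i], 3, 150)
    for (r in reads) {
      cand <- detect_bsj(r, det$index, det$genome)
      expect_identical(cand$chrom, tr$chrom[i])
      expect_equal(cand$start, tr$start[i])
      expect_equal(cand$end, tr$end[i])
      expect_identical(cand$strand, tr$strand[i])
      expect_identical(cand$splice_signal, "GT/AG")
    }
  }
  ## an intra-exon linear read maps end-to-end and is not a BSJ
  ex <- ds$exons[1, ]
  lin <- substr(ds$genome[[ex$chrom]], ex$start + 1, ex$start + 150)
  expect_null(detect_bsj(lin, det$index, det$genome))
  res <- call_bsj_readset(lin, det$index, det$genome)
  expect_equal(nrow(res$candidates), 0)
  expect_equal(unname(res$stats["linear"]), 1)
})

test_that("destroying the splice-signal flank suppresses the call", {
  ds <- default_dataset()
  det <- default_detection()
  tr <- ds$manifest$circ_truth
  i <- which(tr$strand == "+")[1]
  set.seed(32)
  r <- simulate_bsj_reads(tr$spliced_sequence[i], 1, 150)
  mut <- det$genome
  chrom <- tr$chrom[i]
  ## AG acceptor flank at [start-2, start) -> AC
  substr(mut[[chrom]], tr$start[i] - 1, tr$start[i]) <- "AC"
  idx_mut <- build_index(mut)
  expect_null(detect_bsj(r, idx_mut, mut))
  expect_false(is.null(detect_bsj(r, det$index, det$genome)))
})

test_that("the unique-read filter keeps >=2 distinct sequences in some sample", {
  base <- data.frame(chrom = "chr1", start = 100L, end = 600L, strand = "+",
                     stringsAsFactors = FALSE)
  two_distinct <- rbind(cbind(base, read_seq = "AAA", sample_id = "s1"),
                        cbind(base, read_seq = "CCC", sample_id = "s1"))
  kept <- aggregate_candidates(two_distinct)$junctions
  expect_equal(nrow(kept), 1)
  expect_equal(kept$s1, 2L)
  three_copies <- rbind(cbind(base, read_seq = "AAA", sample_id = "s1"),
                        cbind(base, read_seq = "AAA", sample_id = "s1"),
                        cbind(base, read_seq = "AAA", sample_id = "s1"))
  expect_equal(nrow(aggregate_candidates(three_copies)$junctions), 0)
})

test_that("credibility filters match a brute-force oracle on random candidates", {
  set.seed(41)
  n_junc <- 30
  coords <- data.frame(chrom = sample(c("chr1", "chr2"), n_junc, TRUE),
                       start = sample(1000:5000, n_junc),
                       strand = sample(c("+", "-"), n_junc, TRUE))
  coords$end <- coords$start + sample(200:800, n_junc)
  rows <- coords[sample(n_junc, 100, replace = TRUE), ]
  rows$read_seq <- paste0("R", sample(1:4, 100, replace = TRUE))
  rows$sample_id <- sample(paste0("s", 1:3), 100, replace = TRUE)
  agg <- aggregate_candidates(rows)
  in_circseq <- coord_key(coords)[rbinom(n_junc, 1, 0.6) == 1]
  cred <- merge_dual_evidence(agg$junctions,
                              coords[coord_key(coords) %in% in_circseq, ])
  expect_identical(sort(coord_key(cred)),
                   brute_force_credible(rows, 2L, in_circseq))
})

test_that("dual-library merge requires exact coordinate agreement", {
  a <- data.frame(chrom = "chr1", start = c(100L, 300L), end = c(600L, 900L),
                  strand = "+", s1 = c(3L, 2L))
  b <- data.frame(chrom = "chr1", start = c(100L, 301L), end = c(600L, 900L),
                  strand = "+")
  cred <- merge_dual_evidence(a, b)
  expect_equal(nrow(cred), 1)          # the 1-nt-shifted junction is distinct
  expect_equal(cred$start, 100L)
  expect_equal(cred$s1, 3L)            # counts carried from the whole-tx arm
})

test_that("spliced sequences join annotated exons and respect strand", {
  set.seed(51)
  genome <- list(chr1 = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                              collapse = ""))
  ann <- data.frame(chrom = "chr1", feature_type = "exon",
                    start = c(100L, 300L), end = c(200L, 400L), strand = "+",
                    gene_id = "g", transcript_id = "g.t1", stringsAsFactors = FALSE)
  circ <- list(chrom = "chr1", start = 100L, end = 400L, strand = "+")
  sq <- spliced_sequence(circ, ann, genome)
  expect_equal(nchar(sq), 200)
  expect_identical(sq, paste0(substr(genome$chr1, 101, 200),
                              substr(genome$chr1, 301, 400)))
  ## no annotation -> genomic substring
  plain <- spliced_sequence(list(chrom = "chr1", start = 500L, end = 800L,
                                 strand = "+"), NULL, genome)
  expect_identical(plain, substr(genome$chr1, 501, 800))
  ## minus strand is the reverse complement of the plus-strand result
  ann_m <- ann; ann_m$strand <- "-"
  circ_m <- circ; circ_m$strand <- "-"
  expect_identical(spliced_sequence(circ_m, ann_m, genome), revcomp(sq))
  ## exon extending outside the span is an error
  ann_bad <- ann; ann_bad$end[2] <- 450L
  expect_error(spliced_sequence(circ, ann_bad, genome), "outside")
  ## multi-exon manifest circRNAs reproduce their recorded spliced sequence
  ds <- default_dataset()
  tr <- ds$manifest$circ_truth
  multi <- tr[tr$n_exons > 1, ][1, ]
  expect_identical(spliced_sequence(as.list(multi[, c("chrom", "start", "end", "strand")]),
                                    ds$annotation, as.list(ds$genome)),
                   multi$spliced_sequence)
})

test_that("candidate coordinates are invariant to read order", {
  ds <- default_dataset()
  det <- default_detection()
  reads <- ds$read_sets$wholetx[[1]]
  set.seed(61)
  shuf <- reads[sample(nrow(reads)), ]
  a <- call_bsj_readset(reads, det$index, det$genome, sample_id = "s")
  b <- call_bsj_readset(shuf, det$index, det$genome, sample_id = "s")
  key <- function(x) sort(paste(x$chrom, x$start, x$end, x$strand, x$read_seq))
  expect_identical(key(a$candidates), key(b$candidates))
})
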