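#' Simulation configuration
#'
#' Parameters of the synthetic dataset generator. Defaults emulate the study
#' design the pipeline targets: a 4-stage (D0, D15, D85, Y2) x 3-replicate
#' bulk design, 150 nt whole-transcriptome reads, 50 nt small-RNA reads, and
#' a panel of implanted circRNAs whose genomic flanks carry the canonical
#' AG (acceptor) / GT (donor) splice signal.
#'
#' @param seed integer RNG seed; identical seeds give byte-identical outputs.
#' @param n_chromosomes,chromosome_length genome shape (nt).
#' @param n_genes number of multi-exon protein-coding genes.
#' @param exons_per_gene integer range `c(min, max)`.
#' @param n_circ number of implanted circRNAs (each in a distinct host gene).
#' @param n_mirna,n_lncrna numbers of mature miRNAs / lncRNAs.
#' @param wholetx_read_length,smallrna_read_length read lengths (nt).
#' @param bsj_coverage BSJ-spanning reads per junction per sample.
#' @param linear_coverage mean fold-coverage of linear transcripts.
#' @param stage_labels,reps_per_stage design labels and replicates per stage.
#' @param nb_dispersion negative-binomial dispersion (variance = mu + a*mu^2).
#' @param effect_log2fc designed stage effect size on the log2 scale.
#' @param fraction_junction_only_mres fraction of circRNAs that receive a
#'   miRNA response element split across the back-splice junction (and hence
#'   absent from the linear sequence by construction).
#' @param error_rate uniform substitution rate in simulated reads (default 0:
#'   the exact-match caller is exercised on clean reads; error mode probes
#'   robustness).
#' @param lib_size_sd sd of log library-size factors (log-normal(0, sd)).
#' @param utr3_length length of the 3'UTR carved from each transcript end.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chromosome_length = 60000L,
                              n_genes = 60L,
                              exons_per_gene = c(2L, 4L),
                              n_circ = 50L,
                              n_mirna = 24L,
                              n_lncrna = 30L,
                              wholetx_read_length = 150L,
                              smallrna_read_length = 50L,
                              bsj_coverage = 10L,
                              linear_coverage = 1,
                              stage_labels = c("D0", "D15", "D85", "Y2"),
                              reps_per_stage = 3L,
                              nb_dispersion = 0.05,
                              effect_log2fc = 2,
                              fraction_junction_only_mres = 0.2,
                              error_rate = 0,
                              lib_size_sd = 0.1,
                              utr3_length = 150L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
              n_circ = as.integer(n_circ), n_mirna = as.integer(n_mirna),
              n_lncrna = as.integer(n_lncrna),
              wholetx_read_length = as.integer(wholetx_read_length),
              smallrna_read_length = as.integer(smallrna_read_length),
              bsj_coverage = as.integer(bsj_coverage),
              linear_coverage = linear_coverage,
              stage_labels = stage_labels, reps_per_stage = as.integer(reps_per_stage),
              nb_dispersion = nb_dispersion, effect_log2fc = effect_log2fc,
              fraction_junction_only_mres = fraction_junction_only_mres,
              error_rate = error_rate, lib_size_sd = lib_size_sd,
              utr3_length = as.integer(utr3_length))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$reps_per_stage < 2L) {
    stop("configuration infeasible: reps_per_stage must be >= 2 for differential expression")
  }
  if (cfg$n_circ > cfg$n_genes) {
    stop("configuration infeasible: n_circ (", cfg$n_circ,
         ") exceeds the number of host genes (", cfg$n_genes,
         "); each circRNA needs its own gene's exon pair")
  }
  if (cfg$nb_dispersion <= 0) stop("configuration infeasible: nb_dispersion must be positive")
  if (cfg$exons_per_gene[1] < 2L) {
    stop("configuration infeasible: genes need >= 2 exons (the transcript-last exon hosts the 3'UTR)")
  }
  if (cfg$fraction_junction_only_mres < 0 || cfg$fraction_junction_only_mres > 1) {
    stop("configuration infeasible: fraction_junction_only_mres must be in [0, 1]")
  }
  if (cfg$wholetx_read_length < 42L) {
    stop("configuration infeasible: whole-transcriptome reads must be >= 42 nt (two 20 nt anchors + 1 nt each side)")
  }
  invisible(cfg)
}

## designed stage archetypes: rows are cluster patterns over the 4 stages,
## values in [0, 1] scale the log2 effect size. Four single-stage-selective
## patterns, a down ramp, an up ramp and a mid-peak.
stage_archetypes <- function(n_stages = 4L) {
  stopifnot(n_stages == 4L)
  rbind(
    c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1),
    c(1, 2 / 3, 1 / 3, 0), c(0, 1 / 3, 2 / 3, 1), c(0, 1, 1, 0)
  )
}

## ---- internal builders -----------------------------------------------------

.place_genes <- function(cfg) {
  genes <- list(); exons <- list()
  chrom_i <- 1L; cursor <- 300L
  for (g in seq_len(cfg$n_genes)) {
    nex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1L)
    exlen <- sample(200:400, nex, replace = TRUE)
    inlen <- if (nex > 1L) sample(100:250, nex - 1L, replace = TRUE) else integer(0)
    span <- sum(exlen) + sum(inlen)
    if (cursor + span + 300L > cfg$chromosome_length) {
      chrom_i <- chrom_i + 1L; cursor <- 300L
      if (chrom_i > cfg$n_chromosomes) {
        stop("configuration infeasible: ", cfg$n_genes, " genes do not fit in ",
             cfg$n_chromosomes, " chromosome(s) of ", cfg$chromosome_length, " nt")
      }
    }
    strand <- sample(c("+", "-"), 1L)
    starts <- cursor + cumsum(c(0L, exlen[-nex] + inlen))
    ends <- starts + exlen
    gid <- sprintf("gene%03d", g)
    rank_tx <- if (strand == "+") seq_len(nex) else rev(seq_len(nex))
    genes[[g]] <- data.frame(gene_id = gid, chrom = paste0("chr", chrom_i),
                             strand = strand, start = cursor, end = cursor + span,
                             n_exons = nex, stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(gene_id = gid, chrom = paste0("chr", chrom_i),
                             strand = strand, start = starts, end = ends,
                             rank_tx = rank_tx, stringsAsFactors = FALSE)
    cursor <- cursor + span + sample(200:500, 1L)
  }
  if (10L * max(vapply(genes, function(x) x$end - x$start, numeric(1))) >
      cfg$chromosome_length) {
    stop("configuration infeasible: chromosome_length must be >= 10 x the longest gene span")
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
}

## transcript-ordered exon table for one gene
.tx_exons <- function(exons, gid) {
  ex <- exons[exons$gene_id == gid, , drop = FALSE]
  ex[order(ex$rank_tx), , drop = FALSE]
}

## spliced sequence of transcript-ordered exons
.splice_exons <- function(genome, ex) {
  pieces <- substring(genome[[ex$chrom[1]]], ex$start + 1L, ex$end)
  if (ex$strand[1] == "-") pieces <- revcomp(pieces)
  paste(pieces, collapse = "")
}

## map a spliced-coordinate interval [pos, pos+len) (transcript orientation)
## to a genomic interval; the interval must fall inside a single exon.
.spliced_to_genomic <- function(ex, pos, len) {
  cum <- cumsum(c(0L, ex$end - ex$start))
  i <- findInterval(pos, cum, rightmost.closed = FALSE)
  off <- pos - cum[i]
  if (pos + len > cum[i + 1L]) stop("implant crosses an exon boundary")
  if (ex$strand[1] == "+") {
    c(ex$start[i] + off, ex$start[i] + off + len)
  } else {
    c(ex$end[i] - off - len, ex$end[i] - off)
  }
}

## write a transcript-orientation motif into the genome at spliced coords
.implant_spliced <- function(genome, ex, pos, motif) {
  g <- .spliced_to_genomic(ex, pos, nchar(motif))
  m <- if (ex$strand[1] == "+") motif else revcomp(motif)
  genome[[ex$chrom[1]]] <- replace0(genome[[ex$chrom[1]]], g[1], m)
  genome
}

.overlaps <- function(occ, chrom, start, end) {
  o <- occ[[chrom]]
  !is.null(o) && any(o$start < end & start < o$end)
}

.occupy <- function(occ, chrom, start, end) {
  occ[[chrom]] <- rbind(occ[[chrom]], data.frame(start = start, end = end))
  occ
}

## ---- main generator --------------------------------------------------------

#' Generate a synthetic dataset with a ground-truth manifest
#'
#' Builds a small multi-chromosome genome with multi-exon genes, implants
#' circRNAs (AG...GT genomic flanks, strand-aware), mature miRNAs whose seed
#' complements are written into 3'UTRs, lncRNAs, circRNA bodies and -- split
#' across the back-splice junction -- into circRNA termini, then simulates
#' BSJ-spanning and linear reads, small-RNA reads, and negative-binomial
#' count matrices with designed stage-selective profiles and designed
#' negative miRNA-target correlations. Everything implanted is recorded in
#' the manifest, which is the oracle for all recovery tests.
#'
#' circRNAs circularize 1-3 consecutive transcript-order exons and never
#' include the transcript-last exon (reserved for the 3'UTR). Exon lengths
#' (200-400 nt) exceed the read length minus one anchor, so both arms of
#' every BSJ read are genomically contiguous and the junction is recoverable
#' by exact anchor extension.
#'
#' @param config a [simulation_config()].
#' @param reads simulate read sets (default `TRUE`); `FALSE` skips FASTQ-level
#'   simulation for count-only studies.
#' @return a `synthetic_dataset` list with elements `genome` (named character),
#'   `annotation` (feature data.frame), `mirna`, `lncrna`, `utr3`,
#'   `transcripts`, `circ_seqs` (named character vectors), `read_sets`,
#'   `counts` (list of class matrices), `sample_info`, `manifest`
#'   (circ_truth, mre_truth, novel_junction_pairs, expression_design,
#'   de_truth, cluster_archetype) and `config`.
#' @export
generate_dataset <- function(config = simulation_config(), reads = TRUE) {
  cfg <- validate_simulation_config(config)
  set.seed(cfg$seed)
  n_samples <- length(cfg$stage_labels) * cfg$reps_per_stage

  ## 1. genome ----------------------------------------------------------------
  genome <- stats::setNames(as.list(random_dna(cfg$n_chromosomes, cfg$chromosome_length)),
                            paste0("chr", seq_len(cfg$n_chromosomes)))
  placed <- .place_genes(cfg)
  genes <- placed$genes; exons <- placed$exons
  occ <- list()

  ## 2. circRNAs: pick host genes, spans of 1-3 transcript-consecutive exons
  ##    excluding the transcript-last exon; implant splice-signal flanks.
  host <- sample(genes$gene_id, cfg$n_circ)
  circ_truth <- vector("list", cfg$n_circ)
  circ_exons <- vector("list", cfg$n_circ)
  for (i in seq_len(cfg$n_circ)) {
    ex <- .tx_exons(exons, host[i])
    nex <- nrow(ex)
    nspan <- sample.int(min(3L, nex - 1L), 1L)
    a <- sample.int(nex - nspan, 1L)   # transcript ranks a..a+nspan-1, last exon excluded
    sel <- ex[a:(a + nspan - 1L), , drop = FALSE]
    s <- min(sel$start); e <- max(sel$end)
    strand <- sel$strand[1]; chrom <- sel$chrom[1]
    if (strand == "+") {   # transcript-orientation acceptor AG | circ | donor GT
      genome[[chrom]] <- replace0(genome[[chrom]], s - 2L, "AG")
      genome[[chrom]] <- replace0(genome[[chrom]], e, "GT")
    } else {               # reverse complement on the minus strand
      genome[[chrom]] <- replace0(genome[[chrom]], s - 2L, "AC")
      genome[[chrom]] <- replace0(genome[[chrom]], e, "CT")
    }
    occ <- .occupy(occ, chrom, s - 2L, s)
    occ <- .occupy(occ, chrom, e, e + 2L)
    circ_exons[[i]] <- sel
    circ_truth[[i]] <- data.frame(
      circ_id = sprintf("circ%03d", i), chrom = chrom, start = s, end = e,
      strand = strand, host_gene = host[i], n_exons = nspan,
      spliced_length = sum(sel$end - sel$start), stringsAsFactors = FALSE)
  }
  circ_truth <- do.call(rbind, circ_truth)
  names(circ_exons) <- circ_truth$circ_id

  ## 3. mature miRNAs with distinct seeds ------------------------------------
  mirna <- character(cfg$n_mirna)
  repeat {
    mirna <- as_rna(random_dna(cfg$n_mirna, 22L))
    if (!anyDuplicated(substr(mirna, 2L, 8L))) break
  }
  names(mirna) <- sprintf("miR-%03d", seq_len(cfg$n_mirna))
  seed_comp <- stats::setNames(revcomp(as_dna(substr(mirna, 2L, 8L))), names(mirna))

  ## 4. MRE implants ----------------------------------------------------------
  mre <- list()
  utr_len <- cfg$utr3_length

  ## 4a. one 3'UTR site per miRNA, each in a distinct gene
  utr_genes <- sample(genes$gene_id, cfg$n_mirna)
  for (i in seq_len(cfg$n_mirna)) {
    ex <- .tx_exons(exons, utr_genes[i])
    tx_len <- sum(ex$end - ex$start)
    for (try in 1:50) {
      off <- sample.int(utr_len - 27L, 1L) + 9L      # inside the UTR, away from edges
      pos <- tx_len - utr_len + off
      g <- .spliced_to_genomic(ex, pos, 7L)
      if (!.overlaps(occ, ex$chrom[1], g[1], g[2])) break
      if (try == 50) stop("could not place 3'UTR MRE for ", names(mirna)[i])
    }
    genome <- .implant_spliced(genome, ex, pos, seed_comp[i])
    occ <- .occupy(occ, ex$chrom[1], g[1], g[2])
    mre[[length(mre) + 1L]] <- data.frame(
      mirna_id = names(mirna)[i], target_id = utr_genes[i], target_class = "utr3",
      site_start = off, site_end = off + 7L, stringsAsFactors = FALSE)
  }

  ## 4b. lncRNAs, one site per miRNA in a distinct lncRNA
  lnc_len <- sample(400:800, cfg$n_lncrna, replace = TRUE)
  lncrna <- stats::setNames(random_dna(cfg$n_lncrna, 1L), sprintf("lnc%03d", seq_len(cfg$n_lncrna)))
  for (j in seq_len(cfg$n_lncrna)) lncrna[j] <- random_dna(1L, lnc_len[j])
  lnc_targets <- sample(names(lncrna), cfg$n_mirna)
  for (i in seq_len(cfg$n_mirna)) {
    L <- nchar(lncrna[lnc_targets[i]])
    pos <- sample.int(L - 107L, 1L) + 49L
    lncrna[lnc_targets[i]] <- replace0(lncrna[lnc_targets[i]], pos, seed_comp[i])
    mre[[length(mre) + 1L]] <- data.frame(
      mirna_id = names(mirna)[i], target_id = lnc_targets[i], target_class = "lncrna",
      site_start = pos, site_end = pos + 7L, stringsAsFactors = FALSE)
  }

  ## 4c. junction-spanning sites: seed complement split across the BSJ
  n_junc <- round(cfg$fraction_junction_only_mres * cfg$n_circ)
  junc_circs <- if (n_junc > 0) sample(circ_truth$circ_id, n_junc) else character(0)
  junc_mirna <- stats::setNames(sample(names(mirna), n_junc, replace = TRUE), junc_circs)
  for (cid in junc_circs) {
    ex <- circ_exons[[cid]]
    L <- sum(ex$end - ex$start)
    sc <- seed_comp[junc_mirna[cid]]
    a <- sample(2:5, 1L)                               # first a nt at the spliced end
    genome <- .implant_spliced(genome, ex, L - a, substr(sc, 1L, a))
    genome <- .implant_spliced(genome, ex, 0L, substr(sc, a + 1L, 7L))
    g1 <- .spliced_to_genomic(ex, L - a, a); g2 <- .spliced_to_genomic(ex, 0L, 7L - a)
    occ <- .occupy(occ, ex$chrom[1], g1[1], g1[2])
    occ <- .occupy(occ, ex$chrom[1], g2[1], g2[2])
    joff <- min(100L, L)
    mre[[length(mre) + 1L]] <- data.frame(
      mirna_id = junc_mirna[cid], target_id = cid, target_class = "circ_junction",
      site_start = joff - a, site_end = joff + (7L - a), stringsAsFactors = FALSE)
  }

  ## 4d. body sites in circRNAs not used for junction MREs, > 100 nt from ends
  body_pool <- setdiff(circ_truth$circ_id[circ_truth$spliced_length >= 230L], junc_circs)
  n_body <- min(length(body_pool), round(0.2 * cfg$n_circ))
  body_circs <- if (n_body > 0) sample(body_pool, n_body) else character(0)
  body_mirna <- stats::setNames(sample(names(mirna), n_body, replace = TRUE), body_circs)
  for (cid in body_circs) {
    ex <- circ_exons[[cid]]
    L <- sum(ex$end - ex$start)
    for (try in 1:50) {
      pos <- sample(100:(L - 107L), 1L)
      g <- tryCatch(.spliced_to_genomic(ex, pos, 7L), error = function(e) NULL)
      if (!is.null(g) && !.overlaps(occ, ex$chrom[1], g[1], g[2])) break
      g <- NULL
      if (try == 50) break
    }
    if (is.null(g)) next
    genome <- .implant_spliced(genome, ex, pos, seed_comp[body_mirna[cid]])
    occ <- .occupy(occ, ex$chrom[1], g[1], g[2])
    mre[[length(mre) + 1L]] <- data.frame(
      mirna_id = body_mirna[cid], target_id = cid, target_class = "circ_body",
      site_start = pos, site_end = pos + 7L, stringsAsFactors = FALSE)
  }

  ## 4e. purge chance linear occurrences of junction-MRE seeds so that the
  ##     implanted junction site is junction-only by construction
  for (cid in junc_circs) {
    ex <- circ_exons[[cid]]
    sc <- seed_comp[junc_mirna[cid]]
    for (round_i in 1:20) {
      spliced <- .splice_exons(genome, ex)
      hits <- find_fixed(sc, spliced)
      if (length(hits) == 0L) break
      h <- hits[1]
      fixed <- FALSE
      for (k in seq_len(7L)) {      # mutate one free base of the occurrence
        g <- .spliced_to_genomic(ex, h + k - 1L, 1L)
        if (!.overlaps(occ, ex$chrom[1], g[1], g[2])) {
          cur <- substr0(spliced, h + k - 1L, h + k)
          repl <- setdiff(c("A", "C", "G", "T"), cur)[sample.int(3L, 1L)]
          genome <- .implant_spliced(genome, ex, h + k - 1L, repl)
          fixed <- TRUE
          break
        }
      }
      if (!fixed) stop("could not make junction MRE unique for ", cid)
    }
  }
  mre_truth <- do.call(rbind, mre)

  ## 5. final sequences --------------------------------------------------------
  transcripts <- stats::setNames(vapply(genes$gene_id, function(g) {
    .splice_exons(genome, .tx_exons(exons, g))
  }, character(1)), genes$gene_id)
  utr3 <- stats::setNames(substring(transcripts, nchar(transcripts) - utr_len + 1L),
                          names(transcripts))
  circ_seqs <- stats::setNames(vapply(circ_truth$circ_id, function(cid) {
    .splice_exons(genome, circ_exons[[cid]])
  }, character(1)), circ_truth$circ_id)
  circ_truth$spliced_sequence <- unname(circ_seqs)

  ## junction-only pair truth by exhaustive substring scan
  novel_pairs <- .scan_novel_pairs(circ_seqs, seed_comp)

  ## 6. expression design ------------------------------------------------------
  A <- stage_archetypes(length(cfg$stage_labels))
  design <- .build_expression_design(cfg, genes$gene_id, names(mirna), names(lncrna),
                                     circ_truth$circ_id, mre_truth, A)

  ## 7. counts -----------------------------------------------------------------
  sample_info <- data.frame(
    sample_id = paste0(rep(cfg$stage_labels, each = cfg$reps_per_stage), "_",
                       rep(seq_len(cfg$reps_per_stage), length(cfg$stage_labels))),
    stage = rep(cfg$stage_labels, each = cfg$reps_per_stage),
    stringsAsFactors = FALSE)
  sf <- stats::rlnorm(n_samples, 0, cfg$lib_size_sd)
  counts <- lapply(design$means, function(m) {
    simulate_counts(m, sample_info$stage, cfg$nb_dispersion,
                    size_factors = sf, sample_ids = sample_info$sample_id)
  })

  ## 8. reads -------------------------------------------------------------------
  read_sets <- if (reads) {
    .simulate_read_sets(cfg, genome, transcripts, circ_seqs, mirna,
                        counts$mirna, sample_info)
  } else {
    NULL
  }

  structure(list(
    genome = stats::setNames(unlist(genome), names(genome)),
    annotation = .as_annotation(genes, exons, utr_len),
    genes = genes, exons = exons,
    mirna = mirna, lncrna = lncrna, utr3 = utr3, transcripts = transcripts,
    circ_seqs = circ_seqs,
    read_sets = read_sets, counts = counts, size_factors = sf,
    sample_info = sample_info,
    manifest = list(circ_truth = circ_truth, mre_truth = mre_truth,
                    novel_junction_pairs = novel_pairs,
                    expression_design = design$means,
                    de_truth = design$de_truth,
                    cluster_archetype = design$archetype,
                    designed_axes = design$designed_axes),
    config = cfg), class = "synthetic_dataset")
}

## pair is junction-only iff the seed complement straddles the BSJ in the
## pseudo-sequence and never occurs in the linear spliced sequence
.scan_novel_pairs <- function(circ_seqs, seed_comp) {
  out <- list()
  for (cid in names(circ_seqs)) {
    sq <- circ_seqs[[cid]]
    L <- nchar(sq)
    joff <- min(100L, L)
    pseudo <- paste0(substring(sq, L - joff + 1L), substring(sq, 1L, joff))
    for (m in names(seed_comp)) {
      if (length(find_fixed(seed_comp[[m]], sq)) > 0L) next
      hits <- find_fixed(seed_comp[[m]], pseudo)
      if (any(hits < joff & hits + 7L > joff)) {
        out[[length(out) + 1L]] <- data.frame(circ_id = cid, mirna_id = m,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(circ_id = character(0), mirna_id = character(0)))
  }
  do.call(rbind, out)
}

.build_expression_design <- function(cfg, gene_ids, mirna_ids, lnc_ids, circ_ids,
                                     mre_truth, A) {
  n_arch <- nrow(A)
  lfc <- cfg$effect_log2fc
  flat <- rep(0, ncol(A))
  pattern_of <- function(arch) if (arch == 0L) flat else A[arch, ]
  inverted <- function(p) max(p) - p

  ## Half of the miRNAs carry a designed stage response; the rest are flat so
  ## that median-of-ratios normalization keeps a stable anchor (the estimator
  ## assumes most features are not changing). Designed sponge miRNAs use only
  ## the graded archetypes (ramps, mid-peak): a single-stage-selective pattern
  ## against its mirror yields expected Spearman rho of only ~ -0.55 across
  ## 3 high + 9 exchangeable samples, too weak for the rho < -0.6 gate even
  ## without counting noise.
  graded <- which(apply(A, 1, function(p) length(unique(p)) >= 3 ||
                          sum(p == max(p)) >= 2))
  n_designed <- ceiling(length(mirna_ids) / 2)
  arch_mirna <- stats::setNames(rep(0L, length(mirna_ids)), mirna_ids)
  designed_mirnas <- mirna_ids[seq_len(n_designed)]
  arch_mirna[designed_mirnas] <- rep_len(graded, n_designed)
  pat <- list()
  pat$mirna <- stats::setNames(lapply(arch_mirna, pattern_of), mirna_ids)

  assign_class <- function(ids, class_name) {
    p <- stats::setNames(vector("list", length(ids)), ids)
    arch <- stats::setNames(rep(NA_integer_, length(ids)), ids)
    tgt <- mre_truth[mre_truth$target_id %in% ids &
                       mre_truth$mirna_id %in% designed_mirnas, , drop = FALSE]
    free <- setdiff(ids, tgt$target_id)
    ## free features: half flat, the rest cycle the archetypes
    arch[free] <- rep_len(c(0L, 0L, seq_len(n_arch)), length(free))
    for (id in free) p[[id]] <- pattern_of(arch[[id]])
    for (k in seq_len(nrow(tgt))) {    # targets mirror their miRNA's profile
      id <- tgt$target_id[k]
      p[[id]] <- inverted(pat$mirna[[tgt$mirna_id[k]]])
    }
    list(p = p, arch = arch, designed = tgt)
  }
  mr <- assign_class(gene_ids, "mrna")
  ln <- assign_class(lnc_ids, "lncrna")
  ci <- assign_class(circ_ids, "circ")

  ## designed ceRNA axes: (ceRNA, miRNA, mRNA) where both the ceRNA and the
  ## mRNA mirror the same designed miRNA
  mk_axes <- function(ce, class_name) {
    ax <- merge(ce$designed[, c("target_id", "mirna_id")],
                mr$designed[, c("mirna_id", "target_id")], by = "mirna_id")
    if (nrow(ax) == 0L) {
      return(data.frame(cerna_id = character(0), mirna_id = character(0),
                        mrna_id = character(0), cerna_class = character(0)))
    }
    data.frame(cerna_id = ax$target_id.x, mirna_id = ax$mirna_id,
               mrna_id = ax$target_id.y, cerna_class = class_name,
               stringsAsFactors = FALSE)
  }
  designed_axes <- rbind(mk_axes(ci, "circRNA"), mk_axes(ln, "lncRNA"))

  mk_means <- function(p_list) {
    base <- stats::runif(length(p_list), 6, 9)
    m <- t(vapply(seq_along(p_list), function(i) 2^(base[i] + lfc * p_list[[i]]),
                  numeric(length(cfg$stage_labels))))
    dimnames(m) <- list(names(p_list), cfg$stage_labels)
    m
  }
  means <- list(mirna = mk_means(pat$mirna), mrna = mk_means(mr$p),
                lncrna = mk_means(ln$p), circ = mk_means(ci$p))

  cmp <- utils::combn(cfg$stage_labels, 2L)
  de_truth <- do.call(rbind, lapply(names(means), function(cl) {
    m <- means[[cl]]
    do.call(rbind, lapply(seq_len(ncol(cmp)), function(j) {
      data.frame(class = cl, feature_id = rownames(m),
                 group_a = cmp[1, j], group_b = cmp[2, j],
                 true_log2fc = log2(m[, cmp[2, j]] / m[, cmp[1, j]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  de_truth$sign <- sign(round(de_truth$true_log2fc, 10))

  archetype <- rbind(
    data.frame(class = "mirna", feature_id = mirna_ids, archetype = unname(arch_mirna)),
    data.frame(class = "mrna", feature_id = gene_ids, archetype = unname(mr$arch)),
    data.frame(class = "lncrna", feature_id = lnc_ids, archetype = unname(ln$arch)),
    data.frame(class = "circ", feature_id = circ_ids, archetype = unname(ci$arch)))

  list(means = means, de_truth = de_truth, archetype = archetype,
       designed_axes = designed_axes)
}

.as_annotation <- function(genes, exons, utr_len) {
  g <- data.frame(chrom = genes$chrom, feature_type = "gene", start = genes$start,
                  end = genes$end, strand = genes$strand, gene_id = genes$gene_id,
                  transcript_id = paste0(genes$gene_id, ".t1"), stringsAsFactors = FALSE)
  e <- data.frame(chrom = exons$chrom, feature_type = "exon", start = exons$start,
                  end = exons$end, strand = exons$strand, gene_id = exons$gene_id,
                  transcript_id = paste0(exons$gene_id, ".t1"), stringsAsFactors = FALSE)
  rbind(g, e)
}

## ---- reads -----------------------------------------------------------------

#' Simulate BSJ-spanning reads for one circRNA
#'
#' Each read is a contiguous window of the (rolling-circle) repeated spliced
#' sequence that crosses the back-splice junction with at least 21 nt on each
#' side, so both 20 nt terminal anchors map to opposite genomic flanks.
#' Junction offsets are sampled without replacement, making reads distinct
#' whenever enough offsets exist.
#'
#' @param spliced spliced circRNA sequence.
#' @param n number of reads.
#' @param read_length read length (nt).
#' @param error_rate uniform substitution probability per base.
#' @param rolling allow reads longer than the spliced sequence by rolling-
#'   circle concatenation.
#' @return character vector of `n` read sequences.
#' @export
simulate_bsj_reads <- function(spliced, n, read_length = 150L, error_rate = 0,
                               rolling = FALSE) {
  L <- nchar(spliced)
  if (n == 0L) return(character(0))
  if (L < read_length && !rolling) {
    stop("spliced length ", L, " < read length ", read_length,
         " and rolling-circle mode is off")
  }
  jmax <- min(L, read_length - 21L)
  if (jmax < 21L) stop("spliced sequence too short to place a junction-spanning read")
  offs <- 21:jmax
  j <- if (n <= length(offs)) sample(offs, n) else sample(offs, n, replace = TRUE)
  rep_seq <- strrep(spliced, ceiling(read_length / L) + 1L)
  reads <- substring(rep_seq, L - j + 1L, L - j + read_length)
  if (error_rate > 0) reads <- .add_errors(reads, error_rate)
  reads
}

.add_errors <- function(reads, rate) {
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(stats::runif(n) < rate)
    for (i in hit) {
      cur <- substr(r, i, i)
      substr(r, i, i) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
    r
  }, character(1), USE.NAMES = FALSE)
}

.simulate_read_sets <- function(cfg, genome, transcripts, circ_seqs, mirna,
                                mirna_counts, sample_info) {
  rl <- cfg$wholetx_read_length
  linear_reads <- function(prefix, coverage) {
    out <- list()
    for (g in names(transcripts)) {
      tx <- transcripts[[g]]
      n <- max(0L, round(coverage * nchar(tx) / rl))
      if (n == 0L) next
      starts <- sample.int(nchar(tx) - rl + 1L, n, replace = TRUE)
      reads <- substring(tx, starts, starts + rl - 1L)
      if (cfg$error_rate > 0) reads <- .add_errors(reads, cfg$error_rate)
      out[[g]] <- data.frame(id = sprintf("%s_%s_%d", prefix, g, seq_len(n)),
                             seq = reads, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  bsj_reads <- function(prefix) {
    out <- list()
    for (cid in names(circ_seqs)) {
      reads <- simulate_bsj_reads(circ_seqs[[cid]], cfg$bsj_coverage, rl,
                                  error_rate = cfg$error_rate)
      out[[cid]] <- data.frame(id = sprintf("%s_%s_%d", prefix, cid,
                                            seq_len(length(reads))),
                               seq = reads, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  wholetx <- stats::setNames(lapply(sample_info$sample_id, function(s) {
    rbind(linear_reads(paste0(s, "_lin"), cfg$linear_coverage),
          bsj_reads(paste0(s, "_bsj")))
  }), sample_info$sample_id)
  circseq <- rbind(linear_reads("pool_lin", cfg$linear_coverage / 5),
                   bsj_reads("pool_bsj"))
  adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
  smallrna <- stats::setNames(lapply(sample_info$sample_id, function(s) {
    cnt <- mirna_counts[, s]
    seqs <- rep(substr(paste0(as_dna(mirna), adapter), 1L, cfg$smallrna_read_length), cnt)
    data.frame(id = sprintf("%s_sr_%d", s, seq_along(seqs)), seq = seqs,
               stringsAsFactors = FALSE)
  }), sample_info$sample_id)
  list(wholetx = wholetx, circseq = circseq, smallrna = smallrna)
}

## ---- counts ----------------------------------------------------------------

#' Simulate a negative-binomial count matrix from designed stage means
#'
#' `counts[f, s] ~ NB(mean = design[f, stage(s)] * size_factor[s],
#' dispersion = a)` with `Var = mu + a mu^2`. Library-size factors default to
#' log-normal(0, 0.1) draws.
#'
#' @param design numeric matrix of per-feature per-stage means (> 0).
#' @param stages character vector of per-sample stage labels (must match
#'   design columns).
#' @param dispersion NB dispersion a > 0.
#' @param size_factors optional per-sample positive factors; drawn
#'   log-normally when `NULL`.
#' @param sample_ids optional column names.
#' @param lib_size_sd sd of log size factors when drawn here.
#' @return integer count matrix, features x samples.
#' @export
simulate_counts <- function(design, stages, dispersion, size_factors = NULL,
                            sample_ids = NULL, lib_size_sd = 0.1) {
  if (dispersion <= 0) stop("dispersion must be positive")
  if (any(design <= 0)) stop("design means must be positive")
  stopifnot(all(stages %in% colnames(design)))
  n_s <- length(stages)
  if (is.null(size_factors)) size_factors <- stats::rlnorm(n_s, 0, lib_size_sd)
  mu <- design[, stages, drop = FALSE] %*% diag(size_factors, n_s)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
                   nrow = nrow(design),
                   dimnames = list(rownames(design),
                                   sample_ids %||% paste0(stages, "_", seq_len(n_s))))
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate stage-archetype expression profiles for clustering benchmarks
#'
#' Emits per-sample profiles drawn as `archetype[stage] + N(0, noise_sd)`,
#' one block of features per archetype, with the true cluster labels.
#'
#' @param n_per_cluster features per archetype.
#' @param noise_sd Gaussian noise sd on the archetype value.
#' @param stage_labels stage labels (4).
#' @param reps_per_stage replicates per stage.
#' @return list with `profiles` (matrix features x samples), `stages`,
#'   `truth` (integer archetype per feature).
#' @export
simulate_archetype_profiles <- function(n_per_cluster = 10L, noise_sd = 0.1,
                                        stage_labels = c("D0", "D15", "D85", "Y2"),
                                        reps_per_stage = 3L) {
  A <- stage_archetypes(length(stage_labels))
  stages <- rep(stage_labels, each = reps_per_stage)
  n_feat <- nrow(A) * n_per_cluster
  truth <- rep(seq_len(nrow(A)), each = n_per_cluster)
  base <- A[truth, match(stages, stage_labels), drop = FALSE]
  profiles <- base + matrix(stats::rnorm(length(base), 0, noise_sd), nrow = n_feat)
  dimnames(profiles) <- list(sprintf("feat%03d", seq_len(n_feat)),
                             paste0(stages, "_", rep(seq_len(reps_per_stage),
                                                     length(stage_labels))))
  list(profiles = profiles, stages = stages, truth = truth)
}

## ---- writing ---------------------------------------------------------------

#' Write a synthetic dataset to disk
#'
#' Emits genome FASTA, annotation GTF (1-based inclusive), reads as FASTQ
#' (Phred+33, constant quality), count TSVs, and the ground-truth manifest as
#' tabular text plus a BED (0-based half-open) of circRNA intervals. Output
#' is deterministic: the same dataset writes byte-identical files.
#'
#' @param ds a `synthetic_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  dir.create(file.path(dir, "manifest"), showWarnings = FALSE)
  write_fasta(ds$genome, file.path(dir, "genome.fa"))
  write_gtf(ds$annotation, file.path(dir, "annotation.gtf"))
  write_fasta(ds$mirna, file.path(dir, "mirna.fa"))
  write_fasta(ds$lncrna, file.path(dir, "lncrna.fa"))
  write_fasta(ds$utr3, file.path(dir, "utr3.fa"))
  write_fasta(ds$transcripts, file.path(dir, "transcripts.fa"))
  write_fasta(ds$circ_seqs, file.path(dir, "circ_spliced.fa"))
  for (s in names(ds$read_sets$wholetx)) {
    write_fastq(ds$read_sets$wholetx[[s]], file.path(dir, "reads", paste0("wholetx_", s, ".fastq")))
  }
  write_fastq(ds$read_sets$circseq, file.path(dir, "reads", "circseq_pool.fastq"))
  for (s in names(ds$read_sets$smallrna)) {
    write_fastq(ds$read_sets$smallrna[[s]], file.path(dir, "reads", paste0("smallrna_", s, ".fastq")))
  }
  for (cl in names(ds$counts)) {
    write_counts(ds$counts[[cl]], file.path(dir, paste0("counts_", cl, ".tsv")))
  }
  man <- ds$manifest
  utils::write.table(man$circ_truth, file.path(dir, "manifest", "circ_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(data.frame(chrom = man$circ_truth$chrom, start = man$circ_truth$start,
                       end = man$circ_truth$end, name = man$circ_truth$circ_id,
                       score = 0, strand = man$circ_truth$strand),
            file.path(dir, "manifest", "circ_truth.bed"))
  utils::write.table(man$mre_truth, file.path(dir, "manifest", "mre_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(man$novel_junction_pairs,
                     file.path(dir, "manifest", "novel_junction_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(man$designed_axes,
                     file.path(dir, "manifest", "designed_axes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cl in names(man$expression_design)) {
    utils::write.table(data.frame(feature = rownames(man$expression_design[[cl]]),
                                  man$expression_design[[cl]], check.names = FALSE),
                       file.path(dir, "manifest", paste0("expression_design_", cl, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(man$de_truth, file.path(dir, "manifest", "de_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(man$cluster_archetype, file.path(dir, "manifest", "cluster_archetype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$sample_info, file.path(dir, "manifest", "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- ds$config
  utils::write.table(data.frame(parameter = names(cfg),
                                value = vapply(cfg, function(x) paste(x, collapse = ","),
                                               character(1))),
                     file.path(dir, "manifest", "params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
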