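#' Heterozygous sites from a pileup
#'
#' Tallies per-position base counts (primary alignments with mapping quality
#' at least `min_mapq`; indels ignored) over a region and emits sites whose
#' depth reaches `het_min_depth` and whose non-reference allele fraction
#' falls inside the heterozygous window `[het_af_lo, het_af_hi]`.
#'
#' @param bam SAM/BAM path.
#' @param ref Reference `DNAStringSet`.
#' @param chrom,start,end Region (1-based inclusive).
#' @param cfg A [bnd_config()].
#' @return Tibble: `chrom`, `pos`, `ref_allele`, `alt_allele`, `depth`,
#'   `alt_fraction`.
#' @export
pileup_het_sites <- function(bam, ref, chrom, start, end,
                             cfg = bnd_config()) {
  cfg <- as_bnd_config(cfg)
  if (!chrom %in% names(ref)) stop("no such contig: ", chrom, call. = FALSE)
  clen <- length(ref[[chrom]])
  if (start < 1 || end > clen || start > end)
    stop("region outside contig ", chrom, " (length ", clen, ")",
         call. = FALSE)
  bamf <- prepare_bam(bam)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  sbp <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    which = gr, mapqFilter = cfg$min_mapq)
  pp <- Rsamtools::PileupParam(max_depth = 10000L, min_base_quality = 0L,
                               min_mapq = cfg$min_mapq,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  pu <- Rsamtools::pileup(bamf, scanBamParam = sbp, pileupParam = pp)
  if (nrow(pu) == 0L)
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          ref_allele = character(), alt_allele = character(),
                          depth = integer(), alt_fraction = numeric()))
  pu <- pu[pu$nucleotide %in% BASES, ]
  empty <- tibble::tibble(chrom = character(), pos = numeric(),
                          ref_allele = character(), alt_allele = character(),
                          depth = integer(), alt_fraction = numeric())
  if (nrow(pu) == 0L) return(empty)
  # vectorized per-position reduction: total depth, then the strongest
  # non-reference allele
  ref_chars <- strsplit(as.character(
    Biostrings::subseq(ref[[chrom]], start, end)), "")[[1]]
  pu$refbase <- ref_chars[pu$pos - start + 1]
  depth_tab <- rowsum(pu$count, pu$pos)
  depth_of <- stats::setNames(depth_tab[, 1], rownames(depth_tab))
  alt <- pu[as.character(pu$nucleotide) != pu$refbase, ]
  if (nrow(alt) == 0L) return(empty)
  alt <- alt[order(alt$pos, -alt$count), ]
  alt <- alt[!duplicated(alt$pos), ]
  dp <- unname(depth_of[as.character(alt$pos)])
  af <- alt$count / dp
  keep <- dp >= cfg$het_min_depth & af >= cfg$het_af_lo & af <= cfg$het_af_hi
  alt <- alt[keep, ]
  if (nrow(alt) == 0L) return(empty)
  tibble::tibble(chrom = chrom, pos = as.numeric(alt$pos),
                 ref_allele = alt$refbase,
                 alt_allele = as.character(alt$nucleotide),
                 depth = as.integer(dp[keep]), alt_fraction = af[keep])
}

#' Read-by-site allele matrix
#'
#' For every read overlapping the sites, extracts the read base at each site
#' from the alignment (CIGAR walk): the reference allele codes 0, the
#' alternate allele 1, anything else (third bases, deletions, no coverage) is
#' `NA`. Reads covering no site are dropped.
#'
#' @param bam SAM/BAM path.
#' @param sites Het-site tibble from [pileup_het_sites()] (one chromosome).
#' @param cfg A [bnd_config()].
#' @return List of class `bnd_allele_matrix`: `m` (reads x sites matrix of
#'   0/1/NA), `read_ids`, `sites`.
#' @export
allele_matrix <- function(bam, sites, cfg = bnd_config()) {
  cfg <- as_bnd_config(cfg)
  stopifnot(nrow(sites) >= 1L, length(unique(sites$chrom)) == 1L)
  sites <- sites[order(sites$pos), ]
  bamf <- prepare_bam(bam)
  gr <- GenomicRanges::GRanges(sites$chrom[1],
                               IRanges::IRanges(min(sites$pos),
                                                max(sites$pos)))
  sbp <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    what = c("qname", "pos", "cigar", "seq", "mapq"),
    which = gr, mapqFilter = cfg$min_mapq)
  res <- Rsamtools::scanBam(bamf, param = sbp)[[1]]
  nrec <- length(res$qname)
  if (nrec == 0L) stop("no alignments overlap the sites", call. = FALSE)
  ops_l <- GenomicAlignments::explodeCigarOps(res$cigar)
  lens_l <- GenomicAlignments::explodeCigarOpLengths(res$cigar)
  reads <- unique(res$qname)
  m <- matrix(NA_real_, nrow = length(reads), ncol = nrow(sites),
              dimnames = list(reads, NULL))
  spos <- sites$pos
  for (i in seq_len(nrec)) {
    ops <- ops_l[[i]]; lens <- lens_l[[i]]
    ref_consume <- ops %in% c("M", "D", "N", "=", "X")
    q_consume <- ops %in% c("M", "I", "S", "=", "X")
    ref_w <- ifelse(ref_consume, lens, 0L)
    q_w <- ifelse(q_consume, lens, 0L)
    ref_starts <- res$pos[i] + cumsum(c(0L, ref_w[-length(ref_w)]))
    q_starts <- 1L + cumsum(c(0L, q_w[-length(q_w)]))
    ref_end <- res$pos[i] + sum(ref_w) - 1L
    hit <- which(spos >= res$pos[i] & spos <= ref_end)
    if (length(hit) == 0L) next
    seqchars <- NULL
    for (k in hit) {
      p <- spos[k]
      j <- findInterval(p, ref_starts)
      # walk back over ops that do not consume reference
      while (j >= 1L && !ref_consume[j]) j <- j - 1L
      if (j < 1L) next
      if (!ops[j] %in% c("M", "=", "X")) next  # deletion at the site
      qpos <- q_starts[j] + (p - ref_starts[j])
      if (is.null(seqchars)) seqchars <- as.character(res$seq[i])
      base <- substr(seqchars, qpos, qpos)
      val <- if (base == sites$ref_allele[k]) 0 else
        if (base == sites$alt_allele[k]) 1 else NA_real_
      ri <- res$qname[i]
      if (is.na(m[ri, k])) m[ri, k] <- val
    }
  }
  keep <- rowSums(!is.na(m)) > 0L
  m <- m[keep, , drop = FALSE]
  structure(list(m = m, read_ids = rownames(m), sites = sites),
            class = "bnd_allele_matrix")
}

# MEC of a fixed bipartition: per site and per group, the minority-allele
# count is the minimal number of flips making that group consistent.
group_flips <- function(m, rows) {
  if (length(rows) == 0L) return(0)
  sub <- m[rows, , drop = FALSE]
  ones <- colSums(sub == 1, na.rm = TRUE)
  nn <- colSums(!is.na(sub))
  sum(pmin(ones, nn - ones))
}

#' Minimum-error-correction score of a read bipartition
#'
#' @param m An allele matrix (`bnd_allele_matrix` or plain 0/1/NA matrix).
#' @param partition Integer vector of 1/2 labels, one per read.
#' @return The MEC count (invariant under swapping the two labels).
#' @export
mec_score <- function(m, partition) {
  if (inherits(m, "bnd_allele_matrix")) m <- m$m
  stopifnot(length(partition) == nrow(m))
  group_flips(m, which(partition == 1L)) +
    group_flips(m, which(partition == 2L))
}

majority_alleles <- function(m, rows) {
  if (length(rows) == 0L) return(rep(NA_real_, ncol(m)))
  sub <- m[rows, , drop = FALSE]
  ones <- colSums(sub == 1, na.rm = TRUE)
  nn <- colSums(!is.na(sub))
  out <- ifelse(nn == 0, NA_real_, ifelse(ones > nn / 2, 1, 0))
  out
}

# connected components of sites linked by reads covering both: phasing is
# only defined within such a phase set, never across a coverage gap
site_phase_sets <- function(m) {
  s <- ncol(m)
  parent <- seq_len(s)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(nrow(m))) {
    def <- which(!is.na(m[i, ]))
    if (length(def) < 2L) next
    for (k in seq_along(def)[-1]) {
      a <- find(def[k - 1L]); b <- find(def[k])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(s), find, integer(1))
  match(roots, unique(roots))
}

phase_exact <- function(m) {
  n <- nrow(m)
  best <- NULL
  best_mec <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    part <- c(1L, as.integer(bitwAnd(bitwShiftR(mask, 0:(n - 2)), 1L)) + 1L)
    sc <- mec_score(m, part)
    if (sc < best_mec) {
      best_mec <- sc
      best <- part
    }
  }
  list(partition = best, mec = best_mec)
}

phase_greedy <- function(m, n_restarts = 10L, seed = 1L) {
  n <- nrow(m)
  s <- ncol(m)
  refine <- function(part) {
    for (it in 1:100) {
      cons1 <- majority_alleles(m, which(part == 1L))
      cons2 <- majority_alleles(m, which(part == 2L))
      changed <- FALSE
      for (i in seq_len(n)) {
        row <- m[i, ]
        d1 <- sum(row != cons1, na.rm = TRUE)
        d2 <- sum(row != cons2, na.rm = TRUE)
        new <- if (d1 < d2) 1L else if (d2 < d1) 2L else part[i]
        if (new != part[i]) {
          part[i] <- new
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    part
  }
  # positional sweep seed: assign reads left to right so every read is
  # compared against consensus built from overlapping reads
  sweep_seed <- function() {
    first_col <- apply(m, 1, function(r) which(!is.na(r))[1])
    ord <- order(first_col, -rowSums(!is.na(m)))
    part <- integer(n)
    ones <- matrix(0, nrow = 2, ncol = s)
    nn <- matrix(0, nrow = 2, ncol = s)
    for (i in ord) {
      row <- m[i, ]
      def <- which(!is.na(row))
      score <- function(g) {
        sel <- def[nn[g, def] > 0]
        if (length(sel) == 0L) return(c(0, 0))
        cons <- as.integer(ones[g, sel] > nn[g, sel] / 2)
        c(sum(row[sel] != cons), length(sel))
      }
      s1 <- score(1L); s2 <- score(2L)
      g <- if (s1[2] == 0 && s2[2] == 0) 1L
        else if (s2[2] == 0) { if (s1[1] > s1[2] / 2) 2L else 1L }
        else if (s1[2] == 0) { if (s2[1] > s2[2] / 2) 1L else 2L }
        else if (s1[1] / s1[2] <= s2[1] / s2[2]) 1L else 2L
      part[i] <- g
      nn[g, def] <- nn[g, def] + 1
      ones[g, def] <- ones[g, def] + row[def]
    }
    part
  }
  # single-read reassignment (refine) can stall one flip short of the
  # optimum; a pairwise move pass escapes those saddle points on small
  # instances
  pair_improve <- function(part, sc) {
    if (n > 40L) return(list(part = part, sc = sc))
    repeat {
      improved <- FALSE
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          cand <- part
          cand[c(i, j)] <- 3L - cand[c(i, j)]
          cand <- refine(cand)
          sc2 <- mec_score(m, cand)
          if (sc2 < sc) {
            part <- cand
            sc <- sc2
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    list(part = part, sc = sc)
  }
  best <- NULL
  best_mec <- Inf
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      part <- if (r == 1L) sweep_seed()
        else sample(c(1L, 2L), n, replace = TRUE)
      part <- refine(part)
      sc <- mec_score(m, part)
      if (sc < best_mec) {
        best_mec <- sc
        best <- part
      }
      if (best_mec == 0) break
    }
    pi <- pair_improve(best, best_mec)
    best <- pi$part
    best_mec <- pi$sc
  })
  list(partition = best, mec = best_mec)
}

#' Partition reads into two haplotypes by minimum error correction
#'
#' Finds a bipartition of the reads minimizing the MEC objective. Instances
#' of up to `exact_max` reads are solved exactly by enumeration; larger ones
#' use greedy consensus seeding plus iterative reassignment with random
#' restarts (deterministic given `cfg$rng_seed`).
#'
#' @param m A `bnd_allele_matrix` (or plain 0/1/NA matrix).
#' @param cfg A [bnd_config()].
#' @param method `"auto"` (default), `"exact"`, or `"heuristic"`.
#' @param exact_max Largest read count solved exactly under `"auto"`.
#'   Default 12.
#' @param n_restarts Restarts for the heuristic. Default 10.
#' @return List of class `bnd_phase`: `assignment` (named 1/2 vector),
#'   `h1_alleles`, `h2_alleles` (per-site majority alleles), `mec`,
#'   `phase_set` (per-site block id; haplotype labels are arbitrary across
#'   blocks), `sv_haplotype` (filled by [assign_sv_haplotype()]), `sites`.
#' @export
phase_reads <- function(m, cfg = bnd_config(),
                        method = c("auto", "exact", "heuristic"),
                        exact_max = 12L, n_restarts = 10L) {
  cfg <- as_bnd_config(cfg)
  method <- match.arg(method)
  sites <- NULL
  if (inherits(m, "bnd_allele_matrix")) {
    sites <- m$sites
    m <- m$m
  }
  if (nrow(m) < 2L || ncol(m) < 1L)
    stop("phasing needs at least 2 reads and 1 site", call. = FALSE)
  if (all(is.na(m))) stop("degenerate allele matrix: all missing",
                          call. = FALSE)
  res <- switch(method,
    exact = phase_exact(m),
    heuristic = phase_greedy(m, n_restarts, seed = cfg$rng_seed),
    auto = if (nrow(m) <= exact_max) phase_exact(m) else
      phase_greedy(m, n_restarts, seed = cfg$rng_seed))
  assignment <- stats::setNames(res$partition, rownames(m))
  structure(list(
    assignment = assignment,
    h1_alleles = majority_alleles(m, which(res$partition == 1L)),
    h2_alleles = majority_alleles(m, which(res$partition == 2L)),
    mec = res$mec,
    phase_set = site_phase_sets(m),
    sv_haplotype = "unassigned",
    sites = sites
  ), class = "bnd_phase")
}

#' Assign a rearrangement to a haplotype
#'
#' The junction belongs to a haplotype when at least 80% of the
#' junction-supporting reads present in the allele matrix fall in one
#' partition; with fewer than 2 informative junction reads the call stays
#' unassigned.
#'
#' @param partition A `bnd_phase` from [phase_reads()].
#' @param junction_read_ids Character vector of junction-supporting read ids.
#' @param purity Required fraction. Default 0.8.
#' @return The `bnd_phase` with `sv_haplotype` set to `"H1"`, `"H2"` or
#'   `"unassigned"`.
#' @export
assign_sv_haplotype <- function(partition, junction_read_ids, purity = 0.8) {
  present <- intersect(junction_read_ids, names(partition$assignment))
  partition$sv_haplotype <- "unassigned"
  if (length(present) >= 2L) {
    f1 <- mean(partition$assignment[present] == 1L)
    if (f1 >= purity) partition$sv_haplotype <- "H1"
    else if (1 - f1 >= purity) partition$sv_haplotype <- "H2"
  }
  partition
}

#' Phase reads around a breakpoint
#'
#' Convenience wrapper: detects heterozygous sites in a `phase_flank` window
#' on each side of the breakpoint, builds the allele matrix, partitions the
#' reads, and assigns the junction to a haplotype.
#'
#' @param bam SAM/BAM path.
#' @param ref Reference `DNAStringSet`.
#' @param chrom,pos Breakpoint locus.
#' @param junction_read_ids Reads supporting the junction.
#' @param cfg A [bnd_config()].
#' @return List with `sites`, `matrix`, `phase`.
#' @export
phase_region <- function(bam, ref, chrom, pos, junction_read_ids = character(),
                         cfg = bnd_config()) {
  cfg <- as_bnd_config(cfg)
  clen <- length(ref[[chrom]])
  start <- max(1, pos - cfg$phase_flank)
  end <- min(clen, pos + cfg$phase_flank)
  sites <- pileup_het_sites(bam, ref, chrom, start, end, cfg)
  if (nrow(sites) == 0L)
    return(list(sites = sites, matrix = NULL, phase = NULL))
  am <- allele_matrix(bam, sites, cfg)
  ph <- phase_reads(am, cfg)
  ph <- assign_sv_haplotype(ph, junction_read_ids)
  list(sites = sites, matrix = am, phase = ph)
}

#' Write phased sites as a minimal VCF
#'
#' Emits one record per het site with a phased `GT` (`0|1` when haplotype 1
#' carries the reference allele); the `PS` tag identifies the phase set
#' (connected block of sites linked by reads), named by the block's first
#' position.
#'
#' @param partition A `bnd_phase` carrying its `sites`.
#' @param path Output file.
#' @param sample Sample name.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(partition, path, sample = "SAMPLE") {
  sites <- partition$sites
  if (is.null(sites)) stop("partition carries no site table", call. = FALSE)
  ps_id <- partition$phase_set
  if (is.null(ps_id)) ps_id <- rep(1L, nrow(sites))
  ps <- vapply(ps_id, function(g) min(sites$pos[ps_id == g]), numeric(1))
  ps <- format(ps, scientific = FALSE, trim = TRUE)
  gt <- ifelse(is.na(partition$h1_alleles), "./.",
               paste0(partition$h1_alleles, "|",
                      ifelse(is.na(partition$h2_alleles),
                             1 - partition$h1_alleles,
                             partition$h2_alleles)))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=nanobnd",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  recs <- paste(sites$chrom, format(sites$pos, scientific = FALSE,
                                    trim = TRUE),
                ".", sites$ref_allele, sites$alt_allele, ".", "PASS", ".",
                "GT:PS", paste0(gt, ":", ps), sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}
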