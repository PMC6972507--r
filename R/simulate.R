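#' @importFrom Biostrings DNAStringSet
NULL

BASES <- c("A", "C", "G", "T")

# run code under a temporary RNG state so generators are bit-reproducible for
# a fixed seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Nanopore-like per-base error model
#'
#' Defaults (6% mismatch, 4% insertion, 5% deletion) give a BLAST-style read
#' identity of roughly 0.85, the regime of R9.4-era nanopore data.
#'
#' @param mismatch_rate,ins_rate,del_rate Per-base probabilities in `[0, 1)`.
#' @return A list of class `bnd_error_model`.
#' @export
error_model <- function(mismatch_rate = 0.06, ins_rate = 0.04,
                        del_rate = 0.05) {
  stopifnot(mismatch_rate >= 0, mismatch_rate < 1,
            ins_rate >= 0, ins_rate < 1, del_rate >= 0, del_rate < 1)
  structure(list(mismatch_rate = mismatch_rate, ins_rate = ins_rate,
                 del_rate = del_rate), class = "bnd_error_model")
}

#' Generate a random reference genome
#'
#' Uniform-random sequence, optionally stamped with tandem copies of a
#' 300-base "Alu-like" repeat unit (to exercise repeat-region calling) and
#' with N-runs (to exercise centromere/gap flagging).
#'
#' @param lengths Named integer vector of contig lengths (>= 10 kb each).
#' @param seed Integer seed; same seed gives byte-identical output.
#' @param repeat_spec Optional data frame with columns `chrom`, `start`:
#'   stamp positions for the repeat unit.
#' @param n_runs Optional data frame with columns `chrom`, `start`, `end`:
#'   intervals overwritten with `N`.
#' @param repeat_unit_length Length of the stamped unit. Default 300.
#' @return A `DNAStringSet`; the repeat unit (if any) is attached as
#'   attribute `repeat_unit`.
#' @export
make_reference <- function(lengths, seed = 1L, repeat_spec = NULL,
                           n_runs = NULL, repeat_unit_length = 300L) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("contig lengths must be named", call. = FALSE)
  if (any(lengths < 10000))
    stop("contigs must be at least 10 kb", call. = FALSE)
  with_seed(seed, {
    seqs <- DNAStringSet(vapply(lengths, random_dna, character(1)))
    names(seqs) <- names(lengths)
    unit <- NULL
    feats <- list()
    if (!is.null(repeat_spec)) {
      unit <- random_dna(repeat_unit_length)
      for (i in seq_len(nrow(repeat_spec))) {
        ch <- repeat_spec$chrom[i]
        s <- repeat_spec$start[i]
        e <- s + repeat_unit_length - 1
        feats[[length(feats) + 1L]] <- c(ch, s, e)
        Biostrings::subseq(seqs[[ch]], s, e) <- Biostrings::DNAString(unit)
      }
    }
    if (!is.null(n_runs)) {
      for (i in seq_len(nrow(n_runs))) {
        ch <- n_runs$chrom[i]
        s <- n_runs$start[i]
        e <- n_runs$end[i]
        feats[[length(feats) + 1L]] <- c(ch, s, e)
        Biostrings::subseq(seqs[[ch]], s, e) <-
          Biostrings::DNAString(strrep("N", e - s + 1))
      }
    }
    if (length(feats) > 1L) {
      fm <- do.call(rbind, feats)
      gr <- GenomicRanges::GRanges(fm[, 1], IRanges::IRanges(
        as.numeric(fm[, 2]), as.numeric(fm[, 3])))
      if (length(GenomicRanges::reduce(gr)) < length(gr) ||
          sum(GenomicRanges::width(GenomicRanges::reduce(gr))) <
            sum(GenomicRanges::width(gr)))
        stop("stamped features overlap", call. = FALSE)
    }
    attr(seqs, "repeat_unit") <- unit
    seqs
  })
}

# A "haplome" is one haplotype's genome: sequences plus a block map tying
# every derivative interval back to reference coordinates (aligned = FALSE
# for novel junction insertions), plus the junction truth table.
new_haplome <- function(seqs, blocks, junctions = NULL) {
  structure(list(seqs = seqs, blocks = blocks, junctions = junctions),
            class = "bnd_haplome")
}

identity_blocks <- function(seqs) {
  tibble::tibble(der_chrom = names(seqs), der_start = 1,
                 der_end = as.numeric(Biostrings::width(seqs)),
                 chrom = names(seqs), ref_start = 1,
                 ref_end = as.numeric(Biostrings::width(seqs)),
                 strand = "+", aligned = TRUE)
}

#' Wrap a genome as an unrearranged haplotype
#' @param seqs A `DNAStringSet`.
#' @return A `bnd_haplome`.
#' @export
as_haplome <- function(seqs) {
  if (inherits(seqs, "bnd_haplome")) return(seqs)
  new_haplome(seqs, identity_blocks(seqs))
}

#' Rearrangement event specification
#'
#' @param kind `"reciprocal_translocation"` or `"inversion"`.
#' @param chromA,posA First breakpoint (last retained base of the left part).
#' @param chromB,posB Second breakpoint; for inversions `chromB` must equal
#'   `chromA` and `posB > posA` is the distal breakpoint.
#' @param del_a,del_b Junction micro-deletions: bases of chromosome A
#'   (respectively B) lost at the junctions. Negative values duplicate bases
#'   instead (present in both derivatives).
#' @param ins_a,ins_b Random novel bases inserted at the junction of the
#'   first (respectively second) derivative.
#' @param carrier_haplotype Which haplotype (1 or 2) carries the event.
#' @return A list of class `bnd_event`.
#' @export
event_spec <- function(kind = c("reciprocal_translocation", "inversion"),
                       chromA, posA, chromB = chromA, posB,
                       del_a = 0L, del_b = 0L, ins_a = 0L, ins_b = 0L,
                       carrier_haplotype = 2L) {
  kind <- match.arg(kind)
  if (kind == "inversion" && (chromB != chromA || posB <= posA))
    stop("inversion needs chromB == chromA and posB > posA", call. = FALSE)
  if (ins_a < 0 || ins_b < 0) stop("insertions must be >= 0", call. = FALSE)
  structure(list(kind = kind, chromA = chromA, posA = posA, chromB = chromB,
                 posB = posB, del_a = as.integer(del_a),
                 del_b = as.integer(del_b), ins_a = as.integer(ins_a),
                 ins_b = as.integer(ins_b),
                 carrier_haplotype = as.integer(carrier_haplotype)),
            class = "bnd_event")
}

canonical_junction <- function(chrom1, pos1, side1, chrom2, pos2, side2,
                               svclass, ins_len) {
  if (chrom2 < chrom1 || (chrom2 == chrom1 && pos2 < pos1)) {
    tmp <- list(chrom1, pos1, side1)
    chrom1 <- chrom2; pos1 <- pos2; side1 <- side2
    chrom2 <- tmp[[1]]; pos2 <- tmp[[2]]; side2 <- tmp[[3]]
  }
  tibble::tibble(chrom1 = chrom1, pos1 = pos1, side1 = side1,
                 chrom2 = chrom2, pos2 = pos2, side2 = side2,
                 orientation = paste0(side_to_char(side1),
                                      side_to_char(side2)),
                 svclass = svclass, ins_len = ins_len)
}

#' Apply a rearrangement to a genome
#'
#' Builds the derivative chromosomes of a reciprocal translocation or an
#' inversion, together with a block map (derivative interval -> reference
#' interval and strand) and a junction truth table. Junction deletions remove
#' bases immediately distal to the breakpoint on the resuming fragment;
#' junction insertions add random novel sequence at the junction.
#'
#' @param genome A `DNAStringSet` or `bnd_haplome` whose affected chromosomes
#'   are unrearranged.
#' @param event An [event_spec()].
#' @param seed Seed for junction-insertion sequence.
#' @return A `bnd_haplome` whose `junctions` table records the planted
#'   breakends (canonical order), orientations, insertion lengths and the
#'   per-chromosome reciprocal gaps (`del_a`, `del_b`).
#' @export
apply_rearrangement <- function(genome, event, seed = 1L) {
  hap <- as_haplome(genome)
  seqs <- hap$seqs
  for (ch in unique(c(event$chromA, event$chromB))) {
    if (!ch %in% names(seqs)) stop("no such chromosome: ", ch, call. = FALSE)
    blk <- hap$blocks[hap$blocks$der_chrom == ch, ]
    if (nrow(blk) != 1L || blk$chrom != ch || blk$strand != "+")
      stop("chromosome ", ch, " is already rearranged", call. = FALSE)
  }
  in_n_run <- function(ch, pos) {
    as.character(Biostrings::subseq(seqs[[ch]], pos, pos)) == "N"
  }
  if (in_n_run(event$chromA, event$posA) ||
      in_n_run(event$chromB, event$posB))
    stop("breakpoint falls inside an N-run: junction undefined",
         call. = FALSE)
  ins_seq <- with_seed(seed, list(a = random_dna(event$ins_a),
                                  b = random_dna(event$ins_b)))
  lenA <- length(seqs[[event$chromA]])
  lenB <- length(seqs[[event$chromB]])
  sub <- function(ch, s, e) {
    if (s > e) Biostrings::DNAString("")
    else Biostrings::subseq(seqs[[ch]], s, e)
  }
  blocks <- hap$blocks
  if (event$kind == "reciprocal_translocation") {
    if (event$chromA == event$chromB)
      stop("reciprocal translocation needs two chromosomes", call. = FALSE)
    resumeB <- event$posB + 1 + event$del_b
    resumeA <- event$posA + 1 + event$del_a
    if (resumeB < 1 || resumeB > lenB + 1 || resumeA < 1 || resumeA > lenA + 1)
      stop("junction deletion/duplication overruns a contig", call. = FALSE)
    derA_name <- paste0(event$chromA, "_der")
    derB_name <- paste0(event$chromB, "_der")
    derA <- Biostrings::xscat(sub(event$chromA, 1, event$posA),
                              Biostrings::DNAString(ins_seq$a),
                              sub(event$chromB, resumeB, lenB))
    derB <- Biostrings::xscat(sub(event$chromB, 1, event$posB),
                              Biostrings::DNAString(ins_seq$b),
                              sub(event$chromA, resumeA, lenA))
    mk_blocks <- function(der_name, chromL, posL, ins_len, chromR, resumeR,
                          lenR) {
      b <- list()
      cur <- 0
      add <- function(w, chrom, rs, re, strand, aligned) {
        if (w <= 0) return()
        b[[length(b) + 1L]] <<- tibble::tibble(
          der_chrom = der_name, der_start = cur + 1, der_end = cur + w,
          chrom = chrom, ref_start = rs, ref_end = re, strand = strand,
          aligned = aligned)
        cur <<- cur + w
      }
      add(posL, chromL, 1, posL, "+", TRUE)
      add(ins_len, NA_character_, NA, NA, "+", FALSE)
      add(lenR - resumeR + 1, chromR, resumeR, lenR, "+", TRUE)
      do.call(rbind, b)
    }
    newA <- mk_blocks(derA_name, event$chromA, event$posA, event$ins_a,
                      event$chromB, resumeB, lenB)
    newB <- mk_blocks(derB_name, event$chromB, event$posB, event$ins_b,
                      event$chromA, resumeA, lenA)
    keep <- !(names(seqs) %in% c(event$chromA, event$chromB))
    out_seqs <- c(seqs[keep], DNAStringSet(list(derA, derB)))
    names(out_seqs) <- c(names(seqs)[keep], derA_name, derB_name)
    out_blocks <- rbind(blocks[blocks$der_chrom %in% names(seqs)[keep], ],
                        newA, newB)
    junc <- rbind(
      canonical_junction(event$chromA, event$posA, "end",
                         event$chromB, resumeB, "start",
                         "translocation", event$ins_a),
      canonical_junction(event$chromB, event$posB, "end",
                         event$chromA, resumeA, "start",
                         "translocation", event$ins_b))
  } else {
    if (event$posB > lenA) stop("posB outside contig", call. = FALSE)
    inv_start <- event$posA + 1 + event$del_a
    resume <- event$posB + 1 + event$del_b
    if (inv_start > event$posB || resume < 1 || resume > lenA + 1)
      stop("junction deletion overruns the inverted segment", call. = FALSE)
    der_name <- paste0(event$chromA, "_der")
    der <- Biostrings::xscat(
      sub(event$chromA, 1, event$posA),
      Biostrings::DNAString(ins_seq$a),
      Biostrings::reverseComplement(sub(event$chromA, inv_start, event$posB)),
      Biostrings::DNAString(ins_seq$b),
      sub(event$chromA, resume, lenA))
    b <- list()
    cur <- 0
    add <- function(w, rs, re, strand, aligned) {
      if (w <= 0) return()
      b[[length(b) + 1L]] <<- tibble::tibble(
        der_chrom = der_name, der_start = cur + 1, der_end = cur + w,
        chrom = if (aligned) event$chromA else NA_character_,
        ref_start = rs, ref_end = re, strand = strand, aligned = aligned)
      cur <<- cur + w
    }
    add(event$posA, 1, event$posA, "+", TRUE)
    add(event$ins_a, NA, NA, "+", FALSE)
    add(event$posB - inv_start + 1, inv_start, event$posB, "-", TRUE)
    add(event$ins_b, NA, NA, "+", FALSE)
    add(lenA - resume + 1, resume, lenA, "+", TRUE)
    keep <- names(seqs) != event$chromA
    out_seqs <- c(seqs[keep], DNAStringSet(list(der)))
    names(out_seqs) <- c(names(seqs)[keep], der_name)
    out_blocks <- rbind(blocks[blocks$der_chrom %in% names(seqs)[keep], ],
                        do.call(rbind, b))
    junc <- rbind(
      canonical_junction(event$chromA, event$posA, "end",
                         event$chromA, event$posB, "end",
                         "inversion", event$ins_a),
      canonical_junction(event$chromA, inv_start, "start",
                         event$chromA, resume, "start",
                         "inversion", event$ins_b))
  }
  junc$junction_id <- paste0("J", seq_len(nrow(junc)))
  junc$gapA <- event$del_a
  junc$gapB <- event$del_b
  new_haplome(out_seqs, out_blocks, junctions = junc)
}

#' Delete an interval from one chromosome of a haplotype
#'
#' Utility for planting copy-number losses: removes `start..end` (1-based
#' inclusive) and updates the block map.
#'
#' @param genome A `DNAStringSet` or `bnd_haplome` with the target chromosome
#'   unrearranged.
#' @param chrom,start,end Interval to remove.
#' @return A `bnd_haplome`.
#' @export
delete_interval <- function(genome, chrom, start, end) {
  hap <- as_haplome(genome)
  seqs <- hap$seqs
  len <- length(seqs[[chrom]])
  stopifnot(start >= 1, end <= len, start <= end)
  der <- Biostrings::xscat(Biostrings::subseq(seqs[[chrom]], 1, start - 1),
                           Biostrings::subseq(seqs[[chrom]], end + 1,
                                              len))
  seqs[[chrom]] <- der
  blocks <- hap$blocks[hap$blocks$der_chrom != chrom, ]
  nb <- tibble::tibble(
    der_chrom = chrom,
    der_start = c(1, start), der_end = c(start - 1, len - (end - start + 1)),
    chrom = chrom, ref_start = c(1, end + 1), ref_end = c(start - 1, len),
    strand = "+", aligned = TRUE)
  nb <- nb[nb$der_end >= nb$der_start, ]
  new_haplome(seqs, rbind(blocks, nb), junctions = hap$junctions)
}

#' Plant heterozygous SNPs
#'
#' Haplotype 1 is the reference; haplotype 2 carries substitutions at
#' Bernoulli(`rate`) positions, never inside N-runs.
#'
#' @param ref Reference `DNAStringSet`.
#' @param rate Per-base heterozygosity, in `(0, 0.01)`.
#' @param seed Integer seed.
#' @return List with `hap1`, `hap2` (both `bnd_haplome`) and `variants`
#'   (tibble of `chrom`, `pos`, `ref`, `alt`).
#' @export
plant_het_variants <- function(ref, rate, seed = 1L) {
  stopifnot(rate > 0, rate < 0.01)
  with_seed(seed, {
    hap2 <- ref
    vars <- list()
    for (ch in names(ref)) {
      len <- length(ref[[ch]])
      pos <- which(stats::runif(len) < rate)
      if (length(pos) == 0L) next
      chars <- strsplit(as.character(ref[[ch]]), "")[[1]]
      pos <- pos[chars[pos] %in% BASES]
      if (length(pos) == 0L) next
      alt <- unname(vapply(chars[pos], function(b)
        sample(setdiff(BASES, b), 1), character(1)))
      mut <- chars
      mut[pos] <- alt
      hap2[[ch]] <- Biostrings::DNAString(paste(mut, collapse = ""))
      vars[[ch]] <- tibble::tibble(chrom = ch, pos = pos, ref = chars[pos],
                                   alt = alt)
    }
    variants <- if (length(vars)) do.call(rbind, vars) else
      tibble::tibble(chrom = character(), pos = numeric(),
                     ref = character(), alt = character())
    rownames(variants) <- NULL
    list(hap1 = as_haplome(ref), hap2 = as_haplome(hap2),
         variants = variants)
  })
}

# --- read simulation ---------------------------------------------------------

# Realize sequencing errors over n true bases: returns condensed CIGAR ops in
# source orientation, tallies, query length, and (optionally) the read
# subsequence. Insertions are placed before emitted bases; deletions drop the
# base; mismatches substitute one of the three other bases. When neither the
# sequence nor a CIGAR is needed (`with_ops = FALSE`), only the error COUNTS
# are sampled — binomial draws with the same distribution as the per-base
# process, at a fraction of the cost.
gen_ops <- function(n, true_chars, em, with_seq, with_ops = TRUE) {
  if (n == 0L)
    return(list(ops = character(0), lens = integer(0), n_match = 0,
                n_mismatch = 0, n_ins = 0, n_del = 0, qlen = 0, seq = ""))
  if (em$mismatch_rate == 0 && em$ins_rate == 0 && em$del_rate == 0) {
    return(list(ops = "M", lens = n, n_match = n, n_mismatch = 0, n_ins = 0,
                n_del = 0, qlen = n,
                seq = if (with_seq) paste(true_chars, collapse = "") else ""))
  }
  if (!with_seq && !with_ops) {
    n_del <- stats::rbinom(1L, n, em$del_rate)
    n_ins <- stats::rbinom(1L, n, em$ins_rate)
    n_mis <- stats::rbinom(1L, n - n_del, em$mismatch_rate)
    return(list(ops = NULL, lens = NULL, n_match = n - n_del - n_mis,
                n_mismatch = n_mis, n_ins = n_ins, n_del = n_del,
                qlen = n - n_del + n_ins, seq = ""))
  }
  del <- stats::runif(n) < em$del_rate
  ins <- stats::runif(n) < em$ins_rate
  mis <- stats::runif(n) < em$mismatch_rate & !del
  main_op <- ifelse(del, "D", "M")
  n_ins_tot <- sum(ins)
  labels <- c(rep("I", n_ins_tot), main_op)
  keys <- c(which(ins) - 0.5, seq_len(n))
  ord <- order(keys)
  r <- rle(labels[ord])
  seq_out <- ""
  if (with_seq) {
    out <- true_chars
    if (any(mis)) {
      idx <- sample.int(3L, sum(mis), replace = TRUE)
      alt_tab <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                       G = c("A", "C", "T"), T = c("A", "C", "G"))
      cur <- out[mis]
      cur[!cur %in% BASES] <- "A"
      out[mis] <- alt_tab[cbind(match(cur, rownames(alt_tab)), idx)]
    }
    emit <- c(sample(BASES, n_ins_tot, replace = TRUE), ifelse(del, "", out))
    seq_out <- paste(emit[ord], collapse = "")
  }
  list(ops = r$values, lens = r$lengths, n_match = n - sum(del) - sum(mis),
       n_mismatch = sum(mis), n_ins = n_ins_tot, n_del = sum(del),
       qlen = n - sum(del) + n_ins_tot, seq = seq_out)
}

#' Simulate nanopore-like reads from a diploid genome
#'
#' Reads alternate between the two haplotypes until the target total depth
#' (relative to the haploid reference length) is reached. Start positions are
#' uniform over each haplotype; lengths are lognormal with the given mean,
#' truncated to 1-100 kb, so the length N50 exceeds the mean as in real
#' nanopore libraries. Errors follow the [error_model()]. Per-read provenance
#' (haplotype, source interval, error realization per reference block) is
#' retained so that [simulate_alignments()] can emit exactly consistent SAM.
#'
#' @param haplotypes List of one or two `bnd_haplome` objects (haplotypes of
#'   one individual).
#' @param depth Target total fold-coverage (both haplotypes combined).
#' @param mean_len Mean read length in bases. Default 13000.
#' @param sdlog Lognormal sd on the log scale. Default 0.55.
#' @param em An [error_model()]; use `error_model(0, 0, 0)` for noiseless.
#' @param seed Integer seed.
#' @param sequences Keep read sequences (needed for FASTQ, phasing and
#'   junction-sequence checks). `FALSE` gives a faster structural-only
#'   simulation whose SAM carries `SEQ` as `*`.
#' @param cigars Realize per-base error placement (needed to emit SAM
#'   records). Defaults to `sequences`; with both `FALSE` only error counts
#'   are sampled (same distribution, much faster) and the simulation can only
#'   feed the in-memory segment table.
#' @return A list of class `bnd_sim`: `reads` (truth tibble), `haplotypes`,
#'   `em`, plus internal per-read alignment detail.
#' @export
simulate_reads <- function(haplotypes, depth, mean_len = 13000, sdlog = 0.55,
                           em = error_model(), seed = 1L, sequences = TRUE,
                           cigars = sequences) {
  stopifnot(depth > 0)
  if (sequences && !cigars)
    stop("sequences = TRUE requires cigars = TRUE", call. = FALSE)
  if (inherits(haplotypes, "bnd_haplome")) haplotypes <- list(haplotypes)
  haplotypes <- lapply(haplotypes, as_haplome)
  n_hap <- length(haplotypes)
  stopifnot(n_hap %in% c(1L, 2L))
  hap_chroms <- lapply(haplotypes, function(h)
    stats::setNames(as.numeric(Biostrings::width(h$seqs)), names(h$seqs)))
  hap_chars <- if (sequences) {
    lapply(haplotypes, function(h)
      lapply(stats::setNames(names(h$seqs), names(h$seqs)), function(ch)
        strsplit(as.character(h$seqs[[ch]]), "")[[1]]))
  } else NULL
  hap_tot <- vapply(hap_chroms, sum, numeric(1))
  target <- depth * mean(hap_tot)
  meanlog <- log(mean_len) - sdlog^2 / 2
  # equally sized haplotypes alternate strictly (low-variance depth split);
  # unequal ones (e.g. a planted deletion) are sampled proportionally to
  # their genome size, as molecules would be
  equal_haps <- n_hap == 2L && hap_tot[1] == hap_tot[2]
  with_seed(seed, {
    reads <- list()
    detail <- list()
    total <- 0
    k <- 0L
    while (total < target) {
      k <- k + 1L
      h <- if (n_hap == 1L) 1L
        else if (equal_haps) ((k - 1L) %% 2L) + 1L
        else sample.int(2L, 1L, prob = hap_tot)
      hp <- haplotypes[[h]]
      clens <- hap_chroms[[h]]
      ch <- sample(names(clens), 1, prob = clens)
      L <- round(stats::rlnorm(1, meanlog, sdlog))
      L <- min(max(L, 1000), 100000)
      s <- sample.int(clens[[ch]], 1)
      e <- min(s + L - 1, clens[[ch]])
      t_strand <- if (stats::runif(1) < 0.5) "+" else "-"
      rid <- sprintf("read%06d", k)
      blocks <- hp$blocks[hp$blocks$der_chrom == ch, ]
      blocks <- blocks[blocks$der_end >= s & blocks$der_start <= e, ]
      blocks <- blocks[order(blocks$der_start), ]
      if (sum(blocks$aligned) > 4L)
        stop("read spans more than 3 junctions: unsupported", call. = FALSE)
      portions <- list()
      qcur <- 0
      chars <- if (sequences) hap_chars[[h]][[ch]] else NULL
      for (bi in seq_len(nrow(blocks))) {
        a <- max(s, blocks$der_start[bi])
        b <- min(e, blocks$der_end[bi])
        g <- gen_ops(b - a + 1, if (sequences) chars[a:b] else NULL,
                     em, sequences, with_ops = cigars)
        if (g$qlen == 0) next
        portions[[length(portions) + 1L]] <- list(
          der_a = a, der_b = b, q_start = qcur + 1, q_end = qcur + g$qlen,
          block = blocks[bi, ], ops = g$ops, lens = g$lens,
          n_match = g$n_match, n_mismatch = g$n_mismatch, n_ins = g$n_ins,
          n_del = g$n_del, seq = g$seq)
        qcur <- qcur + g$qlen
      }
      if (length(portions) == 0L) next
      total <- total + (e - s + 1)
      reads[[length(reads) + 1L]] <- list(
        read_id = rid, haplotype = h, der_chrom = ch, der_start = s,
        der_end = e, seq_strand = t_strand, read_length = qcur,
        n_aligned_segments = sum(vapply(portions, function(p)
          p$block$aligned, logical(1))))
      detail[[length(detail) + 1L]] <- list(read_id = rid,
                                            seq_strand = t_strand,
                                            read_length = qcur,
                                            portions = portions)
    }
    reads_df <- tibble::tibble(
      read_id = vapply(reads, `[[`, character(1), "read_id"),
      haplotype = vapply(reads, `[[`, integer(1), "haplotype"),
      der_chrom = vapply(reads, `[[`, character(1), "der_chrom"),
      der_start = vapply(reads, function(r) as.numeric(r$der_start),
                         numeric(1)),
      der_end = vapply(reads, function(r) as.numeric(r$der_end), numeric(1)),
      seq_strand = vapply(reads, `[[`, character(1), "seq_strand"),
      read_length = vapply(reads, function(r) as.numeric(r$read_length),
                           numeric(1)),
      n_aligned_segments = vapply(reads, function(r)
        as.numeric(r$n_aligned_segments), numeric(1)))
    structure(list(reads = reads_df, detail = detail,
                   haplotypes = haplotypes, em = em, seed = seed,
                   sequences = sequences, cigars = cigars,
                   mean_len = mean_len, depth = depth),
              class = "bnd_sim")
  })
}

#' Write simulated reads as FASTQ
#'
#' @param sim A `bnd_sim` from [simulate_reads()] with `sequences = TRUE`.
#' @param path Output FASTQ.
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(sim, path) {
  if (!sim$sequences)
    stop("simulation was run with sequences = FALSE", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (d in sim$detail) {
    seqs <- vapply(d$portions, `[[`, character(1), "seq")
    rd <- paste(seqs, collapse = "")
    if (d$seq_strand == "-")
      rd <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rd)))
    writeLines(c(paste0("@", d$read_id), rd, "+",
                 strrep("I", nchar(rd))), con)
  }
  invisible(path)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Emit emulated alignments for simulated reads
#'
#' Converts the per-read truth of a [simulate_reads()] run into alignments in
#' reference coordinates: one record per aligned reference block a read
#' overlaps, with the longest segment primary and the rest supplementary
#' (SA-linked), junction-side clipping as soft clips, and CIGAR/NM consistent
#' with the realized errors. This emulates a long-read aligner so that the
#' calling pipeline can be exercised without one.
#'
#' @param sim A `bnd_sim`.
#' @param ref Reference `DNAStringSet` (for header contig lengths).
#' @param sam_path If non-NULL, write a SAM file there.
#' @param mapq Mapping quality given to every record. Default 60.
#' @return A `bnd_segments` tibble of the same alignments, invisibly carrying
#'   contig lengths.
#' @export
simulate_alignments <- function(sim, ref, sam_path = NULL, mapq = 60L) {
  if (!is.null(sam_path) && isFALSE(sim$cigars))
    stop("SAM output needs per-base error placement; rerun simulate_reads ",
         "with cigars = TRUE", call. = FALSE)
  ctg <- stats::setNames(as.numeric(Biostrings::width(ref)), names(ref))
  seg_rows <- list()
  sam_lines <- if (!is.null(sam_path))
    c("@HD\tVN:1.6\tSO:unknown",
      paste0("@SQ\tSN:", names(ctg), "\tLN:",
             format(unname(ctg), scientific = FALSE, trim = TRUE)))
    else NULL
  for (d in sim$detail) {
    RL <- d$read_length
    t_minus <- d$seq_strand == "-"
    aligned <- Filter(function(p) isTRUE(p$block$aligned), d$portions)
    if (length(aligned) == 0L) next
    recs <- lapply(aligned, function(p) {
      blk <- p$block
      if (blk$strand == "+") {
        rs <- blk$ref_start + (p$der_a - blk$der_start)
        re <- rs + (p$der_b - p$der_a)
      } else {
        re <- blk$ref_end - (p$der_a - blk$der_start)
        rs <- blk$ref_end - (p$der_b - blk$der_start)
      }
      sam_minus <- xor(blk$strand == "-", t_minus)
      if (t_minus) {
        rds <- RL + 1 - p$q_end; rde <- RL + 1 - p$q_start
      } else {
        rds <- p$q_start; rde <- p$q_end
      }
      ops <- p$ops; lens <- p$lens
      if (blk$strand == "-") { ops <- rev(ops); lens <- rev(lens) }
      # position of the aligned sub-read within the stored (reference
      # orientation) sequence
      if (blk$strand == "+") { ss <- p$q_start; se <- p$q_end }
      else { ss <- RL + 1 - p$q_end; se <- RL + 1 - p$q_start }
      list(chrom = blk$chrom, ref_start = rs, ref_end = re,
           sam_strand = if (sam_minus) "-" else "+",
           read_start = rds, read_end = rde,
           ops = ops, lens = lens, lead = ss - 1, trail = RL - se,
           stored_fwd = blk$strand == "+",
           n_match = p$n_match, n_mismatch = p$n_mismatch,
           n_ins = p$n_ins, n_del = p$n_del,
           nm = p$n_mismatch + p$n_ins + p$n_del)
    })
    span <- vapply(recs, function(r) r$read_end - r$read_start, numeric(1))
    primary <- which.max(span)
    for (i in seq_along(recs)) {
      r <- recs[[i]]
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        read_id = d$read_id, chrom = r$chrom, ref_start = r$ref_start,
        ref_end = r$ref_end, strand = r$sam_strand, mapq = as.integer(mapq),
        read_start = r$read_start, read_end = r$read_end,
        read_length = RL, n_match = r$n_match, n_mismatch = r$n_mismatch,
        n_ins = r$n_ins, n_del = r$n_del, is_primary = i == primary,
        stringsAsFactors = FALSE)
    }
    if (!is.null(sam_path)) {
      cigar_of <- function(r) {
        core <- paste0(r$lens, r$ops, collapse = "")
        paste0(if (r$lead > 0) paste0(r$lead, "S") else "",
               core,
               if (r$trail > 0) paste0(r$trail, "S") else "")
      }
      sa_of <- function(i) {
        others <- setdiff(seq_along(recs), i)
        if (length(others) == 0L) return(NULL)
        paste0(vapply(others, function(j) {
          r <- recs[[j]]
          paste(r$chrom, format(r$ref_start, scientific = FALSE, trim = TRUE),
                r$sam_strand, cigar_of(r), mapq, r$nm, sep = ",")
        }, character(1)), collapse = ";")
      }
      read_der <- if (sim$sequences)
        paste(vapply(d$portions, `[[`, character(1), "seq"), collapse = "")
        else NULL
      for (i in seq_along(recs)) {
        r <- recs[[i]]
        flag <- 0L
        if (r$sam_strand == "-") flag <- flag + 16L
        if (i != primary) flag <- flag + 2048L
        seq_field <- "*"
        if (sim$sequences)
          seq_field <- if (r$stored_fwd) read_der else revcomp_chr(read_der)
        sa <- sa_of(i)
        tags <- c(paste0("NM:i:", r$nm),
                  if (!is.null(sa)) paste0("SA:Z:", sa, ";"))
        sam_lines[[length(sam_lines) + 1L]] <- paste(
          d$read_id, flag, r$chrom,
          format(r$ref_start, scientific = FALSE, trim = TRUE),
          mapq, cigar_of(r), "*", 0, 0, seq_field, "*",
          paste(tags, collapse = "\t"), sep = "\t")
      }
    }
  }
  if (!is.null(sam_path)) writeLines(unlist(sam_lines), sam_path)
  seg <- do.call(rbind, seg_rows)
  as_segments(seg, contigs = ctg)
}

#' One-call synthetic sample
#'
#' Convenience wrapper that plants heterozygous SNPs on haplotype 2, applies
#' the rearrangement events to their carrier haplotypes, simulates reads at
#' the requested depth, and emits emulated alignments (and optionally SAM /
#' FASTQ files).
#'
#' @param ref Reference `DNAStringSet`.
#' @param events List of [event_spec()] objects (may be empty).
#' @param depth Total fold-coverage.
#' @param het_rate Heterozygous SNP rate (0 disables SNP planting).
#' @param em An [error_model()].
#' @param mean_len Mean read length.
#' @param seed Integer seed driving every random choice.
#' @param sequences Keep read sequences.
#' @param cigars Realize per-base error placement (see [simulate_reads()]);
#'   required when `sam_path` is given.
#' @param sam_path,fastq_path Optional output files.
#' @return List with `segments` (alignment table), `sim` (read truth),
#'   `junctions` (planted junction table), `variants` (planted SNPs),
#'   `haplotypes`, and `sam_path`.
#' @export
simulate_sv_sample <- function(ref, events = list(), depth = 10,
                               het_rate = 0, em = error_model(),
                               mean_len = 13000, seed = 1L,
                               sequences = TRUE, cigars = sequences,
                               sam_path = NULL, fastq_path = NULL) {
  if (inherits(events, "bnd_event")) events <- list(events)
  if (het_rate > 0) {
    hv <- plant_het_variants(ref, het_rate, seed = seed + 1L)
    haps <- list(hv$hap1, hv$hap2)
    variants <- hv$variants
  } else {
    haps <- list(as_haplome(ref), as_haplome(ref))
    variants <- tibble::tibble(chrom = character(), pos = numeric(),
                               ref = character(), alt = character())
  }
  junctions <- list()
  for (i in seq_along(events)) {
    ev <- events[[i]]
    h <- ev$carrier_haplotype
    haps[[h]] <- apply_rearrangement(haps[[h]], ev, seed = seed + 10L + i)
    junctions[[i]] <- haps[[h]]$junctions
  }
  junctions <- if (length(junctions)) do.call(rbind, junctions) else NULL
  sim <- simulate_reads(haps, depth = depth, mean_len = mean_len, em = em,
                        seed = seed, sequences = sequences, cigars = cigars)
  if (!is.null(fastq_path)) write_sim_fastq(sim, fastq_path)
  segments <- simulate_alignments(sim, ref, sam_path = sam_path)
  list(segments = segments, sim = sim, junctions = junctions,
       variants = variants, haplotypes = haps, sam_path = sam_path)
}
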