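# Shared fixtures and independent oracles, built in code at test time.

# one row of a segment table with consistent tallies
seg_row <- function(read_id, chrom, ref_start, ref_end, strand = "+",
                    mapq = 60L, read_start, read_end,
                    read_length = read_end + 100,
                    n_mismatch = 0, n_ins = 0, n_del = 0,
                    is_primary = TRUE) {
  span <- ref_end - ref_start + 1
  tibble::tibble(read_id = read_id, chrom = chrom, ref_start = ref_start,
                 ref_end = ref_end, strand = strand, mapq = as.integer(mapq),
                 read_start = read_start, read_end = read_end,
                 read_length = read_length,
                 n_match = span - n_mismatch - n_del,
                 n_mismatch = n_mismatch, n_ins = n_ins, n_del = n_del,
                 is_primary = is_primary)
}

# brute-force N50: largest L among the lengths such that reads >= L hold at
# least half the total bases
n50_oracle <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  min(lengths)
}

# brute-force MEC: enumerate every bipartition
mec_oracle <- function(m) {
  n <- nrow(m)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    part <- as.integer(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L)) + 1L
    best <- min(best, mec_score(m, part))
  }
  best
}

# brute-force single-linkage clustering: repeated expansion over the
# both-breakends-within-tol relation inside a stratum
cluster_oracle <- function(ev, tol) {
  n <- nrow(ev)
  adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    ev$chrom1[i] == ev$chrom1[j] && ev$chrom2[i] == ev$chrom2[j] &&
      ev$orientation[i] == ev$orientation[j] &&
      abs(ev$pos1[i] - ev$pos1[j]) <= tol &&
      abs(ev$pos2[i] - ev$pos2[j]) <= tol
  }))
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  comp
}

# random planted-haplotype allele matrix for phasing tests
random_allele_matrix <- function(n_reads, n_sites, err = 0.05,
                                 miss = 0.15) {
  truth <- sample(c(0L, 1L), n_reads, replace = TRUE)
  h <- matrix(rep(sample(c(0, 1), n_sites, replace = TRUE), each = n_reads),
              nrow = n_reads)
  m <- ifelse(matrix(truth, n_reads, n_sites) == 1L, h, 1 - h)
  flip <- matrix(runif(n_reads * n_sites) < err, n_reads, n_sites)
  m[flip] <- 1 - m[flip]
  m[matrix(runif(n_reads * n_sites) < miss, n_reads, n_sites)] <- NA
  # every read needs one informative entry
  for (i in seq_len(n_reads)) if (all(is.na(m[i, ]))) m[i, 1] <- h[i, 1]
  rownames(m) <- paste0("r", seq_len(n_reads))
  m
}

# small cached references so repeated tests do not regenerate them
.fixture_env <- new.env()
fixture_ref2 <- function() {
  if (is.null(.fixture_env$ref2))
    .fixture_env$ref2 <- make_reference(c(chrA = 3e5, chrB = 3e5), seed = 101)
  .fixture_env$ref2
}

# a noiseless heterozygous translocation sample over the cached reference
fixture_trans <- function() {
  if (is.null(.fixture_env$trans)) {
    sam <- tempfile(fileext = ".sam")
    ev <- event_spec("reciprocal_translocation", "chrA", 150000,
                     "chrB", 200000, carrier_haplotype = 2L)
    .fixture_env$trans <- simulate_sv_sample(
      fixture_ref2(), list(ev), depth = 10, het_rate = 0.001,
      em = error_model(0, 0, 0), seed = 103, sequences = TRUE,
      sam_path = sam)
  }
  .fixture_env$trans
}
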