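test_that("MEC scoring counts minimal flips and is label-symmetric", {
  m <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  rownames(m) <- paste0("r", 1:4)
  expect_equal(mec_score(m, c(1, 1, 2, 2)), 0)
  expect_equal(mec_score(m, c(2, 2, 1, 1)), 0)
  m2 <- m; m2[1, 2] <- 1
  expect_equal(mec_score(m2, c(1, 1, 2, 2)), 1)
  # mixing the haplotypes costs the minority count at each site
  expect_equal(mec_score(m, c(1, 2, 1, 2)), 4)
  set.seed(3)
  for (i in 1:25) {
    mm <- random_allele_matrix(6, 4)
    part <- sample(c(1L, 2L), 6, replace = TRUE)
    expect_equal(mec_score(mm, part), mec_score(mm, 3L - part))
  }
})

test_that("phasing separates clean haplotypes and matches brute force", {
  m <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  rownames(m) <- paste0("r", 1:4)
  ph <- phase_reads(m)
  expect_equal(ph$mec, 0)
  expect_equal(unname(ph$assignment[1]), unname(ph$assignment[2]))
  expect_equal(unname(ph$assignment[3]), unname(ph$assignment[4]))
  expect_false(ph$assignment[1] == ph$assignment[3])
  expect_equal(sort(c(ph$h1_alleles[1], ph$h2_alleles[1])), c(0, 1))

  m2 <- m; m2[1, 2] <- 1
  ph2 <- phase_reads(m2)
  expect_equal(ph2$mec, mec_oracle(m2))
  expect_equal(ph2$mec, 1)

  expect_error(phase_reads(m[1, , drop = FALSE]), "at least 2")
  m_na <- matrix(NA_real_, 3, 2, dimnames = list(paste0("r", 1:3), NULL))
  expect_error(phase_reads(m_na), "missing")
})

test_that("heuristic MEC equals exhaustive search on random small matrices", {
  cfg <- bnd_config(rng_seed = 5)
  set.seed(99)
  for (i in 1:60) {
    m <- random_allele_matrix(sample(4:10, 1), sample(3:8, 1))
    exact <- phase_reads(m, cfg, method = "exact")
    heur <- phase_reads(m, cfg, method = "heuristic")
    expect_equal(heur$mec, exact$mec)
    expect_equal(exact$mec, mec_oracle(m))
  }
})

test_that("phasing is deterministic for a fixed seed", {
  set.seed(1)
  m <- random_allele_matrix(20, 12)
  cfg <- bnd_config(rng_seed = 42)
  a <- phase_reads(m, cfg, method = "heuristic")
  b <- phase_reads(m, cfg, method = "heuristic")
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$mec, b$mec)
})

test_that("SV haplotype assignment needs 2+ reads and 80% purity", {
  part <- structure(list(assignment = stats::setNames(
    c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
    paste0("r", 1:10)), mec = 0), class = "bnd_phase")
  expect_equal(assign_sv_haplotype(part, paste0("r", 1:5))$sv_haplotype, "H1")
  expect_equal(assign_sv_haplotype(part, paste0("r", 6:10))$sv_haplotype,
               "H2")
  # 3 vs 2 split: 60% < 80%
  expect_equal(assign_sv_haplotype(part, paste0("r", 4:8))$sv_haplotype,
               "unassigned")
  # fewer than 2 informative junction reads
  expect_equal(assign_sv_haplotype(part, "r1")$sv_haplotype, "unassigned")
  expect_equal(assign_sv_haplotype(part, c("r1", "zz"))$sv_haplotype,
               "unassigned")
})

test_that("het detection applies depth and allele-fraction gates", {
  res <- fixture_trans()
  ref <- fixture_ref2()
  cfg <- bnd_config()
  sites <- pileup_het_sites(res$sam_path, ref, "chrA", 50000, 250000, cfg)
  truth <- res$variants[res$variants$chrom == "chrA", ]
  # every reported site is a planted SNP with the right alleles
  idx <- match(sites$pos, truth$pos)
  expect_true(all(!is.na(idx)))
  expect_equal(sites$ref_allele, truth$ref[idx])
  expect_equal(sites$alt_allele, truth$alt[idx])
  # most planted SNPs in the window are recovered at 10x
  in_win <- truth$pos >= 50000 & truth$pos <= 250000
  expect_gt(nrow(sites) / sum(in_win), 0.8)
  expect_true(all(sites$depth >= cfg$het_min_depth))
  expect_true(all(sites$alt_fraction >= 0.2 & sites$alt_fraction <= 0.8))
  expect_error(pileup_het_sites(res$sam_path, ref, "chrA", 1, 1e7, cfg),
               "outside")
})

test_that("allele matrix rows reflect the reads' source haplotypes", {
  res <- fixture_trans()
  ref <- fixture_ref2()
  sites <- pileup_het_sites(res$sam_path, ref, "chrA", 50000, 250000)
  am <- allele_matrix(res$sam_path, sites)
  expect_true(all(rowSums(!is.na(am$m)) >= 1))
  hap <- stats::setNames(res$sim$reads$haplotype, res$sim$reads$read_id)
  row_frac_alt <- rowMeans(am$m == 1, na.rm = TRUE)
  # noiseless: haplotype-2 reads carry the alt allele everywhere
  expect_true(all(row_frac_alt[hap[rownames(am$m)] == 2] == 1))
  expect_true(all(row_frac_alt[hap[rownames(am$m)] == 1] == 0))
})

test_that("noisy allele-matrix rows still track their source haplotype", {
  # at known het sites, reads with ~15% per-base errors should agree with
  # their haplotype of origin at >= 90% of informative entries
  ref <- fixture_ref2()
  sam <- tempfile(fileext = ".sam")
  res <- simulate_sv_sample(ref, list(), depth = 10, het_rate = 0.001,
                            em = error_model(), seed = 202,
                            sequences = TRUE, sam_path = sam)
  truth <- res$variants[res$variants$chrom == "chrA" &
                          res$variants$pos >= 50000 &
                          res$variants$pos <= 250000, ]
  sites <- tibble::tibble(chrom = truth$chrom, pos = truth$pos,
                          ref_allele = truth$ref, alt_allele = truth$alt,
                          depth = 10L, alt_fraction = 0.5)
  am <- allele_matrix(sam, sites)
  hap <- stats::setNames(res$sim$reads$haplotype, res$sim$reads$read_id)
  expected <- ifelse(hap[rownames(am$m)] == 2L, 1, 0)
  agree <- vapply(seq_len(nrow(am$m)), function(i)
    mean(am$m[i, ] == expected[i], na.rm = TRUE), numeric(1))
  informative <- rowSums(!is.na(am$m)) >= 3
  # a 6% mismatch rate leaves ~98% of informative entries on the source
  # haplotype; rows with few sites can still dip below 90% individually
  expect_gte(mean(agree[informative]), 0.9)
  expect_gt(mean(agree[informative] >= 0.9), 0.85)
})

test_that("a noiseless diploid phases with zero switch errors and the
           rearrangement lands on its carrier haplotype", {
  res <- fixture_trans()
  ref <- fixture_ref2()
  calls <- call_breakpoints(split_read_evidence(res$segments))
  jreads <- unique(unlist(strsplit(calls$read_ids, ",")))
  out <- phase_region(res$sam_path, ref, "chrA", 150000,
                      junction_read_ids = jreads,
                      cfg = bnd_config(phase_flank = 100000))
  ph <- out$phase
  expect_equal(ph$mec, 0)
  # switch errors within phase sets: planted SNPs all sit on one source
  # haplotype, so inside every phased block one partition must carry the alt
  # allele at every site (labels are arbitrary across blocks)
  switches <- 0L
  for (g in unique(ph$phase_set)) {
    h1 <- ph$h1_alleles[ph$phase_set == g]
    h1 <- h1[!is.na(h1)]
    switches <- switches + sum(diff(h1) != 0)
  }
  expect_equal(switches, 0L)
  # the rearrangement is assigned to one haplotype, and in the block holding
  # the breakpoint that haplotype carries the alt alleles (it is the SNP
  # carrier, haplotype 2 of the simulation)
  expect_true(ph$sv_haplotype %in% c("H1", "H2"))
  bp_block <- ph$phase_set[which.min(abs(out$sites$pos - 150000))]
  sv_alleles <- if (ph$sv_haplotype == "H1") ph$h1_alleles else ph$h2_alleles
  in_block <- ph$phase_set == bp_block
  expect_true(all(sv_alleles[in_block] == 1, na.rm = TRUE))
  # junction reads really are haplotype-2 reads
  hap <- stats::setNames(res$sim$reads$haplotype, res$sim$reads$read_id)
  expect_true(all(hap[intersect(jreads, names(ph$assignment))] == 2))
  # deterministic given the same inputs and seed
  out2 <- phase_region(res$sam_path, ref, "chrA", 150000,
                       junction_read_ids = jreads,
                       cfg = bnd_config(phase_flank = 100000))
  expect_identical(out$phase$assignment, out2$phase$assignment)

  # phased sites write as a valid minimal VCF
  vcf <- tempfile(fileext = ".vcf")
  write_phased_vcf(ph, vcf)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(out$sites))
  expect_match(body[1], "GT:PS")
})
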