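test_that("locus strings parse to positions and confidence intervals", {
  l <- parse_locus("6:167281717")
  expect_equal(l$chrom, "6")
  expect_equal(l$pos, 167281717)
  expect_equal(c(l$ci_lo, l$ci_hi), c(0, 0))

  r <- parse_locus("22:20326956~20327048")
  expect_equal(r$pos, 20326956)
  expect_equal(r$ci_hi, 20327048 - 20326956)

  expect_error(parse_locus("chrX"), "malformed")
  expect_error(parse_locus("chr1:5~2"), "malformed")

  # format is the inverse of parse
  for (s in c("6:167281717", "22:20326956~20327048", "chrM:1")) {
    p <- parse_locus(s)
    expect_equal(format_locus(p$chrom, p$pos, p$ci_lo, p$ci_hi), s)
  }
})

test_that("N50 matches the brute-force oracle, including edge cases", {
  expect_equal(read_length_n50(5), 5)
  expect_equal(read_length_n50(c(10, 20, 30)), n50_oracle(c(10, 20, 30)))
  expect_equal(read_length_n50(c(10, 20, 30)), 30)
  expect_equal(read_length_n50(c(1, 1, 1, 1, 10)), 10)
  expect_error(read_length_n50(numeric(0)), "empty")

  set.seed(42)
  for (i in 1:1000) {
    lens <- sample.int(5000, sample(1:40, 1), replace = TRUE)
    expect_equal(read_length_n50(lens), n50_oracle(lens))
  }
})

test_that("segment identity is BLAST-style and scale invariant", {
  expect_equal(segment_identity(85, 5, 5, 5), 0.85)
  expect_equal(segment_identity(100, 0, 0, 0), 1.0)
  expect_equal(segment_identity(0, 10, 0, 0), 0.0)
  expect_error(segment_identity(0, 0, 0, 0), "undefined")
  set.seed(7)
  for (i in 1:50) {
    t <- sample.int(50, 4)
    k <- sample.int(9, 1)
    expect_equal(segment_identity(t[1], t[2], t[3], t[4]),
                 segment_identity(k * t[1], k * t[2], k * t[3], k * t[4]))
  }
})

test_that("1-based inclusive and 0-based half-open conversions invert", {
  set.seed(11)
  s1 <- sample.int(1e6, 200)
  e1 <- s1 + sample.int(1e4, 200) - 1
  ho <- nanobnd:::to_halfopen(s1, e1)
  back <- nanobnd:::to_onebased(ho$start, ho$end)
  expect_equal(back$start, s1)
  expect_equal(back$end, e1)
  expect_equal(ho$end - ho$start, e1 - s1 + 1)
})

test_that("qc_summary computes depth, coverage and identity", {
  # depth is aligned reference bases over non-N length
  seg <- rbind(
    seg_row("r1", "c1", 1, 100, read_start = 1, read_end = 100,
            read_length = 100),
    seg_row("r2", "c1", 301, 500, read_start = 1, read_end = 200,
            read_length = 200)
  )
  qc <- qc_summary(as_segments(seg), c(c1 = 1000))
  expect_equal(qc$depth, 300 / 1000)
  expect_equal(qc$coverage_rate, 300 / 1000)
  expect_equal(qc$n_reads, 2L)
  expect_equal(qc$n_mapped_bases, 300)
  expect_equal(qc$mean_identity, 1)

  # single read covering 1-100 of a 1000-base genome: coverage rate 10%
  one <- as_segments(seg_row("r1", "c1", 1, 100, read_start = 1,
                             read_end = 100, read_length = 100))
  expect_equal(qc_summary(one, c(c1 = 1000))$coverage_rate, 0.10)

  # zero mapped reads: zero report with a warning flag
  empty <- as_segments(seg[0, ])
  expect_warning(qc0 <- qc_summary(empty, c(c1 = 1000)), "zero")
  expect_true(qc0$no_reads)
  expect_equal(qc0$depth, 0)
})

test_that("flat 10x simulation covers nearly the whole genome", {
  ref <- make_reference(c(chr1 = 1e6), seed = 55)
  sim <- simulate_reads(as_haplome(ref), depth = 10,
                        em = error_model(0, 0, 0), seed = 56,
                        sequences = FALSE)
  seg <- simulate_alignments(sim, ref)
  qc <- qc_summary(seg, ref)
  expect_gte(qc$coverage_rate, 0.99)
  # depth x non-N length equals total aligned bases
  expect_equal(qc$depth * 1e6, sum(seg$ref_end - seg$ref_start + 1))
})

test_that("breakend VCF encodes orientation and round-trips", {
  calls <- rbind(
    tibble::tibble(call_id = "BND0001", chrom1 = "chrA", pos1 = 50000,
                   ci1_lo = 0, ci1_hi = 0, side1 = "end", chrom2 = "chrB",
                   pos2 = 60001, ci2_lo = 0, ci2_hi = 0, side2 = "start",
                   orientation = "+-", svclass = "translocation",
                   support = 9L, read_ids = "r1,r2", median_insertion = 0,
                   imprecise = FALSE, low_support = FALSE,
                   source = "nanobnd"),
    tibble::tibble(call_id = "BND0002", chrom1 = "chrA", pos1 = 70000,
                   ci1_lo = 0, ci1_hi = 92, side1 = "start", chrom2 = "chrB",
                   pos2 = 80000, ci2_lo = -10, ci2_hi = 5, side2 = "end",
                   orientation = "-+", svclass = "translocation",
                   support = 2L, read_ids = "r3", median_insertion = 12,
                   imprecise = TRUE, low_support = TRUE, source = "nanobnd"))
  path <- tempfile(fileext = ".vcf")
  write_breakend_vcf(calls, c(chrA = 1e6, chrB = 1e6), path)
  lines <- readLines(path)
  rec1 <- grep("^chrA\t50000\t", lines, value = TRUE)
  expect_match(rec1, "N\\[chrB:60001\\[", all = FALSE)
  rec2 <- grep("^chrA\t70000\t", lines, value = TRUE)
  expect_match(rec2, "CIPOS=0,92")
  expect_match(rec2, "IMPRECISE")

  back <- read_breakend_vcf(path)
  expect_equal(nrow(back), 2L)
  keep <- c("call_id", "chrom1", "pos1", "ci1_lo", "ci1_hi", "side1",
            "chrom2", "pos2", "ci2_lo", "ci2_hi", "side2", "orientation",
            "svclass", "support", "median_insertion", "imprecise",
            "low_support", "source")
  expect_equal(as.data.frame(back[keep]), as.data.frame(calls[keep]),
               ignore_attr = TRUE)
  expect_equal(attr(back, "contigs"), c(chrA = 1e6, chrB = 1e6))

  # all four orientations survive a round trip through the ALT encoding
  for (o in c("+-", "-+", "++", "--")) {
    s1 <- if (substr(o, 1, 1) == "+") "end" else "start"
    s2 <- if (substr(o, 2, 2) == "+") "end" else "start"
    cl <- calls[1, ]
    cl$side1 <- s1; cl$side2 <- s2; cl$orientation <- o
    write_breakend_vcf(cl, c(chrA = 1e6, chrB = 1e6), path)
    rt <- read_breakend_vcf(path)
    expect_equal(rt$orientation, o)
    expect_equal(rt$side1, s1)
    expect_equal(rt$side2, s2)
  }

  # an orphan breakend is an error naming the record
  lines <- readLines(path)
  writeLines(lines[-length(lines)], path)
  expect_error(read_breakend_vcf(path), "orphan")
})

test_that("BEDPE output uses widened half-open intervals and round-trips", {
  calls <- tibble::tibble(call_id = "BND0001", chrom1 = "chrA", pos1 = 50000,
                          ci1_lo = 0, ci1_hi = 0, side1 = "end",
                          chrom2 = "chrB", pos2 = 60001, ci2_lo = 0,
                          ci2_hi = 92, side2 = "start", orientation = "+-",
                          svclass = "translocation", support = 9L,
                          read_ids = "", median_insertion = 0,
                          imprecise = TRUE, low_support = FALSE,
                          source = "nanobnd")
  path <- tempfile(fileext = ".bedpe")
  write_bedpe(calls, path)
  f <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(as.numeric(f[2:3]), c(49999, 50000))
  expect_equal(as.numeric(f[5:6]), c(60000, 60001 + 92))
  expect_equal(f[9:10], c("+", "-"))
  back <- read_bedpe(path)
  expect_equal(back$pos1, calls$pos1)
  expect_equal(back$pos2, calls$pos2)
  expect_equal(back$orientation, calls$orientation)
  expect_equal(back$support, calls$support)
  expect_equal(back$ci2_hi, 92)
})

test_that("BED reader validates lines and reports the offender", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr18\t28685000\t28686000\tAluY",
               "chr18\t30000000\t30000300\tAluSx3"), path)
  bed <- read_bed(path)
  expect_equal(bed$name, c("AluY", "AluSx3"))
  expect_equal(bed$start[1], 28685000)
  writeLines(c("chr18\t100\t200\tok", "chr18\tnot_a_number\t300"), path)
  expect_error(read_bed(path), "line 2")
})

test_that("SAM parsing recovers truth segments exactly (round trip)", {
  res <- fixture_trans()
  parsed <- read_alignments(res$sam_path)
  a <- res$segments[order(res$segments$read_id, res$segments$read_start), ]
  b <- parsed[order(parsed$read_id, parsed$read_start), ]
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
  expect_equal(contigs(parsed), c(chrA = 3e5, chrB = 3e5))
  # exactly one primary record per read
  prim <- tapply(parsed$is_primary, parsed$read_id, sum)
  expect_true(all(prim == 1))
})
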