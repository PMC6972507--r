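mk_ev <- function(read_id, pos1, pos2, chrom1 = "chrA", chrom2 = "chrB",
                  orientation = "+-", svclass = "translocation",
                  read_gap = 0) {
  tibble::tibble(read_id = read_id, chrom1 = chrom1, pos1 = pos1,
                 side1 = if (substr(orientation, 1, 1) == "+") "end"
                   else "start",
                 chrom2 = chrom2, pos2 = pos2,
                 side2 = if (substr(orientation, 2, 2) == "+") "end"
                   else "start",
                 orientation = orientation, svclass = svclass,
                 read_gap = read_gap, min_mapq = 60, min_identity = 1)
}

mk_call <- function(call_id, chrom1, pos1, side1, chrom2, pos2, side2,
                    support = 5L, imprecise = FALSE, read_ids = NULL,
                    median_insertion = 0) {
  side_chr <- function(s) if (s == "end") "+" else "-"
  if (is.null(read_ids))
    read_ids <- paste0(call_id, "_r", seq_len(support), collapse = ",")
  else support <- length(strsplit(read_ids, ",")[[1]])
  tibble::tibble(call_id = call_id, chrom1 = chrom1, pos1 = pos1,
                 ci1_lo = 0, ci1_hi = 0, side1 = side1, chrom2 = chrom2,
                 pos2 = pos2, ci2_lo = 0, ci2_hi = 0, side2 = side2,
                 orientation = paste0(side_chr(side1), side_chr(side2)),
                 svclass = if (chrom1 == chrom2) "inversion"
                   else "translocation",
                 support = as.integer(support), read_ids = read_ids,
                 median_insertion = median_insertion, imprecise = imprecise,
                 low_support = FALSE, source = "nanobnd")
}

test_that("evidence clusters by single linkage within strata", {
  cfg <- bnd_config()
  ev <- rbind(mk_ev("r1", 50000, 70000), mk_ev("r2", 50004, 70003),
              mk_ev("r3", 49998, 69995))
  cl <- cluster_evidence(ev, cfg)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]), 3L)

  # two evidences 5 kb apart stay separate at tol 1000
  ev2 <- rbind(mk_ev("r1", 50000, 70000), mk_ev("r2", 55000, 70000))
  expect_length(cluster_evidence(ev2, cfg), 2L)

  # identical positions, opposite orientations: never merged
  ev3 <- rbind(mk_ev("r1", 50000, 70000, orientation = "+-"),
               mk_ev("r2", 50000, 70000, orientation = "-+"))
  expect_length(cluster_evidence(ev3, cfg), 2L)

  # chain linkage: a-b and b-c within tol, a-c beyond -> one cluster
  ev4 <- rbind(mk_ev("r1", 50000, 70000), mk_ev("r2", 50900, 70000),
               mk_ev("r3", 51800, 70000))
  expect_length(cluster_evidence(ev4, cfg), 1L)
})

test_that("clustering agrees with the brute-force oracle on random evidence", {
  cfg <- bnd_config()
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    ev <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_ev(paste0("r", i),
            pos1 = 50000 + sample.int(8000, 1),
            pos2 = 70000 + sample.int(8000, 1))))
    got <- cluster_evidence(ev, cfg)
    oracle <- cluster_oracle(ev, cfg$cluster_tol)
    expect_equal(length(got), length(unique(oracle)))
    expect_setequal(
      vapply(got, function(g) paste(sort(g$read_id), collapse = ","),
             character(1)),
      vapply(split(ev$read_id, oracle), function(x)
        paste(sort(x), collapse = ","), character(1)))
  }
})

test_that("consensus takes the lower-middle median with min/max CI", {
  cfg <- bnd_config()
  ev <- rbind(mk_ev("r1", 1000, 70000), mk_ev("r2", 1004, 70000),
              mk_ev("r3", 998, 70000))
  call <- consensus_breakpoint(ev, cfg)
  expect_equal(call$pos1, 1000)
  expect_equal(c(call$ci1_lo, call$ci1_hi), c(-2, 4))
  expect_equal(call$support, 3L)
  expect_false(call$imprecise)

  # even count: lower-middle member
  ev_even <- rbind(mk_ev("r1", 1000, 70000), mk_ev("r2", 1006, 70000))
  expect_equal(consensus_breakpoint(ev_even, cfg)$pos1, 1000)

  # a single member is emitted but flagged
  single <- consensus_breakpoint(ev[1, ], cfg)
  expect_equal(single$pos1, 1000)
  expect_true(single$low_support)
  expect_true(single$imprecise)

  # one read counted once even with two evidences
  dup <- rbind(mk_ev("r1", 1000, 70000), mk_ev("r1", 1002, 70002))
  expect_equal(consensus_breakpoint(dup, cfg)$support, 1L)
})

test_that("reciprocal pairing recovers the printed 79-base micro-deletion", {
  # derivative 1 retains chr22 through 20656021; derivative 2 resumes chr22
  # at 20656101: 79 bases (chr22:20656022-20656100) are in neither
  calls <- rbind(
    mk_call("BND0001", "chr22", 20656021, "end", "chr8", 125495366, "start"),
    mk_call("BND0002", "chr22", 20656101, "start", "chr8", 125495365, "end"))
  ev <- pair_reciprocal(calls)
  expect_true(ev$paired)
  expect_equal(ev$gapA, 79)
  # the deleted interval is stop+1 .. resume-1, inclusive length 79
  expect_equal(ev$stopA + 1, 20656022)
  expect_equal(ev$resumeA - 1, 20656100)
  expect_equal((ev$resumeA - 1) - (ev$stopA + 1) + 1, 79)
  expect_equal(ev$gapB, 0)
  expect_equal(ev$support_total, 10)

  # a perfectly balanced event has zero gaps on both chromosomes
  bal <- rbind(
    mk_call("BND0001", "chrA", 50000, "end", "chrB", 60001, "start"),
    mk_call("BND0002", "chrA", 50001, "start", "chrB", 60000, "end"))
  evb <- pair_reciprocal(bal)
  expect_equal(c(evb$gapA, evb$gapB), c(0, 0))

  # junction duplication shows as a negative gap
  dup <- rbind(
    mk_call("BND0001", "chrA", 50000, "end", "chrB", 60001, "start"),
    mk_call("BND0002", "chrA", 49851, "start", "chrB", 60000, "end"))
  expect_equal(pair_reciprocal(dup)$gapA, -150)

  # far-apart junctions are not paired
  far <- rbind(
    mk_call("BND0001", "chrA", 50000, "end", "chrB", 60001, "start"),
    mk_call("BND0002", "chrA", 2050001, "start", "chrB", 60000, "end"))
  evf <- pair_reciprocal(far)
  expect_equal(sum(evf$paired), 0)
  expect_equal(nrow(evf), 2L)
})

test_that("planted junction deletions and duplications are recovered", {
  ref <- fixture_ref2()
  for (d in c(0, 79, -150)) {
    evs <- event_spec("reciprocal_translocation", "chrA", 150000, "chrB",
                      200000, del_a = d)
    res <- simulate_sv_sample(ref, list(evs), depth = 10,
                              em = error_model(0, 0, 0), seed = 80 + d,
                              sequences = FALSE)
    calls <- call_breakpoints(split_read_evidence(res$segments))
    evt <- pair_reciprocal(calls)
    expect_equal(evt$gapA[evt$paired], d)
    expect_equal(evt$gapB[evt$paired], 0)
  }
})

test_that("call-set merging is tolerant, commutative and idempotent", {
  cfg <- bnd_config()
  a <- mk_call("BND0001", "chrA", 50000, "end", "chrB", 60001, "start",
               read_ids = "r1,r2,r3")
  b <- mk_call("X1", "chrA", 50020, "end", "chrB", 60010, "start",
               read_ids = "r3,r4")
  m <- merge_callsets(a, b, cfg = cfg)
  expect_equal(nrow(m), 1L)
  expect_equal(m$support, 4L)  # union of reads
  expect_equal(m$source, "merged")
  # support-weighted median: set1 (weight 3) wins the lower-middle
  expect_equal(m$pos1, 50000)

  # disjoint calls are both kept with source tags
  c2 <- mk_call("Y1", "chrA", 90000, "end", "chrB", 99000, "start")
  m2 <- merge_callsets(a, c2, cfg = cfg, labels = c("s1", "s2"))
  expect_equal(nrow(m2), 2L)
  expect_setequal(m2$source, c("s1", "s2"))

  # merging a set with itself changes nothing material
  m3 <- merge_callsets(a, a, cfg = cfg)
  expect_equal(m3$pos1, a$pos1)
  expect_equal(m3$pos2, a$pos2)
  expect_equal(m3$support, a$support)
  expect_setequal(strsplit(m3$read_ids, ",")[[1]],
                  strsplit(a$read_ids, ",")[[1]])

  # commutative at the level of locus/orientation/read union
  m_ab <- merge_callsets(a, b, cfg = cfg)
  m_ba <- merge_callsets(b, a, cfg = cfg)
  expect_equal(m_ab[c("chrom1", "chrom2", "orientation", "support")],
               m_ba[c("chrom1", "chrom2", "orientation", "support")])
  expect_equal(sort(strsplit(m_ab$read_ids, ",")[[1]]),
               sort(strsplit(m_ba$read_ids, ",")[[1]]))

  # different orientations never match
  d <- mk_call("Z1", "chrA", 50000, "start", "chrB", 60001, "end")
  expect_equal(nrow(merge_callsets(a, d, cfg = cfg)), 2L)
})

test_that("breakends are annotated by half-open BED containment", {
  calls <- rbind(
    mk_call("BND0001", "chr18", 28685658, "end", "chr21", 29073597, "start"),
    mk_call("BND0002", "chr18", 28686001, "end", "chr21", 1000, "start"))
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr18\t28685000\t28686000\tAluY",
               "chr18\t28685500\t28687000\tL1PA4"), bed)
  ann <- annotate_calls(calls, bed)
  # overlapping features are reported in file order
  expect_equal(ann$label1[1], "AluY,L1PA4")
  expect_equal(ann$label2[1], "")
  # a breakend whose 0-based coordinate equals a feature end is outside it
  expect_equal(ann$label1[2], "L1PA4")
})

test_that("breakends near long reference N-runs are flagged imprecise", {
  ref <- make_reference(c(chrC = 5e4), seed = 61,
                        n_runs = data.frame(chrom = "chrC", start = 20000,
                                            end = 20299))
  near <- mk_call("BND0001", "chrC", 21000, "end", "chrC", 40000, "end")
  far <- mk_call("BND0002", "chrC", 30000, "end", "chrC", 45000, "end")
  out <- flag_near_gaps(rbind(near, far), ref)
  expect_equal(out$imprecise, c(TRUE, FALSE))
  # short N-runs do not trigger the flag
  ref2 <- make_reference(c(chrC = 5e4), seed = 61,
                         n_runs = data.frame(chrom = "chrC", start = 20000,
                                             end = 20049))
  expect_equal(flag_near_gaps(rbind(near, far), ref2)$imprecise,
               c(FALSE, FALSE))
})

test_that("junction sequences reconstruct the derivative across junctions", {
  ref <- fixture_ref2()
  evs <- event_spec("reciprocal_translocation", "chrA", 150000, "chrB",
                    200000)
  res <- simulate_sv_sample(ref, list(evs), depth = 10,
                            em = error_model(0, 0, 0), seed = 90,
                            sequences = FALSE)
  # support is not under test here: accept single-read junctions as precise
  cfg1 <- bnd_config(min_support = 1)
  calls <- call_breakpoints(split_read_evidence(res$segments, cfg1), cfg1)
  js <- junction_sequence(ref, calls, flank = 400)
  expect_equal(unique(Biostrings::width(js)), 800L)
  ders <- res$haplotypes[[2]]$seqs
  for (i in seq_along(js)) {
    hits <- sum(vapply(names(ders), function(ch)
      Biostrings::countPattern(js[[i]], ders[[ch]]), integer(1)))
    expect_equal(hits, 1L)
  }

  # inversion: the distal flank appears reverse-complemented
  evi <- event_spec("inversion", "chrA", 100000, posB = 250000)
  resi <- simulate_sv_sample(ref, list(evi), depth = 10,
                             em = error_model(0, 0, 0), seed = 91,
                             sequences = FALSE)
  calls_i <- call_breakpoints(split_read_evidence(resi$segments, cfg1), cfg1)
  js_i <- junction_sequence(ref, calls_i, flank = 400)
  der <- resi$haplotypes[[2]]$seqs[["chrA_der"]]
  for (i in seq_along(js_i))
    expect_equal(Biostrings::countPattern(js_i[[i]], der), 1L)
  pp <- calls_i[calls_i$orientation == "++", ]
  distal <- Biostrings::subseq(js_i[[which(calls_i$orientation == "++")]],
                               401, 800)
  expect_equal(as.character(distal),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(ref[["chrA"]], pp$pos2 - 399, pp$pos2))))

  # imprecise calls are refused; flank overruns truncate with a warning
  impr <- mk_call("BND0009", "chrA", 150000, "end", "chrB", 200001, "start",
                  imprecise = TRUE)
  expect_error(junction_sequence(ref, impr, flank = 100), "imprecise")
  edge <- mk_call("BND0010", "chrA", 100, "end", "chrB", 200001, "start")
  expect_warning(js_e <- junction_sequence(ref, edge, flank = 400),
                 "truncated")
  expect_equal(Biostrings::width(js_e), 100 + 400)
})
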