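# VCF 4.2 breakend records are written and parsed directly: the bracketed
# ALT encoding of mate locus and orientation is the whole payload here, and
# it maps one-to-one onto the calls-table side/orientation model.

bnd_alt <- function(side, mate_chrom, mate_pos, mate_side, ref_base = "N") {
  mate <- paste0(mate_chrom, ":",
                 format(mate_pos, scientific = FALSE, trim = TRUE))
  if (side == "end") {
    if (mate_side == "start") paste0(ref_base, "[", mate, "[")
    else paste0(ref_base, "]", mate, "]")
  } else {
    if (mate_side == "end") paste0("]", mate, "]", ref_base)
    else paste0("[", mate, "[", ref_base)
  }
}

parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec(
    "^([ACGTN]*)([\\[\\]])([^:\\[\\]]+):([0-9]+)([\\[\\]])([ACGTN]*)$", alt,
    perl = TRUE))[[1]]
  if (length(m) == 0L || m[3] != m[6])
    stop("unparseable breakend ALT: ", alt, call. = FALSE)
  side <- if (nzchar(m[2])) "end" else "start"
  mate_side <- if (m[3] == "[") "start" else "end"
  list(side = side, mate_chrom = m[4], mate_pos = as.numeric(m[5]),
       mate_side = mate_side)
}

#' Write breakend calls as a VCF 4.2 file
#'
#' Emits two mated BND records per junction with `MATEID` cross-references,
#' bracketed ALT alleles encoding orientation, and `SVTYPE`, `SR` (supporting
#' split reads), `CIPOS`, `INSLEN` (junction insertion), `SVCLASS` and
#' `SOURCE` INFO keys; imprecise calls carry the `IMPRECISE` flag.
#'
#' @param calls Calls tibble.
#' @param contigs Named vector of contig lengths for the header.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_breakend_vcf <- function(calls, contigs, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=nanobnd",
    paste0("##contig=<ID=", names(contigs), ",length=",
           format(unname(contigs), scientific = FALSE, trim = TRUE), ">"),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Supporting split reads\">",
    "##INFO=<ID=RNAMES,Number=.,Type=String,Description=\"Supporting read names\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
    "##INFO=<ID=INSLEN,Number=1,Type=Integer,Description=\"Median inserted bases at the junction\">",
    "##INFO=<ID=SVCLASS,Number=1,Type=String,Description=\"translocation, inversion or intra_other\">",
    "##INFO=<ID=SOURCE,Number=1,Type=String,Description=\"Call set of origin\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakend\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  recs <- character(0)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (!cl$chrom1 %in% names(contigs) || !cl$chrom2 %in% names(contigs))
      stop("call ", cl$call_id, " references a contig without a known length",
           call. = FALSE)
    ids <- paste0(cl$call_id, c("_1", "_2"))
    info <- function(k, mate, ci_lo, ci_hi) {
      x <- c(paste0("SVTYPE=BND"),
             paste0("MATEID=", mate),
             paste0("SR=", cl$support),
             if (nzchar(cl$read_ids)) paste0("RNAMES=", cl$read_ids),
             paste0("CIPOS=", ci_lo, ",", ci_hi),
             paste0("INSLEN=", cl$median_insertion),
             paste0("SVCLASS=", cl$svclass),
             paste0("SOURCE=", cl$source))
      if (cl$imprecise) x <- c(x, "IMPRECISE")
      paste(x, collapse = ";")
    }
    filt <- if (cl$low_support) "LOW_SUPPORT" else "PASS"
    recs <- c(recs,
      paste(cl$chrom1, format(cl$pos1, scientific = FALSE, trim = TRUE),
            ids[1], "N",
            bnd_alt(cl$side1, cl$chrom2, cl$pos2, cl$side2), ".",
            filt, info(1, ids[2], cl$ci1_lo, cl$ci1_hi), sep = "\t"),
      paste(cl$chrom2, format(cl$pos2, scientific = FALSE, trim = TRUE),
            ids[2], "N",
            bnd_alt(cl$side2, cl$chrom1, cl$pos1, cl$side1), ".",
            filt, info(2, ids[1], cl$ci2_lo, cl$ci2_hi), sep = "\t"))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a breakend VCF written by [write_breakend_vcf()]
#'
#' @param path VCF file with mated BND records.
#' @return Calls tibble; contig lengths from the header are attached as the
#'   `contigs` attribute.
#' @export
read_breakend_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "##")]
  body <- lines[!startsWith(lines, "#")]
  ctg_lines <- hdr[startsWith(hdr, "##contig=")]
  ctg <- NULL
  if (length(ctg_lines) > 0L) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", ctg_lines)
    lens <- as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg_lines))
    ctg <- stats::setNames(lens, ids)
  }
  if (length(body) == 0L) {
    out <- empty_calls()
    attr(out, "contigs") <- ctg
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  get_info <- function(info, key, default = NA_character_) {
    parts <- strsplit(info, ";", fixed = TRUE)[[1]]
    hit <- parts[startsWith(parts, paste0(key, "="))]
    if (length(hit) == 0L) return(default)
    sub(paste0("^", key, "="), "", hit[1])
  }
  rec <- tibble::tibble(
    chrom = vapply(f, `[[`, character(1), 1),
    pos = as.numeric(vapply(f, `[[`, character(1), 2)),
    id = vapply(f, `[[`, character(1), 3),
    alt = vapply(f, `[[`, character(1), 5),
    filter = vapply(f, `[[`, character(1), 7),
    info = vapply(f, `[[`, character(1), 8)
  )
  rec$mateid <- vapply(rec$info, get_info, character(1), "MATEID")
  first <- rec[!duplicated(pmin(rec$id, rec$mateid)), ]
  rows <- lapply(seq_len(nrow(first)), function(i) {
    r <- first[i, ]
    mate <- rec[rec$id == r$mateid, ]
    if (nrow(mate) != 1L)
      stop("orphan breakend record: ", r$id, call. = FALSE)
    a <- parse_bnd_alt(r$alt)
    ci1 <- as.numeric(strsplit(get_info(r$info, "CIPOS", "0,0"), ",")[[1]])
    ci2 <- as.numeric(strsplit(get_info(mate$info, "CIPOS", "0,0"), ",")[[1]])
    ev <- tibble::tibble(
      call_id = sub("_[12]$", "", r$id),
      chrom1 = r$chrom, pos1 = r$pos, ci1_lo = ci1[1], ci1_hi = ci1[2],
      side1 = a$side,
      chrom2 = mate$chrom, pos2 = mate$pos, ci2_lo = ci2[1], ci2_hi = ci2[2],
      side2 = a$mate_side,
      orientation = paste0(side_to_char(a$side), side_to_char(a$mate_side)),
      svclass = get_info(r$info, "SVCLASS"),
      support = as.integer(get_info(r$info, "SR", "1")),
      read_ids = get_info(r$info, "RNAMES", ""),
      median_insertion = as.numeric(get_info(r$info, "INSLEN", "0")),
      imprecise = grepl("(^|;)IMPRECISE($|;)", r$info),
      low_support = r$filter == "LOW_SUPPORT",
      source = get_info(r$info, "SOURCE", "unknown")
    )
    # restore canonical breakend order (writer emits breakend 1 first, so
    # this is a no-op on round trips, but foreign files may differ)
    if (ev$chrom2 < ev$chrom1 ||
        (ev$chrom2 == ev$chrom1 && ev$pos2 < ev$pos1)) {
      ev[, c("chrom1", "pos1", "ci1_lo", "ci1_hi", "side1",
             "chrom2", "pos2", "ci2_lo", "ci2_hi", "side2")] <-
        ev[, c("chrom2", "pos2", "ci2_lo", "ci2_hi", "side2",
               "chrom1", "pos1", "ci1_lo", "ci1_hi", "side1")]
      ev$orientation <- paste0(side_to_char(ev$side1),
                               side_to_char(ev$side2))
    }
    ev
  })
  out <- do.call(rbind, rows)
  attr(out, "contigs") <- ctg
  out
}

#' Write calls as BEDPE
#'
#' One line per junction; intervals are 0-based half-open, widened by the
#' confidence interval; strand columns carry the breakend orientation
#' characters.
#'
#' @param calls Calls tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(calls, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- vapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    paste(cl$chrom1, fmt(cl$pos1 + cl$ci1_lo - 1), fmt(cl$pos1 + cl$ci1_hi),
          cl$chrom2, fmt(cl$pos2 + cl$ci2_lo - 1), fmt(cl$pos2 + cl$ci2_hi),
          cl$call_id, cl$support,
          substr(cl$orientation, 1, 1), substr(cl$orientation, 2, 2),
          cl$svclass, fmt(cl$pos1), fmt(cl$pos2), fmt(cl$median_insertion),
          tolower(cl$imprecise), cl$source, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BEDPE written by [write_bedpe()]
#'
#' @param path BEDPE file.
#' @return Calls tibble (read ids are not stored in BEDPE and come back
#'   empty).
#' @export
read_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_calls())
  f <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(f, function(x) {
    if (length(x) < 16L)
      stop("BEDPE line has ", length(x), " fields; expected 16", call. = FALSE)
    pos1 <- as.numeric(x[12]); pos2 <- as.numeric(x[13])
    side1 <- if (x[9] == "+") "end" else "start"
    side2 <- if (x[10] == "+") "end" else "start"
    tibble::tibble(
      call_id = x[7],
      chrom1 = x[1], pos1 = pos1,
      ci1_lo = as.numeric(x[2]) + 1 - pos1, ci1_hi = as.numeric(x[3]) - pos1,
      side1 = side1,
      chrom2 = x[4], pos2 = pos2,
      ci2_lo = as.numeric(x[5]) + 1 - pos2, ci2_hi = as.numeric(x[6]) - pos2,
      side2 = side2,
      orientation = paste0(x[9], x[10]),
      svclass = x[11],
      support = as.integer(x[8]),
      read_ids = "",
      median_insertion = as.numeric(x[14]),
      imprecise = x[15] == "true",
      low_support = FALSE,
      source = x[16]
    )
  })
  do.call(rbind, rows)
}

#' Read a (repeat-annotation) BED file
#'
#' Minimal validated reader for 3+ column BED; the fourth column, when
#' present, is the feature name.
#'
#' @param path BED file.
#' @return Tibble with `chrom`, `start` (0-based), `end` (exclusive), `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  rows <- lapply(which(keep), function(i) {
    x <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(x) < 3L || is.na(suppressWarnings(as.numeric(x[2]))) ||
        is.na(suppressWarnings(as.numeric(x[3]))))
      stop("malformed BED line ", i, " in ", path, call. = FALSE)
    tibble::tibble(chrom = x[1], start = as.numeric(x[2]),
                   end = as.numeric(x[3]),
                   name = if (length(x) >= 4L) x[4] else ".")
  })
  if (length(rows) == 0L)
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), name = character()))
  do.call(rbind, rows)
}
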