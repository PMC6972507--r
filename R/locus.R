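#' Parse a breakpoint locus string
#'
#' Breakpoint positions are written either as a single base
#' (`"6:167281717"`) or as a range when the junction could not be pinned to
#' one base (`"22:20326956~20327048"`). The ranged form is represented as the
#' lower bound plus a right-sided confidence interval covering the span.
#'
#' @param text Character vector of locus strings, `"CHROM:POS"` or
#'   `"CHROM:POS~POS"`. Commas inside numbers are tolerated.
#' @return A tibble with columns `chrom`, `pos` (1-based), `ci_lo`, `ci_hi`
#'   (signed offsets around `pos`; `0,0` when precise).
#' @examples
#' parse_locus("6:167281717")
#' parse_locus("22:20326956~20327048")
#' @export
parse_locus <- function(text) {
  stopifnot(is.character(text), length(text) >= 1L)
  one <- function(s) {
    s0 <- gsub(",", "", trimws(s), fixed = TRUE)
    m <- regmatches(s0, regexec("^([^:[:space:]]+):([0-9]+)(~([0-9]+))?$", s0))[[1]]
    if (length(m) == 0L)
      stop("malformed locus '", s, "': expected CHROM:POS or CHROM:POS~POS",
           call. = FALSE)
    pos <- as.numeric(m[3])
    hi <- if (nzchar(m[5])) as.numeric(m[5]) else pos
    if (pos < 1 || hi < pos)
      stop("malformed locus '", s, "': positions must satisfy 1 <= POS <= POS2",
           call. = FALSE)
    list(chrom = m[2], pos = pos, ci_lo = 0, ci_hi = hi - pos)
  }
  parts <- lapply(text, one)
  tibble::tibble(
    chrom = vapply(parts, `[[`, character(1), "chrom"),
    pos = vapply(parts, `[[`, numeric(1), "pos"),
    ci_lo = vapply(parts, `[[`, numeric(1), "ci_lo"),
    ci_hi = vapply(parts, `[[`, numeric(1), "ci_hi")
  )
}

#' Format loci as breakpoint strings
#'
#' Inverse of [parse_locus()]: precise loci print as `CHROM:POS`, imprecise
#' ones as `CHROM:POS~POS`.
#'
#' @param chrom,pos,ci_lo,ci_hi Vectors as in the tibble from [parse_locus()].
#' @return Character vector.
#' @export
format_locus <- function(chrom, pos, ci_lo = 0, ci_hi = 0) {
  lo <- pos + ci_lo
  hi <- pos + ci_hi
  ifelse(ci_lo == 0 & ci_hi == 0,
         paste0(chrom, ":", format(pos, scientific = FALSE, trim = TRUE)),
         paste0(chrom, ":", format(lo, scientific = FALSE, trim = TRUE),
                "~", format(hi, scientific = FALSE, trim = TRUE)))
}

# 1-based inclusive <-> 0-based half-open interval conversion. All user-facing
# coordinates are 1-based inclusive; BED/BEDPE output is 0-based half-open.
to_halfopen <- function(start1, end1) {
  list(start = start1 - 1, end = end1)
}

to_onebased <- function(start0, end0) {
  list(start = start0 + 1, end = end0)
}
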