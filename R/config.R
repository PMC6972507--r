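#' Pipeline configuration
#'
#' Bundles every tunable threshold of the toolkit in a single validated
#' object, so that all stages share one source of defaults.
#'
#' @param min_mapq Minimum mapping quality for a segment to contribute
#'   split-read evidence. Default 20.
#' @param min_segment_len Minimum aligned length (bases) of each segment of a
#'   split read. Default 200.
#' @param cluster_tol Maximum distance (bases) between breakends for two
#'   pieces of evidence to be single-linkage clustered. Default 1000; nanopore
#'   junction jitter routinely exceeds 100 bp, while genuinely distinct
#'   junctions in a karyotype-scale event are megabases apart.
#' @param min_support Number of distinct spanning reads below which a call is
#'   flagged (not dropped) as low-support. Default 3.
#' @param min_sv_len Minimum span (bases) for intra-chromosomal events;
#'   shorter same-strand pairs are treated as alignment artifacts. Default 50.
#' @param merge_tol Maximum breakend distance (bases) when matching calls
#'   across two call sets. Default 200.
#' @param cnv_window Window size (bases) for read-depth CNV estimation.
#'   Default 10000.
#' @param cnv_log2_thresh Absolute log2-ratio above which a window is
#'   considered non-neutral. Default 0.4.
#' @param cnv_min_windows Minimum run length (windows) for a CNV segment.
#'   Default 3.
#' @param phase_flank Flank (bases) on each side of a breakpoint used for
#'   haplotype phasing. Default 2e6.
#' @param het_min_depth Minimum pileup depth to call a heterozygous site.
#'   Default 5.
#' @param het_af_lo,het_af_hi Allele-fraction window for heterozygous sites.
#'   Defaults 0.2 and 0.8.
#' @param rng_seed Integer seed used by stages with randomized tie-breaking.
#'
#' @return An object of class `bnd_config` (a named list).
#' @examples
#' cfg <- bnd_config(min_support = 5)
#' cfg$min_support
#' @export
bnd_config <- function(min_mapq = 20L,
                       min_segment_len = 200L,
                       cluster_tol = 1000L,
                       min_support = 3L,
                       min_sv_len = 50L,
                       merge_tol = 200L,
                       cnv_window = 10000L,
                       cnv_log2_thresh = 0.4,
                       cnv_min_windows = 3L,
                       phase_flank = 2000000L,
                       het_min_depth = 5L,
                       het_af_lo = 0.2,
                       het_af_hi = 0.8,
                       rng_seed = 1L) {
  cfg <- list(
    min_mapq = as.integer(min_mapq),
    min_segment_len = as.integer(min_segment_len),
    cluster_tol = as.integer(cluster_tol),
    min_support = as.integer(min_support),
    min_sv_len = as.integer(min_sv_len),
    merge_tol = as.integer(merge_tol),
    cnv_window = as.integer(cnv_window),
    cnv_log2_thresh = as.numeric(cnv_log2_thresh),
    cnv_min_windows = as.integer(cnv_min_windows),
    phase_flank = as.integer(phase_flank),
    het_min_depth = as.integer(het_min_depth),
    het_af_lo = as.numeric(het_af_lo),
    het_af_hi = as.numeric(het_af_hi),
    rng_seed = as.integer(rng_seed)
  )
  sizes <- c("min_segment_len", "cluster_tol", "min_support", "min_sv_len",
             "merge_tol", "cnv_window", "cnv_min_windows", "phase_flank",
             "het_min_depth")
  for (s in sizes) {
    if (is.na(cfg[[s]]) || cfg[[s]] <= 0L)
      stop("config: '", s, "' must be a positive integer", call. = FALSE)
  }
  if (is.na(cfg$min_mapq) || cfg$min_mapq < 0L)
    stop("config: 'min_mapq' must be >= 0", call. = FALSE)
  if (!(cfg$het_af_lo >= 0 && cfg$het_af_lo < cfg$het_af_hi &&
        cfg$het_af_hi <= 1))
    stop("config: allele-fraction bounds need 0 <= af_lo < af_hi <= 1",
         call. = FALSE)
  if (cfg$cnv_log2_thresh <= 0)
    stop("config: 'cnv_log2_thresh' must be positive", call. = FALSE)
  structure(cfg, class = "bnd_config")
}

#' @export
print.bnd_config <- function(x, ...) {
  cat("nanobnd configuration\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_bnd_config <- function(cfg) {
  if (is.null(cfg)) return(bnd_config())
  if (inherits(cfg, "bnd_config")) return(cfg)
  if (is.list(cfg)) return(do.call(bnd_config, cfg))
  stop("expected a bnd_config object", call. = FALSE)
}
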