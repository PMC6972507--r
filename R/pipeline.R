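#' Run the breakpoint-analysis pipeline
#'
#' Executes QC, split-read extraction, clustering/consensus calling,
#' reciprocal pairing and, optionally, merging with a second call set and
#' repeat-BED annotation, writing VCF/BEDPE/TSV outputs when an output prefix
#' is given.
#'
#' @param bam SAM/BAM of long-read alignments.
#' @param ref Reference FASTA path or `DNAStringSet`.
#' @param cfg A [bnd_config()].
#' @param merge_with Optional second call set: a VCF written by
#'   [write_breakend_vcf()] or a calls tibble.
#' @param annotation Optional repeat BED path or tibble.
#' @param out_prefix Optional output prefix; writes `<prefix>.vcf`,
#'   `<prefix>.bedpe`, `<prefix>.calls.tsv`, `<prefix>.qc.tsv` and
#'   `<prefix>.manifest.json`.
#' @param sample Sample label.
#' @return List with `qc`, `evidence`, `calls`, `events`, `manifest`.
#' @export
run_pipeline <- function(bam, ref, cfg = bnd_config(), merge_with = NULL,
                         annotation = NULL, out_prefix = NULL,
                         sample = "sample") {
  cfg <- as_bnd_config(cfg)
  t0 <- Sys.time()
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  names(ref) <- sub("\\s.*$", "", names(ref))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  segments <- stage("read_alignments", read_alignments(bam, cfg))
  qc <- stage("qc", suppressWarnings(qc_summary(segments, ref)))
  evidence <- stage("splitread", split_read_evidence(segments, cfg))
  calls <- stage("caller", call_breakpoints(evidence, cfg))
  calls <- stage("gap_flagging", flag_near_gaps(calls, ref))
  if (!is.null(merge_with)) {
    other <- if (is.character(merge_with)) read_breakend_vcf(merge_with)
      else merge_with
    calls <- stage("merge", merge_callsets(calls, other, cfg = cfg,
                                           labels = c("nanobnd", "external")))
  }
  if (!is.null(annotation))
    calls <- stage("annotate", annotate_calls(calls, annotation))
  events <- stage("pairing", pair_reciprocal(calls))
  manifest <- list(
    tool = "nanobnd",
    version = as.character(utils::packageVersion("nanobnd")),
    sample = sample,
    config = unclass(cfg),
    inputs = list(bam = if (is.character(bam)) normalizePath(bam) else "?",
                  n_contigs = length(ref)),
    counts = list(n_reads = qc$n_reads, n_evidence = nrow(evidence),
                  n_calls = nrow(calls), n_events = nrow(events)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(out_prefix)) {
    ctg <- stats::setNames(Biostrings::width(ref), names(ref))
    write_breakend_vcf(calls, ctg, paste0(out_prefix, ".vcf"))
    write_bedpe(calls, paste0(out_prefix, ".bedpe"))
    utils::write.table(calls, paste0(out_prefix, ".calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(qc_table(qc, sample), paste0(out_prefix, ".qc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, paste0(out_prefix, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(qc = qc, evidence = evidence, calls = calls, events = events,
       manifest = manifest)
}
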