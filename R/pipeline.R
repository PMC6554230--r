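#' Run the full quantitation and refinement pipeline
#'
#' Wires the stages end to end: (optional) spectrum-level quantitation,
#' the exclusion cascade, the cross-replicate catalog, and the protein
#' rollup. Input is either per-replicate PSM tables that already carry
#' ratios, or per-replicate spectra plus identification tables to be
#' quantified first. Returns a run report with per-stage counts
#' (identified, discarded per reason, retained, proteins) per replicate.
#'
#' @param psm_tables list of `psm_table` data.frames, one per replicate
#'   (used as-is when `spectra` is NULL).
#' @param design a `design_table`.
#' @param spectra optional list (per replicate) of `spectrum` lists; when
#'   given, `identifications` must supply the matching PSM identities
#'   and quantitation is (re)computed from the spectra.
#' @param identifications optional list (per replicate) of data.frames
#'   with `scan_id`, `sequence`, `accessions`, `annotation`, `score`.
#' @param panel a [reporter_panel()].
#' @param method `"RSPI"` or `"RPA"` (spectrum-level extraction
#'   strategy; ignored when quantifying from `psm_tables`).
#' @param score_threshold identification score cut-off (default 30
#'   mascot / 95 paragon).
#' @param scale score scale, `"mascot"` or `"paragon"`.
#' @param min_frequency minimum frequency index for the rollup.
#' @param weights rollup weighting, `"signal"` or `"uniform"`.
#' @return object of class `cirq_run`: `filter` (the `filter_report`),
#'   `catalog`, `proteins`, `report` (per-replicate count table),
#'   `settings`.
#' @export
run_pipeline <- function(psm_tables = NULL, design, spectra = NULL,
                         identifications = NULL, panel = reporter_panel(),
                         method = c("RSPI", "RPA"),
                         score_threshold = NULL,
                         scale = c("mascot", "paragon"),
                         min_frequency = 5, weights = "signal") {
  method <- match.arg(method)
  scale <- match.arg(scale)

  if (!is.null(spectra)) {
    if (is.null(identifications)) {
      stop("'identifications' are required when quantifying from spectra")
    }
    reps <- sort(unique(design$replicate_id))
    if (length(spectra) != length(reps)) {
      stop("need one spectra list per design replicate")
    }
    psm_tables <- lapply(seq_along(reps), function(k) {
      r <- reps[k]
      quantify_spectra(spectra[[k]], identifications[[k]], panel,
                       method = method,
                       reference = design_reference(design, r)$channel,
                       replicate_id = r)
    })
  }
  if (is.null(psm_tables)) stop("either 'psm_tables' or 'spectra' is required")
  psm <- do.call(rbind, psm_tables)

  filt <- circ_filter(psm, score_threshold = score_threshold, scale = scale)
  catalog <- build_catalog(filt, design)
  proteins <- rollup_proteins(catalog, min_frequency = min_frequency,
                              weights = weights)

  report <- filt$per_replicate
  names(report)[names(report) == "input"] <- "identified"
  prot_by_rep <- vapply(report$replicate_id, function(r) {
    length(unique(catalog$entries$accession[
      catalog$entries$replicate_id == r]))
  }, integer(1))
  report$proteins_cataloged <- prot_by_rep

  structure(
    list(filter = filt, catalog = catalog, proteins = proteins,
         report = report,
         settings = list(method = method,
                         score_threshold = filt$score_threshold,
                         scale = scale, min_frequency = min_frequency,
                         weights = weights)),
    class = "cirq_run"
  )
}

#' @export
print.cirq_run <- function(x, ...) {
  s <- x$settings
  cat("Pipeline run (", s$method, ", ", s$scale, " score > ",
      s$score_threshold, ", frequency >= ", s$min_frequency, ")\n", sep = "")
  print(x$report, row.names = FALSE)
  cat("Retained PSMs: ", nrow(x$filter$retained), " of ", x$filter$n_input,
      "; reported proteins: ", length(unique(x$proteins$accession)),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.cirq_run <- function(object, ...) {
  cat("Per-replicate identified peptides: ")
  print(summarize_sets(object$report$identified))
  cat("Per-replicate discarded peptides:  ")
  print(summarize_sets(object$report$discarded))
  invisible(object)
}
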