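#' MS/MS spectrum container
#'
#' Minimal spectrum representation used throughout the package: a scan
#' identifier, optional precursor information, and a peak list. Peaks are
#' stored as a two-column matrix (`mz`, `intensity`) sorted by ascending
#' m/z; intensities must be non-negative and the list may be empty.
#'
#' `mode` declares how the peak list is to be interpreted: `"centroid"`
#' (one stick per ion population) or `"profile"` (a sampled intensity
#' trace). Area-based quantitation is only meaningful in profile mode.
#'
#' @param scan_id character scan identifier (MGF TITLE).
#' @param peaks numeric matrix or data.frame with columns mz and
#'   intensity; re-sorted by m/z if needed.
#' @param precursor_mz precursor m/z in Da, or NA.
#' @param precursor_charge integer precursor charge (>= 1), or NA.
#' @param mode `"centroid"` or `"profile"`.
#' @return object of class `spectrum`.
#' @examples
#' s <- spectrum("scan=1", cbind(c(114.11, 115.11), c(1000, 500)))
#' nrow(s$peaks)
#' @export
spectrum <- function(scan_id, peaks = NULL, precursor_mz = NA_real_,
                     precursor_charge = NA_integer_,
                     mode = c("centroid", "profile")) {
  mode <- match.arg(mode)
  if (is.null(peaks) || NROW(peaks) == 0L) {
    peaks <- matrix(numeric(0), ncol = 2L)
  } else {
    peaks <- as.matrix(peaks)
    if (ncol(peaks) != 2L) stop("'peaks' must have two columns (mz, intensity)")
    storage.mode(peaks) <- "double"
    if (any(!is.finite(peaks))) stop("non-finite peak values")
    if (any(peaks[, 2L] < 0)) stop("negative peak intensity")
    if (is.unsorted(peaks[, 1L], strictly = FALSE)) {
      peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
    }
  }
  colnames(peaks) <- c("mz", "intensity")
  if (!is.na(precursor_charge) && precursor_charge < 1L) {
    stop("precursor charge must be >= 1")
  }
  structure(
    list(scan_id = as.character(scan_id),
         precursor_mz = as.numeric(precursor_mz),
         precursor_charge = as.integer(precursor_charge),
         peaks = peaks, mode = mode),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat("MS/MS spectrum '", x$scan_id, "' (", x$mode, ", ",
      nrow(x$peaks), " peaks)\n", sep = "")
  if (!is.na(x$precursor_mz)) {
    cat("  precursor m/z ", format(x$precursor_mz),
        if (!is.na(x$precursor_charge)) paste0(" (", x$precursor_charge, "+)"),
        "\n", sep = "")
  }
  invisible(x)
}
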