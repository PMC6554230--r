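#' Extract reporter signals as sums of peak intensities (RSPI)
#'
#' For each channel, the raw signal is the summed intensity of every peak
#' whose m/z lies within `tolerance` of the channel's theoretical m/z
#' (window inclusive at both edges). Peak height is proportional to the
#' detector ion count, so this strategy reads the reporter ion count
#' directly; it applies equally to centroid and profile data. An empty
#' window yields 0.
#'
#' @param spec a [spectrum()].
#' @param panel a [reporter_panel()].
#' @return object of class `channel_signal`: raw per-channel counts, no
#'   correction applied yet.
#' @export
extract_rspi <- function(spec, panel) {
  raw <- vapply(panel$channels, function(ch) {
    lo <- panel$mz[[ch]] - panel$tolerance
    hi <- panel$mz[[ch]] + panel$tolerance
    mz <- spec$peaks[, 1L]
    sum(spec$peaks[mz >= lo & mz <= hi, 2L])
  }, numeric(1))
  channel_signal(raw, method = "RSPI")
}

#' Extract reporter signals as trapezoidal peak areas (RPA)
#'
#' For each channel, the raw signal is the trapezoidal integral of the
#' profile intensity trace over the window `[mz - tol, mz + tol]`, with
#' linear interpolation of the trace at the window edges. Units are
#' counts * Da. This is only meaningful for profile spectra: a centroid
#' spectrum is accepted with a warning, but each zero-width stick
#' contributes zero area, so all signals degenerate to 0. Windows with
#' fewer than two in-window profile samples also yield 0 and are counted
#' in the `n_degenerate` attribute.
#'
#' @inheritParams extract_rspi
#' @return object of class `channel_signal` (method `"RPA"`).
#' @export
extract_rpa <- function(spec, panel) {
  if (spec$mode != "profile") {
    warning("RPA on a centroid spectrum: zero-width peaks have zero area")
    sig <- channel_signal(stats::setNames(rep(0, length(panel$channels)),
                                          panel$channels), method = "RPA")
    attr(sig, "n_degenerate") <- length(panel$channels)
    return(sig)
  }
  mz <- spec$peaks[, 1L]
  ity <- spec$peaks[, 2L]
  n_degenerate <- 0L
  raw <- vapply(panel$channels, function(ch) {
    lo <- panel$mz[[ch]] - panel$tolerance
    hi <- panel$mz[[ch]] + panel$tolerance
    inside <- which(mz >= lo & mz <= hi)
    if (length(inside) < 2L) {
      n_degenerate <<- n_degenerate + 1L
      return(0)
    }
    x <- mz[inside]
    y <- ity[inside]
    # extend to the exact window edges by linear interpolation when a
    # sample exists just outside; otherwise integrate from the first to
    # the last in-window sample
    i0 <- inside[1L]
    i1 <- inside[length(inside)]
    if (i0 > 1L && mz[i0] > lo) {
      y0 <- ity[i0 - 1L] + (ity[i0] - ity[i0 - 1L]) *
        (lo - mz[i0 - 1L]) / (mz[i0] - mz[i0 - 1L])
      x <- c(lo, x); y <- c(y0, y)
    }
    if (i1 < length(mz) && mz[i1] < hi) {
      y1 <- ity[i1] + (ity[i1 + 1L] - ity[i1]) *
        (hi - mz[i1]) / (mz[i1 + 1L] - mz[i1])
      x <- c(x, hi); y <- c(y, y1)
    }
    sum(diff(x) * (head2(y, -1L) + y[-1L]) / 2)
  }, numeric(1))
  sig <- channel_signal(raw, method = "RPA")
  attr(sig, "n_degenerate") <- n_degenerate
  sig
}

# head(y, -1) without loading utils into the hot path
head2 <- function(x, n) x[seq_len(length(x) + n)]

#' Per-channel reporter signal
#'
#' @param raw named non-negative numeric vector, one entry per channel.
#' @param method `"RSPI"` or `"RPA"`.
#' @param corrected optional named numeric vector of impurity-corrected
#'   signals (normally filled in by [correct_isotopes()]).
#' @return object of class `channel_signal`.
#' @export
channel_signal <- function(raw, method = c("RSPI", "RPA"), corrected = NULL) {
  method <- match.arg(method)
  if (is.null(names(raw))) stop("'raw' must be named by channel")
  if (any(raw < 0)) stop("raw signals must be >= 0")
  structure(list(raw = raw, corrected = corrected, method = method),
            class = "channel_signal")
}

#' @export
print.channel_signal <- function(x, ...) {
  cat("Reporter signal (", x$method, ")\n", sep = "")
  m <- rbind(raw = x$raw)
  if (!is.null(x$corrected)) m <- rbind(m, corrected = x$corrected)
  print(m)
  invisible(x)
}

#' Correct reporter signals for isotope impurity
#'
#' Reagent isotope impurity makes each label leak signal into neighboring
#' channels. With `M[i, j]` the fraction of label `j` observed in channel
#' `i` (the panel's correction matrix), the observed signals are
#' `observed = M %*% true`; this solves the linear system for the true
#' signals. Negative solutions (possible under noise) are clamped to 0
#' and counted in the `n_clamped` attribute; the clamped channels produce
#' null ratios downstream.
#'
#' @param signal a `channel_signal` with raw signals.
#' @param panel a [reporter_panel()]; its `correction` matrix is used.
#' @return the signal with `corrected` filled in.
#' @export
correct_isotopes <- function(signal, panel) {
  M <- panel$correction
  if (kappa(M, exact = TRUE) > 1e8) {
    stop("correction matrix is singular or ill-conditioned")
  }
  x <- solve(M, as.numeric(signal$raw[panel$channels]))
  clamped <- x < 0
  x[clamped] <- 0
  signal$corrected <- stats::setNames(x, panel$channels)
  attr(signal, "n_clamped") <- sum(clamped)
  signal
}

#' Form peptide-level ratios against the reference channel
#'
#' Each non-reference channel's ratio is its corrected signal divided by
#' the corrected reference signal. If the reference signal is 0 all
#' ratios are null (`NA`); a zero channel signal makes that single ratio
#' null. Null ratios are what the downstream quantification-confidence
#' filter discards.
#'
#' @param signal a `channel_signal` with `corrected` filled in.
#' @param reference reference channel label.
#' @param channels panel channel order (defaults to the signal's names).
#' @return object of class `ratio_vector`: named numeric ratios for the
#'   non-reference channels (`NA` = null), with a `reference` field.
#' @export
compute_ratios <- function(signal, reference, channels = NULL) {
  if (is.null(signal$corrected)) {
    stop("apply correct_isotopes() before computing ratios")
  }
  if (is.null(channels)) channels <- names(signal$corrected)
  if (!reference %in% channels) {
    stop("reference channel '", reference, "' is not in the panel")
  }
  corr <- signal$corrected[channels]
  non_ref <- setdiff(channels, reference)
  ref_val <- corr[[reference]]
  ratios <- stats::setNames(rep(NA_real_, length(non_ref)), non_ref)
  if (ref_val > 0) {
    for (ch in non_ref) {
      if (corr[[ch]] > 0) ratios[[ch]] <- corr[[ch]] / ref_val
    }
  }
  structure(list(reference = reference, ratios = ratios),
            class = "ratio_vector")
}

#' @export
print.ratio_vector <- function(x, ...) {
  cat("Channel ratios vs ", x$reference, ":\n", sep = "")
  print(x$ratios)
  invisible(x)
}

#' Quantify one spectrum end to end
#'
#' Composition of signal extraction ([extract_rspi()] or
#' [extract_rpa()]), isotope correction ([correct_isotopes()]) and ratio
#' formation ([compute_ratios()]).
#'
#' @inheritParams extract_rspi
#' @param method `"RSPI"` (sum of peak intensities) or `"RPA"`
#'   (trapezoidal peak area).
#' @param reference reference channel label.
#' @return list with elements `signal` (a `channel_signal`, corrected)
#'   and `ratios` (a `ratio_vector`).
#' @export
quantify_spectrum <- function(spec, panel, method = c("RSPI", "RPA"),
                              reference = "114") {
  method <- match.arg(method)
  sig <- if (method == "RSPI") extract_rspi(spec, panel) else
    extract_rpa(spec, panel)
  sig <- correct_isotopes(sig, panel)
  list(signal = sig, ratios = compute_ratios(sig, reference, panel$channels))
}

#' Quantify a set of identified spectra into a PSM table
#'
#' Joins spectra to their identifications by scan id, extracts and
#' corrects reporter signals, forms ratios against the replicate's
#' reference channel, and returns rows in the canonical `psm_table`
#' layout (the jpf dialect's in-memory form). Null ratios are recorded as
#' 0.0, matching the convention of intensity-based quantitation tools
#' whose output the jpf dialect emulates; the refinement filter treats
#' 0.0 and null alike.
#'
#' @param spectra list of [spectrum()] objects.
#' @param ids data.frame of identifications with columns `scan_id`,
#'   `sequence`, `accessions`, `annotation`, `score`.
#' @param panel a [reporter_panel()].
#' @param method `"RSPI"` or `"RPA"`.
#' @param reference reference channel label for this replicate.
#' @param replicate_id replicate id stored on every row.
#' @return a `psm_table` data.frame.
#' @export
quantify_spectra <- function(spectra, ids, panel,
                             method = c("RSPI", "RPA"),
                             reference = "114",
                             replicate_id = NA_integer_) {
  method <- match.arg(method)
  by_scan <- stats::setNames(spectra,
                             vapply(spectra, `[[`, character(1), "scan_id"))
  missing <- setdiff(ids$scan_id, names(by_scan))
  if (length(missing)) {
    stop("no spectrum for scan id(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  channels <- panel$channels
  n <- nrow(ids)
  out <- data.frame(
    scan_id = ids$scan_id, sequence = ids$sequence,
    accessions = ids$accessions, annotation = ids$annotation,
    score = as.numeric(ids$score), stringsAsFactors = FALSE
  )
  imat <- matrix(NA_real_, n, length(channels))
  rmat <- matrix(NA_real_, n, length(channels))
  for (k in seq_len(n)) {
    q <- quantify_spectrum(by_scan[[ids$scan_id[k]]], panel, method, reference)
    imat[k, ] <- q$signal$corrected[channels]
    r <- q$ratios$ratios
    rmat[k, match(names(r), channels)] <- ifelse(is.na(r), 0, r)
  }
  for (j in seq_along(channels)) out[[paste0("i", channels[j])]] <- imat[, j]
  out$ref_channel <- reference
  for (j in seq_along(channels)) {
    out[[paste0("ratio_", channels[j])]] <-
      if (channels[j] == reference) NA_real_ else rmat[, j]
  }
  out$replicate_id <- as.integer(replicate_id)
  attr(out, "dialect") <- "jpf"
  class(out) <- c("psm_table", "data.frame")
  out
}
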