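#' Reporter-ion panel for iTRAQ 4-plex quantitation
#'
#' A panel bundles everything needed to read reporter signals out of an
#' MS/MS spectrum: the channel labels, their theoretical m/z positions,
#' the extraction tolerance, and the isotope-impurity mixing matrix.
#'
#' The default theoretical m/z values are the standard iTRAQ 4-plex
#' reporter masses (114.1112, 115.1083, 116.1116, 117.1150 Da). The
#' default tolerance of 0.05 Da matches common practice for high
#' resolution TOF instruments.
#'
#' @param channels character vector of channel labels, in panel order.
#' @param mz numeric vector of theoretical reporter m/z (Da), one per
#'   channel.
#' @param tolerance half-width (Da) of the extraction window around each
#'   theoretical m/z; the window is inclusive at both edges.
#' @param correction 4x4 mixing matrix: column `j` gives the fraction of
#'   label `j`'s signal observed in each channel (rows). Column sums may
#'   be below 1 (isotope envelope falling outside the panel). Defaults to
#'   the identity (no impurity).
#'
#' @return an object of class `reporter_panel`.
#' @examples
#' p <- reporter_panel()
#' p$mz[["114"]]
#' @export
reporter_panel <- function(channels = c("114", "115", "116", "117"),
                           mz = c(114.1112, 115.1083, 116.1116, 117.1150),
                           tolerance = 0.05,
                           correction = NULL) {
  channels <- as.character(channels)
  n <- length(channels)
  if (n < 2L) stop("a reporter panel needs at least two channels")
  if (length(mz) != n) stop("'mz' must have one value per channel")
  if (anyDuplicated(channels)) stop("duplicate channel labels")
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0) {
    stop("'tolerance' must be a single positive number (Da)")
  }
  mz <- as.numeric(mz)
  names(mz) <- channels

  # extraction windows must not overlap, or a peak could be double-counted
  o <- order(mz)
  gaps <- diff(mz[o])
  if (any(gaps <= 2 * tolerance)) {
    stop("reporter windows overlap: channel spacing must exceed 2*tolerance")
  }

  if (is.null(correction)) {
    correction <- diag(n)
    dimnames(correction) <- list(channels, channels)
  }
  correction <- as.matrix(correction)
  if (!all(dim(correction) == c(n, n))) {
    stop("'correction' must be a ", n, "x", n, " matrix")
  }
  if (is.null(dimnames(correction))) {
    dimnames(correction) <- list(channels, channels)
  }
  if (any(correction < 0)) stop("correction fractions must be >= 0")
  if (any(colSums(correction) > 1 + 1e-9)) {
    stop("each correction column must sum to at most 1")
  }
  if (any(diag(correction) <= 0)) {
    stop("correction diagonal entries must be positive")
  }

  structure(
    list(channels = channels, mz = mz, tolerance = tolerance,
         correction = correction),
    class = "reporter_panel"
  )
}

#' @export
print.reporter_panel <- function(x, ...) {
  cat("Reporter panel (", length(x$channels), " channels, tolerance ",
      x$tolerance, " Da)\n", sep = "")
  print(data.frame(channel = x$channels, mz = unname(x$mz)))
  if (all(x$correction == diag(length(x$channels)))) {
    cat("Correction: identity (no isotope impurity)\n")
  } else {
    cat("Correction matrix (column = label, row = observed channel):\n")
    print(round(x$correction, 4))
  }
  invisible(x)
}

#' Build a mixing matrix from an isotope correction-factor table
#'
#' Reagent certificates list, per label, the percentage of reporter signal
#' appearing −2, −1, +1 and +2 Da away from the nominal channel. This
#' builds the corresponding mixing matrix `M` with `M[i, j]` = fraction of
#' label `j` observed in channel `i`; leakage beyond the panel edge is
#' lost (column sums < 1).
#'
#' @param table data.frame with columns `channel`, `pct_minus2`,
#'   `pct_minus1`, `pct_plus1`, `pct_plus2` (percentages, 0-100).
#' @param channels panel channel order; defaults to the table's channels.
#' @return square mixing matrix with channel dimnames.
#' @seealso [read_correction_table()], [example_correction_table()]
#' @export
correction_matrix <- function(table, channels = NULL) {
  req <- c("channel", "pct_minus2", "pct_minus1", "pct_plus1", "pct_plus2")
  miss <- setdiff(req, names(table))
  if (length(miss)) {
    stop("correction table is missing column(s): ", paste(miss, collapse = ", "))
  }
  table$channel <- as.character(table$channel)
  if (is.null(channels)) channels <- table$channel
  channels <- as.character(channels)
  if (!setequal(table$channel, channels)) {
    stop("correction table channels do not match the panel channels")
  }
  n <- length(channels)
  M <- matrix(0, n, n, dimnames = list(channels, channels))
  offsets <- c(pct_minus2 = -2L, pct_minus1 = -1L, pct_plus1 = 1L, pct_plus2 = 2L)
  for (j in seq_len(n)) {
    row <- table[table$channel == channels[j], , drop = FALSE]
    pct <- unlist(row[1, names(offsets)])
    if (any(pct < 0) || sum(pct) >= 100) {
      stop("impurity percentages for channel ", channels[j], " are invalid")
    }
    M[j, j] <- 1 - sum(pct) / 100
    for (k in seq_along(offsets)) {
      i <- j + offsets[k]
      if (i >= 1L && i <= n) M[i, j] <- M[i, j] + pct[k] / 100
    }
  }
  M
}

#' Example isotope correction-factor table
#'
#' A plausible 4-plex certificate-style table (percent signal at -2/-1/+1/+2
#' Da per label) for demonstrations and tests. These are example values in
#' the range typically printed on reagent certificates; they are synthetic,
#' not any specific reagent lot.
#'
#' @return data.frame in the correction-table layout used by
#'   [correction_matrix()].
#' @export
example_correction_table <- function() {
  data.frame(
    channel = c("114", "115", "116", "117"),
    pct_minus2 = c(0.0, 0.0, 0.0, 0.1),
    pct_minus1 = c(1.0, 2.0, 3.0, 4.0),
    pct_plus1 = c(5.9, 5.6, 4.5, 3.5),
    pct_plus2 = c(0.2, 0.1, 0.1, 0.1),
    stringsAsFactors = FALSE
  )
}
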