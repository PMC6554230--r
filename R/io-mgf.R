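#' Read an MGF (Mascot Generic Format) file
#'
#' Parses BEGIN IONS/END IONS blocks into [spectrum()] objects. `TITLE`
#' becomes the scan id, `PEPMASS` and `CHARGE` are honored when present;
#' ion lines are whitespace-separated `mz intensity` pairs and are
#' re-sorted by ascending m/z if needed.
#'
#' Centroid versus profile interpretation cannot be inferred reliably from
#' an MGF file, so it is declared per file through `mode`.
#'
#' @param path path to an MGF file.
#' @param mode peak mode applied to every spectrum in the file
#'   (`"centroid"`, the default, or `"profile"`).
#' @return list of `spectrum` objects (possibly empty).
#' @export
read_mgf <- function(path, mode = c("centroid", "profile")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  open_line <- 0L
  title <- NA_character_
  pepmass <- NA_real_
  charge <- NA_integer_
  mzs <- ints <- numeric(0)

  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) stop("line ", i, ": BEGIN IONS inside an open block")
      in_block <- TRUE
      open_line <- i
      title <- NA_character_
      pepmass <- NA_real_
      charge <- NA_integer_
      mzs <- ints <- numeric(0)
    } else if (line == "END IONS") {
      if (!in_block) stop("line ", i, ": END IONS without BEGIN IONS")
      if (is.na(title)) title <- paste0("scan_", length(spectra) + 1L)
      spectra[[length(spectra) + 1L]] <- spectrum(
        title, cbind(mzs, ints), precursor_mz = pepmass,
        precursor_charge = charge, mode = mode
      )
      in_block <- FALSE
    } else if (!in_block) {
      next  # header junk outside blocks is ignored
    } else if (grepl("=", line, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", line))
      val <- sub("^[^=]*=", "", line)
      if (key == "TITLE") title <- val
      else if (key == "PEPMASS") {
        pepmass <- suppressWarnings(as.numeric(strsplit(trimws(val), "\\s+")[[1]][1]))
      } else if (key == "CHARGE") {
        charge <- suppressWarnings(as.integer(sub("\\+|-", "", trimws(val))))
      }
    } else {
      xy <- suppressWarnings(as.numeric(strsplit(line, "[\t ]+")[[1]]))
      if (length(xy) < 2L || anyNA(xy[1:2])) {
        stop("line ", i, ": malformed ion line '", lines[i], "'")
      }
      if (xy[2] < 0) stop("line ", i, ": negative intensity")
      mzs <- c(mzs, xy[1])
      ints <- c(ints, xy[2])
    }
  }
  if (in_block) {
    stop("malformed MGF: block opened at line ", open_line,
         " has no END IONS")
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: one BEGIN IONS/END IONS block per spectrum.
#' Peak values are written with enough digits to round-trip through text.
#'
#' @param spectra list of `spectrum` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$scan_id), con)
    if (!is.na(s$precursor_mz)) {
      writeLines(paste0("PEPMASS=", format(s$precursor_mz, digits = 10)), con)
    }
    if (!is.na(s$precursor_charge)) {
      writeLines(paste0("CHARGE=", s$precursor_charge, "+"), con)
    }
    if (nrow(s$peaks)) {
      writeLines(paste(format(s$peaks[, 1], digits = 10, trim = TRUE),
                       format(s$peaks[, 2], digits = 10, trim = TRUE)), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}
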