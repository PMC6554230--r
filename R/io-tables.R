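#' Read a replicate design table
#'
#' The design table maps each iTRAQ channel to an experimental condition,
#' per biological replicate, and flags the reference condition. Rotating
#' the channel assignment between replicates counters tag-related bias,
#' so the mapping is validated per replicate: every channel appears
#' exactly once, and exactly one condition is flagged as reference. The
#' reference condition must be the same in every replicate (ratios are
#' merged across replicates by condition).
#'
#' Expected columns (tab-delimited, header line):
#' `replicate_id`, `condition`, `channel`, `is_reference` (0/1).
#'
#' @param path path to the design file.
#' @return data.frame of class `design_table`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  design_table(d)
}

#' Validate a channel-to-condition design
#'
#' @param d data.frame with columns `replicate_id`, `condition`,
#'   `channel`, `is_reference`.
#' @param channels the full channel set each replicate must cover.
#' @return `d`, classed `design_table`, rows ordered by (replicate, channel).
#' @export
design_table <- function(d, channels = c("114", "115", "116", "117")) {
  req <- c("replicate_id", "condition", "channel", "is_reference")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("design table missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- as.data.frame(d, stringsAsFactors = FALSE)
  d$replicate_id <- as.integer(d$replicate_id)
  d$channel <- as.character(d$channel)
  d$condition <- as.character(d$condition)
  d$is_reference <- as.integer(d$is_reference)
  if (anyNA(d$replicate_id)) stop("non-integer replicate_id in design")

  refs <- character(0)
  for (r in sort(unique(d$replicate_id))) {
    dr <- d[d$replicate_id == r, , drop = FALSE]
    if (anyDuplicated(dr$channel)) {
      stop("design error: duplicated channel in replicate ", r)
    }
    if (!setequal(dr$channel, channels)) {
      stop("design error: replicate ", r, " does not cover channels ",
           paste(channels, collapse = ", "))
    }
    if (anyDuplicated(dr$condition)) {
      stop("design error: duplicated condition in replicate ", r)
    }
    ref <- dr$condition[dr$is_reference == 1L]
    if (length(ref) != 1L) {
      stop("design error: replicate ", r,
           " must flag exactly one reference condition")
    }
    refs <- c(refs, ref)
  }
  if (length(unique(refs)) != 1L) {
    stop("design error: the reference condition differs between replicates")
  }
  d <- d[order(d$replicate_id, d$channel), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("design_table", "data.frame")
  d
}

#' Channel-to-condition mapping for one replicate
#' @param design a `design_table`.
#' @param replicate replicate id.
#' @return named character vector, names = channels, values = conditions.
#' @export
design_mapping <- function(design, replicate) {
  dr <- design[design$replicate_id == replicate, , drop = FALSE]
  if (!nrow(dr)) stop("replicate ", replicate, " not in design")
  stats::setNames(dr$condition, dr$channel)
}

#' Reference condition and its channel for one replicate
#' @inheritParams design_mapping
#' @return list with `condition` and `channel`.
#' @export
design_reference <- function(design, replicate) {
  dr <- design[design$replicate_id == replicate, , drop = FALSE]
  if (!nrow(dr)) stop("replicate ", replicate, " not in design")
  i <- which(dr$is_reference == 1L)
  list(condition = dr$condition[i], channel = dr$channel[i])
}

#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design)[, c("replicate_id", "condition",
                                               "channel", "is_reference")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonical in-memory PSM column layout shared by both dialect readers
psm_columns <- function(channels = c("114", "115", "116", "117")) {
  c("scan_id", "sequence", "accessions", "annotation", "score",
    paste0("i", channels), "ref_channel", paste0("ratio_", channels),
    "replicate_id")
}

empty_psm_table <- function(dialect = "jpf",
                            channels = c("114", "115", "116", "117")) {
  cols <- psm_columns(channels)
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  for (cc in c("score", paste0("i", channels), paste0("ratio_", channels))) {
    df[[cc]] <- numeric(0)
  }
  df$replicate_id <- integer(0)
  attr(df, "dialect") <- dialect
  class(df) <- c("psm_table", "data.frame")
  df
}

parse_ratio_cell <- function(x, where) {
  # empty cell / "NA" is the null sentinel; numeric 0.0 is stored as read
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  filled <- !(x == "" | toupper(x) == "NA")
  v <- suppressWarnings(as.numeric(x[filled]))
  if (anyNA(v)) {
    bad <- which(filled)[which(is.na(v))[1]]
    stop("non-numeric ratio cell in row ", bad, " of ", where)
  }
  out[filled] <- v
  out
}

#' Read a peptide-spectrum-match table
#'
#' Two tab-delimited dialects are supported. The `jpf` dialect emulates
#' the output of intensity-based reporter quantitation tools: columns
#' `sequence`, `accession`, `annotation`, `score`, `i114`..`i117`, and a
#' ratio column `r<ch>_<ref>` for each non-reference channel (the
#' reference channel is encoded in the ratio column names). The
#' `peptide_summary` dialect emulates a vendor peptide summary export:
#' `Sequence`, `Accessions`, `Names`, `Conf`, `Used`, and ratio columns
#' named `<ch>:<ref>`. Neither vendor documents its exact columns, so
#' both dialects are reconstructions, versioned by their header lines.
#'
#' Blank or `NA` ratio cells become null ratios (`NA`), distinct from a
#' literal `0.0`, which is stored as read; both are discarded later by
#' the quantification-confidence filter, but provenance is kept.
#'
#' @param path path to the table.
#' @param dialect `"jpf"` or `"peptide_summary"`.
#' @param replicate_id replicate the table belongs to (one file per
#'   replicate); stored on every row.
#' @return data.frame of class `psm_table` in the canonical layout
#'   (per-channel `i*` intensities, `ratio_*` columns, `ref_channel`).
#' @export
read_psm_table <- function(path, dialect = c("jpf", "peptide_summary"),
                           replicate_id = NA_integer_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  channels <- c("114", "115", "116", "117")

  if (dialect == "jpf") {
    fixed <- c("sequence", "accession", "annotation", "score",
               paste0("i", channels))
    ratio_cols <- grep("^r[0-9]+_[0-9]+$", names(raw), value = TRUE)
    expected <- c(fixed, "r<ch>_<ref> x3")
    if (length(setdiff(fixed, names(raw))) || length(ratio_cols) != 3L) {
      stop("unknown jpf header; expected columns: ",
           paste(expected, collapse = ", "))
    }
    refs <- unique(sub("^r[0-9]+_", "", ratio_cols))
    if (length(refs) != 1L || !refs %in% channels) {
      stop("jpf ratio columns must share one reference channel")
    }
    ref <- refs
    out <- empty_psm_table("jpf")
    if (nrow(raw)) {
      out <- data.frame(
        scan_id = if ("scan_id" %in% names(raw)) raw$scan_id else NA_character_,
        sequence = raw$sequence,
        accessions = raw$accession,
        annotation = raw$annotation,
        score = as.numeric(raw$score),
        stringsAsFactors = FALSE
      )
      for (ch in channels) out[[paste0("i", ch)]] <- as.numeric(raw[[paste0("i", ch)]])
      out$ref_channel <- ref
      for (ch in channels) {
        col <- paste0("r", ch, "_", ref)
        out[[paste0("ratio_", ch)]] <-
          if (ch == ref) NA_real_ else parse_ratio_cell(raw[[col]], path)
      }
      out$replicate_id <- as.integer(replicate_id)
      attr(out, "dialect") <- "jpf"
      class(out) <- c("psm_table", "data.frame")
    }
    return(out)
  }

  # peptide_summary dialect
  fixed <- c("Sequence", "Accessions", "Names", "Conf", "Used")
  ratio_cols <- grep("^[0-9]+:[0-9]+$", names(raw), value = TRUE)
  if (length(setdiff(fixed, names(raw))) || length(ratio_cols) != 3L) {
    stop("unknown peptide_summary header; expected columns: ",
         paste(c(fixed, "<ch>:<ref> x3"), collapse = ", "))
  }
  refs <- unique(sub("^[0-9]+:", "", ratio_cols))
  if (length(refs) != 1L || !refs %in% channels) {
    stop("peptide_summary ratio columns must share one reference channel")
  }
  ref <- refs
  out <- empty_psm_table("peptide_summary")
  if (nrow(raw)) {
    out <- data.frame(
      scan_id = if ("scan_id" %in% names(raw)) raw$scan_id else NA_character_,
      sequence = raw$Sequence,
      accessions = raw$Accessions,
      annotation = raw$Names,
      score = as.numeric(raw$Conf),
      stringsAsFactors = FALSE
    )
    for (ch in channels) out[[paste0("i", ch)]] <- NA_real_
    out$ref_channel <- ref
    for (ch in channels) {
      col <- paste0(ch, ":", ref)
      out[[paste0("ratio_", ch)]] <-
        if (ch == ref) NA_real_ else parse_ratio_cell(raw[[col]], path)
    }
    out$replicate_id <- as.integer(replicate_id)
    out$used <- as.integer(raw$Used)
    attr(out, "dialect") <- "peptide_summary"
    class(out) <- c("psm_table", "data.frame")
  }
  out
}

#' Write a PSM table in one of the supported dialects
#'
#' @param psm canonical `psm_table` data.frame.
#' @param path output path.
#' @param dialect `"jpf"` or `"peptide_summary"`.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psm, path, dialect = c("jpf", "peptide_summary")) {
  dialect <- match.arg(dialect)
  channels <- c("114", "115", "116", "117")
  ref <- if (nrow(psm)) psm$ref_channel[1] else "114"
  non_ref <- setdiff(channels, ref)
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, digits = 8, trim = TRUE,
                                                   scientific = FALSE))
  if (dialect == "jpf") {
    out <- data.frame(
      scan_id = psm$scan_id, sequence = psm$sequence,
      accession = psm$accessions, annotation = psm$annotation,
      score = psm$score, stringsAsFactors = FALSE, check.names = FALSE
    )
    for (ch in channels) out[[paste0("i", ch)]] <- fmt(psm[[paste0("i", ch)]])
    for (ch in non_ref) {
      out[[paste0("r", ch, "_", ref)]] <- fmt(psm[[paste0("ratio_", ch)]])
    }
  } else {
    out <- data.frame(
      scan_id = psm$scan_id, Sequence = psm$sequence,
      Accessions = psm$accessions, Names = psm$annotation,
      Conf = psm$score,
      Used = if ("used" %in% names(psm)) psm$used else 1L,
      stringsAsFactors = FALSE, check.names = FALSE
    )
    for (ch in non_ref) {
      out[[paste0(ch, ":", ref)]] <- fmt(psm[[paste0("ratio_", ch)]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an isotope correction-factor table
#'
#' Tab-delimited with columns `channel`, `pct_minus2`, `pct_minus1`,
#' `pct_plus1`, `pct_plus2` (percentages).
#'
#' @param path path to the table.
#' @return data.frame suitable for [correction_matrix()].
#' @export
read_correction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE)
  req <- c("channel", "pct_minus2", "pct_minus1", "pct_plus1", "pct_plus2")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("correction table missing column(s): ",
                         paste(miss, collapse = ", "))
  d$channel <- as.character(d$channel)
  d
}

#' Write the protein-level quantitation report
#'
#' Tab-delimited, one row per (accession, condition): overall median
#' ratio, per-replicate medians, weighted mean, SD, peptide count and the
#' frequency threshold used. Values round-trip through text at better
#' than 1e-6 relative precision.
#'
#' @param proteins `protein_quant` data.frame from [rollup_proteins()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_report <- function(proteins, path) {
  df <- as.data.frame(proteins)
  num <- vapply(df, is.numeric, logical(1)) &
    !names(df) %in% c("n_peptides", "frequency_threshold")
  for (cc in names(df)[num]) {
    df[[cc]] <- ifelse(is.na(df[[cc]]), "NA",
                       formatC(df[[cc]], digits = 9, format = "g"))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein report written by [write_protein_report()]
#' @param path path to the report.
#' @return data.frame of class `protein_quant`.
#' @export
read_protein_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = "character", na.strings = "NA")
  for (cc in setdiff(names(d), c("accession", "condition"))) {
    d[[cc]] <- as.numeric(d[[cc]])
  }
  if ("n_peptides" %in% names(d)) d$n_peptides <- as.integer(d$n_peptides)
  if ("frequency_threshold" %in% names(d)) {
    d$frequency_threshold <- as.integer(d$frequency_threshold)
  }
  class(d) <- c("protein_quant", "data.frame")
  d
}

#' Read a paired reference-measurement table
#'
#' Orthogonal method measurements (for example Western-blot ratios) in
#' the layout `protein`, `condition`, `replicate`, `ratio`.
#'
#' @param path path to the tab-delimited table.
#' @return data.frame with those four columns.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE)
  req <- c("protein", "condition", "replicate", "ratio")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("reference table missing column(s): ",
                         paste(miss, collapse = ", "))
  d$ratio <- as.numeric(d$ratio)
  d
}

#' @export
write_reference_table <- function(ref, path) {
  utils::write.table(ref[, c("protein", "condition", "replicate", "ratio")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
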