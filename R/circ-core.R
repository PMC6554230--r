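#' Exclusion cascade for PSM tables
#'
#' Applies the refinement filter to a PSM table, in a fixed criterion
#' order so discard-reason counts are well defined. Each record is
#' discarded at the first failing criterion:
#'
#' 1. `low_score` — identification confidence: the score must be strictly
#'    above the threshold (equality discards). Default thresholds are 30
#'    on the Mascot scale and 95 on the Paragon confidence scale.
#' 2. `null_ratio` — quantification confidence: every condition ratio
#'    must have been calculated; records with a null (`NA`) or `0.0`
#'    ratio in any non-reference channel are discarded.
#' 3. `fragment_annotation` — annotation contains `Fragment`.
#' 4. `reversed_annotation` — annotation contains `REVERSED` (decoy).
#' 5. `shared_peptide` — within a replicate, the same sequence maps to
#'    more than one distinct accession (including multi-accession rows).
#'    Shared-ness is assessed among records that survived criteria 1-4,
#'    which makes the filter idempotent: re-filtering the retained set
#'    discards nothing.
#'
#' @param psm a `psm_table` data.frame (may span several replicates).
#' @param score_threshold identification score cut-off; default 30 for
#'   the Mascot scale, 95 for the Paragon scale.
#' @param scale `"mascot"` or `"paragon"`; names the score scale and sets
#'   the default threshold.
#' @return object of class `filter_report`: `retained` (a `psm_table`),
#'   `discarded_by_reason` (named counts), `per_replicate` (counts per
#'   replicate and reason), `n_input`.
#' @export
circ_filter <- function(psm, score_threshold = NULL,
                        scale = c("mascot", "paragon")) {
  scale <- match.arg(scale)
  if (is.null(score_threshold)) {
    score_threshold <- if (scale == "mascot") 30 else 95
  }
  if (!is.numeric(score_threshold) || score_threshold < 0) {
    stop("'score_threshold' must be a non-negative number")
  }
  reasons <- c("low_score", "null_ratio", "fragment_annotation",
               "reversed_annotation", "shared_peptide")
  n <- nrow(psm)
  fail <- rep(NA_character_, n)

  if (n) {
    ratio_cols <- grep("^ratio_", names(psm), value = TRUE)
    non_ref <- lapply(seq_len(n), function(k) {
      setdiff(ratio_cols, paste0("ratio_", psm$ref_channel[k]))
    })
    null_ratio <- vapply(seq_len(n), function(k) {
      r <- as.numeric(psm[k, non_ref[[k]]])
      anyNA(r) || any(r == 0)
    }, logical(1))

    fail[psm$score <= score_threshold] <- "low_score"
    sel <- is.na(fail) & null_ratio
    fail[sel] <- "null_ratio"
    sel <- is.na(fail) & grepl("Fragment", psm$annotation, fixed = TRUE)
    fail[sel] <- "fragment_annotation"
    sel <- is.na(fail) & grepl("REVERSED", psm$annotation, fixed = TRUE)
    fail[sel] <- "reversed_annotation"

    # shared peptides: among survivors of criteria 1-4, per replicate
    surv <- which(is.na(fail))
    if (length(surv)) {
      n_acc <- vapply(strsplit(psm$accessions[surv], ";", fixed = TRUE),
                      function(a) length(unique(trimws(a))), integer(1))
      key <- paste(psm$replicate_id[surv], psm$sequence[surv], sep = "\r")
      acc_per_key <- tapply(psm$accessions[surv], key,
                            function(a) length(unique(a)))
      shared <- n_acc > 1L | acc_per_key[key] > 1L
      fail[surv[shared]] <- "shared_peptide"
    }
  }

  retained <- psm[is.na(fail), , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "dialect") <- attr(psm, "dialect")
  class(retained) <- c("psm_table", "data.frame")

  by_reason <- stats::setNames(
    vapply(reasons, function(r) sum(fail == r, na.rm = TRUE), integer(1)),
    reasons)
  reps <- sort(unique(psm$replicate_id))
  per_rep <- do.call(rbind, lapply(reps, function(r) {
    in_rep <- psm$replicate_id == r
    cnt <- vapply(reasons, function(rr) sum(fail[in_rep] == rr, na.rm = TRUE),
                  integer(1))
    data.frame(replicate_id = r, input = sum(in_rep),
               retained = sum(in_rep & is.na(fail)),
               discarded = sum(in_rep & !is.na(fail)),
               t(cnt), check.names = FALSE)
  }))

  structure(
    list(retained = retained, discarded_by_reason = by_reason,
         per_replicate = per_rep, n_input = n,
         score_threshold = score_threshold, scale = scale),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Refinement filter (", x$scale, " score > ", x$score_threshold,
      ")\n", sep = "")
  cat("  input:    ", x$n_input, " PSMs\n", sep = "")
  cat("  retained: ", nrow(x$retained), "\n", sep = "")
  cat("  discarded:", x$n_input - nrow(x$retained))
  if (x$n_input > 0) {
    cat(sprintf(" (%.1f%%)", 100 * (x$n_input - nrow(x$retained)) / x$n_input))
  }
  cat("\n  by reason:\n")
  for (r in names(x$discarded_by_reason)) {
    cat(sprintf("    %-20s %d\n", r, x$discarded_by_reason[[r]]))
  }
  invisible(x)
}

#' Build the cross-replicate peptide catalog
#'
#' Re-keys each retained PSM's channel ratios to condition ratios through
#' its replicate's channel mapping (so that rotated tag assignments line
#' up across replicates), then assigns every (sequence, accession) pair a
#' frequency index: the number of replicates in which it was retained
#' with full quantitation. Entries are ordered by (accession, sequence).
#'
#' @param reports a `filter_report`, a retained `psm_table`, or a list of
#'   either (one per replicate).
#' @param design a `design_table` covering every replicate present.
#' @return object of class `peptide_catalog`: `entries` (long data.frame
#'   sequence/accession/replicate_id/condition/ratio/weight), `frequency`
#'   (per-pair frequency index), `n_replicates`.
#' @export
build_catalog <- function(reports, design) {
  as_retained <- function(x) {
    if (inherits(x, "filter_report")) x$retained else x
  }
  if (inherits(reports, "filter_report") || is.data.frame(reports)) {
    psm <- as_retained(reports)
  } else {
    psm <- do.call(rbind, lapply(reports, as_retained))
  }
  if (!nrow(psm)) stop("no retained PSMs to catalog")

  reps <- sort(unique(psm$replicate_id))
  missing <- setdiff(reps, unique(design$replicate_id))
  if (length(missing)) {
    stop("replicate(s) ", paste(missing, collapse = ", "),
         " are missing from the design")
  }

  entry_list <- vector("list", length(reps))
  for (k in seq_along(reps)) {
    r <- reps[k]
    map <- design_mapping(design, r)
    ref <- design_reference(design, r)
    rows <- psm[psm$replicate_id == r, , drop = FALSE]
    bad <- rows$ref_channel != ref$channel
    if (any(bad)) {
      stop("replicate ", r, ": PSM reference channel disagrees with design")
    }
    non_ref <- setdiff(names(map), ref$channel)
    icols <- paste0("i", names(map))
    have_sig <- all(icols %in% names(rows))
    w <- if (have_sig) rowSums(as.matrix(rows[, icols]), na.rm = TRUE) else
      rep(NA_real_, nrow(rows))
    w[!is.finite(w) | w <= 0] <- NA_real_
    entry_list[[k]] <- do.call(rbind, lapply(non_ref, function(ch) {
      data.frame(sequence = rows$sequence, accession = rows$accessions,
                 replicate_id = r, condition = unname(map[[ch]]),
                 ratio = as.numeric(rows[[paste0("ratio_", ch)]]),
                 weight = w, stringsAsFactors = FALSE)
    }))
  }
  entries <- do.call(rbind, entry_list)
  entries <- entries[order(entries$accession, entries$sequence,
                           entries$replicate_id, entries$condition), ]
  rownames(entries) <- NULL

  key <- paste(entries$sequence, entries$accession, sep = "\r")
  freq <- tapply(entries$replicate_id, key,
                 function(r) length(unique(r)))
  pair <- do.call(rbind, strsplit(names(freq), "\r", fixed = TRUE))
  frequency <- data.frame(sequence = pair[, 1], accession = pair[, 2],
                          frequency_index = as.integer(freq),
                          stringsAsFactors = FALSE)
  frequency <- frequency[order(frequency$accession, frequency$sequence), ]
  rownames(frequency) <- NULL

  structure(
    list(entries = entries, frequency = frequency,
         n_replicates = length(unique(design$replicate_id))),
    class = "peptide_catalog"
  )
}

#' @export
print.peptide_catalog <- function(x, ...) {
  cat("Peptide catalog: ", nrow(x$frequency), " (sequence, accession) pairs, ",
      x$n_replicates, " replicates\n", sep = "")
  cat("Frequency index distribution:\n")
  print(table(x$frequency$frequency_index))
  invisible(x)
}

#' Roll peptides up to protein-level ratios
#'
#' For every (accession, condition), pools the condition ratios of all
#' catalog peptides whose frequency index is at least `min_frequency` and
#' reports: the overall median (even counts average the central pair),
#' per-replicate medians, an intensity-weighted mean (weights are the
#' summed corrected reporter signals of each PSM, falling back to
#' uniform weights when signals are unavailable), and the sample
#' standard deviation (absent with fewer than two pooled ratios). No
#' normalization or other transformation is applied.
#'
#' @param catalog a `peptide_catalog`.
#' @param min_frequency minimum frequency index (1..number of
#'   replicates) a peptide must reach to contribute.
#' @param weights `"signal"` (default) or `"uniform"`.
#' @return data.frame of class `protein_quant`, one row per (accession,
#'   condition): `overall_median`, `med_rep<r>` columns, `weighted_mean`,
#'   `sd`, `n_peptides` (distinct sequences), `n_ratios` (pooled ratios),
#'   `frequency_threshold`.
#' @export
rollup_proteins <- function(catalog, min_frequency = 5,
                            weights = c("signal", "uniform")) {
  weights <- match.arg(weights)
  R <- catalog$n_replicates
  if (min_frequency < 1 || min_frequency > R) {
    stop("'min_frequency' must be between 1 and ", R)
  }
  fr <- catalog$frequency
  keep_pairs <- fr[fr$frequency_index >= min_frequency, , drop = FALSE]
  e <- catalog$entries
  key <- paste(e$sequence, e$accession, sep = "\r")
  e <- e[key %in% paste(keep_pairs$sequence, keep_pairs$accession, sep = "\r"),
         , drop = FALSE]
  if (!nrow(e)) {
    out <- data.frame(accession = character(0), condition = character(0))
    class(out) <- c("protein_quant", "data.frame")
    return(out)
  }
  reps <- sort(unique(catalog$entries$replicate_id))

  grp <- split(e, list(e$accession, e$condition), drop = TRUE, sep = "\r")
  rows <- lapply(grp, function(g) {
    w <- if (weights == "uniform" || anyNA(g$weight)) rep(1, nrow(g)) else
      g$weight
    med_rep <- stats::setNames(rep(NA_real_, length(reps)),
                               paste0("med_rep", reps))
    for (r in reps) {
      rr <- g$ratio[g$replicate_id == r]
      if (length(rr)) med_rep[[paste0("med_rep", r)]] <- stats::median(rr)
    }
    cbind(
      data.frame(accession = g$accession[1], condition = g$condition[1],
                 overall_median = stats::median(g$ratio),
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(med_rep)),
      data.frame(weighted_mean = sum(w * g$ratio) / sum(w),
                 sd = if (nrow(g) >= 2) stats::sd(g$ratio) else NA_real_,
                 n_peptides = length(unique(g$sequence)),
                 n_ratios = nrow(g))
    )
  })
  out <- do.call(rbind, rows)
  out$frequency_threshold <- as.integer(min_frequency)
  out <- out[order(out$accession, out$condition), ]
  rownames(out) <- NULL
  class(out) <- c("protein_quant", "data.frame")
  out
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("Protein quantitation: ", length(unique(x$accession)), " proteins x ",
      length(unique(x$condition)), " conditions (frequency threshold ",
      if (nrow(x)) x$frequency_threshold[1] else NA, ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}
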