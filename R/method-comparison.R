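#' Paired measurements from two quantitation methods
#'
#' Pairs the test method's ratios (`y`, e.g. reporter-ion ratios) with an
#' orthogonal reference method's ratios (`x`, e.g. Western blot) for the
#' same (protein, condition, replicate) labels. Pairs with a missing
#' member are excluded and counted, so downstream statistics run on
#' pairwise-complete data with an audit trail.
#'
#' @param x reference-method values.
#' @param y test-method values (same length).
#' @param labels optional data.frame of pair labels (protein, condition,
#'   replicate).
#' @return object of class `paired_measurements` with complete pairs and
#'   an `excluded_pairs` count.
#' @export
paired_measurements <- function(x, y, labels = NULL) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  structure(
    list(x = as.numeric(x[ok]), y = as.numeric(y[ok]),
         labels = if (!is.null(labels)) labels[ok, , drop = FALSE],
         excluded_pairs = sum(!ok)),
    class = "paired_measurements"
  )
}

#' Bland-Altman agreement between two quantitation methods
#'
#' Computes the paired differences `d = y - x` (test minus reference, on
#' the raw ratio scale, no transformation), their mean (the bias), their
#' sample standard deviation, and the 95% limits of agreement
#' `bias +/- 1.96 * sd`. The classic 1.96 normal multiplier is used, not
#' a t quantile.
#'
#' @param pairs a [paired_measurements()] (or any list with numeric `x`
#'   and `y` of equal length).
#' @return object of class `comparison_result` with fields `bias`,
#'   `sd_diff`, `loa_lower`, `loa_upper`, `n_pairs`, `excluded_pairs`.
#' @examples
#' p <- paired_measurements(c(1, 2, 3), c(1.1, 2.0, 3.2))
#' bland_altman(p)$bias
#' @export
bland_altman <- function(pairs) {
  x <- pairs$x; y <- pairs$y
  n <- length(x)
  if (n < 2L) stop("Bland-Altman needs at least 2 complete pairs")
  d <- y - x
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_lower = bias - 1.96 * sd_diff,
         loa_upper = bias + 1.96 * sd_diff,
         r = NA_real_, t_stat = NA_real_, p_two_sided = NA_real_,
         n_pairs = n,
         excluded_pairs = if (is.null(pairs$excluded_pairs)) 0L else
           pairs$excluded_pairs),
    class = "comparison_result"
  )
}

#' Pearson correlation with zero-slope test
#'
#' Product-moment correlation between the two methods and the two-sided
#' t test of zero association (`t = r * sqrt(n - 2) / sqrt(1 - r^2)`,
#' n - 2 degrees of freedom). A significant result rejects the zero-slope
#' hypothesis, i.e. the methods co-vary.
#'
#' @inheritParams bland_altman
#' @param alpha significance threshold for the zero-slope verdict.
#' @return object of class `comparison_result` with fields `r`, `t_stat`,
#'   `p_two_sided`, `nonzero_slope`, `n_pairs`, `excluded_pairs`.
#' @export
pearson_test <- function(pairs, alpha = 0.05) {
  x <- pairs$x; y <- pairs$y
  n <- length(x)
  if (n < 3L) stop("Pearson test needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(
    list(bias = NA_real_, sd_diff = NA_real_,
         loa_lower = NA_real_, loa_upper = NA_real_,
         r = unname(ct$estimate), t_stat = unname(ct$statistic),
         p_two_sided = ct$p.value,
         nonzero_slope = ct$p.value < alpha,
         n_pairs = n,
         excluded_pairs = if (is.null(pairs$excluded_pairs)) 0L else
           pairs$excluded_pairs),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Method comparison (n = ", x$n_pairs, " pairs",
      if (x$excluded_pairs > 0) paste0(", ", x$excluded_pairs, " excluded"),
      ")\n", sep = "")
  if (!is.na(x$bias)) {
    cat(sprintf("  bias %.3f +/- %.3f, 95%% LoA [%.3f, %.3f]\n",
                x$bias, x$sd_diff, x$loa_lower, x$loa_upper))
  }
  if (!is.na(x$r)) {
    cat(sprintf("  Pearson r = %.3f (t = %.3f, P = %.4g; %s slope)\n",
                x$r, x$t_stat, x$p_two_sided,
                if (isTRUE(x$nonzero_slope)) "non-zero" else "zero"))
  }
  invisible(x)
}

#' Mean and sample standard deviation over per-set values
#'
#' Summarizes per-replicate counts or percentages as `mean +/- sd`
#' (sample SD, n - 1 denominator), with rounding matched to the input
#' kind: integers for counts, one decimal for percentages.
#'
#' @param values numeric vector, one value per set/replicate.
#' @param kind `"count"` (round to integers) or `"percent"` (one
#'   decimal).
#' @return object of class `set_summary` with `values`, `mean`, `sd`,
#'   and their rounded forms `mean_rounded`, `sd_rounded`.
#' @examples
#' summarize_sets(c(5, 5, 5))$mean
#' @export
summarize_sets <- function(values, kind = c("count", "percent")) {
  kind <- match.arg(kind)
  if (!length(values)) stop("need at least one value")
  m <- mean(values)
  s <- if (length(values) >= 2) stats::sd(values) else NA_real_
  digits <- if (kind == "count") 0L else 1L
  structure(
    list(values = values, mean = m, sd = s,
         mean_rounded = round(m, digits),
         sd_rounded = if (is.na(s)) NA_real_ else round(s, digits),
         kind = kind),
    class = "set_summary"
  )
}

#' @export
print.set_summary <- function(x, ...) {
  cat(format(x$mean_rounded), "+/-", format(x$sd_rounded),
      paste0("(n = ", length(x$values), " sets)\n"))
  invisible(x)
}

#' Normalize reference measurements to a housekeeping protein
#'
#' Divides each (condition, replicate) reference ratio by the value of a
#' named reference protein in the same (condition, replicate); standard
#' practice for blot densitometry before comparison with reporter-ion
#' ratios.
#'
#' @param ref reference table (`protein`, `condition`, `replicate`,
#'   `ratio`).
#' @param reference_protein protein to normalize by.
#' @return the table with normalized ratios, the reference protein rows
#'   removed.
#' @export
normalize_reference <- function(ref, reference_protein) {
  norm <- ref[ref$protein == reference_protein, , drop = FALSE]
  if (!nrow(norm)) stop("reference protein '", reference_protein,
                        "' not found in the table")
  key <- function(d) paste(d$condition, d$replicate, sep = "\r")
  denom <- stats::setNames(norm$ratio, key(norm))
  rest <- ref[ref$protein != reference_protein, , drop = FALSE]
  rest$ratio <- rest$ratio / as.numeric(denom[key(rest)])
  rest[is.finite(rest$ratio), , drop = FALSE]
}

#' Pair protein-level reporter ratios with reference measurements
#'
#' Joins a [rollup_proteins()] table with a reference-method table on
#' (protein, condition), pairing the reference measurement of each
#' replicate with the protein's per-replicate median ratio (falling back
#' to the overall median when the replicate median is unavailable).
#'
#' @param proteins `protein_quant` data.frame.
#' @param ref reference table (`protein`, `condition`, `replicate`,
#'   `ratio`).
#' @return a [paired_measurements()] object.
#' @export
pair_with_reference <- function(proteins, ref) {
  key <- paste(proteins$accession, proteins$condition, sep = "\r")
  idx <- match(paste(ref$protein, ref$condition, sep = "\r"), key)
  y <- rep(NA_real_, nrow(ref))
  for (k in seq_len(nrow(ref))) {
    i <- idx[k]
    if (is.na(i)) next
    col <- paste0("med_rep", ref$replicate[k])
    v <- if (col %in% names(proteins)) proteins[[col]][i] else NA_real_
    if (!is.finite(v)) v <- proteins$overall_median[i]
    y[k] <- v
  }
  paired_measurements(ref$ratio, y,
                      labels = ref[, c("protein", "condition", "replicate")])
}
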