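# shared fixtures: tiny panels, spectra and PSM tables built in code

identity_panel <- function(tolerance = 0.05) {
  reporter_panel(tolerance = tolerance)
}

impure_panel <- function() {
  reporter_panel(correction = correction_matrix(example_correction_table()))
}

# centroid spectrum with one stick per reporter channel at the given heights
stick_spectrum <- function(heights, panel = identity_panel(),
                           scan_id = "scan=1", extra = NULL) {
  mz <- unname(panel$mz)
  pk <- cbind(mz, heights)
  pk <- pk[heights > 0, , drop = FALSE]
  if (!is.null(extra)) pk <- rbind(pk, extra)
  spectrum(scan_id, pk, mode = "centroid")
}

# profile spectrum: Gaussian trace per channel, sampled on a regular grid
gaussian_spectrum <- function(heights, sigma, panel = identity_panel(),
                              step = 0.002, scan_id = "scan=1") {
  sigma <- rep_len(sigma, length(heights))
  pk <- do.call(rbind, lapply(seq_along(heights), function(j) {
    if (heights[j] <= 0) return(NULL)
    center <- unname(panel$mz[j])
    x <- seq(center - panel$tolerance, center + panel$tolerance, by = step)
    cbind(x, heights[j] * exp(-(x - center)^2 / (2 * sigma[j]^2)))
  }))
  spectrum(scan_id, pk, mode = "profile")
}

# minimal canonical PSM table; ratios default to fully quantified
make_psm <- function(sequence = "PEPTIDEK", accessions = "PROT001",
                     annotation = "Protein PROT001", score = 50,
                     ratios = c(`115` = 1, `116` = 1, `117` = 1),
                     ref_channel = "114", replicate_id = 1L,
                     intensities = c(`114` = 1000, `115` = 1000,
                                     `116` = 1000, `117` = 1000)) {
  n <- max(length(sequence), length(score), length(annotation),
           length(accessions))
  df <- data.frame(
    scan_id = sprintf("s%03d", seq_len(n)),
    sequence = rep_len(sequence, n), accessions = rep_len(accessions, n),
    annotation = rep_len(annotation, n), score = rep_len(score, n),
    stringsAsFactors = FALSE
  )
  for (ch in c("114", "115", "116", "117")) {
    df[[paste0("i", ch)]] <- rep_len(unname(intensities[ch]), n)
  }
  df$ref_channel <- ref_channel
  for (ch in c("114", "115", "116", "117")) {
    df[[paste0("ratio_", ch)]] <-
      if (ch == ref_channel) NA_real_ else rep_len(unname(ratios[ch]), n)
  }
  df$replicate_id <- as.integer(replicate_id)
  attr(df, "dialect") <- "jpf"
  class(df) <- c("psm_table", "data.frame")
  df
}

# random PSM table over several replicates, for property-style tests
random_psm_table <- function(n = 60, n_replicates = 3, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tabs <- lapply(seq_len(n_replicates), function(r) {
    ratios <- matrix(round(exp(rnorm(3 * n, 0, 0.4)), 3), ncol = 3)
    # sprinkle nulls and zeros
    ratios[sample(length(ratios), ceiling(length(ratios) * 0.08))] <- 0
    tab <- make_psm(
      sequence = replicate(n, paste0(
        paste(sample(LETTERS[1:20], 8, TRUE), collapse = ""), "K")),
      accessions = sprintf("PROT%03d", sample(1:8, n, TRUE)),
      annotation = sample(c("Protein X", "Protein Y (Fragment)",
                            "REVERSED Protein Z"), n, TRUE,
                          prob = c(0.8, 0.1, 0.1)),
      score = round(runif(n, 5, 80), 1), replicate_id = r
    )
    for (ch in c("115", "116", "117")) {
      tab[[paste0("ratio_", ch)]] <- ratios[, match(ch, c("115", "116", "117"))]
    }
    tab
  })
  do.call(rbind, tabs)
}

extdata <- function(name) system.file("extdata", name, package = "cirq")
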