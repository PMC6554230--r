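# run code with a locally fixed RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default rotating channel design
#'
#' Builds a five-replicate design in which the channel-to-condition
#' assignment rotates between replicates to decouple conditions from
#' tags: replicate 1 assigns the conditions to 114..117 in order,
#' replicates 2 and 3 shift the assignment by one and two channels, and
#' replicates 4 and 5 repeat the first assignment. The first condition
#' is the reference.
#'
#' @param n_replicates number of biological replicates.
#' @param conditions four condition names; the first is the reference.
#' @return a `design_table`.
#' @export
default_design <- function(n_replicates = 5,
                           conditions = c("Control", "CsA", "Tac", "VIVIT")) {
  if (length(conditions) != 4L) stop("exactly four conditions are required")
  channels <- c("114", "115", "116", "117")
  shift_for <- function(r) if (r <= 3L) r - 1L else 0L
  rows <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    s <- shift_for(r)
    ch <- channels[((seq_along(conditions) - 1L + s) %% 4L) + 1L]
    data.frame(replicate_id = r, condition = conditions, channel = ch,
               is_reference = as.integer(conditions == conditions[1L]),
               stringsAsFactors = FALSE)
  }))
  design_table(rows)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with defaults
#' representing a small but realistic 4-plex experiment: five replicates
#' with a rotating tag design, multiplicative lognormal peptide noise,
#' an additive background floor in every channel (the driver of ratio
#' compression), occasional missing channels, and small fractions of
#' decoy (`REVERSED`), fragment-annotated and shared peptides.
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein integer range (min, max) of peptides per
#'   protein.
#' @param n_replicates number of biological replicates.
#' @param conditions four condition names, reference first.
#' @param design optional `design_table`; defaults to
#'   [default_design()].
#' @param log2_fold_changes optional matrix (proteins x conditions) of
#'   true log2 fold changes vs the reference; by default each
#'   non-reference (protein, condition) has probability `de_prob` of a
#'   +/-1 log2 change.
#' @param de_prob probability of a unit log2 change when
#'   `log2_fold_changes` is not supplied.
#' @param peptide_noise_sd SD of multiplicative lognormal noise applied
#'   per channel measurement (natural-log scale).
#' @param background_floor additive background counts added to every
#'   channel; pulls observed ratios toward 1.
#' @param base_intensity_meanlog,base_intensity_sdlog lognormal
#'   parameters of per-peptide base reporter intensity (counts).
#' @param missing_channel_prob probability that a channel's reporter is
#'   absent from a given spectrum.
#' @param decoy_fraction,fragment_fraction,shared_peptide_fraction
#'   fractions of peptides annotated `REVERSED`, `Fragment`, or mapped
#'   to two accessions.
#' @param score_true_mean,score_true_sd,score_decoy_mean,score_decoy_sd
#'   parameters of the identification-score distributions (Mascot-like
#'   scale) for target and decoy peptides.
#' @param peak_shape `"centroid"` (reporter sticks) or `"gaussian"`
#'   (profile traces).
#' @param gaussian_sigma range (min, max) of profile peak sigma in Da.
#' @param sample_step profile sampling step in Da.
#' @param seed integer RNG seed; a fixed seed makes the generator fully
#'   deterministic.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 30,
                              peptides_per_protein = c(3, 8),
                              n_replicates = 5,
                              conditions = c("Control", "CsA", "Tac", "VIVIT"),
                              design = NULL,
                              log2_fold_changes = NULL,
                              de_prob = 0.2,
                              peptide_noise_sd = 0.12,
                              background_floor = 50,
                              base_intensity_meanlog = log(5000),
                              base_intensity_sdlog = 0.5,
                              missing_channel_prob = 0.02,
                              decoy_fraction = 0.05,
                              fragment_fraction = 0.05,
                              shared_peptide_fraction = 0.05,
                              score_true_mean = 60, score_true_sd = 15,
                              score_decoy_mean = 18, score_decoy_sd = 8,
                              peak_shape = c("centroid", "gaussian"),
                              gaussian_sigma = c(0.008, 0.012),
                              sample_step = 0.002,
                              seed = 1L) {
  peak_shape <- match.arg(peak_shape)
  probs <- c(missing_channel_prob, decoy_fraction, fragment_fraction,
             shared_peptide_fraction, de_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  if (peptide_noise_sd < 0 || background_floor < 0) {
    stop("'peptide_noise_sd' and 'background_floor' must be >= 0")
  }
  if (is.null(design)) design <- default_design(n_replicates, conditions)
  structure(
    list(n_proteins = as.integer(n_proteins),
         peptides_per_protein = as.integer(peptides_per_protein),
         n_replicates = as.integer(n_replicates),
         conditions = conditions, design = design,
         log2_fold_changes = log2_fold_changes, de_prob = de_prob,
         peptide_noise_sd = peptide_noise_sd,
         background_floor = background_floor,
         base_intensity_meanlog = base_intensity_meanlog,
         base_intensity_sdlog = base_intensity_sdlog,
         missing_channel_prob = missing_channel_prob,
         decoy_fraction = decoy_fraction,
         fragment_fraction = fragment_fraction,
         shared_peptide_fraction = shared_peptide_fraction,
         score_true_mean = score_true_mean, score_true_sd = score_true_sd,
         score_decoy_mean = score_decoy_mean, score_decoy_sd = score_decoy_sd,
         peak_shape = peak_shape, gaussian_sigma = gaussian_sigma,
         sample_step = sample_step, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

random_peptide <- function(n_residues) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
          "N", "P", "Q", "S", "T", "V", "W", "Y")
  paste0(paste(sample(aa, n_residues, replace = TRUE), collapse = ""), "K")
}

#' Simulate a complete 4-plex dataset with known ground truth
#'
#' Generates, per replicate, one MS/MS spectrum and one PSM row per
#' peptide. Each peptide draws a lognormal base intensity; the condition
#' fold changes act through the replicate's channel mapping; every
#' channel measurement gets multiplicative lognormal noise; label
#' impurity mixes the channels through the panel's correction matrix;
#' the additive background floor is added to every channel (this is what
#' compresses observed ratios toward 1); channels drop out at the
#' missing-channel probability. Spectra contain the four reporter
#' regions (sticks or Gaussian profiles) plus a few non-reporter
#' distractor peaks. PSM rows carry the signals and ratios exactly as
#' spectrum-level extraction + correction would produce them.
#'
#' @param config a [simulation_config()].
#' @param panel a [reporter_panel()]; its correction matrix is used for
#'   forward mixing (and is what a consumer should use to un-mix).
#' @return object of class `cirq_simulation`: `spectra` (list per
#'   replicate of `spectrum` lists), `psm_tables` (list per replicate of
#'   `psm_table`), `design`, `panel`, `truth` (protein-level true
#'   ratios, peptide annotations, the config).
#' @export
simulate_dataset <- function(config = simulation_config(),
                             panel = reporter_panel()) {
  with_seed(config$seed, {
    n_cond <- length(config$conditions)
    reference <- config$conditions[1L]

    lfc <- config$log2_fold_changes
    if (is.null(lfc)) {
      lfc <- matrix(0, config$n_proteins, n_cond,
                    dimnames = list(NULL, config$conditions))
      for (j in which(config$conditions != reference)) {
        hit <- stats::runif(config$n_proteins) < config$de_prob
        lfc[hit, j] <- sample(c(-1, 1), sum(hit), replace = TRUE)
      }
    }
    accessions <- sprintf("PROT%03d", seq_len(config$n_proteins))
    rownames(lfc) <- accessions

    truth_proteins <- do.call(rbind, lapply(seq_len(config$n_proteins),
                                            function(i) {
      data.frame(accession = accessions[i], condition = config$conditions,
                 true_ratio = 2 ^ lfc[i, ], stringsAsFactors = FALSE,
                 row.names = NULL)
    }))

    # peptide roster: sequence, parent accession, annotation flags, score
    n_pep <- sample(seq(config$peptides_per_protein[1],
                        config$peptides_per_protein[2]),
                    config$n_proteins, replace = TRUE)
    parent <- rep(seq_len(config$n_proteins), n_pep)
    total <- length(parent)
    sequences <- character(total)
    for (i in seq_len(total)) {
      repeat {
        s <- random_peptide(sample(8:14, 1))
        if (!s %in% sequences[seq_len(i - 1L)]) break
      }
      sequences[i] <- s
    }
    is_decoy <- stats::runif(total) < config$decoy_fraction
    is_fragment <- !is_decoy & stats::runif(total) < config$fragment_fraction
    is_shared <- !is_decoy & !is_fragment &
      stats::runif(total) < config$shared_peptide_fraction

    acc_str <- accessions[parent]
    annotation <- paste0("Protein ", acc_str)
    if (any(is_shared)) {
      other <- vapply(parent[is_shared], function(p) {
        sample(setdiff(seq_len(config$n_proteins), p), 1)
      }, integer(1))
      acc_str[is_shared] <- paste(accessions[parent[is_shared]],
                                  accessions[other], sep = ";")
    }
    annotation[is_fragment] <- paste0(annotation[is_fragment], " (Fragment)")
    annotation[is_decoy] <- paste0("REVERSED ", annotation[is_decoy])

    truth_peptides <- data.frame(
      sequence = sequences, accessions = acc_str,
      parent_accession = accessions[parent],
      is_decoy = is_decoy, is_fragment = is_fragment, is_shared = is_shared,
      stringsAsFactors = FALSE
    )

    channels <- panel$channels
    M <- panel$correction
    spectra <- vector("list", config$n_replicates)
    psm_tables <- vector("list", config$n_replicates)

    for (r in seq_len(config$n_replicates)) {
      map <- design_mapping(config$design, r)
      ref_ch <- design_reference(config$design, r)$channel
      fold <- 2 ^ lfc[, map[channels], drop = FALSE]  # proteins x channels

      base <- stats::rlnorm(total, config$base_intensity_meanlog,
                            config$base_intensity_sdlog)
      score <- pmax(0, stats::rnorm(
        total,
        ifelse(is_decoy, config$score_decoy_mean, config$score_true_mean),
        ifelse(is_decoy, config$score_decoy_sd, config$score_true_sd)))

      rep_spectra <- vector("list", total)
      imat <- matrix(NA_real_, total, length(channels))
      rmat <- matrix(NA_real_, total, length(channels))

      for (k in seq_len(total)) {
        noise <- exp(stats::rnorm(length(channels), 0,
                                  config$peptide_noise_sd))
        counts <- base[k] * fold[parent[k], ] * noise
        heights <- as.numeric(M %*% counts) + config$background_floor
        # a missing channel means the reporter window is empty: no peak at
        # all, hence a zero signal and a null ratio downstream
        heights[stats::runif(length(channels)) <
                  config$missing_channel_prob] <- 0
        scan_id <- sprintf("rep%d_scan%05d", r, k)
        rep_spectra[[k]] <- synth_reporter_spectrum(scan_id, heights, panel,
                                                    config)
        # what extraction + correction recovers from those peak heights
        corr <- as.numeric(solve(M, heights))
        corr[corr < 0] <- 0
        imat[k, ] <- corr
        ref_val <- corr[match(ref_ch, channels)]
        for (j in seq_along(channels)) {
          if (channels[j] == ref_ch) next
          rmat[k, j] <- if (ref_val > 0 && corr[j] > 0) corr[j] / ref_val
          else 0
        }
      }

      tab <- data.frame(
        scan_id = sprintf("rep%d_scan%05d", r, seq_len(total)),
        sequence = sequences, accessions = acc_str,
        annotation = annotation, score = score, stringsAsFactors = FALSE
      )
      for (j in seq_along(channels)) tab[[paste0("i", channels[j])]] <- imat[, j]
      tab$ref_channel <- ref_ch
      for (j in seq_along(channels)) {
        tab[[paste0("ratio_", channels[j])]] <-
          if (channels[j] == ref_ch) NA_real_ else rmat[, j]
      }
      tab$replicate_id <- r
      attr(tab, "dialect") <- "jpf"
      class(tab) <- c("psm_table", "data.frame")

      spectra[[r]] <- rep_spectra
      psm_tables[[r]] <- tab
    }

    structure(
      list(spectra = spectra, psm_tables = psm_tables,
           design = config$design, panel = panel,
           truth = structure(list(proteins = truth_proteins,
                                  peptides = truth_peptides,
                                  log2_fold_changes = lfc,
                                  config = config),
                             class = "ground_truth")),
      class = "cirq_simulation"
    )
  })
}

# one synthetic MS/MS spectrum: four reporter regions + distractor peaks
synth_reporter_spectrum <- function(scan_id, heights, panel, config) {
  if (config$peak_shape == "centroid") {
    mz <- unname(panel$mz)
    ity <- heights
    keep <- ity > 0
    mz <- mz[keep]; ity <- ity[keep]
    n_extra <- sample(2:5, 1)
    mz <- c(mz, stats::runif(n_extra, 200, 900))
    ity <- c(ity, stats::runif(n_extra, 50, 5000))
    spectrum(scan_id, cbind(mz, ity),
             precursor_mz = stats::runif(1, 400, 1200),
             precursor_charge = sample(2:3, 1), mode = "centroid")
  } else {
    sigma <- stats::runif(length(heights), config$gaussian_sigma[1],
                          config$gaussian_sigma[2])
    grids <- lapply(seq_along(heights), function(j) {
      if (heights[j] <= 0) return(NULL)
      center <- unname(panel$mz[j])
      x <- seq(center - panel$tolerance, center + panel$tolerance,
               by = config$sample_step)
      cbind(x, heights[j] * exp(-(x - center)^2 / (2 * sigma[j]^2)))
    })
    pk <- do.call(rbind, grids)
    n_extra <- sample(2:5, 1)
    pk <- rbind(pk, cbind(stats::runif(n_extra, 200, 900),
                          stats::runif(n_extra, 50, 5000)))
    spectrum(scan_id, pk, precursor_mz = stats::runif(1, 400, 1200),
             precursor_charge = sample(2:3, 1), mode = "profile")
  }
}

#' Simulate a spike-in benchmarking scenario
#'
#' Mimics a standard-mixture benchmark: a subset of proteins is spiked
#' at known relative abundances across four conditions N1, UP, DOWN, N2
#' (1.00, 1.25, 0.75, 1.00; i.e. a 25% increase and a 25% decrease
#' against two unchanged channels), while background proteins sit at
#' 1.00 everywhere. N1 is the reference condition.
#'
#' @param n_spike number of spiked proteins.
#' @param n_background number of unchanged background proteins.
#' @param ... further arguments passed to [simulation_config()]
#'   (e.g. `background_floor`, `seed`, `n_replicates`).
#' @param panel a [reporter_panel()].
#' @return a `cirq_simulation`; spiked accessions start with `UPS`.
#' @export
simulate_spikein <- function(n_spike = 12, n_background = 18, ...,
                             panel = reporter_panel()) {
  conditions <- c("N1", "UP", "DOWN", "N2")
  n <- n_spike + n_background
  lfc <- matrix(0, n, 4, dimnames = list(NULL, conditions))
  lfc[seq_len(n_spike), "UP"] <- log2(1.25)
  lfc[seq_len(n_spike), "DOWN"] <- log2(0.75)
  config <- simulation_config(n_proteins = n, conditions = conditions,
                              log2_fold_changes = lfc,
                              decoy_fraction = 0, fragment_fraction = 0,
                              shared_peptide_fraction = 0, ...)
  sim <- simulate_dataset(config, panel)
  # relabel the spiked subset so it is recognizable downstream
  spiked <- sprintf("PROT%03d", seq_len(n_spike))
  ups <- sprintf("UPS%03d", seq_len(n_spike))
  swap <- function(x) {
    i <- match(x, spiked)
    ifelse(is.na(i), x, ups[i])
  }
  for (r in seq_along(sim$psm_tables)) {
    sim$psm_tables[[r]]$accessions <- swap(sim$psm_tables[[r]]$accessions)
  }
  sim$truth$proteins$accession <- swap(sim$truth$proteins$accession)
  sim$truth$peptides$accessions <- swap(sim$truth$peptides$accessions)
  sim$truth$peptides$parent_accession <-
    swap(sim$truth$peptides$parent_accession)
  rownames(sim$truth$log2_fold_changes) <-
    swap(rownames(sim$truth$log2_fold_changes))
  sim
}

#' Simulate an orthogonal reference measurement table
#'
#' Produces paired reference ratios (a Western-blot surrogate) for every
#' (protein, non-reference condition, replicate): the true ratio times
#' multiplicative lognormal noise.
#'
#' @param truth a `ground_truth` (from a `cirq_simulation`).
#' @param noise_sd SD of the lognormal noise (natural-log scale).
#' @param seed RNG seed.
#' @return data.frame `protein`, `condition`, `replicate`, `ratio`.
#' @export
simulate_reference <- function(truth, noise_sd = 0.2, seed = 1L) {
  config <- truth$config
  reference <- config$conditions[1L]
  tp <- truth$proteins[truth$proteins$condition != reference, , drop = FALSE]
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
      data.frame(protein = tp$accession, condition = tp$condition,
                 replicate = r,
                 ratio = tp$true_ratio *
                   exp(stats::rnorm(nrow(tp), 0, noise_sd)),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' @export
print.cirq_simulation <- function(x, ...) {
  n_psm <- sum(vapply(x$psm_tables, nrow, integer(1)))
  cat("Synthetic 4-plex dataset: ",
      length(unique(x$truth$proteins$accession)), " proteins, ",
      length(x$psm_tables), " replicates, ", n_psm, " PSMs\n", sep = "")
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth: ", length(unique(x$proteins$accession)), " proteins x ",
      length(unique(x$proteins$condition)), " conditions; ",
      nrow(x$peptides), " peptides\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' One MGF and one jpf-dialect PSM table per replicate, plus the design
#' table and the protein-level ground truth.
#'
#' @param sim a `cirq_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(sim$psm_tables)) {
    write_mgf(sim$spectra[[r]], file.path(dir, sprintf("rep%d.mgf", r)))
    write_psm_table(sim$psm_tables[[r]],
                    file.path(dir, sprintf("rep%d.jpf", r)), "jpf")
  }
  write_design(sim$design, file.path(dir, "design.tsv"))
  utils::write.table(sim$truth$proteins, file.path(dir, "truth_proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
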