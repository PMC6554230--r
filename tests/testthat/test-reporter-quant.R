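test_that("RSPI sums all in-window peak intensities", {
  p <- identity_panel()
  # no peaks below 120 Da -> all-zero signal
  s <- spectrum("t", cbind(c(250, 300), c(10, 20)))
  expect_equal(unname(extract_rspi(s, p)$raw), c(0, 0, 0, 0))
  # one centroid exactly at the channel-114 position
  s <- spectrum("t", cbind(114.1112, 1000))
  expect_equal(unname(extract_rspi(s, p)$raw), c(1000, 0, 0, 0))
  # two peaks inside the 114 window sum together
  s <- spectrum("t", cbind(c(114.10, 114.12), c(300, 200)))
  expect_equal(extract_rspi(s, p)$raw[["114"]], 500)
  # window boundary is inclusive
  s <- spectrum("t", cbind(114.1112 + 0.05, 77))
  expect_equal(extract_rspi(s, p)$raw[["114"]], 77)
})

test_that("RSPI equals a brute-force scan on random spectra", {
  p <- identity_panel()
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    s <- spectrum("t", cbind(runif(n, 113.9, 117.4), runif(n, 0, 1e4)))
    got <- extract_rspi(s, p)$raw
    # independent O(n * channels) scan
    want <- vapply(p$channels, function(ch) {
      tot <- 0
      for (k in seq_len(nrow(s$peaks))) {
        if (abs(s$peaks[k, 1] - p$mz[[ch]]) <= p$tolerance) {
          tot <- tot + s$peaks[k, 2]
        }
      }
      tot
    }, numeric(1))
    expect_equal(got, want)
  }
})

test_that("RPA integrates a flat trace to height x width", {
  p <- identity_panel()
  h <- 400
  x <- seq(114.1112 - 0.06, 114.1112 + 0.06, by = 0.002)
  s <- spectrum("t", cbind(x, rep(h, length(x))), mode = "profile")
  expect_equal(extract_rpa(s, p)$raw[["114"]], h * 2 * p$tolerance,
               tolerance = 1e-9)
  # empty windows integrate to zero
  expect_equal(extract_rpa(s, p)$raw[["116"]], 0)
})

test_that("RPA matches a dense-grid integration oracle for Gaussian peaks", {
  p <- identity_panel()
  h <- 1234
  sigma <- 0.01
  s <- gaussian_spectrum(c(h, 0, 0, 0), sigma, p, step = 0.002)
  got <- extract_rpa(s, p)$raw[["114"]]
  # oracle: trapezoid on a 1e-4 Da grid of the same analytic trace
  xg <- seq(114.1112 - p$tolerance, 114.1112 + p$tolerance, by = 1e-4)
  yg <- h * exp(-(xg - 114.1112)^2 / (2 * sigma^2))
  oracle <- sum(diff(xg) * (yg[-length(yg)] + yg[-1]) / 2)
  expect_equal(got, oracle, tolerance = 0.005)
  # and both agree with the closed form h * sigma * sqrt(2*pi)
  expect_equal(got, h * sigma * sqrt(2 * pi), tolerance = 0.005)
})

test_that("RPA on centroid data warns and degenerates to zero area", {
  p <- identity_panel()
  s <- stick_spectrum(c(1000, 800, 600, 400), p)
  expect_warning(sig <- extract_rpa(s, p), "centroid")
  expect_equal(unname(sig$raw), c(0, 0, 0, 0))
})

test_that("isotope correction inverts the declared mixing model", {
  p <- identity_panel()
  # identity correction leaves signals unchanged
  sig <- channel_signal(c(`114` = 94, `115` = 6, `116` = 0, `117` = 0))
  expect_equal(correct_isotopes(sig, p)$corrected, sig$raw)

  # 6% of 114 leaks into 115: observed (94, 6, 0, 0) -> true (100, 0, 0, 0)
  M <- diag(4); M[2, 1] <- 0.06; M[1, 1] <- 0.94
  dimnames(M) <- list(p$channels, p$channels)
  p2 <- reporter_panel(correction = M)
  out <- correct_isotopes(sig, p2)$corrected
  expect_equal(unname(out), c(100, 0, 0, 0), tolerance = 1e-9)

  # all-zero raw stays all-zero
  z <- channel_signal(setNames(rep(0, 4), p$channels))
  expect_equal(unname(correct_isotopes(z, p2)$corrected), rep(0, 4))
})

test_that("correction round-trips forward mixing for random true signals", {
  p <- impure_panel()
  M <- p$correction
  set.seed(21)
  for (i in 1:25) {
    true <- runif(4, 0, 1e4)
    observed <- as.numeric(M %*% true)
    sig <- channel_signal(setNames(observed, p$channels))
    expect_equal(unname(correct_isotopes(sig, p)$corrected), true,
                 tolerance = 1e-9)
  }
})

test_that("ill-conditioned correction matrices are refused", {
  M <- matrix(c(0.5, 0.5, 0, 0,
                0.5, 0.5, 0, 0,
                0, 0, 1, 0,
                0, 0, 0, 1), 4, 4)
  dimnames(M) <- list(c("114", "115", "116", "117"),
                      c("114", "115", "116", "117"))
  p <- reporter_panel(correction = M)
  sig <- channel_signal(setNames(c(1, 1, 1, 1), p$channels))
  expect_error(correct_isotopes(sig, p), "ill-conditioned|singular")
})

test_that("ratios divide by the reference and null out zero signals", {
  sig <- channel_signal(setNames(c(200, 100, 400, 100),
                                 c("114", "115", "116", "117")))
  sig$corrected <- sig$raw
  rv <- compute_ratios(sig, "114")
  expect_equal(rv$ratios, c(`115` = 0.5, `116` = 2.0, `117` = 0.5))

  sig$corrected[["114"]] <- 0
  expect_true(all(is.na(compute_ratios(sig, "114")$ratios)))

  sig$corrected <- setNames(c(300, 300, 0, 300), names(sig$raw))
  rv <- compute_ratios(sig, "114")
  expect_equal(rv$ratios[["115"]], 1)
  expect_true(is.na(rv$ratios[["116"]]))
  expect_error(compute_ratios(sig, "118"), "not in the panel")
})

test_that("quantify_spectrum composes extract -> correct -> ratio", {
  p <- identity_panel()
  q <- quantify_spectrum(stick_spectrum(rep(1000, 4), p), p, "RSPI", "114")
  expect_equal(unname(q$ratios$ratios), c(1, 1, 1))
  q <- quantify_spectrum(stick_spectrum(1000 * c(1, 1.25, 0.75, 1), p),
                         p, "RSPI", "114")
  expect_equal(q$ratios$ratios, c(`115` = 1.25, `116` = 0.75, `117` = 1),
               tolerance = 1e-9)
})

test_that("ratios are invariant under global intensity scaling", {
  p <- impure_panel()
  set.seed(31)
  heights <- runif(4, 100, 5000)
  for (method in c("RSPI", "RPA")) {
    mk <- function(k) {
      if (method == "RSPI") stick_spectrum(k * heights, p)
      else gaussian_spectrum(k * heights, 0.01, p)
    }
    r1 <- quantify_spectrum(mk(1), p, method, "114")$ratios$ratios
    r7 <- quantify_spectrum(mk(7.3), p, method, "114")$ratios$ratios
    expect_equal(r7, r1, tolerance = 1e-9)
  }
})

test_that("RSPI is width-invariant while RPA tracks peak width", {
  p <- identity_panel()
  h <- c(1000, 1000, 0, 0)            # equal heights ...
  sigma <- c(0.008, 0.016, 0.01, 0.01) # ... twice the width on channel 115
  prof <- gaussian_spectrum(h, sigma, p, step = 5e-4)

  # apex-centroided view of the same peaks: RSPI recovers the height ratio
  apex <- stick_spectrum(h, p)
  r_rspi <- quantify_spectrum(apex, p, "RSPI", "114")$ratios$ratios
  expect_equal(r_rspi[["115"]], 1, tolerance = 1e-9)

  # RPA's ratio is inflated by the width ratio instead
  r_rpa <- quantify_spectrum(prof, p, "RPA", "114")$ratios$ratios
  expect_equal(r_rpa[["115"]], sigma[2] / sigma[1], tolerance = 0.01)
})

test_that("quantify_spectra builds a jpf-layout table keyed by scan id", {
  p <- identity_panel()
  spectra <- list(stick_spectrum(c(100, 200, 300, 400), p, scan_id = "a"),
                  stick_spectrum(c(100, 0, 100, 100), p, scan_id = "b"))
  ids <- data.frame(scan_id = c("a", "b"), sequence = c("AAK", "CCK"),
                    accessions = c("P1", "P2"), annotation = "Protein",
                    score = c(40, 50), stringsAsFactors = FALSE)
  tab <- quantify_spectra(spectra, ids, p, "RSPI", "114", replicate_id = 2)
  expect_s3_class(tab, "psm_table")
  expect_equal(tab$ratio_115, c(2, 0))  # zero channel recorded as 0.0
  expect_equal(tab$ratio_117, c(4, 1))
  expect_equal(tab$replicate_id, c(2L, 2L))
  expect_error(quantify_spectra(spectra, transform(ids, scan_id = c("a", "zz")),
                                p, "RSPI", "114"), "no spectrum")
})
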