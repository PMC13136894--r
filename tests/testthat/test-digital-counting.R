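test_that("reactor detection recovers the lattice with high recall and precision", {
  expect_equal(nrow(detect_reactors(matrix(0, 50, 50), 4)), 0)

  p <- frad_array_params(rows = 40, cols = 25, positive_fraction = 0.005)
  arr <- gen_frad_images(p, seed = 17)
  tab <- detect_reactors(arr$fill, expected_radius_px = 4)
  truth <- arr$truth$reactors
  # match each detection to nearest true reactor within half a pitch
  d2 <- outer(tab$row, truth$row, "-")^2 + outer(tab$col, truth$col, "-")^2
  nearest <- sqrt(apply(d2, 1, min))
  matched_true <- unique(apply(d2, 1, which.min)[nearest < 6])
  recall <- length(matched_true) / nrow(truth)
  precision <- sum(nearest < 6) / nrow(tab)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
  # sub-pixel centroids: mean localization error well under a pixel
  expect_lt(mean(nearest[nearest < 6]), 0.5)
})

test_that("intensity extraction reproduces the generating components", {
  # constant channel: every reactor reads the constant
  p <- frad_array_params(rows = 5, cols = 5, pixel_noise_sd = 0)
  arr <- gen_frad_images(p, seed = 2)
  tab <- detect_reactors(arr$fill, 4)
  const <- matrix(42, nrow(arr$fill), ncol(arr$fill))
  tab2 <- extract_reactor_intensities(tab, list(ch1 = const))
  expect_equal(tab2$intensity_ch1, rep(42, nrow(tab2)))

  # generator positives/negatives: extracted means near the component means
  p2 <- frad_array_params(rows = 20, cols = 20, positive_fraction = 0.1)
  arr2 <- gen_frad_images(p2, seed = 3)
  t2 <- detect_reactors(arr2$fill, 4)
  t2 <- extract_reactor_intensities(t2, list(fill = arr2$fill,
                                             ch1 = arr2$channels[[1]]))
  hi <- t2$intensity_ch1[t2$intensity_ch1 > 500]
  lo <- t2$intensity_ch1[t2$intensity_ch1 <= 500]
  expect_equal(length(hi), 40)  # quota: 0.1 * 400
  expect_lt(abs(mean(hi) - 1000), 3 * 50 / sqrt(length(hi)) + 2)
  expect_lt(abs(mean(lo) - 100), 3 * 10 / sqrt(length(lo)) + 2)
})

test_that("trimmed Gaussian threshold isolates the negative mode", {
  set.seed(4)
  pure <- rnorm(2000, 100, 10)
  m <- fit_intensity_threshold(pure, k = 3)
  expect_equal(m$threshold, 130, tolerance = 0.02)
  # ~0.13% of a pure negative population exceeds mu + 3 sigma
  expect_lt(mean(pure > m$threshold), 5e-3)
  # per-field default: k = qnorm(1 - alpha/n), expected false calls ~ alpha
  mauto <- fit_intensity_threshold(pure, mixture_diagnostic = FALSE)
  expect_equal(mauto$k, qnorm(1 - 0.05 / 2000), tolerance = 1e-6)
  expect_lte(sum(pure > mauto$threshold), 2)

  # 95:5 bimodal mixture: no positive is missed and the false-positive rate
  # stays at the 3-sigma tail of the negative component (~0.13%)
  truth <- rep(c(FALSE, TRUE), times = c(1900, 100))
  x <- c(rnorm(1900, 100, 10), rnorm(100, 1000, 50))
  m2 <- fit_intensity_threshold(x, k = 3)
  expect_equal(sum(truth & x <= m2$threshold), 0)       # no false negatives
  expect_lt(mean(!truth & x > m2$threshold), 4e-3)
  # threshold insensitive (within 1%) to the 5% positive contamination
  expect_lt(abs(m2$threshold - m$threshold) / m$threshold, 0.01)
  # two-component diagnostic resolves the modes, and posterior assignment
  # under the fitted mixture classifies against truth almost perfectly
  expect_false(is.null(m2$mixture))
  expect_equal(sort(m2$mixture$means), c(100, 1000), tolerance = 0.05)
  mx <- m2$mixture
  post_pos <- mx$weights[2] * dnorm(x, mx$means[2], mx$sds[2]) >
    mx$weights[1] * dnorm(x, mx$means[1], mx$sds[1])
  if (mx$means[1] > mx$means[2]) post_pos <- !post_pos
  expect_lt(mean(post_pos != truth), 1e-3)

  expect_error(fit_intensity_threshold(rnorm(10)), ">= 50")
})

test_that("false-positive filters remove debris and close pairs, and are conjunctive", {
  # array with debris: candidates detected in the EXPRESSION channel include
  # debris blobs, which the ROI (fill-membership) filter must remove
  p <- frad_array_params(rows = 10, cols = 25, positive_fraction = 0.02,
                         debris_n = 6, debris_intensity_range = c(800, 1500))
  arr <- gen_frad_images(p, seed = 23)
  cand <- detect_reactors(arr$channels[[1]], 4)   # positives + debris
  expect_gt(nrow(cand), 5)
  cand <- extract_reactor_intensities(cand, list(fill = arr$fill,
                                                 ch1 = arr$channels[[1]]))
  # fill model must come from genuine reactors (fill-channel detections)
  rt <- detect_reactors(arr$fill, 4)
  rt <- extract_reactor_intensities(rt, list(fill = arr$fill))
  fill_model <- fit_intensity_threshold(rt$intensity_fill, k = 5,
                                        mixture_diagnostic = FALSE)
  flt <- filter_false_positives(cand, fill_model, min_separation_px = 0.8 * 12)
  deb <- arr$truth$debris
  for (i in seq_len(nrow(deb))) {
    d <- sqrt((flt$row - deb$row[i])^2 + (flt$col - deb$col[i])^2)
    j <- which.min(d)
    if (d[j] < 3) expect_false(flt$roi_pass[j])   # debris candidate rejected
  }
  # true positives keep all flags
  pos_truth <- arr$truth$reactors[arr$truth$positive[, 1], ]
  for (i in seq_len(nrow(pos_truth))) {
    d <- sqrt((flt$row - pos_truth$row[i])^2 + (flt$col - pos_truth$col[i])^2)
    expect_true(flt$pass_all[which.min(d)])
  }

  # proximity: both members of a close pair are dropped
  tab <- data.frame(id = 1:3, row = c(10, 14, 60), col = c(10, 10, 60),
                    radius = 4, intensity_fill = c(500, 500, 500),
                    intensity_ch1 = c(100, 100, 100))
  fm <- structure(list(mu_neg = 500, sigma_neg = 30, weight_neg = 1,
                       threshold = 650, k = 5), class = "intensity_model")
  out <- filter_false_positives(tab, fm, min_separation_px = 9.6)
  expect_equal(out$proximity_pass, c(FALSE, FALSE, TRUE))
  expect_equal(out$pass_all, c(FALSE, FALSE, TRUE))
  # conjunctive flags: pass_all equals the AND of the three flags
  expect_equal(out$pass_all,
               out$intensity_pass & out$roi_pass & out$proximity_pass)

  # clean array: nothing removed
  clean <- gen_frad_images(frad_array_params(rows = 8, cols = 8), seed = 5)
  ct <- detect_reactors(clean$fill, 4)
  ct <- extract_reactor_intensities(ct, list(fill = clean$fill,
                                             ch1 = clean$channels[[1]]))
  cfm <- fit_intensity_threshold(ct$intensity_fill, k = 5,
                                 mixture_diagnostic = FALSE)
  cflt <- filter_false_positives(ct, cfm, min_separation_px = 9.6)
  expect_true(all(cflt$pass_all))
})

test_that("positive-fraction counting applies Wilson intervals per replicate", {
  tab <- data.frame(id = 1:1000, row = seq(0, 999) * 20, col = 0, radius = 4,
                    intensity_fill = 500,
                    intensity_ch1 = c(rep(100, 995), rep(1000, 5)))
  tab$intensity_pass <- tab$roi_pass <- tab$proximity_pass <- tab$pass_all <- TRUE
  model <- structure(list(mu_neg = 100, sigma_neg = 10, weight_neg = 1,
                          threshold = 130, k = 3), class = "intensity_model")
  dc <- count_positive_fraction(tab, "ch1", model)
  expect_equal(dc$fraction, 0.005)
  expect_equal(unname(dc$ci),
               unname(wilson_ci(5, 1000)[c("lower", "upper")]))
  tab$intensity_ch1 <- 100
  expect_equal(count_positive_fraction(tab, "ch1", model)$fraction, 0)
})

test_that("end-to-end fraction recovery: 95% CIs cover truth in >= 90% of runs", {
  fractions <- c(0, 0.002, 0.01, 0.05)
  covered <- logical(0)
  for (f in fractions) {
    for (s in 1:8) {
      dc <- count_array(f, seed = 2000 + 13 * s + round(1e4 * f))
      covered <- c(covered,
                   dc$ci["lower"] <= f && f <= dc$ci["upper"])
    }
  }
  expect_gte(mean(covered), 0.9)
})

test_that("counting is invariant to affine rescaling and to the other channel", {
  p <- frad_array_params(rows = 10, cols = 25, n_channels = 2,
                         positive_fraction = c(0.02, 0.04))
  arr <- gen_frad_images(p, seed = 31)
  tab <- detect_reactors(arr$fill, 4)
  base_tab <- extract_reactor_intensities(tab, list(fill = arr$fill,
                                                    ch1 = arr$channels[[1]],
                                                    ch2 = arr$channels[[2]]))
  fm <- fit_intensity_threshold(base_tab$intensity_fill, k = 5,
                                mixture_diagnostic = FALSE)
  count_ch <- function(tab, ch) {
    m <- fit_intensity_threshold(tab[[paste0("intensity_", ch)]],
                                 mixture_diagnostic = FALSE)
    flt <- filter_false_positives(tab, fm, min_separation_px = 9.6)
    count_positive_fraction(flt, ch, m)$fraction
  }
  f1 <- count_ch(base_tab, "ch1")
  # affine rescale of the expression channel, threshold refitted: same calls
  resc <- base_tab
  resc$intensity_ch1 <- 3.7 * resc$intensity_ch1 + 55
  expect_equal(count_ch(resc, "ch1"), f1)
  # permuting channel 2 leaves channel 1 calls unchanged
  perm <- base_tab
  set.seed(1)
  perm$intensity_ch2 <- sample(perm$intensity_ch2)
  expect_equal(count_ch(perm, "ch1"), f1)
})

test_that("pseudo-positive floor and concentration bracketing follow their rules", {
  expect_equal(pseudo_positive_threshold(c(0.02, 0.02, 0.02)), 0.02)
  expect_equal(pseudo_positive_threshold(c(0.01, 0.02, 0.03)), 0.05)
  expect_error(pseudo_positive_threshold(0.01), ">= 2")

  # crossing between 0.5 and 1 (concentration units nM)
  br <- bracket_threshold_concentration(c(0.25, 0.5, 1, 2),
                                        c(0.0001, 0.0002, 0.004, 0.02),
                                        theta_pp = 0.0005)
  expect_equal(br$c_low, 0.5)
  expect_equal(br$c_high, 1)
  # crossing between 25 and 50
  br2 <- bracket_threshold_concentration(c(5, 25, 50, 100),
                                         c(0, 0.0001, 0.003, 0.01),
                                         theta_pp = 0.0005)
  expect_equal(c(br2$c_low, br2$c_high), c(25, 50))
  # all above: open-ended below the lowest tested concentration
  br3 <- bracket_threshold_concentration(c(1, 2), c(0.1, 0.2), theta_pp = 0.01)
  expect_equal(c(br3$c_low, br3$c_high), c(-Inf, 1))
  # none above: open-ended upwards
  br4 <- bracket_threshold_concentration(c(1, 2), c(0, 0), theta_pp = 0.01)
  expect_equal(c(br4$c_low, br4$c_high), c(2, Inf))
})

test_that("Poisson occupancy converts concentration to per-reactor statistics", {
  expect_equal(expected_occupancy(0)$lambda, 0)
  expect_equal(expected_occupancy(0)$p_occupied, 0)
  occ <- expected_occupancy(1.2e-15, reactor_volume = 50e-15)
  expect_equal(occ$lambda, 1.2e-15 * 50e-15 * 6.02214076e23, tolerance = 1e-12)
  expect_equal(occ$lambda, 3.6e-5, tolerance = 0.01)
  # P(>=1) ~ lambda for lambda << 1
  expect_equal(occ$p_occupied / occ$lambda, 1, tolerance = 1e-4)
})
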