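test_that("segmentation finds isolated droplets and rejects merged blobs", {
  expect_identical(segment_droplets(matrix(5, 64, 64)), list())

  p <- droplet_image_params(size = 256, n_droplets = 10, radius_range = c(6, 10),
                            pc = 15, outside_mean = 25, noise_sd = 1)
  im <- gen_droplet_image(p, seed = 21)
  masks <- segment_droplets(im$image)
  expect_length(masks, 10)
  # each true centre matched by a detected centroid within 1 px
  cent <- t(vapply(masks, `[[`, numeric(2), "centroid"))
  for (i in seq_len(10)) {
    d <- sqrt((cent[, 1] - im$truth$row[i])^2 + (cent[, 2] - im$truth$col[i])^2)
    expect_lt(min(d), 1)
  }

  # two overlapping disks merge into a non-circular region: rejected
  img <- matrix(10, 120, 120)
  rr <- row(img) - 1; cc <- col(img) - 1
  img[(rr - 60)^2 + (cc - 50)^2 <= 100] <- 200
  img[(rr - 60)^2 + (cc - 66)^2 <= 100] <- 200
  merged <- segment_droplets(img, circularity_min = 0.8)
  expect_length(merged, 0)
  # ... but accepted with the filter relaxed
  expect_length(segment_droplets(img, circularity_min = 0.2), 1)
})

test_that("partition coefficient is exact on noiseless synthetic truth", {
  # uniform image over a constructed mask: PC = 1
  img <- matrix(50, 80, 80)
  rr <- row(img) - 1; cc <- col(img) - 1
  pix <- which((rr - 40)^2 + (cc - 40)^2 <= 64, arr.ind = TRUE)
  mask <- structure(list(pixels = unname(pix) - 1L, centroid = c(40, 40),
                         radius = 8, circularity = 1, area = nrow(pix)),
                    class = "droplet_mask")
  pm <- partition_coefficient(img, mask)
  expect_equal(pm$pc_raw, 1)

  # generator truth PC = 19.1, no noise: recovered exactly
  p <- droplet_image_params(size = 200, n_droplets = 5, radius_range = c(7, 10),
                            pc = 19.1, outside_mean = 25, noise_sd = 0)
  im <- gen_droplet_image(p, seed = 2)
  res <- quantify_droplets(im$image)
  expect_equal(nrow(res), 5)
  expect_equal(res$pc_raw, rep(19.1, 5))
})

test_that("PC recovery stays within 10% at 5% noise across the reported PC range", {
  for (pc_true in c(19.1, 93.4, 1093)) {
    p <- droplet_image_params(size = 256, n_droplets = 10,
                              radius_range = c(6, 10), pc = pc_true,
                              outside_mean = 25, noise_sd = 0.05 * 25)
    im <- gen_droplet_image(p, seed = 31 + round(pc_true))
    res <- quantify_droplets(im$image)
    expect_gte(nrow(res), 8)
    rel_err <- abs(mean(res$pc_raw) - pc_true) / pc_true
    expect_lt(rel_err, 0.1)
  }
})

test_that("PC estimation is invariant to a global intensity scale", {
  p <- droplet_image_params(size = 160, n_droplets = 4, pc = 30,
                            outside_mean = 25, noise_sd = 1)
  im <- gen_droplet_image(p, seed = 5)
  a <- quantify_droplets(im$image)
  b <- quantify_droplets(im$image * 7.3)
  expect_equal(a$pc_raw, b$pc_raw, tolerance = 1e-12)
})

test_that("eroded-empty masks and non-positive backgrounds raise errors", {
  img <- matrix(1, 40, 40)
  tiny <- structure(list(pixels = cbind(20L, 20L), centroid = c(20, 20),
                         radius = 1, circularity = 1, area = 1),
                    class = "droplet_mask")
  expect_error(partition_coefficient(img, tiny, erosion_px = 3), "empty")
  expect_error(partition_coefficient(matrix(0, 40, 40), tiny, erosion_px = 0),
               "<= 0")
})

test_that("tail fit recovers exact and Poisson-noised lifetimes", {
  # exact exponential counts: tau to numerical precision
  t <- seq(0.04, 20, by = 0.08)
  exact <- data.frame(time_ns = t, counts = 1e5 * exp(-t / 2.5))
  fit <- fit_flim_lifetime(exact)
  expect_equal(fit$tau, 2.5, tolerance = 1e-9)

  # multinomially sampled decays: unbiased within 3 s.e. over seeds
  taus <- vapply(1:30, function(s)
    fit_flim_lifetime(gen_flim_decay(3, 1e6, 0.08, 256, seed = 100 + s))$tau,
    numeric(1))
  se <- stats::sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - 3), 3 * se)

  # bi-exponential input fits but is flagged by the goodness statistic
  bi <- data.frame(time_ns = t,
                   counts = round(8e4 * exp(-t / 1) + 2e4 * exp(-t / 8)))
  bifit <- fit_flim_lifetime(bi)
  expect_gt(bifit$reduced_chisq, 1.5)
  expect_lt(fit$reduced_chisq, 1.5)

  expect_error(fit_flim_lifetime(data.frame(time_ns = t,
                                            counts = rep(0, length(t)))),
               "nonzero")
})

test_that("lifetime correction rescales PC by the quantum-yield ratio", {
  expect_equal(flim_correct_pc(100, 3, 3), 100)
  expect_equal(flim_correct_pc(100, 4, 3.2), 80)
  expect_error(flim_correct_pc(100, -1, 3), "tau_in")

  # round trip: render the raw (intensity) PC including the quantum-yield
  # factor tau_in/tau_out, measure, correct, recover the true PC
  pc_true <- 50; tau_in <- 4; tau_out <- 3
  p <- droplet_image_params(size = 160, n_droplets = 5,
                            pc = pc_true * tau_in / tau_out,
                            outside_mean = 25, noise_sd = 0)
  im <- gen_droplet_image(p, seed = 3)
  res <- quantify_droplets(im$image, tau_in = tau_in, tau_out = tau_out)
  expect_equal(res$pc_corrected, rep(pc_true, 5), tolerance = 1e-12)
})

test_that("FRET efficiency identities and monotonicity hold", {
  expect_equal(fret_efficiency(0, 10), 0)
  expect_equal(fret_efficiency(10, 10, gamma = 1), 0.5)
  expect_equal(fret_efficiency(84.9, 15.1, gamma = 1), 0.849)
  expect_error(fret_efficiency(0, 0), "undefined")

  fa <- seq(0.5, 50, length.out = 20)
  # strictly increasing in F_A, decreasing in F_D and gamma
  expect_true(all(diff(fret_efficiency(fa, 10, 1)) > 0))
  expect_true(all(diff(fret_efficiency(10, fa, 1)) < 0))
  gs <- seq(0.2, 5, length.out = 20)
  e_g <- vapply(gs, function(g) fret_efficiency(10, 10, g), numeric(1))
  expect_true(all(diff(e_g) < 0))
})

test_that("gamma calibration inverts the reference-efficiency relation", {
  # single measurement at E_ref = 0.5: gamma = F_A / F_D
  expect_equal(estimate_gamma(30, 20, 0.5), 1.5, tolerance = 1e-8)

  # round trip with gamma_true = 2 over heterogeneous intensities
  set.seed(8)
  fd <- runif(10, 10, 100)
  g_true <- 2; e_true <- 0.7
  fa <- e_true / (1 - e_true) * g_true * fd   # each pair has E = 0.7 exactly
  expect_equal(estimate_gamma(fa, fd, 0.7), 2, tolerance = 1e-8)
  # recovered gamma reproduces the double-labelled control efficiency
  g <- estimate_gamma(fa, fd, 0.881)
  expect_equal(mean(fret_efficiency(fa, fd, g)), 0.881, tolerance = 1e-9)
  expect_error(estimate_gamma(10, 10, 1.2), "e_reference")
})
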