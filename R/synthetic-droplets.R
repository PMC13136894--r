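#' Parameters for the synthetic droplet-image generator
#'
#' Describes a field of view containing phase-separated condensate droplets
#' with prescribed partition coefficients (PC): each droplet's noiseless
#' interior intensity is `pc * outside_mean`, emulating a fluorescence image
#' in which a labelled species is enriched inside the dense phase.
#'
#' @param size image side length in pixels (square image).
#' @param n_droplets number of droplets to place.
#' @param radius_range length-2 numeric, min/max droplet radius in pixels
#'   (minimum 2 px).
#' @param pc true partition coefficient(s), recycled to `n_droplets`; must be
#'   positive (1 means no enrichment).
#' @param outside_mean mean intensity of the dilute phase (arbitrary units).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param tau_in,tau_out optional fluorescence lifetimes (ns) inside/outside
#'   droplets, carried as paired ground truth for lifetime-correction tests.
#' @return an object of class `droplet_image_params`.
#' @seealso [gen_droplet_image()]
#' @export
droplet_image_params <- function(size = 256L, n_droplets = 10L,
                                 radius_range = c(6, 12), pc = 10,
                                 outside_mean = 25, noise_sd = 0,
                                 tau_in = NULL, tau_out = NULL) {
  assert_scalar_num(size, "size", lower = 16)
  assert_scalar_num(n_droplets, "n_droplets", lower = 1)
  stopifnot(length(radius_range) == 2L, all(radius_range >= 2),
            radius_range[1] <= radius_range[2])
  if (any(pc <= 0)) stop("`pc` must be > 0", call. = FALSE)
  assert_scalar_num(outside_mean, "outside_mean", lower = 0, strict_lower = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (!is.null(tau_in)) assert_scalar_num(tau_in, "tau_in", lower = 0, strict_lower = TRUE)
  if (!is.null(tau_out)) assert_scalar_num(tau_out, "tau_out", lower = 0, strict_lower = TRUE)
  structure(list(size = as.integer(size), n_droplets = as.integer(n_droplets),
                 radius_range = as.numeric(radius_range),
                 pc = rep_len(as.numeric(pc), n_droplets),
                 outside_mean = outside_mean, noise_sd = noise_sd,
                 tau_in = tau_in, tau_out = tau_out),
            class = "droplet_image_params")
}

#' Generate a synthetic droplet image with ground truth
#'
#' Places non-overlapping flat-top circular droplets on a uniform dilute-phase
#' background and adds Gaussian noise. The noiseless interior mean of droplet
#' i is exactly `pc[i] * outside_mean`, so downstream partition-coefficient
#' estimators can be scored against embedded truth.
#'
#' @param params a [droplet_image_params()] object.
#' @param seed integer seed; output is bit-reproducible per (params, seed).
#' @param max_tries placement attempts per droplet before giving up.
#' @return list with components
#'   \describe{
#'     \item{image}{numeric matrix of intensities (rows x cols).}
#'     \item{labels}{integer matrix, 0 = background, i = droplet i.}
#'     \item{truth}{data.frame with one row per droplet: id, centre row/col
#'       (0-based), radius, true pc, and tau_in/tau_out when supplied.}
#'   }
#' @examples
#' p <- droplet_image_params(size = 128, n_droplets = 4, pc = 20,
#'                           outside_mean = 25, noise_sd = 0)
#' im <- gen_droplet_image(p, seed = 1)
#' mean(im$image[im$labels == 1]) / mean(im$image[im$labels == 0])
#' @export
gen_droplet_image <- function(params, seed, max_tries = 2000L) {
  stopifnot(inherits(params, "droplet_image_params"))
  with_local_seed(seed, {
    n <- params$n_droplets
    size <- params$size
    radii <- stats::runif(n, params$radius_range[1], params$radius_range[2])
    centres <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (k in seq_len(max_tries)) {
        cand <- stats::runif(2, radii[i] + 2, size - radii[i] - 3)
        ok <- TRUE
        if (i > 1L) {
          d <- sqrt(rowSums((centres[seq_len(i - 1L), , drop = FALSE] -
                               matrix(cand, i - 1L, 2, byrow = TRUE))^2))
          ok <- all(d > radii[i] + radii[seq_len(i - 1L)] + 3)
        }
        if (ok) {
          centres[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place all droplets without overlap; ",
             "reduce n_droplets or radii", call. = FALSE)
    }
    rr <- matrix(rep(seq_len(size) - 1, size), size, size)         # row index
    cc <- matrix(rep(seq_len(size) - 1, each = size), size, size)  # col index
    image <- matrix(params$outside_mean, size, size)
    labels <- matrix(0L, size, size)
    for (i in seq_len(n)) {
      inside <- (rr - centres[i, 1])^2 + (cc - centres[i, 2])^2 <= radii[i]^2
      image[inside] <- params$pc[i] * params$outside_mean
      labels[inside] <- i
    }
    if (params$noise_sd > 0)
      image <- image + matrix(stats::rnorm(size * size, 0, params$noise_sd),
                              size, size)
    truth <- data.frame(id = seq_len(n), row = centres[, 1], col = centres[, 2],
                        radius = radii, pc = params$pc)
    if (!is.null(params$tau_in)) truth$tau_in <- params$tau_in
    if (!is.null(params$tau_out)) truth$tau_out <- params$tau_out
    list(image = image, labels = labels, truth = truth)
  })
}

#' Generate a synthetic fluorescence-lifetime decay histogram
#'
#' Distributes `n_photons` over time bins according to a single-exponential
#' decay `exp(-t / lifetime)` truncated to the acquisition window, as recorded
#' by time-correlated single photon counting. Counts are drawn multinomially,
#' so the total photon number is exact.
#'
#' @param lifetime fluorescence lifetime tau in ns (> 0; `Inf` gives uniform
#'   counts across the window).
#' @param n_photons total photons to distribute (>= 1).
#' @param bin_width bin width in ns.
#' @param n_bins number of bins (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `time_ns` (bin midpoint) and `counts`.
#' @examples
#' h <- gen_flim_decay(3, 1e5, 0.08, 256, seed = 1)
#' @export
gen_flim_decay <- function(lifetime, n_photons, bin_width, n_bins, seed) {
  assert_scalar_num(n_photons, "n_photons", lower = 1)
  assert_scalar_num(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  if (!is.numeric(n_bins) || n_bins < 1)
    stop("decay window must contain at least one bin", call. = FALSE)
  if (!is.numeric(lifetime) || length(lifetime) != 1L || lifetime <= 0)
    stop("`lifetime` must be > 0", call. = FALSE)
  n_bins <- as.integer(n_bins)
  edges <- (0:n_bins) * bin_width
  if (is.infinite(lifetime)) {
    p <- rep(1 / n_bins, n_bins)
  } else {
    p <- exp(-edges[-(n_bins + 1)] / lifetime) - exp(-edges[-1] / lifetime)
    p <- p / sum(p)
  }
  counts <- with_local_seed(seed, as.vector(stats::rmultinom(1, n_photons, p)))
  data.frame(time_ns = edges[-(n_bins + 1)] + bin_width / 2, counts = counts)
}
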