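#' Parameters for the synthetic femtoliter reactor-array generator
#'
#' Describes a rectangular lattice of sealed femtoliter reactors imaged in a
#' fill channel (a dye present in every reactor, used for detection) plus one
#' or more expression channels in which each reactor draws its intensity from
#' either a negative (no expression) or positive (expressed protein) Gaussian
#' component. Off-lattice debris objects are bright in the expression channels
#' but absent from the fill channel, providing unambiguous truth for the
#' ROI-comparison and proximity false-positive filters.
#'
#' Per-channel arguments (`neg_mean`, `neg_sd`, `pos_mean`, `pos_sd`,
#' `positive_fraction`) are recycled to `n_channels`.
#'
#' @param rows,cols lattice dimensions.
#' @param pitch_px centre-to-centre reactor spacing in pixels
#'   (must exceed `2 * radius_px`).
#' @param radius_px reactor radius in pixels.
#' @param n_channels number of expression channels.
#' @param neg_mean,neg_sd negative-component intensity distribution.
#' @param pos_mean,pos_sd positive-component intensity distribution
#'   (`pos_mean` must exceed `neg_mean` channel-wise).
#' @param positive_fraction true fraction of expressing reactors per channel,
#'   in \[0, 1\].
#' @param debris_n number of off-lattice debris objects.
#' @param debris_intensity_range length-2 range of debris intensities.
#' @param fill_mean,fill_sd per-reactor intensity distribution of the fill
#'   channel.
#' @param pixel_noise_sd additive Gaussian pixel noise applied to every
#'   channel.
#' @return an object of class `frad_array_params`.
#' @seealso [gen_frad_images()]
#' @export
frad_array_params <- function(rows = 40L, cols = 25L, pitch_px = 12L,
                              radius_px = 4, n_channels = 1L,
                              neg_mean = 100, neg_sd = 10,
                              pos_mean = 1000, pos_sd = 50,
                              positive_fraction = 0.005,
                              debris_n = 0L, debris_intensity_range = c(500, 1500),
                              fill_mean = 500, fill_sd = 30,
                              pixel_noise_sd = 2) {
  stopifnot(rows >= 1, cols >= 1, n_channels >= 1)
  assert_scalar_num(pitch_px, "pitch_px", lower = 2 * radius_px, strict_lower = TRUE)
  assert_scalar_num(radius_px, "radius_px", lower = 1)
  nc <- as.integer(n_channels)
  neg_mean <- rep_len(neg_mean, nc); neg_sd <- rep_len(neg_sd, nc)
  pos_mean <- rep_len(pos_mean, nc); pos_sd <- rep_len(pos_sd, nc)
  positive_fraction <- rep_len(positive_fraction, nc)
  if (any(pos_mean <= neg_mean))
    stop("`pos_mean` must exceed `neg_mean` in every channel", call. = FALSE)
  if (any(positive_fraction < 0 | positive_fraction > 1))
    stop("`positive_fraction` must lie in [0, 1]", call. = FALSE)
  if (any(c(neg_sd, pos_sd) <= 0)) stop("intensity s.d. must be > 0", call. = FALSE)
  assert_scalar_num(pixel_noise_sd, "pixel_noise_sd", lower = 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch_px = as.numeric(pitch_px), radius_px = as.numeric(radius_px),
                 n_channels = nc, neg_mean = neg_mean, neg_sd = neg_sd,
                 pos_mean = pos_mean, pos_sd = pos_sd,
                 positive_fraction = positive_fraction,
                 debris_n = as.integer(debris_n),
                 debris_intensity_range = as.numeric(debris_intensity_range),
                 fill_mean = fill_mean, fill_sd = fill_sd,
                 pixel_noise_sd = pixel_noise_sd),
            class = "frad_array_params")
}

# paint a flat-top disk into `img` (modified copy returned)
paint_disk <- function(img, row0, col0, radius, value) {
  r1 <- max(1L, floor(row0 - radius) + 1L); r2 <- min(nrow(img), ceiling(row0 + radius) + 1L)
  c1 <- max(1L, floor(col0 - radius) + 1L); c2 <- min(ncol(img), ceiling(col0 + radius) + 1L)
  for (r in r1:r2) for (cl in c1:c2)
    if ((r - 1 - row0)^2 + (cl - 1 - col0)^2 <= radius^2) img[r, cl] <- value
  img
}

#' Generate synthetic reactor-array images with ground truth
#'
#' Renders the fill channel (all reactors bright) and each expression channel
#' (reactor intensities drawn from the channel's negative or positive Gaussian
#' according to the true call), plus off-lattice debris in the expression
#' channels. Positive reactors are assigned by quota by default —
#' `round(positive_fraction * n_reactors)` reactors sampled without
#' replacement — so recovery tests have deterministic truth; set
#' `assignment = "bernoulli"` for independent per-reactor draws.
#'
#' @param params a [frad_array_params()] object.
#' @param seed integer seed.
#' @param assignment `"quota"` (default) or `"bernoulli"`.
#' @return list with components `fill` (matrix), `channels` (list of matrices,
#'   one per expression channel), and `truth`: a list with `reactors`
#'   (data.frame: id, 0-based centre row/col, radius), `positive` (logical
#'   matrix, reactors x channels), `intensity` (numeric matrix of the drawn
#'   per-reactor intensities), and `debris` (data.frame of debris objects).
#' @examples
#' p <- frad_array_params(rows = 10, cols = 10, positive_fraction = 0.05)
#' arr <- gen_frad_images(p, seed = 1)
#' sum(arr$truth$positive[, 1])
#' @export
gen_frad_images <- function(params, seed, assignment = c("quota", "bernoulli")) {
  stopifnot(inherits(params, "frad_array_params"))
  assignment <- match.arg(assignment)
  with_local_seed(seed, {
    pitch <- params$pitch_px; rad <- params$radius_px
    n <- params$rows * params$cols
    centre_row <- rep((seq_len(params$rows) - 0.5) * pitch, times = params$cols)
    centre_col <- rep((seq_len(params$cols) - 0.5) * pitch, each = params$rows)
    h <- ceiling(params$rows * pitch); w <- ceiling(params$cols * pitch)

    positive <- matrix(FALSE, n, params$n_channels)
    intensity <- matrix(NA_real_, n, params$n_channels)
    for (ch in seq_len(params$n_channels)) {
      f <- params$positive_fraction[ch]
      if (assignment == "quota") {
        k <- round(f * n)
        if (k > 0) positive[sample.int(n, k), ch] <- TRUE
      } else {
        positive[, ch] <- stats::runif(n) < f
      }
      npos <- sum(positive[, ch])
      intensity[!positive[, ch], ch] <-
        stats::rnorm(n - npos, params$neg_mean[ch], params$neg_sd[ch])
      if (npos > 0)
        intensity[positive[, ch], ch] <-
          stats::rnorm(npos, params$pos_mean[ch], params$pos_sd[ch])
    }
    fill_int <- stats::rnorm(n, params$fill_mean, params$fill_sd)

    fill <- matrix(0, h, w)
    channels <- replicate(params$n_channels, matrix(0, h, w), simplify = FALSE)
    for (i in seq_len(n)) {
      fill <- paint_disk(fill, centre_row[i], centre_col[i], rad, fill_int[i])
      for (ch in seq_len(params$n_channels))
        channels[[ch]] <- paint_disk(channels[[ch]], centre_row[i],
                                     centre_col[i], rad, intensity[i, ch])
    }

    # debris: bright blobs in expression channels only, placed at lattice
    # interstices (cell corners, the farthest points from every reactor
    # centre) with radii capped so debris never touches a reactor disk —
    # filter truth stays unambiguous
    debris <- data.frame(row = numeric(0), col = numeric(0),
                         radius = numeric(0), intensity = numeric(0))
    if (params$debris_n > 0) {
      corner_gap <- pitch / sqrt(2)          # corner-to-centre distance
      drad_max <- min(0.8 * rad, corner_gap - rad - 1.5)
      if (drad_max < 1)
        stop("lattice too dense to place debris clear of every reactor; ",
             "increase pitch or drop debris", call. = FALSE)
      corners <- expand.grid(row = seq_len(params$rows - 1L) * pitch,
                             col = seq_len(params$cols - 1L) * pitch)
      if (nrow(corners) < params$debris_n)
        stop("more debris requested than lattice interstices", call. = FALSE)
      pick <- corners[sample.int(nrow(corners), params$debris_n), , drop = FALSE]
      for (i in seq_len(params$debris_n)) {
        drad <- stats::runif(1, min(1, drad_max), drad_max)
        drow <- pick$row[i] + stats::runif(1, -0.5, 0.5)
        dcol <- pick$col[i] + stats::runif(1, -0.5, 0.5)
        dval <- stats::runif(1, params$debris_intensity_range[1],
                             params$debris_intensity_range[2])
        for (ch in seq_len(params$n_channels))
          channels[[ch]] <- paint_disk(channels[[ch]], drow, dcol, drad, dval)
        debris <- rbind(debris, data.frame(row = drow, col = dcol,
                                           radius = drad, intensity = dval))
      }
    }

    if (params$pixel_noise_sd > 0) {
      fill <- fill + matrix(stats::rnorm(h * w, 0, params$pixel_noise_sd), h, w)
      channels <- lapply(channels, function(m)
        m + matrix(stats::rnorm(h * w, 0, params$pixel_noise_sd), h, w))
    }

    list(fill = fill, channels = channels,
         truth = list(reactors = data.frame(id = seq_len(n),
                                            row = centre_row, col = centre_col,
                                            radius = rad),
                      positive = positive, intensity = intensity,
                      debris = debris))
  })
}
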