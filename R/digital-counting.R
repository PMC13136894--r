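#' Detect femtoliter reactors in the fill channel
#'
#' Reactors carry a fill dye, so every chamber is bright in the fill channel.
#' Detection smooths the image (Gaussian blur at roughly a third of the
#' expected radius), thresholds it globally by between-class variance
#' maximization, labels connected components, and keeps blobs whose
#' equivalent radius lies within ±50% of the expected radius. Centroids are
#' intensity-weighted (sub-pixel).
#'
#' @param fill_image numeric matrix (fill channel).
#' @param expected_radius_px expected reactor radius in pixels.
#' @return data.frame (a reactor table) with columns `id`, `row`, `col`
#'   (0-based sub-pixel centroid) and `radius`; zero rows when nothing is
#'   detected.
#' @examples
#' arr <- gen_frad_images(frad_array_params(rows = 5, cols = 5), seed = 1)
#' nrow(detect_reactors(arr$fill, expected_radius_px = 4))
#' @export
detect_reactors <- function(fill_image, expected_radius_px) {
  stopifnot(is.matrix(fill_image))
  assert_scalar_num(expected_radius_px, "expected_radius_px", lower = 1)
  empty <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      radius = numeric(0))
  rng <- range(fill_image)
  if (diff(rng) == 0) return(empty)
  norm <- (fill_image - rng[1]) / diff(rng)
  sigma <- max(0.5, expected_radius_px / 3)
  sm <- EBImage::gblur(EBImage::Image(norm), sigma = sigma)
  thr <- EBImage::otsu(sm)
  labels <- EBImage::bwlabel(sm > thr)
  n_obj <- max(labels)
  if (n_obj == 0) return(empty)
  lab_vec <- as.integer(labels)
  idx_all <- which(lab_vec > 0)
  rows <- (idx_all - 1) %% nrow(fill_image)
  cols <- (idx_all - 1) %/% nrow(fill_image)
  w <- pmax(fill_image[idx_all] - rng[1], 0)
  lab <- lab_vec[idx_all]
  area <- tabulate(lab, n_obj)
  radius <- sqrt(area / pi)
  wsum <- as.numeric(rowsum(w, lab)[, 1])
  crow <- as.numeric(rowsum(rows * w, lab)[, 1]) / wsum
  ccol <- as.numeric(rowsum(cols * w, lab)[, 1]) / wsum
  keep <- radius >= 0.5 * expected_radius_px &
    radius <= 1.5 * expected_radius_px & wsum > 0
  out <- data.frame(id = seq_len(sum(keep)), row = crow[keep],
                    col = ccol[keep], radius = radius[keep])
  rownames(out) <- NULL
  out
}

#' Extract per-reactor mean intensities from channel images
#'
#' Computes, for each detected reactor, the mean intensity over a disk of the
#' detected radius centred at its centroid, in every supplied channel image.
#' Mean (rather than maximum) disk intensity suppresses hot pixels. Reactors
#' whose disk exceeds the image bounds are dropped with a message.
#'
#' @param reactor_table data.frame from [detect_reactors()].
#' @param channel_images named list of numeric matrices, co-registered with
#'   the detection image (e.g. `list(fill = ..., ch1 = ...)`).
#' @return the reactor table with one added intensity column per channel,
#'   named `intensity_<channel name>`.
#' @export
extract_reactor_intensities <- function(reactor_table, channel_images) {
  stopifnot(is.data.frame(reactor_table), is.list(channel_images),
            length(channel_images) >= 1)
  if (is.null(names(channel_images)) || any(!nzchar(names(channel_images))))
    names(channel_images) <- paste0("ch", seq_along(channel_images))
  dims <- dim(channel_images[[1]])
  ok <- reactor_table$row - reactor_table$radius >= 0 &
    reactor_table$row + reactor_table$radius <= dims[1] - 1 &
    reactor_table$col - reactor_table$radius >= 0 &
    reactor_table$col + reactor_table$radius <= dims[2] - 1
  if (any(!ok))
    message(sum(!ok), " reactor(s) dropped: disk exceeds image bounds")
  tab <- reactor_table[ok, , drop = FALSE]
  for (nm in names(channel_images)) {
    img <- channel_images[[nm]]
    vals <- numeric(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      r0 <- tab$row[i]; c0 <- tab$col[i]; rad <- tab$radius[i]
      rs <- max(1L, floor(r0 - rad) + 1L):min(dims[1], ceiling(r0 + rad) + 1L)
      cs <- max(1L, floor(c0 - rad) + 1L):min(dims[2], ceiling(c0 + rad) + 1L)
      sub <- img[rs, cs, drop = FALSE]
      dmask <- outer((rs - 1 - r0)^2, (cs - 1 - c0)^2, "+") <= rad^2
      vals[i] <- mean(sub[dmask])
    }
    tab[[paste0("intensity_", nm)]] <- vals
  }
  rownames(tab) <- NULL
  tab
}

#' Fit an intensity threshold to one channel by trimmed Gaussian modelling
#'
#' Fits a Gaussian to the dominant (negative, non-expressing) intensity mode
#' by iterative trimming — fit mean/s.d., discard values above
#' `mu + k * sigma`, refit until stable — and sets the positive-call threshold
#' at `theta = mu_neg + k * sigma_neg`. When a second mode is resolvable, a
#' two-component Gaussian mixture fit is attached as a diagnostic.
#'
#' By default the multiplier `k` controls the *per-field* expected number of
#' false calls: `k = qnorm(1 - alpha / n)` (about 3.5 for a 250-reactor
#' field at `alpha = 0.05`), the standard Bonferroni-style outlier bound.
#' A fixed multiplier — e.g. the plain mean +3 s.d. convention — can be
#' requested explicitly, but note that on a Gaussian negative mode a fixed
#' 3-sigma cutoff by itself produces a ~1.4e-3 per-reactor false-call floor,
#' an order of magnitude above the pseudo-positive rates typical of digital
#' expression data.
#'
#' @param intensities numeric vector of per-reactor intensities (>= 50
#'   values; fewer make the threshold unreliable and raise an error).
#' @param k threshold multiplier; `NULL` (default) uses the per-field rule
#'   `qnorm(1 - alpha / n)`.
#' @param alpha per-field expected false-call budget used when `k` is `NULL`.
#' @param max_iter trimming iterations cap.
#' @param mixture_diagnostic fit and attach a two-component mixture model
#'   (default TRUE).
#' @importFrom mclust Mclust mclustBIC
#' @return list of class `intensity_model` with `mu_neg`, `sigma_neg`,
#'   `weight_neg` (fraction of reactors retained by the trim), `threshold`,
#'   `k`, and optionally `mixture` (two-component means/sds/weights) when
#'   resolvable.
#' @examples
#' x <- c(rnorm(950, 100, 10), rnorm(50, 1000, 50))
#' fit_intensity_threshold(x, k = 3)$threshold  # ~130
#' @export
fit_intensity_threshold <- function(intensities, k = NULL, alpha = 0.05,
                                    max_iter = 50L,
                                    mixture_diagnostic = TRUE) {
  intensities <- intensities[is.finite(intensities)]
  if (length(intensities) < 50)
    stop("need >= 50 reactors to fit a reliable threshold", call. = FALSE)
  if (is.null(k) || is.na(k))
    k <- stats::qnorm(1 - alpha / length(intensities))
  assert_scalar_num(k, "k", lower = 0, strict_lower = TRUE)
  keep <- rep(TRUE, length(intensities))
  for (it in seq_len(max_iter)) {
    mu <- mean(intensities[keep]); sg <- stats::sd(intensities[keep])
    if (!is.finite(sg) || sg == 0) break
    new_keep <- intensities <= mu + k * sg
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  mu <- mean(intensities[keep]); sg <- stats::sd(intensities[keep])
  if (!is.finite(sg) || sg <= 0)
    stop("degenerate intensity distribution; cannot fit threshold",
         call. = FALSE)
  model <- list(mu_neg = mu, sigma_neg = sg,
                weight_neg = mean(keep), threshold = mu + k * sg, k = k)
  if (mixture_diagnostic && length(unique(intensities)) > 10) {
    mx <- tryCatch(
      Mclust(intensities, G = 2, verbose = FALSE, modelNames = "V"),
      error = function(e) NULL)
    if (!is.null(mx))
      model$mixture <- list(means = unname(mx$parameters$mean),
                            sds = unname(sqrt(mx$parameters$variance$sigmasq)),
                            weights = unname(mx$parameters$pro))
  }
  structure(model, class = "intensity_model")
}

#' Apply the three false-positive filters to a reactor table
#'
#' Sets three conjunctive flags per reactor:
#' \describe{
#'   \item{intensity_pass}{expression intensity is finite, non-negative and
#'     below the saturation limit.}
#'   \item{roi_pass}{the candidate is a genuine fill-channel reactor: its
#'     fill intensity exceeds the fill model's lower validity bound
#'     `mu_fill - fill_k * sigma_fill` (debris bright only in the expression
#'     channel fails here).}
#'   \item{proximity_pass}{nearest-neighbour distance is at least
#'     `min_separation_px`; both members of a close pair are dropped.}
#' }
#' Only reactors passing all three are counted downstream. The flags are
#' conjunctive, so the order of application cannot change the final set.
#'
#' @param reactor_table output of [extract_reactor_intensities()] containing
#'   an `intensity_fill` column plus one expression-intensity column per
#'   channel.
#' @param fill_model an [fit_intensity_threshold()] model of the fill-channel
#'   intensities (its dominant mode is the true-reactor population).
#' @param min_separation_px minimum centre-to-centre distance; the field's
#'   convention is 0.8x the lattice pitch.
#' @param fill_k multiplier for the fill validity bound (default 5).
#' @param saturation_limit intensity ceiling for `intensity_pass`
#'   (default `Inf`).
#' @param channels character vector of expression channel names (defaults to
#'   every `intensity_*` column except the fill).
#' @return the reactor table with logical columns `intensity_pass`,
#'   `roi_pass`, `proximity_pass` and `pass_all`.
#' @export
filter_false_positives <- function(reactor_table, fill_model,
                                   min_separation_px,
                                   fill_k = 5, saturation_limit = Inf,
                                   channels = NULL) {
  stopifnot(is.data.frame(reactor_table),
            inherits(fill_model, "intensity_model"),
            "intensity_fill" %in% names(reactor_table))
  assert_scalar_num(min_separation_px, "min_separation_px", lower = 0)
  int_cols <- grep("^intensity_", names(reactor_table), value = TRUE)
  if (is.null(channels))
    channels <- setdiff(sub("^intensity_", "", int_cols), "fill")
  expr_cols <- paste0("intensity_", channels)
  stopifnot(all(expr_cols %in% names(reactor_table)))

  n <- nrow(reactor_table)
  expr <- as.matrix(reactor_table[, expr_cols, drop = FALSE])
  intensity_pass <- apply(expr, 1, function(v)
    all(is.finite(v)) && all(v >= 0) && all(v < saturation_limit))

  theta_fill <- fill_model$mu_neg - fill_k * fill_model$sigma_neg
  roi_pass <- reactor_table$intensity_fill > theta_fill

  proximity_pass <- rep(TRUE, n)
  if (n > 1) {
    d <- as.matrix(stats::dist(reactor_table[, c("row", "col")]))
    diag(d) <- Inf
    proximity_pass <- apply(d, 1, min) >= min_separation_px
  }
  reactor_table$intensity_pass <- as.logical(intensity_pass)
  reactor_table$roi_pass <- roi_pass
  reactor_table$proximity_pass <- proximity_pass
  reactor_table$pass_all <- intensity_pass & roi_pass & proximity_pass
  reactor_table
}

#' Digital count: positive fraction of one channel
#'
#' Among reactors passing all filters, calls a reactor positive when its
#' channel intensity exceeds the channel's threshold, and reports the
#' positive fraction with a Wilson 95% confidence interval.
#'
#' @param reactor_table filtered table from [filter_false_positives()].
#' @param channel expression channel name (e.g. `"ch1"`).
#' @param model the channel's [fit_intensity_threshold()] model.
#' @return list of class `digital_count_result` with `n_analyzed`,
#'   `n_positive`, `fraction`, `ci` (Wilson 95%), `threshold`, `channel`.
#' @export
count_positive_fraction <- function(reactor_table, channel, model) {
  stopifnot(is.data.frame(reactor_table), inherits(model, "intensity_model"),
            "pass_all" %in% names(reactor_table))
  col <- paste0("intensity_", channel)
  stopifnot(col %in% names(reactor_table))
  tab <- reactor_table[reactor_table$pass_all, , drop = FALSE]
  if (nrow(tab) == 0) stop("zero reactors pass all filters", call. = FALSE)
  pos <- tab[[col]] > model$threshold
  ci <- wilson_ci(sum(pos), nrow(tab))
  structure(list(n_analyzed = nrow(tab), n_positive = sum(pos),
                 fraction = unname(ci["estimate"]),
                 ci = c(lower = unname(ci["lower"]), upper = unname(ci["upper"])),
                 threshold = model$threshold, channel = channel),
            class = "digital_count_result")
}

#' Pseudo-positive detection floor from no-DNA controls
#'
#' The detection floor for a digital expression signal is defined from
#' replicate no-DNA control experiments as the mean positive-reactor fraction
#' plus three sample standard deviations (n-1 denominator).
#'
#' @param control_fractions numeric vector of control positive fractions, one
#'   per replicate (>= 2 replicates).
#' @param k multiplier on the s.d. (default 3).
#' @return the threshold `mean + k * sd`.
#' @examples
#' pseudo_positive_threshold(c(0.01, 0.02, 0.03))  # 0.05
#' @export
pseudo_positive_threshold <- function(control_fractions, k = 3) {
  if (length(control_fractions) < 2)
    stop("need >= 2 replicate control fractions", call. = FALSE)
  if (any(control_fractions < 0 | control_fractions > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  mean(control_fractions) + k * stats::sd(control_fractions)
}

#' Bracket the threshold concentration on a dose series
#'
#' Given positive fractions measured over a sorted concentration series, finds
#' the interval `(c_low, c_high]` where `c_high` is the smallest tested
#' concentration whose fraction exceeds the pseudo-positive floor and `c_low`
#' the largest tested concentration at or below the floor beneath it. The
#' interval is open-ended (`-Inf` / `Inf`) when every or no concentration
#' exceeds the floor.
#'
#' @param concentrations sorted increasing concentrations (>= 2 values).
#' @param fractions positive fractions at each concentration.
#' @param theta_pp pseudo-positive floor from [pseudo_positive_threshold()].
#' @return list with `c_low`, `c_high` and `exceeds` (logical per point).
#' @examples
#' bracket_threshold_concentration(c(0.25, 0.5, 1, 2), c(0, 0.001, 0.02, 0.1),
#'                                 theta_pp = 0.005)
#' @export
bracket_threshold_concentration <- function(concentrations, fractions,
                                            theta_pp) {
  stopifnot(length(concentrations) >= 2,
            length(concentrations) == length(fractions))
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("`concentrations` must be sorted strictly increasing", call. = FALSE)
  exceeds <- fractions > theta_pp
  if (!any(exceeds))
    return(list(c_low = concentrations[length(concentrations)], c_high = Inf,
                exceeds = exceeds))
  first <- which(exceeds)[1]
  list(c_low = if (first == 1) -Inf else concentrations[first - 1],
       c_high = concentrations[first], exceeds = exceeds)
}

#' Poisson occupancy of femtoliter reactors
#'
#' At template concentration `c` and reactor volume `V`, molecules are
#' Poisson-distributed across reactors with mean
#' `lambda = c * V * N_Avogadro`; the probability a reactor holds at least
#' one template is `1 - exp(-lambda)`.
#'
#' @param concentration template concentration in mol/L (>= 0).
#' @param reactor_volume reactor volume in litres, default 50 fL (`50e-15`).
#' @return list with `lambda` and `p_occupied`.
#' @examples
#' expected_occupancy(1.2e-15)  # 1.2 fM in 50 fL
#' @export
expected_occupancy <- function(concentration, reactor_volume = 50e-15) {
  if (any(concentration < 0)) stop("concentration must be >= 0", call. = FALSE)
  assert_scalar_num(reactor_volume, "reactor_volume", lower = 0,
                    strict_lower = TRUE)
  avogadro <- 6.02214076e23
  lambda <- concentration * reactor_volume * avogadro
  list(lambda = lambda, p_occupied = 1 - exp(-lambda))
}

#' Plot a per-channel intensity histogram with its threshold
#'
#' @param intensities per-reactor intensities of one channel.
#' @param model the channel's [fit_intensity_threshold()] model.
#' @param main plot title.
#' @return invisibly, the histogram object.
#' @export
plot_intensity_model <- function(intensities, model, main = "reactor intensities") {
  h <- graphics::hist(intensities, breaks = 60, main = main,
                      xlab = "mean disk intensity", col = "grey85",
                      border = "grey60")
  graphics::abline(v = model$threshold, col = "red3", lwd = 2)
  graphics::mtext(sprintf("threshold = %.1f (mu + %g sd)", model$threshold,
                          model$k), side = 3, cex = 0.8)
  invisible(h)
}
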