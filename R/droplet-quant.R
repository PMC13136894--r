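#' Segment condensate droplets from a fluorescence image
#'
#' Thresholds the image globally by between-class variance maximization
#' (Otsu), labels connected bright regions, and keeps regions that are large
#' and circular enough to be droplet cross-sections. Touching droplets merged
#' into one irregular region are rejected by the circularity filter rather
#' than split.
#'
#' @param image numeric matrix of finite intensities.
#' @param min_radius_px minimum equivalent radius (`sqrt(area/pi)`) in pixels.
#' @param circularity_min minimum circularity `4*pi*area / perimeter^2`
#'   (1 for a perfect circle; boundary length is measured on the traced
#'   8-connected contour). Default 0.8.
#' @return list of `droplet_mask` objects sorted by area (largest first),
#'   each with fields `pixels` (2-column matrix of 0-based row/col), `centroid`
#'   (0-based row/col), `radius` (equivalent radius, px), `circularity`, and
#'   `area`. A blank image yields an empty list.
#' @examples
#' im <- gen_droplet_image(droplet_image_params(size = 128, n_droplets = 3),
#'                         seed = 1)
#' length(segment_droplets(im$image))
#' @export
segment_droplets <- function(image, min_radius_px = 3, circularity_min = 0.8) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  rng <- range(image)
  if (diff(rng) == 0) return(list())
  norm <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  labels <- EBImage::bwlabel(norm > thr)
  n_obj <- max(labels)
  if (n_obj == 0) return(list())
  contours <- EBImage::ocontour(labels)
  masks <- list()
  for (i in seq_len(n_obj)) {
    idx <- which(labels == i, arr.ind = TRUE)
    area <- nrow(idx)
    radius <- sqrt(area / pi)
    if (radius < min_radius_px) next
    ct <- contours[[i]]
    if (is.null(ct) || nrow(ct) < 3) next
    steps <- sqrt(rowSums((ct - ct[c(2:nrow(ct), 1), ])^2))
    perimeter <- sum(steps)
    circ <- min(1, 4 * pi * area / perimeter^2)
    if (circ < circularity_min) next
    masks[[length(masks) + 1L]] <- structure(
      list(pixels = unname(idx) - 1L,
           centroid = c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1),
           radius = radius, circularity = circ, area = area),
      class = "droplet_mask")
  }
  if (length(masks) == 0) return(list())
  masks[order(vapply(masks, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

# logical matrix from a droplet mask
mask_matrix <- function(mask, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[mask$pixels + 1L] <- TRUE
  m
}

#' Partition coefficient of one droplet
#'
#' PC_raw is the mean intensity inside the droplet divided by an estimate of
#' the dilute-phase intensity outside. The interior mean is taken over the
#' mask eroded by `erosion_px` to avoid edge blur; the outside estimate is the
#' median of all pixels at least two radii away from every supplied mask
#' centroid (so neighbouring droplets never contaminate the background).
#'
#' @param image numeric matrix.
#' @param mask a `droplet_mask` from [segment_droplets()].
#' @param all_masks list of all masks in the image used to exclude droplet
#'   neighbourhoods from the background; defaults to `list(mask)`.
#' @param erosion_px erosion depth in pixels before interior averaging
#'   (default 2).
#' @param background_mode `"median"` (default) or `"mean"` of the background
#'   pixels.
#' @return list of class `partition_measurement` with `pc_raw`, `inside_mean`,
#'   `outside_estimate`, and placeholders `pc_corrected`, `tau_in`, `tau_out`
#'   (filled by [flim_correct_pc()]).
#' @export
partition_coefficient <- function(image, mask, all_masks = list(mask),
                                  erosion_px = 2, background_mode = c("median", "mean")) {
  stopifnot(is.matrix(image), inherits(mask, "droplet_mask"))
  background_mode <- match.arg(background_mode)
  if (any(mask$pixels < 0) || any(mask$pixels[, 1] >= nrow(image)) ||
      any(mask$pixels[, 2] >= ncol(image)))
    stop("mask lies outside the image", call. = FALSE)
  mm <- mask_matrix(mask, dim(image))
  if (erosion_px > 0) {
    brush <- EBImage::makeBrush(2 * round(erosion_px) + 1, shape = "disc")
    mm <- EBImage::erode(mm, brush) > 0
  }
  if (!any(mm)) stop("eroded mask is empty; reduce `erosion_px`", call. = FALSE)
  inside_mean <- mean(image[mm])

  rr <- matrix(rep(seq_len(nrow(image)) - 1, ncol(image)), nrow(image))
  cc <- matrix(rep(seq_len(ncol(image)) - 1, each = nrow(image)), nrow(image))
  bg <- matrix(TRUE, nrow(image), ncol(image))
  for (m in all_masks) {
    d2 <- (rr - m$centroid[1])^2 + (cc - m$centroid[2])^2
    bg <- bg & d2 >= (2 * m$radius)^2
  }
  if (!any(bg)) stop("no background pixels >= 2 radii from every mask", call. = FALSE)
  outside <- if (background_mode == "median") stats::median(image[bg]) else
    mean(image[bg])
  if (outside <= 0) stop("outside estimate is <= 0", call. = FALSE)
  structure(list(pc_raw = inside_mean / outside, inside_mean = inside_mean,
                 outside_estimate = outside, pc_corrected = NA_real_,
                 tau_in = NA_real_, tau_out = NA_real_),
            class = "partition_measurement")
}

#' Segment and quantify every droplet in an image
#'
#' Convenience wrapper: segments droplets and computes the partition
#' coefficient of each, optionally applying the lifetime-based quantum-yield
#' correction when both lifetimes are supplied.
#'
#' @inheritParams segment_droplets
#' @inheritParams partition_coefficient
#' @param tau_in,tau_out optional fluorescence lifetimes (ns) inside/outside
#'   droplets for [flim_correct_pc()].
#' @return data.frame with one row per retained droplet: id, centroid row/col,
#'   radius, circularity, pc_raw, pc_corrected, tau_in, tau_out.
#' @export
quantify_droplets <- function(image, min_radius_px = 3, circularity_min = 0.8,
                              erosion_px = 2, tau_in = NULL, tau_out = NULL) {
  masks <- segment_droplets(image, min_radius_px, circularity_min)
  if (length(masks) == 0)
    return(data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      radius = numeric(0), circularity = numeric(0),
                      pc_raw = numeric(0), pc_corrected = numeric(0),
                      tau_in = numeric(0), tau_out = numeric(0)))
  res <- lapply(seq_along(masks), function(i) {
    pm <- partition_coefficient(image, masks[[i]], all_masks = masks,
                                erosion_px = erosion_px)
    pc_corr <- if (!is.null(tau_in) && !is.null(tau_out))
      flim_correct_pc(pm$pc_raw, tau_in, tau_out) else NA_real_
    data.frame(id = i, row = masks[[i]]$centroid[1], col = masks[[i]]$centroid[2],
               radius = masks[[i]]$radius, circularity = masks[[i]]$circularity,
               pc_raw = pm$pc_raw, pc_corrected = pc_corr,
               tau_in = if (is.null(tau_in)) NA_real_ else tau_in,
               tau_out = if (is.null(tau_out)) NA_real_ else tau_out)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
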