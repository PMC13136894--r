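#' Write channel images as a multi-page TIFF
#'
#' Pages are stored as 32-bit float after an affine rescale to \[0, 1\]; the
#' offset and scale are recorded in a small JSON sidecar (`<path>.json`) so
#' [read_image_tiff()] can restore the original intensities.
#'
#' @param channels a numeric matrix or a list of matrices (one page per
#'   channel, e.g. fill first then expression channels).
#' @param path output path.
#' @return invisibly, the scale used.
#' @export
write_image_tiff <- function(channels, path) {
  if (is.matrix(channels)) channels <- list(channels)
  stopifnot(all(vapply(channels, is.matrix, logical(1))))
  lo <- min(vapply(channels, min, numeric(1)))
  hi <- max(vapply(channels, max, numeric(1)))
  scale <- max(hi - lo, .Machine$double.eps)
  pages <- lapply(channels, function(m) (m - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(offset = lo, scale = scale,
                            n_channels = length(channels),
                            channel_names = names(channels)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(scale)
}

#' Read a multi-page TIFF written by [write_image_tiff()]
#'
#' @param path TIFF path.
#' @return list of numeric matrices with original intensities restored (when
#'   the sidecar `<path>.json` is present; otherwise raw \[0,1\] values).
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  offset <- 0; scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    offset <- meta$offset; scale <- meta$scale
  }
  lapply(pages, function(p) {
    m <- p
    attributes(m) <- list(dim = dim(p))
    m * scale + offset
  })
}

#' Write reads to FASTQ
#'
#' Reads flagged unreadable are written with uniformly low base quality
#' (Phred 2); all others with Phred 40.
#'
#' @param reads character vector of sequences.
#' @param path output FASTQ path.
#' @param unreadable logical per read (default all FALSE).
#' @param names read names; default `read_1 ...`.
#' @return invisibly, `path`.
#' @export
write_reads_fastq <- function(reads, path, unreadable = NULL, names = NULL) {
  if (is.null(unreadable)) unreadable <- rep(FALSE, length(reads))
  if (is.null(names)) names <- paste0("read_", seq_along(reads))
  stopifnot(length(unreadable) == length(reads))
  qual_char <- ifelse(unreadable, "#", "I")  # Phred 2 vs Phred 40
  quals <- Biostrings::PhredQuality(vapply(seq_along(reads), function(i)
    strrep(qual_char[i], nchar(reads[i])), character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(Biostrings::DNAStringSet(reads),
                                             quals)
  names(x) <- names
  # Biostrings warns about dropping the (empty) metadata columns it itself
  # attaches to quality-scaled sets; nothing of ours is lost
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(x, path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

#' Read a FASTQ file of reads with mean base qualities
#'
#' @param path FASTQ path.
#' @return list with `reads` (character), `names`, and `mean_quality`
#'   (mean Phred score per read).
#' @export
read_reads_fastq <- function(path) {
  # coercions on quality-scaled sets drop Biostrings' own (empty) metadata
  # columns; that warning carries no information here
  withCallingHandlers({
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    q <- as(Biostrings::quality(x), "IntegerList")
    list(reads = unname(as.character(x)), names = names(x),
         mean_quality = vapply(q, function(v) mean(as.numeric(v)), numeric(1)))
  }, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Read an (amount, Ct) calibration table from CSV
#'
#' @param path CSV with header columns `amount` and `ct` (case-insensitive).
#' @return data.frame with columns `amount`, `ct`.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.csv(path)
  names(tab) <- tolower(names(tab))
  if (!all(c("amount", "ct") %in% names(tab)))
    stop("CSV must have columns `amount` and `ct`", call. = FALSE)
  tab[, c("amount", "ct")]
}

#' Write a machine-readable JSON report
#'
#' @param x a list of results.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
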