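#' Globally align a read to its reference with unit costs
#'
#' Needleman-Wunsch global alignment with match 0, mismatch 1 and gap 1, so
#' the alignment cost equals the Levenshtein edit distance between the
#' sequences. Traceback ties are broken deterministically: substitution is
#' preferred over a gap, and a gap in the read (deletion) over a gap in the
#' reference (insertion).
#'
#' @param read,reference non-empty sequences over \{A,C,G,T,N\} (character
#'   scalars).
#' @return list of class `read_alignment` with gapped strings `read_aligned`
#'   and `ref_aligned` and the alignment `cost` (edit distance).
#' @examples
#' align_read("ACGT", "ACGGT")$cost  # 1
#' @export
align_read <- function(read, reference) {
  if (!nzchar(read) || !nzchar(reference))
    stop("sequences must be non-empty", call. = FALSE)
  a <- batch_align(read, reference)
  structure(list(read_aligned = a$read[1], ref_aligned = a$ref[1],
                 cost = a$cost[1]),
            class = "read_alignment")
}

# vectorized global alignment of many reads against one reference
# (compiled Needleman-Wunsch; reads identical to the reference skip the DP)
batch_align <- function(reads, reference) {
  reads <- toupper(reads); reference <- toupper(reference)
  if (any(!grepl("^[ACGTN]+$", c(reads, reference))))
    stop("sequences must be over {A,C,G,T,N}", call. = FALSE)
  out <- list(read = reads, ref = rep(reference, length(reads)),
              cost = integer(length(reads)))
  todo <- which(reads != reference)
  if (length(todo) > 0) {
    al <- .nw_align_batch(reads[todo], reference)
    out$read[todo] <- al$read
    out$ref[todo] <- al$ref
    out$cost[todo] <- al$cost
  }
  out
}

# error events from one gapped read/reference pair; runs of gaps merge into
# one multi-base deletion/insertion event
events_from_gapped <- function(read_g, ref_g) {
  empty <- data.frame(position = integer(0), type = character(0),
                      original = character(0), observed = character(0),
                      length = integer(0))
  p <- strsplit(read_g, "")[[1]]
  s <- strsplit(ref_g, "")[[1]]
  bad <- which(p != s)
  if (length(bad) == 0) return(empty)
  refcount <- cumsum(s != "-")
  col_type <- ifelse(p[bad] == "-", "deletion",
                     ifelse(s[bad] == "-", "insertion", "substitution"))
  # merge adjacent gap columns of the same type into one event
  grp <- cumsum(c(TRUE, diff(bad) != 1 | col_type[-1] != col_type[-length(bad)] |
                    col_type[-length(bad)] == "substitution"))
  out <- lapply(split(seq_along(bad), grp), function(ii) {
    cols <- bad[ii]; ty <- col_type[ii[1]]
    pos0 <- if (ty == "insertion") refcount[cols[1]] else refcount[cols[1]] - 1L
    data.frame(position = pos0, type = ty,
               original = paste(s[cols][s[cols] != "-"], collapse = ""),
               observed = paste(p[cols][p[cols] != "-"], collapse = ""),
               length = length(cols))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Extract error events from a read alignment
#'
#' Each aligned column yields at most one event; runs of gap columns are
#' merged into a single multi-base deletion or insertion event whose length
#' is recorded. Positions are 0-based on the reference; an insertion is
#' placed at the reference position before which it occurs.
#'
#' @param alignment a `read_alignment` from [align_read()].
#' @return data.frame with columns position, type (deletion / substitution /
#'   insertion), original, observed, length. Zero rows for a perfect
#'   alignment.
#' @examples
#' extract_errors(align_read("ACGT", "ACTT"))
#' @export
extract_errors <- function(alignment) {
  stopifnot(inherits(alignment, "read_alignment"))
  events_from_gapped(alignment$read_aligned, alignment$ref_aligned)
}

#' Per-base error rate and type spectrum from reads
#'
#' Aligns every read globally to its reference, extracts error events, and
#' estimates the per-base synthesis error rate as total events over total
#' aligned reference bases, with a Wilson 95% confidence interval. Type
#' fractions (deletion / substitution / insertion) are reported whenever at
#' least one event exists.
#'
#' @param reads character vector of read sequences.
#' @param references character vector of reference sequences.
#' @param oligo integer index of each read's reference; defaults to reads
#'   cycling through the references in order (the layout produced by
#'   [gen_oligo_reads()]).
#' @return list with `q_hat`, `ci` (Wilson 95%), `total_events`,
#'   `total_bases`, `type_counts` and `type_fractions` (all-`NA` when no
#'   events were found), and `events`: the pooled per-read event table.
#' @examples
#' sp <- error_spectrum(q = 0.01)
#' d <- assembly_design(150L)
#' r <- gen_oligo_reads(d, sp, n_reads = 200, seed = 1)
#' est <- error_rate_and_spectrum(r$reads, r$references)
#' est$q_hat
#' @export
error_rate_and_spectrum <- function(reads, references, oligo = NULL) {
  if (length(reads) < 1) stop("need >= 1 read", call. = FALSE)
  if (is.null(oligo)) oligo <- rep_len(seq_along(references), length(reads))
  stopifnot(length(oligo) == length(reads))
  total_bases <- sum(nchar(references)[oligo])
  if (total_bases == 0) stop("zero aligned reference bases", call. = FALSE)
  ev_list <- vector("list", length(reads))
  for (j in seq_along(references)) {
    sel <- which(oligo == j)
    if (length(sel) == 0) next
    al <- batch_align(reads[sel], references[j])
    for (i in seq_along(sel)) {
      if (al$cost[i] == 0) next
      ev <- events_from_gapped(al$read[i], al$ref[i])
      if (nrow(ev) > 0) {
        ev$read <- sel[i]; ev$oligo <- j
        ev_list[[sel[i]]] <- ev
      }
    }
  }
  events <- do.call(rbind, ev_list[!vapply(ev_list, is.null, logical(1))])
  n_ev <- if (is.null(events)) 0L else nrow(events)
  types <- c("deletion", "substitution", "insertion")
  if (n_ev > 0) {
    counts <- table(factor(events$type, levels = types))
    fractions <- as.numeric(counts) / n_ev
  } else {
    events <- data.frame(position = integer(0), type = character(0),
                         original = character(0), observed = character(0),
                         length = integer(0), read = integer(0),
                         oligo = integer(0))
    counts <- setNames(rep(0L, 3), types)
    fractions <- rep(NA_real_, 3)
  }
  list(q_hat = n_ev / total_bases,
       ci = wilson_ci(min(n_ev, total_bases), total_bases),
       total_events = n_ev, total_bases = total_bases,
       type_counts = setNames(as.integer(counts), types),
       type_fractions = setNames(fractions, types),
       events = events)
}

#' Classify an assembled clone sequence
#'
#' Partitions sequenced clones into four mutually exclusive classes:
#' \describe{
#'   \item{unreadable}{mean base quality below `min_quality` (default Q20) or
#'     clone length below `min_coverage` (default 50%) of the reference.}
#'   \item{perfect}{no error events.}
#'   \item{sporadic}{at most 3 events, each a substitution or a deletion of
#'     at most 3 nt — the signature of oligo synthesis errors.}
#'   \item{large_deletion}{any deletion of 4 nt or more (misassembly of
#'     truncated oligos), or any damage heavier than the sporadic criterion.}
#' }
#'
#' @param clone clone consensus sequence (character scalar).
#' @param reference designed full-length sequence.
#' @param mean_quality mean Phred quality of the clone's trace; default `Inf`
#'   (quality unknown / good).
#' @param min_quality unreadable cutoff on `mean_quality`, default 20.
#' @param min_coverage unreadable cutoff on clone/reference length ratio,
#'   default 0.5.
#' @return one of `"perfect"`, `"sporadic"`, `"large_deletion"`,
#'   `"unreadable"`.
#' @examples
#' classify_clone("ACGTACGT", "ACGTACGT")
#' @export
classify_clone <- function(clone, reference, mean_quality = Inf,
                           min_quality = 20, min_coverage = 0.5) {
  if (!nzchar(reference)) stop("reference must be non-empty", call. = FALSE)
  if (is.na(mean_quality)) mean_quality <- Inf
  if (mean_quality < min_quality ||
      nchar(clone) < min_coverage * nchar(reference))
    return("unreadable")
  ev <- extract_errors(align_read(clone, reference))
  if (nrow(ev) == 0) return("perfect")
  if (any(ev$type == "deletion" & ev$length >= 4)) return("large_deletion")
  sporadic_ok <- nrow(ev) <= 3 &&
    all(ev$type == "substitution" | (ev$type == "deletion" & ev$length <= 3))
  if (sporadic_ok) return("sporadic")
  "large_deletion"
}

#' Closed-form probability of an error-free ligation assembly
#'
#' Under a uniform, independent per-base synthesis error rate `q` and the
#' assumption that ligation occurs only when every overlap base of every
#' oligo is error-free, the ligation probability is `(1-q)^L_ov` and the
#' probability that a ligated product is completely error-free is
#' `(1-q)^L_free`, where `L_ov` counts the bases lying in overlap regions
#' (one region for each terminal oligo, two for internal ones) and `L_free`
#' the remaining bases. For five 150-nt oligos with 20-nt overlaps,
#' `L_ov = 160` and `L_free = 590`.
#'
#' @param design an [assembly_design()].
#' @param q per-base error rate in \[0, 1).
#' @return list of class `fidelity_prediction` with `p_ligation`,
#'   `p_error_free_given_ligated`, `p_error_free_overall` (their product),
#'   `overlap_bases`, `free_bases`, `q`.
#' @examples
#' pred <- error_free_probability(assembly_design(rep(150L, 5)), q = 0.00151)
#' 100 * pred$p_error_free_given_ligated  # ~41%
#' @export
error_free_probability <- function(design, q) {
  stopifnot(inherits(design, "assembly_design"))
  assert_scalar_num(q, "q", lower = 0, upper = 1 - 1e-12)
  p_lig <- (1 - q)^design$overlap_bases
  p_ef <- (1 - q)^design$free_bases
  structure(list(p_ligation = p_lig,
                 p_error_free_given_ligated = p_ef,
                 p_error_free_overall = p_lig * p_ef,
                 overlap_bases = design$overlap_bases,
                 free_bases = design$free_bases, q = q),
            class = "fidelity_prediction")
}

#' @export
print.fidelity_prediction <- function(x, ...) {
  cat(sprintf("Ligation fidelity at q = %.4g/base (%d overlap + %d free bases)\n",
              x$q, x$overlap_bases, x$free_bases))
  cat(sprintf("  P(ligation)                 = %.4f\n", x$p_ligation))
  cat(sprintf("  P(error-free | ligated)     = %.4f\n",
              x$p_error_free_given_ligated))
  cat(sprintf("  P(error-free assembly)      = %.4f\n", x$p_error_free_overall))
  invisible(x)
}

#' Expected fraction of perfect clones among sequenced assemblies
#'
#' Sequenced clones derive from ligated products, so the expected fraction
#' with a perfect sequence is the closed-form
#' `P(error-free | ligated) = (1-q)^L_free`.
#'
#' @inheritParams error_free_probability
#' @return numeric fraction in \[0, 1\].
#' @export
predict_perfect_clone_fraction <- function(design, q) {
  error_free_probability(design, q)$p_error_free_given_ligated
}
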