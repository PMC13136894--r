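#' Per-base oligo synthesis error spectrum
#'
#' Total per-base error rate `q` together with the fractions of errors that
#' are deletions, substitutions and insertions. Defaults are the
#' NGS-measured values for chemically synthesized oligos used throughout the
#' package: q = 0.151% per base with a 71.4/27.6/1.3% del/sub/ins split.
#' Fractions are renormalized to sum exactly to 1 (they must already be
#' within 0.02 of doing so).
#'
#' @param q per-base total error rate, in \[0, 1).
#' @param deletion,substitution,insertion non-negative type fractions.
#' @return an object of class `error_spectrum` with fields `q` and
#'   `fractions` (named numeric, sums to 1).
#' @export
error_spectrum <- function(q = 0.00151, deletion = 0.714,
                           substitution = 0.276, insertion = 0.013) {
  assert_scalar_num(q, "q", lower = 0, upper = 1 - 1e-12)
  fr <- c(deletion = deletion, substitution = substitution,
          insertion = insertion)
  if (any(fr < 0)) stop("type fractions must be >= 0", call. = FALSE)
  s <- sum(fr)
  if (abs(s - 1) > 0.02)
    stop("type fractions must sum to 1 (within 0.02)", call. = FALSE)
  structure(list(q = q, fractions = fr / s), class = "error_spectrum")
}

#' Oligo assembly design
#'
#' A set of single-stranded oligos that tile a full-length product, annealing
#' through fixed-length complementary overlaps at their termini: terminal
#' oligos carry one overlap region, internal oligos two. Ligation of the
#' nicked duplex yields the assembled product.
#'
#' @param oligos either a character vector of oligo sequences (A/C/G/T) or an
#'   integer vector of oligo lengths in nt.
#' @param overlap overlap length per junction in nt (default 20); must be
#'   shorter than every oligo.
#' @return an object of class `assembly_design` with fields `lengths`,
#'   `sequences` (or NULL), `overlap`, `total_length`, `overlap_bases`
#'   (bases lying in any overlap region, summed over oligos) and
#'   `free_bases`.
#' @examples
#' d <- assembly_design(rep(150L, 5), overlap = 20)
#' d$overlap_bases  # 160
#' d$free_bases     # 590
#' @export
assembly_design <- function(oligos, overlap = 20L) {
  if (length(oligos) == 0) stop("empty design", call. = FALSE)
  if (is.character(oligos)) {
    if (any(!grepl("^[ACGT]+$", oligos)))
      stop("oligo sequences must be over {A,C,G,T}", call. = FALSE)
    sequences <- toupper(oligos)
    lengths <- nchar(sequences)
  } else {
    sequences <- NULL
    lengths <- as.integer(oligos)
    if (any(lengths < 1)) stop("oligo lengths must be >= 1", call. = FALSE)
  }
  assert_scalar_num(overlap, "overlap", lower = 0)
  if (any(overlap >= lengths))
    stop("`overlap` must be shorter than every oligo", call. = FALSE)
  n <- length(lengths)
  # overlaps per oligo: 1 for the two terminal oligos, 2 for internal ones
  n_ov <- if (n == 1L) rep(0L, 1L) else c(1L, rep(2L, max(0L, n - 2L)), 1L)
  overlap_bases <- sum(n_ov) * overlap
  structure(list(lengths = lengths, sequences = sequences,
                 overlap = as.integer(overlap), n_oligos = n,
                 total_length = sum(lengths),
                 overlap_bases = overlap_bases,
                 free_bases = sum(lengths) - overlap_bases),
            class = "assembly_design")
}

# random reference sequences for a length-only design (seeded by caller)
random_oligo_sequences <- function(lengths) {
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate synthetic oligo reads with synthesis errors
#'
#' Emulates NGS reads of individual (unassembled) oligos: every base is
#' independently mutated with probability `spectrum$q`, the error type is
#' drawn from the spectrum's fractions, and insertions/deletions are realized
#' in sequence space (read lengths change). Reads cycle through the design's
#' oligos. Each error is recorded in a ground-truth table.
#'
#' @param design an [assembly_design()]; if it carries no sequences, random
#'   references are generated from the same seed.
#' @param spectrum an [error_spectrum()].
#' @param n_reads number of reads (>= 1).
#' @param seed integer seed.
#' @param unreadable_fraction fraction of reads flagged unreadable
#'   (low-quality), default 0.
#' @return list with `reads` (character vector), `oligo` (integer index of the
#'   reference oligo per read), `references` (character vector),
#'   `unreadable` (logical per read) and `records`: data.frame of true error
#'   events with columns read, oligo, position (0-based on the reference),
#'   type (deletion/substitution/insertion), original, observed.
#' @examples
#' sp <- error_spectrum()
#' d <- assembly_design(150L)
#' r <- gen_oligo_reads(d, sp, n_reads = 100, seed = 1)
#' nrow(r$records) / (100 * 150)  # close to sp$q
#' @export
gen_oligo_reads <- function(design, spectrum, n_reads, seed,
                            unreadable_fraction = 0) {
  stopifnot(inherits(design, "assembly_design"),
            inherits(spectrum, "error_spectrum"))
  assert_scalar_num(n_reads, "n_reads", lower = 1)
  assert_scalar_num(unreadable_fraction, "unreadable_fraction", 0, 1)
  n_reads <- as.integer(n_reads)
  with_local_seed(seed, {
    refs <- design$sequences
    if (is.null(refs)) refs <- random_oligo_sequences(design$lengths)
    ref_chars <- strsplit(refs, "")
    oligo_idx <- rep_len(seq_along(refs), n_reads)
    bases <- c("A", "C", "G", "T")
    types <- names(spectrum$fractions)

    n_err <- stats::rbinom(n_reads, design$lengths[oligo_idx], spectrum$q)
    reads <- refs[oligo_idx]
    rec <- vector("list", sum(n_err > 0))
    ri <- 0L
    for (i in which(n_err > 0L)) {
      ref <- ref_chars[[oligo_idx[i]]]
      L <- length(ref)
      pos <- sort(sample.int(L, n_err[i]))
      type <- sample(types, n_err[i], replace = TRUE,
                     prob = spectrum$fractions)
      out <- as.list(ref)
      original <- observed <- character(n_err[i])
      for (k in seq_along(pos)) {
        p <- pos[k]
        if (type[k] == "substitution") {
          new <- sample(setdiff(bases, ref[p]), 1)
          out[[p]] <- new
          original[k] <- ref[p]; observed[k] <- new
        } else if (type[k] == "deletion") {
          out[[p]] <- character(0)
          original[k] <- ref[p]; observed[k] <- ""
        } else { # insertion before the reference base at `p`
          ins <- sample(bases, 1)
          out[[p]] <- c(ins, ref[p])
          original[k] <- ""; observed[k] <- ins
        }
      }
      reads[i] <- paste(unlist(out), collapse = "")
      ri <- ri + 1L
      rec[[ri]] <- data.frame(read = i, oligo = oligo_idx[i],
                              position = pos - 1L, type = type,
                              original = original, observed = observed)
    }
    records <- if (ri > 0) do.call(rbind, rec[seq_len(ri)]) else
      data.frame(read = integer(0), oligo = integer(0), position = integer(0),
                 type = character(0), original = character(0),
                 observed = character(0))
    unreadable <- stats::runif(n_reads) < unreadable_fraction
    list(reads = reads, oligo = oligo_idx, references = refs,
         unreadable = unreadable, records = records)
  })
}

#' Monte-Carlo simulation of ligation assembly outcomes
#'
#' Brute-force counterpart of the closed-form fidelity model: per trial, one
#' error-bearing synthesis copy of each oligo is drawn; ligation succeeds if
#' and only if every base in every overlap region is error-free, and a ligated
#' product is error-free iff it carries no errors anywhere. Because these
#' events depend only on error positions (never on the error type), the
#' simulation draws per-region error counts directly — binomial per base —
#' which is an exact simulation of both events and keeps millions of trials
#' cheap.
#'
#' @param design an [assembly_design()].
#' @param spectrum an [error_spectrum()] (only `q` matters here).
#' @param n_trials number of Monte-Carlo trials (>= 1).
#' @param seed integer seed.
#' @return list with trial counts and tallies: `p_ligated`,
#'   `p_error_free_given_ligated` (with binomial standard errors `se_*`), and
#'   `clone_class`: fractions among ligated trials of perfect products,
#'   products with 1-3 sporadic single-base errors, and heavier damage.
#' @examples
#' sim <- simulate_assembly(assembly_design(rep(150L, 5)), error_spectrum(),
#'                          n_trials = 1e5, seed = 1)
#' sim$p_error_free_given_ligated
#' @export
simulate_assembly <- function(design, spectrum, n_trials, seed) {
  stopifnot(inherits(design, "assembly_design"),
            inherits(spectrum, "error_spectrum"))
  assert_scalar_num(n_trials, "n_trials", lower = 1)
  n_trials <- as.integer(n_trials)
  q <- spectrum$q
  with_local_seed(seed, {
    e_ov <- stats::rbinom(n_trials, design$overlap_bases, q)
    e_free <- stats::rbinom(n_trials, design$free_bases, q)
    ligated <- e_ov == 0L
    n_lig <- sum(ligated)
    p_lig <- n_lig / n_trials
    if (n_lig > 0) {
      ef <- e_free[ligated] == 0L
      p_ef <- mean(ef)
      nerr <- e_free[ligated]
      cls <- c(perfect = mean(nerr == 0L),
               sporadic = mean(nerr >= 1L & nerr <= 3L),
               heavy = mean(nerr > 3L))
      se_ef <- sqrt(p_ef * (1 - p_ef) / n_lig)
    } else {
      p_ef <- NA_real_; se_ef <- NA_real_
      cls <- c(perfect = NA_real_, sporadic = NA_real_, heavy = NA_real_)
    }
    list(n_trials = n_trials, n_ligated = n_lig,
         p_ligated = p_lig,
         se_ligated = sqrt(p_lig * (1 - p_lig) / n_trials),
         p_error_free_given_ligated = p_ef,
         se_error_free_given_ligated = se_ef,
         clone_class = cls)
  })
}
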