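# Independent brute-force oracles and fixture builders used across tests.

# Levenshtein edit distance by straightforward dynamic programming; kept
# deliberately independent of the alignment code path it checks.
edit_distance_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1,            # deletion in b
                        cur[j] + 1,                 # insertion in b
                        prev[j] + (x[i] != y[j]))   # (mis)match
    }
    prev <- cur
  }
  prev[m + 1]
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# apply k random single-base edits (sub/del/ins) to a sequence
mutate_dna <- function(seq, k, types = c("substitution", "deletion", "insertion")) {
  x <- strsplit(seq, "")[[1]]
  for (i in seq_len(k)) {
    pos <- sample.int(length(x), 1)
    ty <- sample(types, 1)
    if (ty == "substitution") {
      x[pos] <- sample(setdiff(c("A", "C", "G", "T"), x[pos]), 1)
    } else if (ty == "deletion" && length(x) > 1) {
      x <- x[-pos]
    } else {
      x <- append(x, sample(c("A", "C", "G", "T"), 1), after = pos - 1)
    }
  }
  paste(x, collapse = "")
}

# run the digital-counting pipeline end to end on one synthetic array
count_array <- function(true_fraction, seed, rows = 10, cols = 25,
                        radius = 4, pitch = 12, debris_n = 0,
                        assignment = "quota") {
  p <- frad_array_params(rows = rows, cols = cols, pitch_px = pitch,
                         radius_px = radius, positive_fraction = true_fraction,
                         debris_n = debris_n)
  arr <- gen_frad_images(p, seed = seed, assignment = assignment)
  tab <- detect_reactors(arr$fill, radius)
  tab <- extract_reactor_intensities(tab, list(fill = arr$fill,
                                               ch1 = arr$channels[[1]]))
  fill_model <- fit_intensity_threshold(tab$intensity_fill, k = 5,
                                        mixture_diagnostic = FALSE)
  model <- fit_intensity_threshold(tab$intensity_ch1,
                                   mixture_diagnostic = FALSE)
  tab <- filter_false_positives(tab, fill_model,
                                min_separation_px = 0.8 * pitch, fill_k = 5)
  count_positive_fraction(tab, "ch1", model)
}
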