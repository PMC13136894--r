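test_that("alignment cost equals an independent edit-distance oracle", {
  expect_equal(align_read("ACGTACGT", "ACGTACGT")$cost, 0)
  set.seed(42)
  for (i in 1:50) {
    ref <- random_dna(sample(30:60, 1))
    read <- mutate_dna(ref, sample(0:5, 1))
    expect_equal(align_read(read, ref)$cost, edit_distance_dp(read, ref),
                 info = paste("pair", i))
  }
  expect_error(align_read("", "ACGT"), "non-empty")
})

test_that("error extraction types and merges events correctly", {
  expect_equal(nrow(extract_errors(align_read("ACGTAC", "ACGTAC"))), 0)

  # single internal deletion: one 1-nt deletion event at the right position
  ref <- "AACCGGTTACGT"
  ev <- extract_errors(align_read("AACCGTTACGT", ref))  # drop one G at pos 4/5
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "deletion")
  expect_equal(ev$length, 1)

  # 2 substitutions plus a 3-nt deletion: 3 events, the gap run merged
  ref2 <- "AAAACCCCGGGGTTTTAAAACCCC"
  read2 <- ref2
  substr(read2, 2, 2) <- "G"
  substr(read2, 23, 23) <- "T"
  read2 <- paste0(substr(read2, 1, 8), substr(read2, 12, nchar(read2)))
  ev2 <- extract_errors(align_read(read2, ref2))
  expect_equal(sum(ev2$type == "substitution"), 2)
  del <- ev2[ev2$type == "deletion", ]
  expect_equal(nrow(del), 1)
  expect_equal(del$length, 3)
})

test_that("substitution-only synthetic reads round-trip to the generator records", {
  d <- assembly_design(rep(120L, 2))
  sp <- error_spectrum(q = 0.01, deletion = 0, substitution = 1, insertion = 0)
  r <- gen_oligo_reads(d, sp, n_reads = 300, seed = 9)
  est <- error_rate_and_spectrum(r$reads, r$references, r$oligo)
  expect_equal(est$total_events, nrow(r$records))
  got <- est$events[order(est$events$read, est$events$position), ]
  want <- r$records[order(r$records$read, r$records$position), ]
  expect_equal(got$read, want$read)
  expect_equal(got$position, want$position)
  expect_true(all(got$type == "substitution"))
  expect_equal(got$observed, want$observed)
})

test_that("rate and spectrum estimation recovers the generating error model", {
  d <- assembly_design(150L)
  r0 <- gen_oligo_reads(d, error_spectrum(q = 0), n_reads = 20, seed = 1)
  est0 <- error_rate_and_spectrum(r0$reads, r0$references)
  expect_equal(est0$q_hat, 0)
  expect_true(all(is.na(est0$type_fractions)))

  sp <- error_spectrum()  # 0.151%/base, 71.4/27.6/1.3
  r <- gen_oligo_reads(d, sp, n_reads = 1e4, seed = 1)
  est <- error_rate_and_spectrum(r$reads, r$references, r$oligo)
  se <- sqrt(sp$q * (1 - sp$q) / est$total_bases)
  expect_lt(abs(est$q_hat - sp$q), 4 * se)
  # deletion fraction within its multinomial 95% CI around the truth
  expect_gte(est$total_events, 500)
  f_del <- est$type_fractions[["deletion"]]
  ci <- wilson_ci(round(f_del * est$total_events), est$total_events)
  expect_true(ci["lower"] <= sp$fractions[["deletion"]] &&
                sp$fractions[["deletion"]] <= ci["upper"])
  expect_equal(sum(est$type_fractions), 1)
})

test_that("clone classification matches the four-class taxonomy", {
  set.seed(13)
  ref <- random_dna(300)
  expect_equal(classify_clone(ref, ref), "perfect")
  # one 2-nt deletion: sporadic
  two_del <- paste0(substr(ref, 1, 99), substr(ref, 102, 300))
  expect_equal(classify_clone(two_del, ref), "sporadic")
  # three scattered substitutions: sporadic
  subbed <- mutate_dna(ref, 3, types = "substitution")
  expect_equal(classify_clone(subbed, ref), "sporadic")
  # 50-nt internal deletion: large_deletion
  big_del <- paste0(substr(ref, 1, 100), substr(ref, 151, 300))
  expect_equal(classify_clone(big_del, ref), "large_deletion")
  # low quality or low coverage: unreadable
  expect_equal(classify_clone(ref, ref, mean_quality = 10), "unreadable")
  expect_equal(classify_clone(substr(ref, 1, 100), ref), "unreadable")
  # heavy damage beyond the sporadic cap falls through to large_deletion
  heavy <- mutate_dna(ref, 10, types = "substitution")
  expect_equal(classify_clone(heavy, ref), "large_deletion")

  # exhaustiveness property: every random mutant lands in exactly one class
  classes <- c("perfect", "sporadic", "large_deletion", "unreadable")
  for (i in 1:25) {
    clone <- mutate_dna(ref, sample(0:12, 1))
    expect_true(classify_clone(clone, ref) %in% classes)
  }
})

test_that("closed-form fidelity matches its overlap accounting and monotonicity", {
  d <- assembly_design(rep(150L, 5), overlap = 20)
  expect_equal(d$overlap_bases, 160)
  expect_equal(d$free_bases, 590)
  p0 <- error_free_probability(d, 0)
  expect_equal(p0$p_ligation, 1)
  expect_equal(p0$p_error_free_given_ligated, 1)

  pred <- error_free_probability(d, 0.00151)
  expect_equal(100 * pred$p_error_free_given_ligated, 40.94, tolerance = 0.2 / 40.94)
  expect_equal(predict_perfect_clone_fraction(d, 0.00151),
               pred$p_error_free_given_ligated)

  # monotone decreasing in q and in total length
  qs <- c(0, 1e-4, 1e-3, 1e-2, 1e-1)
  ps <- vapply(qs, function(q)
    error_free_probability(d, q)$p_error_free_overall, numeric(1))
  expect_true(all(diff(ps) < 0))
  longer <- assembly_design(rep(150L, 6), overlap = 20)
  expect_lt(error_free_probability(longer, 0.001)$p_error_free_overall,
            error_free_probability(d, 0.001)$p_error_free_overall)
  # zero overlap: equals (1-q)^total
  dz <- assembly_design(rep(150L, 5), overlap = 0)
  expect_equal(error_free_probability(dz, 0.001)$p_error_free_given_ligated,
               (1 - 0.001)^750)
})

test_that("closed form agrees with the Monte-Carlo oracle across error rates", {
  d <- assembly_design(rep(150L, 5))
  sp <- function(q) error_spectrum(q = q)
  n <- 1e5
  for (q in c(1e-3, 1e-2, 1e-1)) {
    sim <- simulate_assembly(d, sp(q), n_trials = n, seed = round(1e4 * q))
    pred <- error_free_probability(d, q)
    # standard errors from the closed-form probabilities, so they stay valid
    # even when almost no trial ligates (q = 0.1 gives P(ligation) ~ 5e-8)
    se_lig <- sqrt(pred$p_ligation * (1 - pred$p_ligation) / n)
    expect_lt(abs(sim$p_ligated - pred$p_ligation), 3 * se_lig + 1e-9)
    if (sim$n_ligated >= 1000) {
      p <- pred$p_error_free_given_ligated
      se_ef <- sqrt(p * (1 - p) / sim$n_ligated)
      expect_lt(abs(sim$p_error_free_given_ligated - p), 3 * se_ef)
    }
  }
})
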