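#' Default pipeline configuration
#'
#' All-synthetic demonstration settings sized so the full pipeline runs in
#' well under a minute. Stage blocks mirror the configurable defaults of the
#' corresponding analysis functions; see the methods vignette for the
#' reasoning behind the study-condition defaults.
#'
#' @return nested named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    stages = c("droplets", "flim", "qpcr", "fidelity", "digital"),
    output_dir = NULL,
    droplets = list(size = 192L, n_droplets = 10L, radius_range = c(6, 10),
                    pc = 19.1, outside_mean = 25, noise_frac = 0.05,
                    erosion_px = 2, circularity_min = 0.8),
    flim = list(tau_in = 3.0, tau_out = 3.6, n_photons = 1e6,
                bin_width = 0.08, n_bins = 256, tail_start_fraction = 0.05),
    qpcr = list(A = 2922, k = 0.71, decades = 10L, noise_sd_ct = 0.3),
    fidelity = list(n_oligos = 5L, oligo_length = 150L, overlap = 20L,
                    q = 0.00151, deletion = 0.714, substitution = 0.276,
                    insertion = 0.013, n_reads = 2000L, n_trials = 200000L),
    digital = list(rows = 40L, cols = 25L, pitch_px = 12, radius_px = 4,
                   neg_mean = 100, neg_sd = 10, pos_mean = 1000, pos_sd = 50,
                   concentrations = c(0.25, 0.5, 1, 2),
                   true_fractions = c(0.0002, 0.0005, 0.02, 0.05),
                   control_pseudo_rate = 1.79e-4, n_control_replicates = 3L,
                   debris_n = 5L, threshold_k = NA_real_, fill_threshold_k = 5,
                   min_separation_factor = 0.8)
  ), class = "pipeline_config")
}

# recursive merge of user values into defaults; unknown keys are collected
merge_config <- function(defaults, user, path = "") {
  errors <- character(0)
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      errors <- c(errors, sprintf("unknown key `%s`", full))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        errors <- c(errors, sprintf("`%s` must be a mapping", full))
        next
      }
      sub <- merge_config(defaults[[key]], user[[key]], full)
      defaults[[key]] <- sub$config
      errors <- c(errors, sub$errors)
    } else {
      val <- user[[key]]
      # YAML sequences of mixed int/float parse as lists; flatten whenever
      # the default is an atomic vector
      if (is.list(val) && !is.list(defaults[[key]])) val <- unlist(val)
      defaults[[key]] <- val
    }
  }
  list(config = defaults, errors = errors)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or accepts a list), merges it into [default_config()],
#' rejects unknown keys, and validates every stage's parameters against the
#' corresponding module's preconditions. All offending keys are reported
#' together.
#'
#' @param config path to a YAML file, a list of overrides, or NULL for pure
#'   defaults.
#' @return a validated `pipeline_config`.
#' @examples
#' cfg <- validate_config(list(digital = list(threshold_k = 2)))
#' cfg$digital$threshold_k
#' @export
validate_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    y <- yaml::read_yaml(config)
    if (is.null(y)) list() else y
  } else if (is.list(config)) unclass(config)
  else stop("`config` must be a path, a list, or NULL", call. = FALSE)

  merged <- merge_config(unclass(default_config()), user)
  errors <- merged$errors
  cfg <- merged$config

  check <- function(expr, msg) {
    ok <- tryCatch(expr, error = function(e) {
      errors <<- c(errors, paste0(msg, ": ", conditionMessage(e))); FALSE
    })
    invisible(ok)
  }
  check(assert_scalar_num(cfg$seed, "seed"), "seed")
  bad_stage <- setdiff(cfg$stages,
                       c("droplets", "flim", "qpcr", "fidelity", "digital"))
  if (length(bad_stage))
    errors <- c(errors, paste0("unknown stage(s): ",
                               paste(bad_stage, collapse = ", ")))
  check({droplet_image_params(cfg$droplets$size, cfg$droplets$n_droplets,
                              cfg$droplets$radius_range, cfg$droplets$pc,
                              cfg$droplets$outside_mean,
                              cfg$droplets$noise_frac * cfg$droplets$outside_mean)
         TRUE}, "droplets")
  check({error_spectrum(cfg$fidelity$q, cfg$fidelity$deletion,
                        cfg$fidelity$substitution, cfg$fidelity$insertion)
         assembly_design(rep(cfg$fidelity$oligo_length, cfg$fidelity$n_oligos),
                         cfg$fidelity$overlap)
         TRUE}, "fidelity")
  check({standard_curve(cfg$qpcr$A, cfg$qpcr$k); TRUE}, "qpcr")
  check({frad_array_params(cfg$digital$rows, cfg$digital$cols,
                           cfg$digital$pitch_px, cfg$digital$radius_px,
                           neg_mean = cfg$digital$neg_mean,
                           neg_sd = cfg$digital$neg_sd,
                           pos_mean = cfg$digital$pos_mean,
                           pos_sd = cfg$digital$pos_sd)
         TRUE}, "digital")
  if (length(cfg$digital$concentrations) != length(cfg$digital$true_fractions))
    errors <- c(errors,
                "digital: `concentrations` and `true_fractions` lengths differ")
  if (length(errors) > 0)
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

# small deterministic polynomial hash of the serialized config
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        na = "null")
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full synthetic-to-analysis pipeline
#'
#' Executes the requested stages in dependency order (generate, then
#' quantify/count, then report): droplet partition-coefficient recovery, FLIM
#' lifetime fitting, qPCR standard-curve calculus, assembly fidelity
#' (alignment pipeline, closed form and Monte-Carlo cross-check), and digital
#' reactor counting across a concentration series with a pseudo-positive
#' floor and threshold-concentration bracket. Re-running with an identical
#' configuration reproduces identical numeric summaries.
#'
#' @param config a `pipeline_config` from [validate_config()], a list of
#'   overrides, a YAML path, or NULL for defaults.
#' @param quiet suppress per-stage progress messages.
#' @return list of class `run_report`: per-stage summary lists plus
#'   `software_version`, `config_hash`, `seed`. When `config$output_dir` is
#'   set, the report is also written there as `run_report.json` together with
#'   per-stage CSV artifacts.
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(stages = c("qpcr", "fidelity")))
#' rep$fidelity$p_error_free_given_ligated
#' }
#' @export
run_pipeline <- function(config = NULL, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  say <- function(...) if (!quiet) message(...)
  out_dir <- cfg$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list(software_version = as.character(utils::packageVersion("dropforge")),
                 config_hash = config_hash(cfg), seed = cfg$seed)
  seed <- as.integer(cfg$seed)
  run_stage <- function(name, expr) {
    say("stage `", name, "` ...")
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if ("droplets" %in% cfg$stages) {
    report$droplets <- run_stage("droplets", {
      dp <- cfg$droplets
      params <- droplet_image_params(dp$size, dp$n_droplets, dp$radius_range,
                                     dp$pc, dp$outside_mean,
                                     dp$noise_frac * dp$outside_mean)
      im <- gen_droplet_image(params, seed = seed + 11L)
      res <- quantify_droplets(im$image, circularity_min = dp$circularity_min,
                               erosion_px = dp$erosion_px)
      if (!is.null(out_dir))
        utils::write.csv(res, file.path(out_dir, "droplet_pc.csv"),
                         row.names = FALSE)
      list(n_true = dp$n_droplets, n_detected = nrow(res),
           pc_true = mean(params$pc), pc_mean = mean(res$pc_raw),
           pc_relative_error = abs(mean(res$pc_raw) - mean(params$pc)) /
             mean(params$pc))
    })
  }
  if ("flim" %in% cfg$stages) {
    report$flim <- run_stage("flim", {
      fp <- cfg$flim
      fits <- lapply(c(inside = fp$tau_in, outside = fp$tau_out), function(tau) {
        h <- gen_flim_decay(tau, fp$n_photons, fp$bin_width, fp$n_bins,
                            seed = seed + 23L + round(tau * 100))
        fit_flim_lifetime(h, fp$tail_start_fraction)
      })
      list(tau_in_true = fp$tau_in, tau_in_fit = fits$inside$tau,
           tau_out_true = fp$tau_out, tau_out_fit = fits$outside$tau,
           quantum_yield_ratio = fits$outside$tau / fits$inside$tau)
    })
  }
  if ("qpcr" %in% cfg$stages) {
    report$qpcr <- run_stage("qpcr", {
      qp <- cfg$qpcr
      truth <- standard_curve(qp$A, qp$k)
      tab <- gen_qpcr_dilution_series(truth, amounts = 10^(seq_len(qp$decades) - 1),
                                      noise_sd_ct = qp$noise_sd_ct,
                                      seed = seed + 37L)
      fit <- fit_standard_curve(tab)
      eff <- curve_slope_and_efficiency(fit)
      if (!is.null(out_dir))
        utils::write.csv(tab, file.path(out_dir, "qpcr_series.csv"),
                         row.names = FALSE)
      list(A = fit$A, k = fit$k, slope = eff$slope,
           efficiency_percent = eff$efficiency_percent,
           r_squared = fit$r_squared)
    })
  }
  if ("fidelity" %in% cfg$stages) {
    report$fidelity <- run_stage("fidelity", {
      fd <- cfg$fidelity
      sp <- error_spectrum(fd$q, fd$deletion, fd$substitution, fd$insertion)
      design <- assembly_design(rep(fd$oligo_length, fd$n_oligos), fd$overlap)
      reads <- gen_oligo_reads(design, sp, fd$n_reads, seed = seed + 41L)
      est <- error_rate_and_spectrum(reads$reads, reads$references, reads$oligo)
      pred <- error_free_probability(design, fd$q)
      sim <- simulate_assembly(design, sp, fd$n_trials, seed = seed + 43L)
      if (!is.null(out_dir)) {
        utils::write.csv(est$events, file.path(out_dir, "error_events.csv"),
                         row.names = FALSE)
        write_reads_fastq(reads$reads, file.path(out_dir, "reads.fastq"),
                          unreadable = reads$unreadable)
      }
      list(q_true = fd$q, q_hat = est$q_hat,
           deletion_fraction = unname(est$type_fractions["deletion"]),
           p_ligation = pred$p_ligation,
           p_error_free_given_ligated = pred$p_error_free_given_ligated,
           mc_p_error_free_given_ligated = sim$p_error_free_given_ligated,
           mc_se = sim$se_error_free_given_ligated)
    })
  }
  if ("digital" %in% cfg$stages) {
    report$digital <- run_stage("digital", {
      dg <- cfg$digital
      count_one <- function(fraction, sd_seed, assignment) {
        params <- frad_array_params(dg$rows, dg$cols, dg$pitch_px,
                                    dg$radius_px, n_channels = 1L,
                                    neg_mean = dg$neg_mean, neg_sd = dg$neg_sd,
                                    pos_mean = dg$pos_mean, pos_sd = dg$pos_sd,
                                    positive_fraction = fraction,
                                    debris_n = dg$debris_n)
        arr <- gen_frad_images(params, seed = sd_seed, assignment = assignment)
        tab <- detect_reactors(arr$fill, dg$radius_px)
        tab <- extract_reactor_intensities(tab, list(fill = arr$fill,
                                                     ch1 = arr$channels[[1]]))
        fill_model <- fit_intensity_threshold(tab$intensity_fill,
                                              k = dg$fill_threshold_k)
        model <- fit_intensity_threshold(tab$intensity_ch1, k = dg$threshold_k)
        tab <- filter_false_positives(tab, fill_model,
                                      min_separation_px =
                                        dg$min_separation_factor * dg$pitch_px,
                                      fill_k = dg$fill_threshold_k)
        count_positive_fraction(tab, "ch1", model)
      }
      controls <- vapply(seq_len(dg$n_control_replicates), function(i)
        count_one(dg$control_pseudo_rate, seed + 50L + i, "bernoulli")$fraction,
        numeric(1))
      theta_pp <- pseudo_positive_threshold(controls)
      series <- vapply(seq_along(dg$concentrations), function(i)
        count_one(dg$true_fractions[i], seed + 60L + i, "quota")$fraction,
        numeric(1))
      bracket <- bracket_threshold_concentration(dg$concentrations, series,
                                                 theta_pp)
      occ <- expected_occupancy(dg$concentrations * 1e-9)
      res <- list(control_fractions = controls, theta_pp = theta_pp,
                  concentrations = dg$concentrations, fractions = series,
                  bracket_low = bracket$c_low, bracket_high = bracket$c_high,
                  lambda = occ$lambda)
      if (!is.null(out_dir))
        utils::write.csv(data.frame(concentration = dg$concentrations,
                                    fraction = series),
                         file.path(out_dir, "digital_series.csv"),
                         row.names = FALSE)
      res
    })
  }
  class(report) <- "run_report"
  if (!is.null(out_dir))
    write_json_report(unclass(report), file.path(out_dir, "run_report.json"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("dropforge run report (seed ", x$seed, ", config ", x$config_hash, ")\n",
      sep = "")
  for (st in setdiff(names(x), c("software_version", "config_hash", "seed"))) {
    cat("\n[", st, "]\n", sep = "")
    vals <- x[[st]]
    for (nm in names(vals))
      cat(sprintf("  %-30s %s\n", nm,
                  paste(signif(unlist(vals[[nm]]), 5), collapse = ", ")))
  }
  invisible(x)
}
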