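#' Draw random phantom specifications from a clinical-like distribution
#'
#' Angle magnitudes follow the dispersion reported for symptomatic
#' forefoot cohorts: |HVA| ~ Normal(30, 14.6) truncated to `[0, 55]`,
#' |IMA| ~ Normal(14.3, 4.3) truncated to `[2, 28]`, MT1 base inclination
#' ~ Normal(97, 3) degrees, with random left/right side. Signs follow the
#' package's right-foot convention (valgus deviations negative).
#'
#' @param n Number of specs.
#' @param image_size Canvas side length in pixels.
#' @param noise_sd Intensity noise SD passed to each spec.
#' @param overlap_factor Metatarsal crowding passed to each spec.
#' @param seed Integer seed; each spec also receives its own derived seed.
#' @return List of [phantom_spec()] objects.
#' @export
random_phantom_specs <- function(n, image_size = 128, noise_sd = 0.05,
                                 overlap_factor = 0.3, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      hva <- -min(max(stats::rnorm(1, 30, 14.6), 0), 55)
      ima <- -min(max(stats::rnorm(1, 14.3, 4.3), 2), 28)
      base <- stats::rnorm(1, 97, 3)
      phantom_spec(image_height = image_size, image_width = image_size,
                   side = sample(c("right", "left"), 1),
                   true_HVA = hva, true_IMA = ima, MT1_base_angle = base,
                   noise_sd = noise_sd, overlap_factor = overlap_factor,
                   seed = seed * 1000L + i)
    })
  })
}

#' Configuration for the end-to-end synthetic validation run
#'
#' Defaults are the desk-scale preset: 128 x 128 phantoms, a small
#' network (`base_filters` 8), and a short training schedule, sized so
#' the whole pipeline runs in minutes on one CPU while exercising every
#' stage of the method.
#'
#' @param n_phantoms Total phantom count (split into train/val/test).
#' @param image_size Canvas and network input size (default 128).
#' @param ratios Train/val/test split ratios.
#' @param base_filters Network width at the finest level (default 8).
#' @param max_epochs,learning_rate,minibatch_size,validation_frequency,validation_patience
#'   Training schedule for the scaled run (the full-scale clinical
#'   defaults live in [train_config()]).
#' @param noise_sd Phantom intensity noise SD.
#' @param rater A [rater_model()] for the simulated manual measurements.
#' @param extraction An [extraction_config()].
#' @param seed Global seed; all stage seeds derive from it.
#' @param out_dir Optional directory for intermediate artifacts (PNGs,
#'   annotation JSONs, checkpoint, CSV report).
#' @return A `run_config` object.
#' @export
run_config <- function(n_phantoms = 60, image_size = 128,
                       ratios = c(0.70, 0.20, 0.10), base_filters = 8,
                       max_epochs = 2, learning_rate = 1e-3,
                       minibatch_size = 7, validation_frequency = 200,
                       validation_patience = 10, noise_sd = 0.05,
                       rater = rater_model(), extraction = extraction_config(),
                       seed = 1L, out_dir = NULL) {
  structure(list(n_phantoms = n_phantoms, image_size = image_size,
                 ratios = ratios, base_filters = base_filters,
                 max_epochs = max_epochs, learning_rate = learning_rate,
                 minibatch_size = minibatch_size,
                 validation_frequency = validation_frequency,
                 validation_patience = validation_patience,
                 noise_sd = noise_sd, rater = rater,
                 extraction = extraction, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Measure one sample with a trained network
#'
#' Standardized convenience wrapper: predicts heatmaps for the sample's
#' image and extracts the angle set, recording the sample's side.
#'
#' @param network A trained `ba_network`.
#' @param sample A `ba_sample`.
#' @param config An [extraction_config()].
#' @return A [measure_image()] result.
#' @export
measure_sample <- function(network, sample, config = extraction_config()) {
  measure_image(network, sample$image, config = config,
                side = sample$annotation$side)
}

#' Run the full synthetic validation pipeline
#'
#' Phantoms -> standardization -> heatmap encoding -> network training ->
#' automatic measurement of held-out phantoms -> simulated manual raters
#' -> validation statistics. Fully reproducible from `config$seed`.
#'
#' @param config A [run_config()].
#' @return List with `report` (a [validation_report()]), `network`, the
#'   held-out `test` samples, their `measurements`, the per-case
#'   simulated `raters`, and `config`.
#' @export
pipeline_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  stage <- function(name, code) {
    t <- Sys.time()
    out <- tryCatch(code, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] %s done in %.1fs", format(Sys.time(), "%H:%M:%S"),
                    name, as.numeric(Sys.time() - t, units = "secs")))
    out
  }

  samples <- stage("phantoms", {
    specs <- random_phantom_specs(config$n_phantoms,
                                  image_size = config$image_size,
                                  noise_sd = config$noise_sd,
                                  seed = config$seed)
    lapply(specs, generate_phantom)
  })
  samples <- stage("standardize", {
    lapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      standardize(s$image, s$annotation, size = config$image_size,
                  id = sprintf("case%03d", i))
    })
  })
  parts <- split_dataset(samples, ratios = config$ratios,
                         seed = config$seed + 1L)
  mcfg <- model_config(input_size = config$image_size,
                       base_filters = config$base_filters)
  tcfg <- train_config(max_epochs = config$max_epochs,
                       minibatch_size = config$minibatch_size,
                       initial_learning_rate = config$learning_rate,
                       validation_frequency = config$validation_frequency,
                       validation_patience = config$validation_patience,
                       seed = config$seed + 2L)
  network <- stage("train", {
    net <- build_model(mcfg, seed = config$seed + 3L)
    train_model(net, parts$train, parts$val, tcfg)
  })
  measurements <- stage("measure", {
    lapply(parts$test, function(s)
      measure_sample(network, s, config$extraction))
  })
  raters <- stage("raters", {
    lapply(seq_along(parts$test), function(i) {
      anns <- simulate_raters(parts$test[[i]]$annotation, config$rater,
                              seed = config$seed * 100L + i)
      lapply(anns, derive_angles)
    })
  })
  report <- stage("stats", {
    auto <- lapply(measurements, function(m) m$angles)
    validation_report(auto, raters)
  })
  out <- list(report = report, network = network, test = parts$test,
              measurements = measurements, raters = raters,
              config = config)
  if (!is.null(config$out_dir)) {
    stage("write", write_run_artifacts(out, config$out_dir))
  }
  message(sprintf("pipeline finished in %.1fs (seed %d, n = %d)",
                  as.numeric(Sys.time() - t0, units = "secs"),
                  config$seed, config$n_phantoms))
  out
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(run$test)) {
    s <- run$test[[i]]
    write_image(s$image, file.path(out_dir, sprintf("%s.png",
                                                    s$provenance$id)))
    write_annotation(s$annotation,
                     file.path(out_dir, sprintf("%s.json",
                                                s$provenance$id)))
  }
  names(run$measurements) <- vapply(run$test, function(s)
    s$provenance$id, character(1))
  write_angles_csv(run$measurements, file.path(out_dir, "angles.csv"))
  utils::write.csv(run$report, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  save_model(run$network, file.path(out_dir, "model.ckpt"))
  invisible(out_dir)
}
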