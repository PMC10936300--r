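pipeline_stage_order <- c("simulate", "beamform", "segment", "spectrum",
                          "split", "train", "predict", "evaluate")

pipeline_deps <- list(
  simulate = character(0),
  beamform = "simulate",
  segment = "simulate",
  spectrum = "segment",
  split = "segment",
  train = "split",
  predict = "train",
  evaluate = "predict"
)

# stable FNV-1a hash of a serialized R object, as 8 hex digits
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2)[-seq_len(14)])  # skip header
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes an ordered subset of stages: `simulate` (synthetic dataset),
#' `beamform` (RF-mode check frames), `segment` (GRF event detection),
#' `spectrum` (sEMG spectrum images), `split` (leave-one-speed-out),
#' `train`, `predict`, `evaluate`. Stage order must respect dependencies;
#' rerunning with an identical config and seed reproduces identical
#' manifests and metrics.
#'
#' @param config named list: `synthetic` (arguments to
#'   [synthetic_config()]), `train` (arguments to [train_config()]),
#'   `fit_cycles`, `held_out` (held-out speed; default the median speed),
#'   `image_source` (`"us"` or `"semg"`).
#' @param stages character vector of stages to run, in order.
#' @param out_dir artifact directory (created if missing).
#' @param seed root seed for every random stream.
#' @param verbose print stage progress.
#' @return Invisible list with the in-memory state (`dataset`, `splits`,
#'   `model`, `predictions`, `report`) and the manifest path.
#' @export
run_pipeline <- function(config = list(), stages = c("simulate", "segment",
                                                     "split", "train",
                                                     "predict", "evaluate"),
                         out_dir = tempfile("pipeline"), seed = 1L,
                         verbose = FALSE) {
  bad <- setdiff(stages, pipeline_stage_order)
  if (length(bad)) abort_invalid(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  stages <- pipeline_stage_order[pipeline_stage_order %in% stages]
  done <- character(0)
  for (st in stages) {
    missing <- setdiff(pipeline_deps[[st]], done)
    if (length(missing)) {
      abort_invalid(sprintf("stage '%s' requires prerequisite stage(s): %s",
                            st, paste(missing, collapse = ", ")))
    }
    done <- c(done, st)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)

  state <- list(seed = seed)
  files <- character(0)
  t_start <- Sys.time()

  syn_args <- config$synthetic
  syn_args$seed <- seed
  syn_cfg <- do.call(synthetic_config, as.list(syn_args))
  fit_cycles <- config$fit_cycles %||% 5L
  image_source <- config$image_source %||% "us"

  for (st in stages) {
    t0 <- Sys.time()
    if (verbose) message("stage: ", st)
    if (st == "simulate") {
      state$dataset <- gen_walking_dataset(syn_cfg)
      for (sp in names(state$dataset$grf_traces)) {
        tr <- state$dataset$grf_traces[[sp]]
        f <- file.path(out_dir, sprintf("grf_%s.csv", sp))
        write_timeseries_csv(
          data.frame(time_s = (seq_along(tr$values) - 1) / tr$fs,
                     grf_n = tr$values), f)
        files <- c(files, basename(f))
      }
    } else if (st == "beamform") {
      # RF-mode spot check: beamform a few synthetic point-scatterer frames
      geom <- transducer_geometry(element_count = 32)
      rf_cfg <- syn_cfg; rf_cfg$rf_mode <- TRUE
      mo <- state$dataset$cycles[[1]]$moment[1:2]
      rfs <- gen_us_sequence(mo, rf_cfg, geometry = geom,
                             peak_norm = state$dataset$peak_moment)
      grid <- list(x_mm = seq(-8, 8, by = 0.25), z_mm = seq(10, 30, by = 0.25),
                   pixel_pitch = 0.25)
      bm <- vapply(rfs, function(rf) {
        envelope_logcompress(das_beamform(rf, grid))$pixels
      }, matrix(0, length(grid$z_mm), length(grid$x_mm)))
      f <- file.path(out_dir, "beamformed.bin")
      write_frame_stack(bm, f, kind = "bmode",
                        attrs = list(pixel_pitch_mm = grid$pixel_pitch))
      files <- c(files, basename(f), paste0(basename(f), ".json"))
    } else if (st == "segment") {
      events <- lapply(names(state$dataset$grf_traces), function(sp) {
        ev <- detect_stance(state$dataset$grf_traces[[sp]],
                            syn_cfg$body_mass)
        list(speed = as.numeric(sp), threshold_newtons = attr(ev, "threshold_newtons"),
             heel_strike = ev$heel_strike, toe_off = ev$toe_off)
      })
      state$events <- events
      f <- file.path(out_dir, "events.json")
      jsonlite::write_json(events, f, auto_unbox = TRUE, digits = NA)
      files <- c(files, basename(f))
    } else if (st == "spectrum") {
      # per-cycle two-channel scalogram sequences, left-padded so each frame
      # keeps its moment label; extrema frozen later from the training fold
      state$spectrum <- lapply(state$dataset$cycles, function(cc) {
        emg <- cbind(matrix(0, nrow(cc$emg), 99L), cc$emg)
        rownames(emg) <- rownames(cc$emg)
        spectrum_image_sequence(emg, norm_extrema = c(0, 1))
      })
    } else if (st == "split") {
      state$splits <- make_splits(state$dataset, fit_cycles = fit_cycles)
      f <- file.path(out_dir, "splits.json")
      jsonlite::write_json(
        lapply(seq_len(nrow(state$splits)), function(i) list(
          held_out = state$splits$held_out[i],
          train = state$splits$train[[i]],
          validation = state$splits$validation[[i]],
          prediction = state$splits$prediction[[i]])),
        f, auto_unbox = TRUE, digits = NA)
      files <- c(files, basename(f))
    } else if (st == "train") {
      held <- config$held_out %||% stats::median(syn_cfg$speeds)
      fold <- which(state$splits$held_out == held)
      if (!length(fold)) abort_invalid(sprintf("no fold with held-out speed %s", held))
      state$fold <- fold
      get_images <- function(idx) {
        if (image_source == "semg") {
          stacks <- state$spectrum[idx]
          n <- sum(vapply(stacks, function(s) dim(s)[3], integer(1)))
          imgs <- array(0, dim = c(dim(stacks[[1]])[1:2], n))
          at <- 0
          for (s in stacks) { imgs[, , at + seq_len(dim(s)[3])] <- s; at <- at + dim(s)[3] }
          imgs
        } else {
          collect_cycles(state$dataset, idx)$images
        }
      }
      tr_idx <- state$splits$train[[fold]]
      va_idx <- state$splits$validation[[fold]]
      tr <- collect_cycles(state$dataset, tr_idx)
      va <- collect_cycles(state$dataset, va_idx)
      tr_images <- get_images(tr_idx)
      va_images <- get_images(va_idx)
      if (image_source == "semg") {
        # freeze spectrum normalization extrema from the training fold only
        ext <- range(tr_images)
        tr_images <- (tr_images - ext[1]) / diff(ext)
        va_images <- pmin(pmax((va_images - ext[1]) / diff(ext), 0), 1)
        state$spectrum_extrema <- ext
      }
      tcfg <- do.call(train_config, as.list(config$train))
      spec <- build_cnn(dim(tr_images)[1:2])
      state$model <- train_moment_net(
        spec, tr_images, tr$labels, tcfg,
        validation = list(images = va_images, labels = va$labels),
        seed = substream_seed(seed, "train"))
      f <- file.path(out_dir, "model.ckpt")
      write_checkpoint(state$model, f)
      files <- c(files, basename(f), paste0(basename(f), ".json"))
    } else if (st == "predict") {
      pr_idx <- state$splits$prediction[[state$fold]]
      pr <- collect_cycles(state$dataset, pr_idx)
      imgs <- if (image_source == "semg") {
        ext <- state$spectrum_extrema
        stacks <- state$spectrum[pr_idx]
        n <- sum(vapply(stacks, function(s) dim(s)[3], integer(1)))
        out <- array(0, dim = c(dim(stacks[[1]])[1:2], n))
        at <- 0
        for (s in stacks) { out[, , at + seq_len(dim(s)[3])] <- s; at <- at + dim(s)[3] }
        pmin(pmax((out - ext[1]) / diff(ext), 0), 1)
      } else pr$images
      state$predictions <- tibble::tibble(
        frame = seq_along(pr$labels), speed = pr$speed, cycle = pr$cycle,
        truth = pr$labels, prediction = predict(state$model, imgs))
      f <- file.path(out_dir, "predictions.csv")
      write_timeseries_csv(
        data.frame(time_s = (state$predictions$frame - 1) / syn_cfg$fs_analog,
                   state$predictions[-1]), f)
      files <- c(files, basename(f))
    } else if (st == "evaluate") {
      held <- state$splits$held_out[state$fold]
      pk <- max(state$predictions$truth)  # peak over all prediction cycles
      on_held <- state$predictions$speed == held
      ser <- eval_series(state$predictions$truth[on_held],
                        state$predictions$prediction[on_held],
                        peak_moment = pk)
      rep <- eval_report(ser)
      rep$pearson_r <- sqrt(r_squared(ser)) *
        sign(stats::cor(ser$y, ser$yhat))
      rep$held_out <- held
      state$report <- rep
      f <- file.path(out_dir, "report.json")
      jsonlite::write_json(as.list(rep), f, auto_unbox = TRUE, digits = NA)
      files <- c(files, basename(f))
    }
    log_line("stage=%s seed=%d wall_s=%.2f", st, seed,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  manifest <- list(
    config_hash = config_hash(list(config = config, stages = stages)),
    seed = seed, stages = stages, files = sort(unique(files))
  )
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  log_line("total wall_s=%.2f",
           as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  invisible(c(state, list(out_dir = out_dir, manifest = mf)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
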