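# Configuration-driven orchestration and file I/O shared by all stages.
#
# All persisted formats are plain text or TIFF: luminance images as 32-bit
# TIFF with a JSON sidecar carrying units and seeds, tables as CSV, fitted
# parameters and manifests as JSON.

#' Write / read a stimulus movie
#'
#' Frames are stored as a multi-page 32-bit TIFF (values are normalized
#' luminance in `[0, 1]`); frame rate, angular resolution, epoch labels, seed
#' and I_max go into a JSON sidecar `<path>.json`.
#'
#' @param movie A [stimulus_movie()].
#' @param path Output TIFF path.
#' @return `path`, invisibly (`write`); a [stimulus_movie()] (`read`).
#' @export
write_stimulus_movie <- function(movie, path) {
  stopifnot(inherits(movie, "stimulus_movie"))
  d <- dim(movie$frames)
  pages <- lapply(seq_len(d[1]), function(i) movie$frames[i, , , drop = TRUE])
  pages <- lapply(pages, function(p) matrix(p, d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(frame_rate = movie$frame_rate,
               degrees_per_pixel = movie$degrees_per_pixel,
               epoch_labels = movie$epoch_labels, seed = movie$seed,
               i_max = movie$i_max)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_movie
#' @export
read_stimulus_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  stimulus_movie(frames, side$frame_rate, side$degrees_per_pixel,
                 side$epoch_labels, side$seed %||% NA_integer_,
                 side$i_max %||% 21.7)
}

#' Write / read a scene as 32-bit TIFF with a JSON sidecar
#'
#' Luminance is stored scaled to `[0, 1]`; the scaling maximum, angular
#' resolution, label and seed are recorded in `<path>.json`.
#'
#' @param scn A [scene()].
#' @param path Output TIFF path.
#' @return `path`, invisibly (`write`); a [scene()] (`read`).
#' @export
write_scene_tiff <- function(scn, path) {
  stopifnot(inherits(scn, "scene"))
  mx <- max(scn$luminance, 1e-300)
  tiff::writeTIFF(scn$luminance / mx, path, bits.per.sample = 32L)
  jsonlite::write_json(list(degrees_per_pixel = scn$degrees_per_pixel,
                            condition_label = scn$condition_label,
                            seed = scn$seed, luminance_max = mx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_tiff
#' @export
read_scene_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scene(img * side$luminance_max, side$degrees_per_pixel,
        side$condition_label, side$seed %||% NA_integer_)
}

#' Read a contrast-response table from CSV
#'
#' Validates the columns expected by [fit_membrane_params()]: `luminance`,
#' `contrast`, `response`, optionally `cell_type` and `signal`.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_contrast_table <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("luminance", "contrast", "response")
  if (!all(need %in% names(tab))) {
    stop_invalid("contrast table needs columns %s", paste(need, collapse = ", "))
  }
  tab
}

#' Write ROI traces to CSV (long format) and read them back
#'
#' Columns `roi`, `trial`, `time_s`, `value`; the frame rate is inferred on
#' read from the time stamps.
#'
#' @param rec A [generate_recording()] result (or an array `[roi, time,
#'   trial]` plus `frame_rate`).
#' @param path CSV file path.
#' @param frame_rate Frame rate when `rec` is a bare array.
#' @return `path` invisibly (`write`); a list with `traces`, `frame_rate`
#'   (`read`).
#' @export
write_roi_traces <- function(rec, path, frame_rate = NULL) {
  if (inherits(rec, "roi_recording")) {
    traces <- rec$traces; frame_rate <- rec$frame_rate
  } else traces <- rec
  d <- dim(traces)
  long <- data.frame(
    roi = rep(seq_len(d[1]), times = d[2] * d[3]),
    trial = rep(seq_len(d[3]), each = d[1] * d[2]),
    time_s = rep(rep((seq_len(d[2]) - 1) / frame_rate, each = d[1]), d[3]),
    value = as.numeric(traces))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_traces
#' @export
read_roi_traces <- function(path) {
  long <- utils::read.csv(path)
  rois <- sort(unique(long$roi)); trials <- sort(unique(long$trial))
  times <- sort(unique(long$time_s))
  traces <- array(0, dim = c(length(rois), length(times), length(trials)))
  long <- long[order(long$trial, long$time_s, long$roi), ]
  traces[] <- long$value
  fr <- if (length(times) > 1) 1 / stats::median(diff(times)) else NA_real_
  list(traces = traces, frame_rate = fr, times = times)
}

## ---- pipeline ---------------------------------------------------------------

pipeline_stage_requirements <- list(
  scenes = character(0),
  circuit = character(0),
  recordings = character(0))

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order and writes every product
#' plus a JSON manifest (package version, global seed, per-stage seeds, MD5
#' hashes of all outputs) into the output directory. Stages: `"scenes"`
#' (synthesize an ensemble and scan pooling sizes), `"circuit"` (simulate Tm
#' contrast-response curves for p = 1 and p = 2), `"recordings"` (ternary
#' noise movie, synthetic recording, reliability and STRF analysis). Each
#' stochastic stage derives its own substream from the global seed. A failing
#' stage aborts with the stage named and leaves a `<stage>.failed` marker;
#' earlier outputs are retained.
#'
#' @param config A list or path to a YAML file. Top-level fields: `stages`
#'   (character vector), `seed` (integer), `out_dir` (directory), plus one
#'   optional list per stage with that stage's parameters (see the stage
#'   functions for names).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("stages", "seed", "out_dir")) {
    if (is.null(config[[field]])) {
      stop_invalid("config validation: missing required field '%s'", field)
    }
  }
  stages <- config$stages
  unknown <- setdiff(stages, names(pipeline_stage_requirements))
  if (length(unknown)) {
    stop_invalid("config validation: unknown stage(s) %s",
                 paste(unknown, collapse = ", "))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(package = "lumigain",
                   version = as.character(utils::packageVersion("lumigain")),
                   seed = seed, stages = list())
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      file.create(file.path(out_dir, paste0(name, ".failed")))
      stop_invalid("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- res
  }
  if ("scenes" %in% stages) run_stage("scenes", function() {
    p <- config$scenes %||% list()
    s_seed <- substream_seed(seed, "scenes")
    ens <- synthesize_scene_ensemble(size = p$size %||% 128,
                                     seed = s_seed)
    scan <- scan_pooling_sizes(ens,
                               diameters = p$diameters %||% c(0.5, 2, 8, 32),
                               n_trajectories = p$n_trajectories %||% 15,
                               seed = s_seed)
    f <- file.path(out_dir, "pooling_scan.csv")
    utils::write.csv(scan$summary, f, row.names = FALSE)
    list(seed = s_seed, outputs = "pooling_scan.csv",
         best_diameter = scan$summary$pooling_diameter[
           which.min(scan$summary$loss_mean)])
  })
  if ("circuit" %in% stages) run_stage("circuit", function() {
    p <- config$circuit %||% list()
    s_seed <- substream_seed(seed, "circuit")
    n <- p$n_traces %||% 200
    rows <- lapply(c(1, 2), function(pp) {
      cc <- simulate_contrast_curves(normalization_params(p = pp),
                                     n_traces = n, seed = s_seed)
      cbind(p = pp, cc$curve, slope_tm = cc$slope_tm,
            slope_input = cc$slope_input)
    })
    f <- file.path(out_dir, "circuit_curves.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    list(seed = s_seed, outputs = "circuit_curves.csv")
  })
  if ("recordings" %in% stages) run_stage("recordings", function() {
    p <- config$recordings %||% list()
    s_seed <- substream_seed(seed, "recordings")
    mov <- make_ternary_noise(noise_spec(element = "stripe",
                                         duration = p$duration %||% 60,
                                         seed = s_seed),
                              screen_geometry())
    man <- recording_manifest(ground_truth_neuron(noise_sd = p$noise_sd %||% 0.1),
                              n_trials = p$n_trials %||% 3, seed = s_seed)
    rec <- generate_recording(man, mov)
    f_tr <- file.path(out_dir, "recording.csv")
    write_roi_traces(rec, f_tr)
    rel <- roi_reliability(t(rec$traces[1, , ]))
    strf <- compute_strf(rowMeans(rec$traces[1, , , drop = TRUE]), mov,
                         rec$frame_rate)
    f_k <- file.path(out_dir, "strf_kernel.csv")
    utils::write.csv(strf$kernel, f_k, row.names = FALSE)
    list(seed = s_seed, outputs = c("recording.csv", "strf_kernel.csv"),
         reliability = rel$reliability, strf_amplitude = strf$amplitude)
  })
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$hashes <- as.list(tools::md5sum(files))
  names(manifest$hashes) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
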