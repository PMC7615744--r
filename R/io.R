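#' Analysis configuration with schema validation
#'
#' Collects every tunable of the analysis pipeline with its default. The
#' configuration is validated strictly: unknown keys are rejected
#' (fail-fast), and every report embeds the resolved configuration as
#' provenance.
#'
#' @param calibration Named list of [calibration_curve()] arguments.
#' @param beta Cytoplasmic buffering capacity used to scale free-Ca
#'   derivatives into total fluxes (pure scaling; always reported).
#' @param diastolic_window Pre-stimulus window defining the diastolic
#'   level, s.
#' @param resting_window Pre-caffeine window defining the resting level, s.
#' @param resting_gap Gap between the resting window and caffeine onset, s.
#' @param fit_window Amplitude-fraction pair delimiting the flux-fit decay.
#' @param mode SERCA fit mode, `"ncx-subtracted"` or `"lumped"`.
#' @param serca_sg_n,ncx_sg_n Savitzky-Golay window lengths (samples) for
#'   the CaT and caffeine recoveries.
#' @param sg_p Savitzky-Golay polynomial order.
#' @param discard_first_n Pre-steady-state beats discarded before
#'   averaging.
#' @param prominence_k Peak-detection threshold in robust noise s.d. units.
#' @param peak_method Caffeine-peak estimator, `"fit"` or `"max"`.
#' @param seed Integer seed recorded for any stochastic step.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(calibration = list(), beta = 100,
                            diastolic_window = 0.05, resting_window = 0.05,
                            resting_gap = 0, fit_window = c(0.9, 0.1),
                            mode = c("ncx-subtracted", "lumped"),
                            serca_sg_n = 11, ncx_sg_n = 41, sg_p = 2,
                            discard_first_n = 2, prominence_k = 4,
                            peak_method = c("fit", "max"), seed = 1L) {
  cfg <- list(version = 1L, calibration = calibration, beta = beta,
              diastolic_window = diastolic_window,
              resting_window = resting_window, resting_gap = resting_gap,
              fit_window = fit_window, mode = match.arg(mode),
              serca_sg_n = serca_sg_n, ncx_sg_n = ncx_sg_n, sg_p = sg_p,
              discard_first_n = discard_first_n, prominence_k = prominence_k,
              peak_method = match.arg(peak_method), seed = as.integer(seed))
  validate_config(cfg)
}

config_schema_keys <- c("version", "calibration", "beta", "diastolic_window",
                        "resting_window", "resting_gap", "fit_window", "mode",
                        "serca_sg_n", "ncx_sg_n", "sg_p", "discard_first_n",
                        "prominence_k", "peak_method", "seed")

#' Validate an analysis configuration against the schema
#'
#' @param cfg A list of configuration values (e.g. from [read_config()]).
#' @return The validated configuration of class `analysis_config`.
#' @export
validate_config <- function(cfg) {
  if (inherits(cfg, "analysis_config")) return(cfg)
  stopifnot(is.list(cfg))
  unknown <- setdiff(names(cfg), config_schema_keys)
  if (length(unknown))
    stop("validate_config: unknown configuration keys: ",
         paste(unknown, collapse = ", "))
  defaults <- list(version = 1L, calibration = list(), beta = 100,
                   diastolic_window = 0.05, resting_window = 0.05,
                   resting_gap = 0, fit_window = c(0.9, 0.1),
                   mode = "ncx-subtracted", serca_sg_n = 11, ncx_sg_n = 41,
                   sg_p = 2, discard_first_n = 2, prominence_k = 4,
                   peak_method = "fit", seed = 1L)
  for (k in names(cfg)) defaults[[k]] <- cfg[[k]]
  cfg <- defaults
  if (!identical(as.integer(cfg$version), 1L))
    stop("validate_config: unsupported config version: ", cfg$version)
  if (!cfg$mode %in% c("ncx-subtracted", "lumped"))
    stop("validate_config: mode must be 'ncx-subtracted' or 'lumped'")
  if (!cfg$peak_method %in% c("fit", "max"))
    stop("validate_config: peak_method must be 'fit' or 'max'")
  if (cfg$beta < 1) stop("validate_config: beta must be >= 1")
  if (length(cfg$fit_window) != 2 || any(cfg$fit_window <= 0) ||
      any(cfg$fit_window >= 1))
    stop("validate_config: fit_window must be two fractions in (0, 1)")
  bad <- setdiff(names(cfg$calibration),
                 c("r_min", "r_max", "kd", "sat_ratio", "id"))
  if (length(bad))
    stop("validate_config: unknown calibration keys: ",
         paste(bad, collapse = ", "))
  do.call(calibration_curve, cfg$calibration)  # side-effect: validates
  structure(cfg, class = "analysis_config")
}

#' Read / write an analysis configuration (YAML or JSON)
#'
#' The format is inferred from the file extension (`.yaml`/`.yml` or
#' `.json`). Unknown keys are rejected on read.
#'
#' @param path File path.
#' @param cfg An [analysis_config()].
#' @return `read_config` returns a validated `analysis_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("read_config: unsupported extension: ", ext))
  if (!is.null(cfg$fit_window)) cfg$fit_window <- as.numeric(cfg$fit_window)
  validate_config(cfg)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  ext <- tolower(tools::file_ext(path))
  x <- unclass(cfg)
  switch(ext,
         yaml = , yml = yaml::write_yaml(x, path),
         json = jsonlite::write_json(x, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         stop("write_config: unsupported extension: ", ext))
  invisible(path)
}

#' Write a fluorescence trace as CSV with a JSON metadata sidecar
#'
#' The CSV holds `time_s` plus either both channels (`ch_num`, `ch_den`)
#' or a precomputed `ratio`; the sidecar (same path with `.json`) holds
#' `stimulus_times_s`, `caffeine_onset_s`, backgrounds, dye and
#' calibration id. The round trip through [read_trace()] is lossless to
#' full double precision.
#'
#' @param trace A [fluorescence_trace()].
#' @param path CSV path; the sidecar replaces its extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  df <- data.frame(time_s = fmt_num(trace$time))
  if (!is.null(trace$ch_num)) {
    df$ch_num <- fmt_num(trace$ch_num)
    df$ch_den <- fmt_num(trace$ch_den)
  } else {
    df$ratio <- fmt_num(trace$ratio)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(stimulus_times_s = trace$stimulus_times,
               caffeine_onset_s = trace$caffeine_onset,
               bg_num = trace$bg_num, bg_den = trace$bg_den,
               dye = trace$dye, calibration_id = trace$calibration_id)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)
sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a fluorescence trace written by [write_trace()]
#'
#' @param path CSV path (a `.json` sidecar next to it is read when
#'   present).
#' @return A [fluorescence_trace()].
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df))
    stop("read_trace: schema error, missing required column(s): time_s")
  two_ch <- all(c("ch_num", "ch_den") %in% names(df))
  if (!two_ch && !"ratio" %in% names(df)) {
    miss <- setdiff(c("ch_num", "ch_den"), names(df))
    stop("read_trace: schema error, missing required column(s): ",
         paste(c(miss, "(or 'ratio')"), collapse = ", "))
  }
  side <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  nz <- function(x, d) if (is.null(x)) d else x
  fluorescence_trace(
    time = df$time_s,
    ch_num = if (two_ch) df$ch_num else NULL,
    ch_den = if (two_ch) df$ch_den else NULL,
    ratio = if (!two_ch) df$ratio else NULL,
    bg_num = nz(side$bg_num, 0), bg_den = nz(side$bg_den, 0),
    stimulus_times = nz(side$stimulus_times_s, numeric(0)),
    caffeine_onset = nz(side$caffeine_onset_s, NA_real_),
    dye = nz(side$dye, "unknown"),
    calibration_id = nz(side$calibration_id, NA_character_))
}

#' Write a calcium-handling report to JSON or CSV
#'
#' JSON keeps the nested structure including fits and provenance; CSV
#' writes the flat one-row metric panel.
#'
#' @param report A [full_report()] result.
#' @param path Output path; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ca_handling_report"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    x <- unclass(report)
    x$fits <- lapply(x$fits, function(f) if (is.null(f)) NULL else unclass(f))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  } else if (ext == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else stop("write_report: unsupported extension: ", ext)
  invisible(path)
}
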