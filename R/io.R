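# File round-tripping: NIfTI for image series and integer-coded masks, CSV for
# curves and cohort tables, YAML for configuration, JSON for results. Every
# text output embeds the package version, the configuration hash and the seed
# in comment/metadata fields, so re-running a stage with identical inputs is
# byte-identical.

mpri_version <- function() {
  as.character(utils::packageVersion("mpri"))
}

# Stable MD5 of an R object via its deparsed YAML-able representation.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(paste(deparse(x), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

meta_header <- function(seed = NA, hash = NA) {
  c(sprintf("# mpri %s", mpri_version()),
    sprintf("# seed=%s", seed),
    sprintf("# config_md5=%s", hash))
}

#' Write time-intensity curves to CSV
#'
#' Columns `frame,value,region,state`; provenance (package version, seed,
#' config hash) is embedded as leading `#` comment lines.
#'
#' @param curves A [tic()], a list of curves, or a nested per-state list of
#'   curve sets.
#' @param path Output file.
#' @param seed,hash Provenance fields for the header.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path, seed = NA, hash = NA) {
  df <- curves_to_df(curves)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

curves_to_df <- function(curves) {
  if (inherits(curves, "tic")) return(as.data.frame(curves))
  if (is.list(curves)) {
    parts <- lapply(curves, curves_to_df)
    return(do.call(rbind, c(parts, list(make.row.names = FALSE))))
  }
  input_error("cannot interpret 'curves' as time-intensity curves")
}

#' Read time-intensity curves from CSV
#'
#' Inverse of [write_curves_csv()]. Comment lines starting with `#` are
#' ignored.
#'
#' @param path CSV file with columns `frame,value,region,state`.
#' @return Nested list: per state, a named list of [tic()]s keyed by region.
#' @export
read_curves_csv <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("frame", "value", "region", "state")
  if (!all(needed %in% names(df)))
    input_error(sprintf("%s must have columns %s", path,
                        paste(needed, collapse = ",")))
  out <- list()
  for (st in unique(df$state)) {
    d_st <- df[df$state == st, , drop = FALSE]
    out[[st]] <- lapply(split(d_st, d_st$region), function(d) {
      d <- d[order(d$frame), , drop = FALSE]
      tic(d$frame, d$value, region = d$region[1], state = st)
    })
    # keep blood first, then sectors in canonical order where present
    ord <- intersect(c("blood", SECTOR_NAMES_4), names(out[[st]]))
    out[[st]] <- out[[st]][c(ord, setdiff(names(out[[st]]), ord))]
  }
  out
}

# Mask coding in NIfTI volumes: 0 background, 1 cavity, 2 un-sectored
# myocardium, 11..(10+k) myocardium sector k.
MASK_CAVITY_CODE <- 1L
MASK_MYO_CODE <- 2L
MASK_SECTOR_BASE <- 10L

#' Write a segmentation mask as integer-coded NIfTI
#'
#' @param mask A [segmentation_mask()].
#' @param path Output `.nii`/`.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "segmentation_mask"))
  coded <- matrix(0L, mask$dim[1], mask$dim[2])
  coded[mask$cavity] <- MASK_CAVITY_CODE
  myo_codes <- ifelse(is.na(mask$sector[mask$myocardium]), MASK_MYO_CODE,
                      MASK_SECTOR_BASE + mask$sector[mask$myocardium])
  coded[mask$myocardium] <- as.integer(myo_codes)
  RNifti::writeNifti(coded, path, datatype = "int16")
  invisible(path)
}

#' Read an integer-coded segmentation mask from NIfTI
#'
#' @param path NIfTI file written by [write_mask_nifti()].
#' @param center,reference_angle Geometry metadata to re-attach (NIfTI stores
#'   only the label volume); defaults to the grid center and angle 0.
#' @return A [segmentation_mask()].
#' @export
read_mask_nifti <- function(path, center = NULL, reference_angle = 0) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  coded <- as.array(RNifti::readNifti(path))
  if (length(dim(coded)) != 2L)
    input_error("a mask volume must be 2-D")
  if (is.null(center)) center <- (dim(coded) + 1) / 2
  cavity <- coded == MASK_CAVITY_CODE
  myocardium <- coded == MASK_MYO_CODE | coded > MASK_SECTOR_BASE
  sector <- matrix(NA_integer_, nrow(coded), ncol(coded))
  sector[coded > MASK_SECTOR_BASE] <-
    as.integer(coded[coded > MASK_SECTOR_BASE] - MASK_SECTOR_BASE)
  n_sec <- max(sector, 0L, na.rm = TRUE)
  sector_names <- if (n_sec == 4L) SECTOR_NAMES_4 else
    paste0("sector", seq_len(max(n_sec, 1L)))
  segmentation_mask(cavity, myocardium, sector, sector_names, center,
                    reference_angle)
}

#' Write / read an image series as NIfTI
#'
#' The series is stored as a 3-D volume `(x, y, frame)` in float64, so the
#' round trip is exact.
#'
#' @param series Numeric array `(x, y, frame)`.
#' @param path NIfTI file.
#' @return `write_series_nifti`: `path` invisibly; `read_series_nifti`: the
#'   array.
#' @export
write_series_nifti <- function(series, path) {
  if (!is.array(series) || length(dim(series)) != 3L)
    input_error("'series' must be a 3-D array (x, y, frame)")
  RNifti::writeNifti(series, path, datatype = "double")
  invisible(path)
}

#' @rdname write_series_nifti
#' @export
read_series_nifti <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) input_error("a series volume must be 3-D")
  arr
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `phantom` (fields of [phantom_config()], with `states`
#' given as `stress_multiplier`/`recovery_multiplier`/`signal_gain`/
#' `baseline_offset`), `analysis` (`window_len`, `k_baseline`, `threshold_sd`,
#' `times100`, `smooth`), `seed`. Missing keys fall back to package defaults.
#'
#' @param path YAML file.
#' @return List with `phantom` (a [phantom_config()]), `analysis`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    config_error(sprintf("malformed YAML in %s: %s", path, conditionMessage(e))))
  if (!is.list(raw)) config_error(sprintf("%s does not contain a mapping", path))
  build_run_config(raw)
}

build_run_config <- function(raw) {
  ph <- raw$phantom %||% list()
  seed <- raw$seed %||% ph$seed %||% 1L
  states <- default_states(
    stress_multiplier = ph$stress_multiplier %||% 2.0,
    recovery_multiplier = ph$recovery_multiplier %||% 1.68,
    signal_gain = unlist(ph$signal_gain %||% c(1, 1, 1)),
    baseline_offset = unlist(ph$baseline_offset %||% c(10, 10, 10))
  )
  config <- tryCatch(
    phantom_config(
      grid = ph$grid %||% 48, cavity_radius = ph$cavity_radius %||% 8,
      r_inner = ph$r_inner %||% 10, r_outer = ph$r_outer %||% 15,
      n_frames = ph$n_frames %||% 50,
      aif = do.call(aif_params, ph$aif %||% list()),
      kinetics = do.call(kinetic_params, ph$kinetics %||% list()),
      states = states, noise_sd = ph$noise_sd %||% 2,
      seed = seed,
      delayed_hyperemia = isTRUE(ph$delayed_hyperemia),
      saturation_smax = ph$saturation_smax %||% Inf
    ),
    mpri_parameter_error = function(e) config_error(conditionMessage(e)),
    mpri_config_error = function(e) config_error(conditionMessage(e))
  )
  an <- raw$analysis %||% list()
  analysis <- list(
    window_len = an$window_len %||% 3L,
    k_baseline = an$k_baseline %||% 5L,
    threshold_sd = an$threshold_sd %||% 2,
    times100 = an$times100 %||% TRUE,
    smooth = isTRUE(an$smooth)
  )
  list(phantom = config, analysis = analysis, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_json_result <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Simulate a subject and write all phantom outputs
#'
#' Writes, per state, the image series and integer-coded mask as NIfTI, all
#' region curves as one CSV, the ground truth as JSON, and an echo of the
#' configuration as YAML.
#'
#' @param config A [phantom_config()], a run-config list from
#'   [read_run_config()], or a path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed override.
#' @return Named list of written paths, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  rc <- coerce_run_config(config)
  if (!is.null(seed)) {
    check_scalar(seed, "seed", integer = TRUE)
    rc$seed <- as.integer(seed)
    rc$phantom$seed <- as.integer(seed)
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    io_error(sprintf("cannot create output directory %s", out_dir))
  hash <- config_hash(rc$phantom)
  sub <- simulate_subject(rc$phantom, render = TRUE)
  paths <- list()
  for (st in names(sub$states)) {
    p_series <- file.path(out_dir, sprintf("series_%s.nii.gz", st))
    p_mask <- file.path(out_dir, sprintf("mask_%s.nii.gz", st))
    write_series_nifti(sub$states[[st]]$series, p_series)
    write_mask_nifti(sub$states[[st]]$mask, p_mask)
    paths[[paste0("series_", st)]] <- p_series
    paths[[paste0("mask_", st)]] <- p_mask
  }
  p_curves <- file.path(out_dir, "curves.csv")
  write_curves_csv(lapply(sub$states, `[[`, "curves"), p_curves,
                   seed = rc$phantom$seed, hash = hash)
  paths$curves <- p_curves
  p_truth <- file.path(out_dir, "truth.json")
  write_json_result(c(list(tool = "mpri", version = mpri_version(),
                           seed = rc$phantom$seed, config_md5 = hash),
                      sub$truth), p_truth)
  paths$truth <- p_truth
  p_cfg <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(serialize_config(rc), p_cfg)
  paths$config <- p_cfg
  message(sprintf("simulated subject (seed %d) -> %s", rc$phantom$seed, out_dir))
  invisible(paths)
}

coerce_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) return(read_run_config(config))
  if (inherits(config, "phantom_config"))
    return(list(phantom = config, analysis = build_run_config(list())$analysis,
                seed = config$seed))
  if (is.list(config) && !is.null(config$phantom)) return(config)
  config_error("'config' must be a phantom_config, a run-config list, or a YAML path")
}

serialize_config <- function(rc) {
  ph <- rc$phantom
  list(
    tool = "mpri", version = mpri_version(), seed = ph$seed,
    phantom = list(
      grid = ph$grid, cavity_radius = ph$cavity_radius,
      r_inner = ph$r_inner, r_outer = ph$r_outer, n_frames = ph$n_frames,
      aif = unclass(ph$aif), kinetics = unclass(ph$kinetics),
      stress_multiplier = ph$states$stress$flow_multiplier,
      recovery_multiplier = ph$states$recovery$flow_multiplier,
      signal_gain = vapply(ph$states, `[[`, numeric(1), "signal_gain"),
      baseline_offset = vapply(ph$states, `[[`, numeric(1), "baseline_offset"),
      noise_sd = ph$noise_sd,
      delayed_hyperemia = ph$delayed_hyperemia,
      saturation_smax = if (is.finite(ph$saturation_smax)) ph$saturation_smax else "Inf"
    ),
    analysis = rc$analysis
  )
}

#' Analyze a subject from files
#'
#' Accepts either a curves CSV (as written by [run_simulate()]) or a directory
#' containing per-state `series_<state>.nii.gz` + `mask_<state>.nii.gz` pairs;
#' in the latter case curves are extracted from the images first. Writes the
#' subject perfusion summary as JSON and the per-curve up-slope table as CSV.
#'
#' @param input Path to a curves CSV or to a [run_simulate()] output directory.
#' @param out_dir Output directory (defaults to the input's directory).
#' @param id,group Subject labels recorded in the outputs.
#' @param window_len,k_baseline,threshold_sd,times100,smooth Analysis
#'   parameters (see [max_upslope()] and [normalize_upslopes()]).
#' @return The `subject_perfusion` object, invisibly.
#' @export
run_analyze <- function(input, out_dir = NULL, id = "subject",
                        group = NA_character_, window_len = 3L,
                        k_baseline = 5L, threshold_sd = 2, times100 = TRUE,
                        smooth = FALSE) {
  states <- c("rest", "stress", "recovery")
  if (dir.exists(input)) {
    curves_file <- file.path(input, "curves.csv")
    series_files <- file.path(input, sprintf("series_%s.nii.gz", states))
    if (all(file.exists(series_files))) {
      curves <- list()
      for (st in states) {
        series <- read_series_nifti(file.path(input, sprintf("series_%s.nii.gz", st)))
        mask_path <- file.path(input, sprintf("mask_%s.nii.gz", st))
        if (!file.exists(mask_path))
          input_error(sprintf("missing mask for state '%s'", st))
        mask <- read_mask_nifti(mask_path)
        curves[[st]] <- extract_state_curves(series, mask, state = st)
      }
    } else if (file.exists(curves_file)) {
      curves <- read_curves_csv(curves_file)
    } else {
      input_error(sprintf(
        "%s contains neither per-state series/mask NIfTI files nor curves.csv",
        input))
    }
    if (is.null(out_dir)) out_dir <- input
  } else if (file.exists(input)) {
    curves <- read_curves_csv(input)
    if (is.null(out_dir)) out_dir <- dirname(input)
  } else {
    io_error(sprintf("no such input: %s", input))
  }
  missing_states <- setdiff(states, names(curves))
  if (length(missing_states) > 0L)
    input_error(sprintf("input lacks state(s): %s",
                        paste(missing_states, collapse = ", ")))
  subject <- analyze_subject(curves, id = id, group = group,
                             window_len = window_len, k_baseline = k_baseline,
                             threshold_sd = threshold_sd, times100 = times100,
                             smooth = smooth)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_json_result(
    list(tool = "mpri", version = mpri_version(),
         id = subject$id, group = subject$group,
         upslope = list(rest = subject$rest, stress = subject$stress,
                        recovery = subject$recovery),
         sectors = subject$sectors,
         mpri_rest = subject$mpri_rest, mpri_recov = subject$mpri_recov,
         percent_reduction = subject$percent_reduction,
         recovery_to_rest = subject$recovery_to_rest,
         delayed = subject$delayed),
    file.path(out_dir, sprintf("subject_%s.json", id)))
  est_rows <- do.call(rbind, lapply(subject$estimates, function(state_ests) {
    do.call(rbind, lapply(state_ests, function(e) {
      data.frame(region = e$region, state = e$state, slope = e$slope,
                 window_start = e$window_start, window_end = e$window_end,
                 r2 = e$r2, baseline = e$baseline, foot = e$foot,
                 stringsAsFactors = FALSE)
    }))
  }))
  p_csv <- file.path(out_dir, sprintf("upslopes_%s.csv", id))
  con <- file(p_csv, "w")
  writeLines(meta_header(), con)
  utils::write.csv(est_rows, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(subject)
}

#' Cohort report from per-subject results
#'
#' @param results data.frame of per-subject results (see [summarize_cohort()])
#'   or a path to a cohort CSV with those columns.
#' @param out_dir Output directory for `cohort_summary.csv`,
#'   `cohort_tests.json` and `cohort_report.txt`.
#' @return The `cohort_summary`, invisibly.
#' @export
run_cohort <- function(results, out_dir) {
  if (is.character(results)) {
    if (!file.exists(results)) io_error(sprintf("no such file: %s", results))
    results <- utils::read.csv(results, comment.char = "#",
                               stringsAsFactors = FALSE)
  }
  summary <- summarize_cohort(results)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p_csv <- file.path(out_dir, "cohort_summary.csv")
  con <- file(p_csv, "w")
  writeLines(meta_header(), con)
  utils::write.csv(summary$group_table, con, row.names = FALSE, quote = FALSE)
  close(con)
  write_json_result(
    list(tool = "mpri", version = mpri_version(),
         group_table = summary$group_table, between = summary$between),
    file.path(out_dir, "cohort_tests.json"))
  txt <- utils::capture.output(print(summary))
  writeLines(c(meta_header(), txt), file.path(out_dir, "cohort_report.txt"))
  invisible(summary)
}
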