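# strict numeric-column reader shared by the CSV dialects
read_strict_csv <- function(path, required) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  df <- utils::read.csv(path, check.names = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_invalid("%s: missing column(s) %s", basename(path),
                 paste(missing, collapse = ", "))
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop_invalid("%s: non-numeric value in column '%s' at data row %d",
                   basename(path), col, if (is.na(bad)) 1L else bad)
    }
    if (anyNA(v))
      stop_invalid("%s: missing/truncated value in column '%s' at data row %d",
                   basename(path), col, which(is.na(v))[1])
  }
  df
}

#' Read and write the marker CSV dialect
#'
#' Columns `time_s` then `<marker>_x/_y/_z` in metres for the six joint
#' markers, plus `spring_end_thigh`/`spring_end_shank` triplets in brace
#' recordings.  Columns are header-keyed, so order does not matter.
#'
#' @param path CSV file path.
#' @return a marker recording data frame (`time` in s, coordinates in m).
#' @export
read_marker_csv <- function(path) {
  base <- unlist(lapply(joint_marker_names(), marker_cols))
  df <- read_strict_csv(path, c("time_s", paste0(base)))
  out <- data.frame(time = df$time_s)
  keep <- grep("_(x|y|z)$", names(df), value = TRUE)
  for (col in keep) out[[col]] <- df[[col]]
  check_uniform_time(out$time, "marker time")
  out
}

#' @rdname read_marker_csv
#' @param markers a marker recording data frame.
#' @return `path`, invisibly (writers).
#' @export
write_marker_csv <- function(markers, path) {
  stopifnot(is.data.frame(markers), "time" %in% names(markers))
  out <- markers
  names(out)[names(out) == "time"] <- "time_s"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and write the load-cell CSV dialect
#'
#' Columns `time_s`, `lc1_N`, `lc2_N`, `lc3_N` (vertical force per load
#' cell, N, at the load-cell rate).
#'
#' @param path CSV file path.
#' @return a force recording data frame (`time`, `lc1`, `lc2`, `lc3`).
#' @export
read_force_csv <- function(path) {
  df <- read_strict_csv(path, c("time_s", "lc1_N", "lc2_N", "lc3_N"))
  out <- data.frame(time = df$time_s, lc1 = df$lc1_N, lc2 = df$lc2_N,
                    lc3 = df$lc3_N)
  check_uniform_time(out$time, "force time")
  out
}

#' @rdname read_force_csv
#' @param forces a force recording data frame.
#' @export
write_force_csv <- function(forces, path) {
  stopifnot(is.data.frame(forces),
            all(c("time", "lc1", "lc2", "lc3") %in% names(forces)))
  utils::write.csv(data.frame(time_s = forces$time, lc1_N = forces$lc1,
                              lc2_N = forces$lc2, lc3_N = forces$lc3),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write the torsion-test CSV dialect
#'
#' Columns `time_s`, `angle_deg`, `moment_Nm`; angles are converted to
#' radians on read.
#'
#' @param path CSV file path.
#' @return a `torsion_recording` data frame (`time` s, `angle` rad, `moment`
#'   N m).
#' @export
read_torsion_csv <- function(path) {
  df <- read_strict_csv(path, c("time_s", "angle_deg", "moment_Nm"))
  out <- data.frame(time = df$time_s, angle = deg2rad(df$angle_deg),
                    moment = df$moment_Nm)
  check_uniform_time(out$time, "torsion time")
  class(out) <- c("torsion_recording", "data.frame")
  out
}

#' @rdname read_torsion_csv
#' @param rec a `torsion_recording` data frame.
#' @export
write_torsion_csv <- function(rec, path) {
  stopifnot(is.data.frame(rec),
            all(c("time", "angle", "moment") %in% names(rec)))
  utils::write.csv(data.frame(time_s = rec$time,
                              angle_deg = rad2deg(rec$angle),
                              moment_Nm = rec$moment),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write / read the simulator ground-truth log
#'
#' JSON-lines: one object per force-rate sample with fields `i`, `M`,
#' `theta_s` (rad) and `Fay`.
#'
#' @param truth the `truth` data frame of a [simulate_phantom()] result.
#' @param path output `.jsonl` path.
#' @export
write_truth_jsonl <- function(truth, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(truth))) {
    writeLines(jsonlite::toJSON(
      list(i = i, M = truth$M[i], theta_s = truth$theta_s[i],
           Fay = truth$Fay[i]),
      auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_truth_jsonl
#' @export
read_truth_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(i = x$i, M = x$M,
               theta_s = if (is.null(x$theta_s)) NA_real_ else x$theta_s,
               Fay = x$Fay)
  })
  do.call(rbind, rows)
}

# ---- run configuration -----------------------------------------------------

default_run_config <- function() {
  list(
    phantom = list(condition = "braceless", lf = 0.32, lt = 0.32),
    gait = list(stride_time = 1, sample_rate = 100, n_cycles = 15,
                keypoints = list(percent = c(0, 15, 40, 72, 100),
                                 angle_deg = c(5, 20, 8, 65, 5)),
                amplitude_scale = 1),
    exo = list(mode = "none", Ks = 0, theta_free_deg = 0, damping_b = 0,
               compliance_c = 1, compliance_d_deg = 0),
    noise = list(marker_sigma = 2e-4, force_sigma = 0.5, seed = 1),
    processing = list(cutoff_hz = 6, order = 4, trim_cycles = 1,
                      marker_rate = 100, force_rate = 1000,
                      mount_angle_deg = 180, lateral_offset = 0.05,
                      spring_arm = 0.06)
  )
}

merge_config <- function(defaults, user) {
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(user[[key]])))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]])
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Resolve a run configuration
#'
#' Loads a YAML configuration (or takes a list), fills in package defaults
#' for every omitted field, and validates the blocks by constructing the
#' corresponding parameter objects.  Angles in the file are degrees; the
#' schema is documented in the methods vignette and mirrored by
#' [default_run_config()].
#'
#' @param config a YAML file path, a list, or `NULL` for pure defaults.
#' @return the resolved configuration list (class `run_config`).
#' @export
resolve_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) {
    if (!file.exists(config)) stop_invalid("config file not found: %s", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop_invalid("'config' must be a file path, list, or NULL")
  cfg <- merge_config(default_run_config(), user)
  # validate by construction
  config_objects(cfg)
  structure(cfg, class = c("run_config", "list"))
}

# build the typed objects a config describes
config_objects <- function(cfg) {
  params <- do.call(phantom_params, c(list(condition = cfg$phantom$condition,
                                           lf = cfg$phantom$lf,
                                           lt = cfg$phantom$lt),
                                      cfg$phantom[setdiff(names(cfg$phantom),
                                                          c("condition", "lf", "lt"))]))
  kp <- cbind(cfg$gait$keypoints$percent, cfg$gait$keypoints$angle_deg)
  gait <- gait_waveform_spec(stride_time = cfg$gait$stride_time,
                             sample_rate = cfg$gait$sample_rate,
                             n_cycles = cfg$gait$n_cycles,
                             keypoints = kp,
                             amplitude_scale = cfg$gait$amplitude_scale)
  exo <- exo_model(mode = cfg$exo$mode, Ks = cfg$exo$Ks,
                   theta_free = deg2rad(cfg$exo$theta_free_deg),
                   damping_b = cfg$exo$damping_b,
                   compliance_c = cfg$exo$compliance_c,
                   compliance_d = deg2rad(cfg$exo$compliance_d_deg))
  noise <- noise_spec(marker_sigma = cfg$noise$marker_sigma,
                      force_sigma = cfg$noise$force_sigma,
                      seed = cfg$noise$seed)
  list(params = params, gait = gait, exo = exo, noise = noise,
       processing = cfg$processing)
}

# small rolling hash of the serialized config, for run provenance
config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(cfg)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
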