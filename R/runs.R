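# write the resolved config + provenance next to every run's outputs
write_provenance <- function(cfg, out_dir, seed) {
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "resolved_config.yaml"))
  meta <- list(config_hash = config_hash(cfg), seed = seed,
               package_version = as.character(utils::packageVersion("kneephantom")),
               r_version = as.character(getRversion()))
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a phantom run from a configuration
#'
#' Generates the gait waveform, forward-simulates the instrumented phantom
#' and writes `markers.csv`, `forces.csv`, `truth.jsonl`, the hexapod command
#' `hexapod.csv`, and the resolved configuration + run metadata into
#' `out_dir`.
#'
#' @param config a YAML path, list, or `NULL` (see [resolve_config()]).
#' @param out_dir output directory (created if missing).
#' @param seed optional override of the configured noise seed.
#' @return the [simulate_phantom()] result, invisibly.
#' @export
run_simulate <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- resolve_config(config)
  if (!is.null(seed)) cfg$noise$seed <- as.integer(seed)
  obj <- config_objects(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- generate_gait_waveform(obj$gait)
  sim <- simulate_phantom(obj$params, traj, obj$exo, obj$noise,
                          marker_rate = obj$processing$marker_rate,
                          force_rate = obj$processing$force_rate,
                          lateral_offset = obj$processing$lateral_offset,
                          spring_arm = obj$processing$spring_arm,
                          mount_angle = deg2rad(obj$processing$mount_angle_deg))
  write_marker_csv(sim$markers, file.path(out_dir, "markers.csv"))
  write_force_csv(sim$forces, file.path(out_dir, "forces.csv"))
  write_truth_jsonl(sim$truth, file.path(out_dir, "truth.jsonl"))
  write_hexapod_csv(plan_hexapod_trajectory(traj, obj$params),
                    file.path(out_dir, "hexapod.csv"))
  write_provenance(cfg, out_dir, cfg$noise$seed)
  invisible(sim)
}

profile_as_list <- function(p) {
  list(basis = p$basis, slope_Nm_per_rad = p$slope, slope_se = p$slope_se,
       x_intercept_deg = p$x_intercept_deg,
       x_intercept_defined = p$x_intercept_defined,
       auc_ratio = p$auc_ratio, r_squared = p$r_squared,
       n_samples = p$n_samples, n_cycles = p$n_cycles)
}

#' Analyze a recorded (or simulated) phantom run
#'
#' Reads the marker and force CSVs, runs [analyze_phantom()] with the
#' configuration's processing block, and writes `loads.csv` and
#' `profile.json` (knee- and spring-basis profiles, deflection regression,
#' tracking RMSE when a target is available) into `out_dir`.
#'
#' @param markers_path,forces_path input CSV paths.
#' @param config a YAML path, list, or `NULL` (see [resolve_config()]).
#' @param out_dir output directory (created if missing).
#' @param target optional commanded [knee_trajectory()] for tracking RMSE;
#'   `TRUE` regenerates it from the config's gait block.
#' @return the [analyze_phantom()] result, invisibly.
#' @export
run_analyze <- function(markers_path, forces_path, config = NULL, out_dir,
                        target = NULL) {
  cfg <- resolve_config(config)
  obj <- config_objects(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  markers <- read_marker_csv(markers_path)
  forces <- read_force_csv(forces_path)
  if (isTRUE(target)) target <- generate_gait_waveform(obj$gait)
  ana <- analyze_phantom(markers, forces, obj$params,
                         stride_time = cfg$gait$stride_time,
                         cutoff = obj$processing$cutoff_hz,
                         order = obj$processing$order,
                         trim_cycles = obj$processing$trim_cycles,
                         mount_angle = deg2rad(obj$processing$mount_angle_deg),
                         target = target)
  write_moment_csv(ana$loads, file.path(out_dir, "loads.csv"))
  out <- list(condition = cfg$exo$mode,
              profile_knee = profile_as_list(ana$profile_knee),
              profile_spring = profile_as_list(ana$profile_spring),
              deflection = ana$deflection,
              rmse_deg = if (is.na(ana$rmse_deg)) NULL else ana$rmse_deg,
              n_cycles_analyzed = ana$n_cycles_analyzed)
  jsonlite::write_json(out, file.path(out_dir, "profile.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(cfg, out_dir, cfg$noise$seed)
  invisible(ana)
}

#' Characterize springs from torsion-test CSVs
#'
#' Reads one torsion CSV per spring, runs [characterize_springs()] (10 Hz
#' zero-phase filtering) and writes `torsion.json` with per-spring and
#' cumulative stiffness.
#'
#' @param paths character vector of torsion CSV paths.
#' @param out_dir output directory (created if missing).
#' @param cutoff filter cutoff (Hz).
#' @return the [characterize_springs()] result, invisibly.
#' @export
run_torsion <- function(paths, out_dir, cutoff = 10) {
  recs <- lapply(paths, read_torsion_csv)
  chr <- characterize_springs(recs, cutoff = cutoff)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(springs = chr$springs, cumulative_Nm_per_rad = chr$cumulative,
              cumulative_se = chr$cumulative_se)
  jsonlite::write_json(out, file.path(out_dir, "torsion.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(chr)
}

#' Combine analyzed conditions into a summary report
#'
#' Collects the `profile.json` of one or more analyzed runs and produces a
#' human-readable JSON report: per-condition metrics, brace-vs-braceless
#' deltas when both conditions are present, and — when a bench cumulative
#' spring stiffness is supplied — the percentage by which each condition's
#' work-loop stiffness differs from the bench value
#' ([stiffness_relative_difference()]).
#'
#' @param run_dirs directories containing `profile.json` (or direct paths to
#'   profile JSON files).
#' @param out_path output JSON path, or `NULL` to skip writing.
#' @param torsion_stiffness optional bench cumulative stiffness (N m/rad).
#' @return the report list, invisibly.
#' @export
run_report <- function(run_dirs, out_path = NULL, torsion_stiffness = NULL) {
  profiles <- lapply(run_dirs, function(d) {
    p <- if (dir.exists(d)) file.path(d, "profile.json") else d
    if (!file.exists(p)) stop_invalid("no profile.json under '%s'", d)
    jsonlite::fromJSON(p)
  })
  names(profiles) <- vapply(profiles, function(p) p$condition, character(1))
  report <- list(conditions = profiles)
  if (all(c("brace", "braceless") %in% names(profiles))) {
    b <- profiles[["brace"]]; bl <- profiles[["braceless"]]
    report$brace_vs_braceless <- list(
      slope_delta_Nm_per_rad = bl$profile_knee$slope_Nm_per_rad -
        b$profile_knee$slope_Nm_per_rad,
      x_intercept_delta_deg = b$profile_knee$x_intercept_deg -
        bl$profile_knee$x_intercept_deg,
      auc_delta = b$profile_knee$auc_ratio - bl$profile_knee$auc_ratio,
      adjusted_slope_delta_Nm_per_rad = bl$profile_spring$slope_Nm_per_rad -
        b$profile_spring$slope_Nm_per_rad)
  }
  if (!is.null(torsion_stiffness)) {
    report$torsion_stiffness_Nm_per_rad <- torsion_stiffness
    report$relative_difference_pct <- lapply(profiles, function(p)
      stiffness_relative_difference(p$profile_knee$slope_Nm_per_rad,
                                    torsion_stiffness))
  }
  if (!is.null(out_path))
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(report)
}
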