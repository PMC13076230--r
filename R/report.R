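#' Read and validate a run configuration
#'
#' A YAML file describing an end-to-end run: the array geometry, the
#' condition list with per-field simulation parameters (for simulated
#' runs) or input stack paths (for quantification of existing stacks), the
#' scoring parameters and the output directory. The parsed configuration
#' is validated up front so a malformed run fails before any computation.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("Config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(config) {
  need <- c("array", "conditions", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0) {
    abort_validation(sprintf(
      "Config is missing required fields: %s", paste(miss, collapse = ", ")
    ))
  }
  a <- config$array
  need_a <- c("mold_diameter_um", "interpillar_um", "height_um")
  miss_a <- setdiff(need_a, names(a))
  if (length(miss_a) > 0) {
    abort_validation(sprintf(
      "Config `array` is missing: %s", paste(miss_a, collapse = ", ")
    ))
  }
  if (!is.null(config$channels)) {
    roles <- unlist(config$channels)
    if (!all(c("PILLAR", "MBP", "NUCLEI") %in% roles)) {
      abort_validation(
        "Config `channels` must map the PILLAR, MBP and NUCLEI roles."
      )
    }
  }
  for (cond in config$conditions) {
    if (is.null(cond$name)) {
      abort_validation("Every condition needs a `name`.")
    }
    for (p in cond$stacks %||% character(0)) {
      if (!file.exists(p)) {
        abort_validation(sprintf("Input stack not found: %s", p))
      }
    }
  }
  structure(config, class = c("run_config", "list"))
}

config_array_spec <- function(config) {
  a <- config$array
  array_spec(
    mold_diameter_um = a$mold_diameter_um,
    interpillar_um = a$interpillar_um,
    height_um = a$height_um,
    swelling_fraction = a$swelling_fraction %||% 0.26,
    rows = a$rows %||% 15L,
    cols = a$cols %||% 15L,
    pixel_size_um = a$pixel_size_um %||% 0.25,
    z_step_um = a$z_step_um %||% 2
  )
}

config_score_bins <- function(config) {
  b <- config$score_bins
  if (is.null(b)) {
    return(score_bins())
  }
  score_bins(
    edges = unlist(b$edges) %||% c(0.05, 0.45, 0.95),
    gap_tolerance_deg = b$gap_tolerance_deg %||% 18
  )
}

#' Simulate a full synthetic dataset to disk
#'
#' For every condition in the configuration, renders the configured number
#' of pillar fields (stack + ground-truth CSV) and, when requested, AFM
#' force curves and lamellar profiles. A JSON manifest lists every file
#' written, together with the seeds used and a hash of the configuration,
#' so a run is reproducible from the manifest alone.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_simulate <- function(config, out_dir) {
  config <- validate_run_config(unclass(config))
  if (!dir.exists(out_dir) &&
    !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    abort_computation(sprintf("Cannot create output directory: %s", out_dir))
  }
  spec <- config_array_spec(config)
  files <- character(0)
  seed0 <- as.integer(config$seed)
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[[ci]]
    n_fields <- cond$n_fields %||% 1L
    for (fi in seq_len(n_fields)) {
      seed <- seed0 + 1000L * ci + fi
      truth <- simulate_field_truth(
        spec,
        coverage = unlist(cond$coverage) %||% 0.5,
        thickness_um = cond$thickness_um %||% 0.66,
        n_nuclei = cond$n_nuclei %||% 10L,
        sample_coverage = isTRUE(cond$sample_coverage),
        seed = seed
      )
      noise <- do.call(noise_model, config$noise %||% list())
      rf <- render_field(spec, truth, noise, seed = seed + 1L)
      stem <- sprintf("%s_field%02d", cond$name, fi)
      stack_path <- file.path(out_dir, paste0(stem, ".tiff"))
      write_stack(rf$stack, stack_path)
      truth_path <- file.path(out_dir, paste0(stem, "_truth.csv"))
      readr::write_csv(truth$pillars, truth_path)
      nuc_path <- file.path(out_dir, paste0(stem, "_nuclei.csv"))
      readr::write_csv(truth$nuclei, nuc_path)
      files <- c(files, stack_path, sidecar_path(stack_path), truth_path, nuc_path)
    }
  }
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = seed0,
    files = files
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Quantify a configured set of pillar-field stacks
#'
#' Runs the full measurement chain for every stack of every condition:
#' maximum-intensity projections (full height for nuclei, base-excluded
#' for myelin), pillar-grid detection, per-pillar wrap measurement, nuclei
#' counting and field summaries. Writes the per-pillar table, the field
#' summary table and a tidy long-format table to `out_dir`, plus a log and
#' a provenance record (configuration hash, seeds, package version).
#'
#' @param config A `run_config`; each condition must list `stacks` paths.
#' @param out_dir Output directory.
#' @return A list with tibbles `per_pillar` and `field_summaries`,
#'   invisibly.
#' @export
run_quantify <- function(config, out_dir) {
  config <- validate_run_config(unclass(config))
  if (!dir.exists(out_dir) &&
    !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    abort_computation(sprintf("Cannot create output directory: %s", out_dir))
  }
  spec <- config_array_spec(config)
  bins <- config_score_bins(config)
  base_z <- config$base_exclusion_um %||% 4
  log_lines <- character(0)
  # the log file must be identical across re-runs, so stage timings go to
  # the console only
  logit <- function(line, elapsed_s) {
    message(sprintf("%s [%.2fs]", line, elapsed_s))
    log_lines <<- c(log_lines, line)
  }

  per_pillar <- list()
  summaries <- list()
  for (cond in config$conditions) {
    stacks <- cond$stacks %||% character(0)
    for (si in seq_along(stacks)) {
      t0 <- Sys.time()
      stack <- read_stack(stacks[si])
      proj_pillar <- max_project(stack, "PILLAR", 0, Inf)
      proj_mbp <- max_project(stack, "MBP", base_z, Inf)
      proj_nuc <- max_project(stack, "NUCLEI", 0, Inf)
      grid <- detect_pillars(
        proj_pillar,
        expected_pitch_um = spec$pitch_um,
        expected_diameter_um = spec$realized_diameter_um
      )
      wraps <- measure_wrapping(proj_mbp, grid, bins = bins)
      nuc <- count_nuclei(proj_nuc)
      extent <- dim(proj_nuc$intensity)[c(2, 1)] * stack$pixel_size_um
      fid <- sprintf("%s_%02d", cond$name, si)
      summ <- summarize_field(
        wraps, nuc$n_cells,
        extent_um = extent, field_id = fid, condition = cond$name
      )
      wraps$field_id <- fid
      wraps$condition <- cond$name
      per_pillar[[fid]] <- dplyr::left_join(
        wraps,
        dplyr::select(
          tibble::as_tibble(grid), "pillar_id", "row", "col",
          "x_um", "y_um", "diameter_um"
        ),
        by = "pillar_id"
      )
      summaries[[fid]] <- summ
      logit(
        sprintf(
          "field %s: %d pillars (%d flagged), %d cells, %.1f%% score 3",
          fid, summ$n_pillars, summ$n_flagged, summ$n_cells, summ$pct_score3
        ),
        as.numeric(Sys.time() - t0, units = "secs")
      )
    }
  }
  if (length(per_pillar) == 0) {
    abort_validation("No input stacks configured: nothing to quantify.")
  }
  per_pillar <- dplyr::bind_rows(per_pillar)
  summaries <- dplyr::bind_rows(summaries)
  long <- summaries |>
    tidyr::pivot_longer(
      cols = dplyr::where(is.numeric),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::select("condition", field = "field_id", "metric", "value")

  readr::write_csv(per_pillar, file.path(out_dir, "per_pillar.csv"))
  readr::write_csv(summaries, file.path(out_dir, "field_summaries.csv"))
  readr::write_csv(long, file.path(out_dir, "field_summaries_long.csv"))
  provenance <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    score_bins = list(
      edges = bins$edges, gap_tolerance_deg = bins$gap_tolerance_deg
    ),
    base_exclusion_um = base_z,
    package_version = as.character(utils::packageVersion("pillarwrap"))
  )
  jsonlite::write_json(
    provenance, file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(per_pillar = per_pillar, field_summaries = summaries))
}
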