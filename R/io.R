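# Configuration loading, delimited-text table I/O, and the end-to-end
# reproduce() driver. All tables are comma-separated UTF-8 with '.'
# decimal; all readers/writers round-trip losslessly.

.default_config <- function() {
  list(
    device = list(type = "gll",
                  reservoir_volume_source = 98, reservoir_volume_sink = 98,
                  channel_length = 1.3, hydraulic_diameter = 192.6,
                  top_volume = 100, bottom_volume = 600,
                  membrane_thickness = 10, pore_diameter = 8,
                  pore_density = 1e5, membrane_area = 0.33, tortuosity = 1),
    ligand = list(name = "VEGF", source_concentration = 100,
                  diffusivity = NULL, hydrodynamic_radius = 3.6,
                  molecular_weight = NULL,
                  temperature = 310, viscosity = 6.9e-4),
    analysis = list(motile_threshold = 20, motile_only = TRUE, alpha = 0.05),
    synth = list(seed = 1, n_cells = 15, n_devices = 3),
    transport = list(total_time = 48, grid_points = 130, bulk_velocity = 0,
                     boundary = "finite")
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with sections `device`, `ligand`,
#' `analysis`, `synth` and `transport`; omitted fields are filled with the
#' characterised-device defaults (the gLL geometry, VEGF ligand, 20 um
#' motility threshold). Unknown keys are rejected with their location.
#' An empty file yields the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- .default_config()
  user <- if (is.null(path)) list() else {
    if (!file.exists(path))
      stop("load_config: file not found: ", path, call. = FALSE)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("load_config: unknown section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(user)) {
    extra <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(extra))
      stop("load_config: unknown key(s) in '", sec, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  if (!cfg$device$type %in% c("gll", "transwell"))
    stop("load_config: device$type must be 'gll' or 'transwell'",
         call. = FALSE)
  # constructors perform the numeric validation
  geom <- config_geometry(cfg)
  lig <- config_ligand(cfg)
  if (cfg$analysis$motile_threshold <= 0)
    stop("load_config: analysis$motile_threshold must be positive",
         call. = FALSE)
  if (cfg$analysis$alpha <= 0 || cfg$analysis$alpha >= 1)
    stop("load_config: analysis$alpha must lie in (0, 1)", call. = FALSE)
  structure(cfg, class = "run_config", geometry = geom, ligand = lig)
}

#' Build domain objects from a run configuration
#'
#' @param cfg A `run_config` (see [load_config()]).
#' @return `config_geometry()` returns a [gll_geometry()] or
#'   [transwell_geometry()]; `config_ligand()` a [ligand_spec()];
#'   `config_transport_params()` a [transport_params()].
#' @export
config_geometry <- function(cfg) {
  d <- cfg$device
  if (d$type == "gll") {
    gll_geometry(reservoir_volume_source = d$reservoir_volume_source,
                 reservoir_volume_sink = d$reservoir_volume_sink,
                 channel_length = d$channel_length,
                 hydraulic_diameter = d$hydraulic_diameter)
  } else {
    transwell_geometry(top_volume = d$top_volume,
                       bottom_volume = d$bottom_volume,
                       membrane_thickness = d$membrane_thickness,
                       pore_diameter = d$pore_diameter,
                       pore_density = d$pore_density,
                       membrane_area = d$membrane_area,
                       tortuosity = d$tortuosity)
  }
}

#' @rdname config_geometry
#' @export
config_ligand <- function(cfg) {
  l <- cfg$ligand
  ligand_spec(l$name, source_concentration = l$source_concentration,
              diffusivity = l$diffusivity,
              hydrodynamic_radius = l$hydrodynamic_radius,
              molecular_weight = l$molecular_weight,
              temperature = l$temperature, viscosity = l$viscosity)
}

#' @rdname config_geometry
#' @export
config_transport_params <- function(cfg) {
  tr <- cfg$transport
  transport_params(total_time = tr$total_time, grid_points = tr$grid_points,
                   bulk_velocity = tr$bulk_velocity, boundary = tr$boundary)
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read and write trajectory tables
#'
#' Trajectory tables are CSV with header `cell_id,time_min,x_um,y_um`, one
#' row per cell per frame. On reading, rows are grouped by cell and sorted
#' by time; cells not present at `t = 0` are dropped (the tracking rule:
#' only cells identified at the start are followed) with a message giving
#' the dropped count.
#'
#' @param path CSV path.
#' @return `read_trajectories()`: a named list of [trajectory()] objects.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("read_trajectories: header must contain ",
         paste(need, collapse = ","), call. = FALSE)
  for (col in c("time_min", "x_um", "y_um"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!is.finite(df$time_min) | !is.finite(df$x_um) |
                 !is.finite(df$y_um))
  if (length(bad))
    stop("read_trajectories: malformed row at line ", bad[1L] + 1L,
         call. = FALSE)
  split_df <- split(df, df$cell_id)
  present_at_0 <- vapply(split_df, function(d) min(d$time_min) == 0, TRUE)
  if (any(!present_at_0))
    message("read_trajectories: dropped ", sum(!present_at_0),
            " cell(s) not present at t = 0")
  out <- lapply(split_df[present_at_0], function(d) {
    d <- d[order(d$time_min), ]
    trajectory(d$cell_id[1L], d$time_min, d$x_um, d$y_um)
  })
  out[order(names(out))]
}

#' @rdname read_trajectories
#' @param trajectories List of [trajectory()] objects.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr)
    data.frame(cell_id = tr$cell_id, time_min = tr$times,
               x_um = tr$x, y_um = tr$y))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and write transwell count tables
#'
#' Count tables are CSV with header `condition,device_id,motile_count`.
#'
#' @param path CSV path.
#' @return `read_counts()`: a named list of TA [condition_dataset()]s.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "device_id", "motile_count")
  if (!all(need %in% names(df)))
    stop("read_counts: header must contain ", paste(need, collapse = ","),
         call. = FALSE)
  lapply(split(df, df$condition), function(d)
    condition_dataset(d$condition[1L], "TA", device_counts = d$motile_count))
}

#' @rdname read_counts
#' @param datasets Named list of TA [condition_dataset()]s.
#' @export
write_counts <- function(datasets, path) {
  rows <- lapply(datasets, function(d)
    data.frame(condition = d$condition,
               device_id = seq_along(d$device_counts),
               motile_count = d$device_counts))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and write CT tables
#'
#' CT tables are CSV with header `condition,gene,replicate,ct`.
#'
#' @param path CSV path.
#' @return `read_ct_table()`: a validated CT table data frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ct_table(df)
  df
}

#' @rdname read_ct_table
#' @param table A CT table.
#' @export
write_ct_table <- function(table, path) {
  validate_ct_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write a concentration profile to delimited text
#'
#' Emits the long-form profile (`position_cm,time_h,concentration,`
#' `normalized_concentration`) and, alongside it, the compartment time
#' courses (`<stem>_compartments.csv`).
#'
#' @param profile A `concentration_profile`.
#' @param path Output CSV path for the long-form profile.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  comp <- profile$reservoir
  names(comp) <- c("time_h", profile$source_label, profile$sink_label)
  utils::write.csv(comp, sub("\\.csv$", "_compartments.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Reproduce the reference analyses on calibrated synthetic data
#'
#' Runs the full chain -- synthetic-data generation calibrated to the
#' reference summaries, migration or expression analysis, and the gated
#' statistical comparison -- for one of three presets:
#' \describe{
#'   \item{`gll-fig4`}{Five trajectory cohorts (C, E, V, VE, EV) calibrated
#'     to the per-condition path-length summaries; emits per-condition
#'     migration summaries side by side with the calibration targets, plus
#'     the gated comparison of path lengths across conditions.}
#'   \item{`ta-fig4`}{Per-device transwell counts for the five conditions;
#'     emits count summaries, fold changes versus control, and the gated
#'     comparison.}
#'   \item{`table2`}{A noise-free CT table realising the receptor-panel
#'     fold targets; emits the recovered 4 x 4 fold matrix.}
#' }
#'
#' @param preset One of `"gll-fig4"`, `"ta-fig4"`, `"table2"`.
#' @param out_dir Output directory for CSV artefacts, or `NULL` to skip
#'   writing.
#' @param seed Integer seed controlling all synthetic draws.
#' @param n_cells,n_devices Cohort sizes.
#' @return A list with the computed tables (and the comparison report
#'   where applicable); identical seeds give identical bundles.
#' @export
reproduce <- function(preset = c("gll-fig4", "ta-fig4", "table2"),
                      out_dir = NULL, seed = 1, n_cells = 15,
                      n_devices = 3) {
  preset <- match.arg(preset)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(obj, file, writer = utils::write.csv) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
    obj
  }
  if (preset == "gll-fig4") {
    targets <- gll_reference_summaries()
    cohorts <- lapply(seq_len(nrow(targets)), function(i) {
      wp <- calibrate_walk(targets$mean_pl[i], targets$sd_pl[i],
                           n_cells = n_cells, seed = seed + i)
      simulate_cohort(wp, condition = targets$condition[i])
    })
    names(cohorts) <- targets$condition
    summaries <- do.call(rbind, lapply(cohorts, summarize_condition))
    summaries$target_mean_pl <- targets$mean_pl
    summaries$target_sd_pl <- targets$sd_pl
    pl_groups <- lapply(cohorts, function(d)
      vapply(d$trajectories, path_length, 1))
    report <- compare_groups(pl_groups, control = "C")
    emit(summaries, "gll_fig4_summaries.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
    emit(report$pairwise, "gll_fig4_pairwise.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
    list(preset = preset, seed = seed, summaries = summaries,
         report = report, cohorts = cohorts)
  } else if (preset == "ta-fig4") {
    targets <- ta_reference_summaries()
    datasets <- lapply(seq_len(nrow(targets)), function(i)
      generate_transwell_counts(targets$mean_count[i], targets$sd_count[i],
                                n_devices = n_devices, seed = seed + i,
                                condition = targets$condition[i]))
    names(datasets) <- targets$condition
    summaries <- do.call(rbind, lapply(datasets, transwell_summary,
                                       control = datasets$C))
    summaries$target_mean_count <- targets$mean_count
    summaries$target_sd_count <- targets$sd_count
    report <- compare_groups(lapply(datasets, `[[`, "device_counts"),
                             control = "C")
    emit(summaries, "ta_fig4_summaries.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
    list(preset = preset, seed = seed, summaries = summaries,
         report = report, datasets = datasets)
  } else {
    targets <- fold_targets(receptor_fold_targets())
    ct <- generate_ct_table(targets, replicates = 3L, seed = seed)
    folds <- expression_matrix(ct, rownames(targets$folds),
                               colnames(targets$folds))
    if (!is.null(out_dir)) {
      write_ct_table(ct, file.path(out_dir, "table2_ct.csv"))
      utils::write.csv(folds, file.path(out_dir, "table2_folds.csv"))
    }
    list(preset = preset, seed = seed, ct_table = ct, folds = folds,
         targets = targets$folds)
  }
}
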