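# Cell-migration quantification: path length, motility, cohort summaries.

#' Single-cell trajectory
#'
#' One cell's sampled positions over a time-lapse assay. The tracking
#' convention is 30-min frames over 6 h (13 positions, 12 intervals), and
#' only cells present at `t = 0` are tracked, so the first time stamp must
#' be 0. Shorter tracks are accepted and flagged as incomplete.
#'
#' @param cell_id Cell label.
#' @param times_min Strictly increasing time stamps, min, starting at 0.
#' @param x_um,y_um Positions, um, in image-frame coordinates with +x along
#'   the gradient axis.
#' @param full_length Expected number of frames for a complete track
#'   (default 13).
#'
#' @return An object of class `trajectory` with a `complete` flag.
#' @export
trajectory <- function(cell_id, times_min, x_um, y_um, full_length = 13L) {
  n <- length(times_min)
  if (n < 2L)
    stop("trajectory: at least 2 time points are required", call. = FALSE)
  if (length(x_um) != n || length(y_um) != n)
    stop("trajectory: times and positions must have equal length",
         call. = FALSE)
  if (any(!is.finite(times_min)) || any(!is.finite(x_um)) || any(!is.finite(y_um)))
    stop("trajectory: non-finite values", call. = FALSE)
  if (any(diff(times_min) <= 0))
    stop("trajectory: times must be strictly increasing", call. = FALSE)
  if (times_min[1L] != 0)
    stop("trajectory: first time stamp must be 0 (only cells present at ",
         "t = 0 are tracked)", call. = FALSE)
  structure(list(cell_id = as.character(cell_id),
                 times = as.numeric(times_min),
                 x = as.numeric(x_um), y = as.numeric(y_um),
                 complete = n >= full_length),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$cell_id, "-", length(x$times), "frames over",
      max(x$times), "min; PL =", signif(path_length(x), 4), "um\n")
  invisible(x)
}

#' Path length of a trajectory
#'
#' Accumulated distance: the sum of Euclidean displacements between
#' consecutive sampled positions,
#' `PL = sum_i sqrt((x[i+1]-x[i])^2 + (y[i+1]-y[i])^2)`.
#'
#' @param traj A [trajectory()].
#' @return Path length, um.
#' @examples
#' path_length(trajectory("c1", c(0, 30), c(0, 3), c(0, 4)))  # 5
#' @export
path_length <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Net displacement of a trajectory
#'
#' Euclidean distance between the first and last sampled positions; always
#' bounded above by [path_length()].
#'
#' @param traj A [trajectory()].
#' @return Net displacement, um.
#' @export
net_displacement <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$x)
  sqrt((traj$x[n] - traj$x[1L])^2 + (traj$y[n] - traj$y[1L])^2)
}

#' Classify a cell as motile
#'
#' A cell is motile when its movement exceeds the threshold of 20 um
#' (about two cell diameters) over the assay -- strictly greater than, so a
#' cell at exactly the threshold is non-motile. The threshold applies to
#' the path length by default; `on = "net"` switches to net displacement
#' for sensitivity analysis.
#'
#' @param traj A [trajectory()].
#' @param threshold Motility threshold, um (default 20).
#' @param on `"path"` (default) or `"net"`: which movement measure the
#'   threshold applies to.
#' @return Logical flag.
#' @export
classify_motile <- function(traj, threshold = 20, on = c("path", "net")) {
  on <- match.arg(on)
  m <- if (on == "path") path_length(traj) else net_displacement(traj)
  m > threshold
}

#' Per-condition dataset of trajectories or device counts
#'
#' Bundles all observations for one experimental condition: tracked
#' trajectories for the microfluidic (gLL) platform, or per-device motile
#' counts for the transwell (TA) platform.
#'
#' @param condition Condition label (conventionally one of `C`, `E`, `V`,
#'   `VE`, `EV`).
#' @param platform `"gLL"` or `"TA"`.
#' @param trajectories List of [trajectory()] objects (gLL).
#' @param device_counts Integer vector of motile-cell counts, one per
#'   device (TA).
#'
#' @return An object of class `condition_dataset`.
#' @export
condition_dataset <- function(condition, platform = c("gLL", "TA"),
                              trajectories = NULL, device_counts = NULL) {
  platform <- match.arg(platform)
  if (platform == "gLL") {
    if (is.null(trajectories) || length(trajectories) == 0L)
      stop("condition_dataset: gLL datasets need trajectories", call. = FALSE)
    if (!all(vapply(trajectories, inherits, TRUE, "trajectory")))
      stop("condition_dataset: 'trajectories' must be trajectory objects",
           call. = FALSE)
    if (length(trajectories) < 10L)
      warning("condition_dataset: fewer than 10 cells for condition '",
              condition, "' (the assay convention is 10-15 per device)",
              call. = FALSE)
  } else {
    if (is.null(device_counts) || length(device_counts) == 0L)
      stop("condition_dataset: TA datasets need device_counts", call. = FALSE)
    if (any(!is.finite(device_counts)) || any(device_counts < 0))
      stop("condition_dataset: counts must be non-negative", call. = FALSE)
    if (length(device_counts) < 3L)
      warning("condition_dataset: fewer than 3 devices for condition '",
              condition, "'", call. = FALSE)
  }
  structure(list(condition = as.character(condition), platform = platform,
                 trajectories = trajectories, device_counts = device_counts),
            class = "condition_dataset")
}

#' @export
print.condition_dataset <- function(x, ...) {
  cat("<condition_dataset>", x$condition, "(", x$platform, "):",
      if (x$platform == "gLL") paste(length(x$trajectories), "trajectories")
      else paste(length(x$device_counts), "devices"), "\n")
  invisible(x)
}

#' Fraction of motile cells in a cohort
#'
#' Percentage of tracked cells classified motile by [classify_motile()].
#'
#' @param data A gLL [condition_dataset()].
#' @param threshold,on Passed to [classify_motile()].
#' @return Motile fraction in percent.
#' @export
motile_fraction <- function(data, threshold = 20, on = "path") {
  stopifnot(inherits(data, "condition_dataset"))
  if (data$platform != "gLL")
    stop("motile_fraction: requires trajectory (gLL) data", call. = FALSE)
  motile <- vapply(data$trajectories, classify_motile, TRUE,
                   threshold = threshold, on = on)
  100 * mean(motile)
}

#' Summarise migration in a trajectory cohort
#'
#' Mean and sample standard deviation (n - 1 denominator) of path lengths,
#' motile fraction, and mean net displacement for one condition. With
#' `motile_only = TRUE` the path-length statistics are restricted to cells
#' classified motile (the reporting convention for per-condition average
#' path lengths); the motile fraction always refers to all tracked cells.
#'
#' @param data A gLL [condition_dataset()].
#' @param motile_only Restrict path-length statistics to motile cells?
#' @param threshold,on Motility classification, see [classify_motile()].
#'
#' @return A one-row data frame of class `migration_summary`: condition,
#'   n_cells, n_motile, motile_fraction (%), mean/sd path length (um),
#'   mean net displacement (um), and a `degenerate` flag set when
#'   `motile_only` finds no motile cells (statistics then `NA`).
#' @export
summarize_condition <- function(data, motile_only = FALSE, threshold = 20,
                                on = "path") {
  stopifnot(inherits(data, "condition_dataset"))
  if (data$platform != "gLL")
    stop("summarize_condition: requires trajectory (gLL) data; use ",
         "transwell_summary() for TA counts", call. = FALSE)
  pl <- vapply(data$trajectories, path_length, 1)
  nd <- vapply(data$trajectories, net_displacement, 1)
  motile <- vapply(data$trajectories, classify_motile, TRUE,
                   threshold = threshold, on = on)
  sel <- if (motile_only) motile else rep(TRUE, length(pl))
  degenerate <- !any(sel)
  out <- data.frame(condition = data$condition,
                    platform = "gLL",
                    n_cells = length(pl),
                    n_motile = sum(motile),
                    motile_fraction = 100 * mean(motile),
                    mean_path_length = if (degenerate) NA_real_ else mean(pl[sel]),
                    sd_path_length = if (degenerate) NA_real_ else stats::sd(pl[sel]),
                    mean_net_displacement = if (degenerate) NA_real_ else mean(nd[sel]),
                    degenerate = degenerate)
  if (sum(sel) == 1L) out$sd_path_length <- 0
  class(out) <- c("migration_summary", "data.frame")
  out
}

#' Summarise transwell motile counts with fold change versus control
#'
#' Mean and sample standard deviation of per-device motile-cell counts,
#' plus the fold change of the condition mean over the control mean (the
#' figure convention; the absolute means are reported alongside).
#'
#' @param data A TA [condition_dataset()].
#' @param control The control TA [condition_dataset()], or `NULL` to omit
#'   the fold change.
#'
#' @return A one-row data frame of class `migration_summary`: condition,
#'   n_devices, mean/sd count, fold_change_vs_control. A single device
#'   yields `NA` standard deviation; a zero control mean yields `NA` fold
#'   change, both with a warning.
#' @export
transwell_summary <- function(data, control = NULL) {
  stopifnot(inherits(data, "condition_dataset"))
  if (data$platform != "TA")
    stop("transwell_summary: requires count (TA) data", call. = FALSE)
  counts <- data$device_counts
  sdv <- if (length(counts) >= 2L) stats::sd(counts) else {
    warning("transwell_summary: single device, SD undefined", call. = FALSE)
    NA_real_
  }
  fc <- NA_real_
  if (!is.null(control)) {
    stopifnot(inherits(control, "condition_dataset"))
    if (control$platform != "TA")
      stop("transwell_summary: control must be TA data", call. = FALSE)
    cm <- mean(control$device_counts)
    if (cm == 0) {
      warning("transwell_summary: control mean is 0, fold change undefined",
              call. = FALSE)
    } else {
      fc <- mean(counts) / cm
    }
  }
  out <- data.frame(condition = data$condition,
                    platform = "TA",
                    n_devices = length(counts),
                    mean_count = mean(counts),
                    sd_count = sdv,
                    fold_change_vs_control = fc)
  class(out) <- c("migration_summary", "data.frame")
  out
}
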