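# Seeded synthetic-data generation: biased-random-walk trajectory cohorts
# with closed-form path-length moments, CT tables realising a target fold
# matrix, and per-device transwell counts.

#' Moments of the per-step displacement length (Rice distribution)
#'
#' A walk step is `(drift + sigma Z1, sigma Z2)` with independent standard
#' normals, so the step length follows a Rice distribution with
#' noncentrality `drift` and scale `sigma`. `rice_mean()` evaluates
#' `sigma * sqrt(pi/2) * L_{1/2}(-drift^2 / (2 sigma^2))` via scaled Bessel
#' functions (stable for strongly directed walks); `rice_var()` uses
#' `E[R^2] = 2 sigma^2 + drift^2`.
#'
#' @param drift Mean displacement per step along the drift axis, um.
#' @param sigma Isotropic per-axis noise SD, um.
#' @return Mean (um) or variance (um^2) of the step length.
#' @export
rice_mean <- function(drift, sigma) {
  if (any(drift < 0) || any(sigma < 0))
    stop("rice_mean: 'drift' and 'sigma' must be non-negative", call. = FALSE)
  if (sigma == 0) return(drift)
  x <- drift^2 / (2 * sigma^2)
  # e^{-x/2} [(1 + x) I0(x/2) + x I1(x/2)] using exponentially scaled I
  lag <- (1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
    x * besselI(x / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * lag
}

#' @rdname rice_mean
#' @export
rice_var <- function(drift, sigma) {
  2 * sigma^2 + drift^2 - rice_mean(drift, sigma)^2
}

# per-step variance-to-squared-mean ratio of a Rice(k*sigma, sigma) step;
# monotone decreasing in k from 4/pi - 1 (Rayleigh) to 0 (deterministic)
.rice_cv2 <- function(k) rice_var(k, 1) / rice_mean(k, 1)^2

#' Biased-random-walk parameters
#'
#' Generative model for a tracked cohort: each cell takes `n_steps` steps
#' of `(drift, 0) + isotropic Gaussian noise`; cell-to-cell variability in
#' migratory vigour is modelled by a per-cell Gamma(mean 1) scale factor
#' with coefficient of variation `drift_cv` multiplying both the drift and
#' the step noise. With `drift_cv = 0` all cells share the same step
#' distribution (the pure Rice family). Sampling follows the imaging
#' convention: 30-min frames, 12 steps (6 h).
#'
#' @param n_cells Number of cells per cohort.
#' @param n_steps Steps per trajectory (default 12).
#' @param dt Frame interval, min (default 30).
#' @param drift Mean step drift along +x, um/step.
#' @param step_sd Isotropic per-axis step noise SD, um/step.
#' @param drift_cv Between-cell coefficient of variation of the per-cell
#'   speed scale (default 0).
#' @param seed Integer seed; cohorts are fully reproducible given the seed.
#' @param start_window Uniform window for starting positions, um
#'   (`c(min, max)`, applied to both axes).
#' @param gradient_coupling Optional list
#'   `list(profile, sensitivity, channel_start_cm, origin_um)` coupling the
#'   walk to a simulated [concentration_profile][solve_gll]: at each step
#'   the drift becomes `drift + sensitivity * (-dC/dx)` evaluated at the
#'   cell's current channel position (frame +x points toward the ligand
#'   source, i.e. down the channel axis), so sensitivity is in
#'   um/step per (ng/mL/cm).
#'
#' @return An object of class `walk_params`.
#' @export
walk_params <- function(n_cells = 15, n_steps = 12, dt = 30,
                        drift = 0, step_sd = 1, drift_cv = 0, seed = NULL,
                        start_window = c(0, 500),
                        gradient_coupling = NULL) {
  if (n_steps < 1 || n_cells < 1)
    stop("walk_params: 'n_cells' and 'n_steps' must be >= 1", call. = FALSE)
  if (drift < 0 || step_sd < 0 || drift_cv < 0)
    stop("walk_params: 'drift', 'step_sd' and 'drift_cv' must be >= 0",
         call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), n_steps = as.integer(n_steps),
                 dt = dt, drift = drift, step_sd = step_sd,
                 drift_cv = drift_cv, seed = seed,
                 start_window = start_window,
                 gradient_coupling = gradient_coupling),
            class = "walk_params")
}

#' Calibrate walk parameters to target path-length moments
#'
#' Inverts the closed-form path-length moments of the walk family to hit a
#' target cohort mean and standard deviation of path length. With
#' homogeneous cells (`heterogeneity = FALSE`) the per-step length is
#' Rice-distributed, and the family bounds the reachable dispersion:
#' `SD(PL) <= mean(PL) * sqrt((4/pi - 1)/n_steps)` (the Rayleigh limit);
#' targets beyond that bound raise an error stating it. The default
#' (`heterogeneity = TRUE`) falls back, for such targets, to a fixed
#' within-cell directedness `k0 = drift/step_sd` plus a per-cell Gamma
#' speed scale whose coefficient of variation is solved exactly from
#' `Var(PL) = n v_w (1 + cv^2) + (n m)^2 cv^2` -- observed cohorts are
#' far more dispersed than any homogeneous-step model allows, which is the
#' usual signature of cell-to-cell motility heterogeneity.
#'
#' @param target_mean_pl Target cohort mean path length, um.
#' @param target_sd_pl Target cohort SD of path length, um.
#' @param n_steps Steps per trajectory.
#' @param heterogeneity Allow the between-cell speed scale when the
#'   homogeneous Rice family cannot reach the target SD?
#' @param k0 Within-cell directedness (drift / step_sd) used in the
#'   heterogeneous branch.
#' @param ... Passed to [walk_params()] (e.g. `n_cells`, `seed`).
#'
#' @return A [walk_params()] whose cohort path-length mean and SD equal
#'   the targets in expectation.
#' @export
calibrate_walk <- function(target_mean_pl, target_sd_pl, n_steps = 12,
                           heterogeneity = TRUE, k0 = 1, ...) {
  if (!is.finite(target_mean_pl) || target_mean_pl <= 0)
    stop("calibrate_walk: 'target_mean_pl' must be positive", call. = FALSE)
  if (!is.finite(target_sd_pl) || target_sd_pl < 0)
    stop("calibrate_walk: 'target_sd_pl' must be >= 0", call. = FALSE)
  m <- target_mean_pl / n_steps           # per-step mean length
  if (target_sd_pl == 0)
    return(walk_params(n_steps = n_steps, drift = m, step_sd = 0,
                       drift_cv = 0, ...))
  r_max <- 4 / pi - 1
  cv2_step <- target_sd_pl^2 / (n_steps * m^2)  # required per-step CV^2
  if (cv2_step <= r_max) {
    # homogeneous Rice family: solve directedness k from the CV ratio
    k <- if (cv2_step == r_max) 0 else
      stats::uniroot(function(k) .rice_cv2(k) - cv2_step,
                     lower = 1e-8, upper = 200, tol = 1e-12)$root
    sigma <- m / rice_mean(k, 1)
    return(walk_params(n_steps = n_steps, drift = k * sigma,
                       step_sd = sigma, drift_cv = 0, ...))
  }
  if (!heterogeneity) {
    stop("calibrate_walk: target SD ", signif(target_sd_pl, 4),
         " um exceeds the homogeneous-walk bound ",
         signif(target_mean_pl * sqrt(r_max / n_steps), 4),
         " um (= mean * sqrt((4/pi - 1)/n_steps)); allow 'heterogeneity' ",
         "or lower the target", call. = FALSE)
  }
  sigma <- m / rice_mean(k0, 1)           # unit-scale within-cell params
  v_w <- rice_var(k0 * sigma, sigma)      # within-cell per-step variance
  cv2 <- (target_sd_pl^2 - n_steps * v_w) /
    (n_steps^2 * m^2 + n_steps * v_w)
  walk_params(n_steps = n_steps, drift = k0 * sigma, step_sd = sigma,
              drift_cv = sqrt(cv2), ...)
}

#' Simulate a trajectory cohort
#'
#' Draws `n_cells` biased-random-walk trajectories from a [walk_params()]
#' model, sampled at the imaging cadence, with uniform random starting
#' positions. Deterministic given `params$seed`.
#'
#' @param params A [walk_params()].
#' @param condition Condition label for the resulting dataset.
#' @return A gLL [condition_dataset()].
#' @export
simulate_cohort <- function(params, condition = "sim") {
  stopifnot(inherits(params, "walk_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_steps
  times <- seq(0, n * params$dt, by = params$dt)
  gc <- params$gradient_coupling
  trajs <- vector("list", params$n_cells)
  for (c_i in seq_len(params$n_cells)) {
    g <- if (params$drift_cv > 0)
      stats::rgamma(1L, shape = 1 / params$drift_cv^2,
                    rate = 1 / params$drift_cv^2) else 1
    x0 <- stats::runif(1L, params$start_window[1L], params$start_window[2L])
    y0 <- stats::runif(1L, params$start_window[1L], params$start_window[2L])
    if (is.null(gc)) {
      dx <- g * params$drift + stats::rnorm(n, 0, g * params$step_sd)
      dy <- stats::rnorm(n, 0, g * params$step_sd)
      x <- x0 + c(0, cumsum(dx)); y <- y0 + c(0, cumsum(dy))
    } else {
      prof <- gc$profile
      start_cm <- if (is.null(gc$channel_start_cm))
        mean(range(prof$positions)) else gc$channel_start_cm
      origin <- if (is.null(gc$origin_um)) x0 else gc$origin_um
      x <- y <- numeric(n + 1L); x[1L] <- x0; y[1L] <- y0
      for (s in seq_len(n)) {
        pos_cm <- start_cm - (x[s] - origin) * 1e-4  # frame +x -> source
        pos_cm <- min(max(pos_cm, min(prof$positions)), max(prof$positions))
        t_h <- min(max(times[s] / 60, min(prof$times)), max(prof$times))
        grad <- sample_field(prof, pos_cm, t_h)[["gradient"]]
        drift_s <- g * (params$drift + gc$sensitivity * max(0, -grad))
        x[s + 1L] <- x[s] + drift_s + stats::rnorm(1L, 0, g * params$step_sd)
        y[s + 1L] <- y[s] + stats::rnorm(1L, 0, g * params$step_sd)
      }
    }
    trajs[[c_i]] <- trajectory(sprintf("%s_cell%03d", condition, c_i),
                               times, x, y)
  }
  condition_dataset(condition, "gLL", trajectories = trajs)
}

#' Fold-change targets for CT-table generation
#'
#' @param folds Numeric matrix of target fold changes, stimuli (rows) x
#'   receptor genes (columns), all positive, with dimnames.
#' @param reference Reference gene label (default `"GAPDH"`).
#' @param control Control condition label (default `"control"`).
#' @param ct_noise_sd Gaussian CT noise SD, cycles (0 = noise-free).
#' @param base_ct_reference,base_ct_target Baseline CT values (cycles) for
#'   the reference gene and for target genes under control conditions.
#' @return An object of class `fold_targets`.
#' @export
fold_targets <- function(folds, reference = "GAPDH", control = "control",
                         ct_noise_sd = 0, base_ct_reference = 18,
                         base_ct_target = 25) {
  folds <- as.matrix(folds)
  if (is.null(rownames(folds)) || is.null(colnames(folds)))
    stop("fold_targets: 'folds' needs stimulus rownames and gene colnames",
         call. = FALSE)
  if (any(!is.finite(folds)) || any(folds <= 0))
    stop("fold_targets: fold changes must be positive", call. = FALSE)
  if (ct_noise_sd < 0)
    stop("fold_targets: 'ct_noise_sd' must be >= 0", call. = FALSE)
  structure(list(folds = folds, reference = reference, control = control,
                 ct_noise_sd = ct_noise_sd,
                 base_ct_reference = base_ct_reference,
                 base_ct_target = base_ct_target),
            class = "fold_targets")
}

#' Generate a CT table realising target fold changes
#'
#' Builds replicate CT measurements whose delta-delta-CT analysis recovers
#' the target fold matrix: the reference gene sits at its baseline CT in
#' every condition, target genes sit at baseline under control and are
#' offset by `-log2(fold)` under each stimulus, and optional Gaussian
#' noise is added per replicate. Noise-free tables round-trip exactly
#' through [expression_matrix()].
#'
#' @param targets A [fold_targets()].
#' @param replicates Replicates per (condition, gene) (default 3).
#' @param seed Integer seed (used only when noise is present).
#' @return A CT table data frame (`condition`, `gene`, `replicate`, `ct`).
#' @export
generate_ct_table <- function(targets, replicates = 3L, seed = NULL) {
  stopifnot(inherits(targets, "fold_targets"))
  if (!is.null(seed)) set.seed(seed)
  stimuli <- rownames(targets$folds)
  genes <- colnames(targets$folds)
  conditions <- c(targets$control, stimuli)
  rows <- list()
  for (cond in conditions) {
    for (g in c(targets$reference, genes)) {
      if (g == targets$reference) {
        base <- targets$base_ct_reference
      } else if (cond == targets$control) {
        base <- targets$base_ct_target
      } else {
        base <- targets$base_ct_target - log2(targets$folds[cond, g])
      }
      ct <- base + if (targets$ct_noise_sd > 0)
        stats::rnorm(replicates, 0, targets$ct_noise_sd) else rep(0, replicates)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, gene = g,
                   replicate = seq_len(replicates), ct = ct)
    }
  }
  validate_ct_table(do.call(rbind, rows))
}

#' Generate per-device transwell motile counts
#'
#' Per-device counts drawn from a Gaussian with the given mean and SD,
#' rounded to integers and truncated at zero.
#'
#' @param mean Target mean count (> 0).
#' @param sd Target SD of counts (>= 0).
#' @param n_devices Number of devices.
#' @param seed Integer seed.
#' @param condition Condition label.
#' @return A TA [condition_dataset()].
#' @export
generate_transwell_counts <- function(mean, sd, n_devices = 3L, seed = NULL,
                                      condition = "sim") {
  if (!is.finite(mean) || mean <= 0)
    stop("generate_transwell_counts: 'mean' must be positive", call. = FALSE)
  if (sd < 0)
    stop("generate_transwell_counts: 'sd' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  counts <- pmax(0, round(stats::rnorm(n_devices, mean, sd)))
  condition_dataset(condition, "TA", device_counts = counts)
}

#' Reference per-condition migration summaries (calibration presets)
#'
#' Printed per-condition summaries of the characterised assays, used as
#' calibration targets for the synthetic generator: mean and SD of motile
#' path length plus motile fraction in the microfluidic (gLL) platform,
#' and per-device motile-count mean and SD in the transwell (TA) platform.
#' Conditions: `C` control, `E` EGF, `V` VEGF, `VE` VEGF-pretreat then
#' EGF, `EV` EGF-pretreat then VEGF.
#'
#' @return A data frame of calibration targets.
#' @export
gll_reference_summaries <- function() {
  data.frame(condition = c("C", "E", "V", "VE", "EV"),
             mean_pl = c(14.2, 39.7, 74.7, 56.3, 28.96),
             sd_pl = c(5.7, 8.96, 17.7, 6.64, 5.6),
             motile_fraction = c(46.67, 93.33, 100, 93.33, NA))
}

#' @rdname gll_reference_summaries
#' @export
ta_reference_summaries <- function() {
  data.frame(condition = c("C", "E", "V", "VE", "EV"),
             mean_count = c(12.1, 36, 87.2, 77.1, 39.7),
             sd_count = c(4.23, 12.8, 25.8, 44.4, 17.7))
}

#' Reference receptor-panel fold-change matrix (calibration preset)
#'
#' Target fold changes of receptor expression (relative to unstimulated
#' control, GAPDH-normalised) after 1-h ligand stimulation: stimuli in
#' rows (EGF, FGF2, FGF8, VEGF), receptor genes in columns (EGF-R,
#' FGFR-2, FGFR-8, VEGF-R).
#'
#' @return A 4 x 4 numeric matrix.
#' @export
receptor_fold_targets <- function() {
  matrix(c(2.2, 2.5, 0.7, 0.2,
           2.7, 1.3, 0.9, 0.7,
           9.3, 2.0, 1.3, 0.4,
           18.9, 5.2, 6.0, 2.8),
         nrow = 4L, byrow = TRUE,
         dimnames = list(c("EGF", "FGF2", "FGF8", "VEGF"),
                         c("EGF-R", "FGFR-2", "FGFR-8", "VEGF-R")))
}
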