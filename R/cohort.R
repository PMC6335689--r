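#' Default cohort bounds for the two critical perioperative parameters
#'
#' Metabolic load M in \[0.5, 25\] and cell death sensitivity beta_ap in
#' \[0.005, 0.12\]: wide enough to contain every parameter combination
#' examined in the threshold and mode-map analyses, centred on the reference
#' human values.
#'
#' @export
default_cohort_bounds <- function() {
  list(M = c(0.5, 25), beta_ap = c(0.005, 0.12))
}

#' Sobol virtual-patient cohort
#'
#' Draws `n` parameter sets whose `varied` coordinates follow a
#' `length(varied)`-dimensional Sobol sequence mapped into `bounds`; all
#' other parameters stay at the reference values. Each row of the design is
#' one virtual patient.
#'
#' @param varied Character vector of parameter names to vary.
#' @param bounds Named list of `c(lower, upper)` per varied parameter
#'   (defaults from [default_cohort_bounds] where available).
#' @param n Number of virtual patients.
#' @param reference Reference parameter set (default [id71_params]).
#' @param scramble,seed,skip Passed to [sobol_seq].
#' @return List of [hep_params] with attribute `design` (the n x d matrix of
#'   varied values).
#' @export
sobol_cohort <- function(varied, bounds = NULL, n = 1000,
                         reference = id71_params(),
                         scramble = FALSE, seed = NULL, skip = 0) {
  bad <- setdiff(varied, hep_param_names)
  if (length(bad)) stop("unknown parameter name: ", paste(bad, collapse = ", "))
  if (is.null(bounds)) bounds <- default_cohort_bounds()[varied]
  if (!all(varied %in% names(bounds)))
    stop("bounds missing for: ",
         paste(setdiff(varied, names(bounds)), collapse = ", "))
  for (nm in varied) {
    b <- bounds[[nm]]
    if (length(b) != 2 || b[2] <= b[1]) stop("invalid bounds for ", nm)
  }
  u <- sobol_seq(n, length(varied), scramble = scramble, seed = seed,
                 skip = skip)
  design <- sapply(seq_along(varied), function(j) {
    b <- bounds[[varied[j]]]
    b[1] + u[, j] * (b[2] - b[1])
  })
  design <- matrix(design, nrow = n, dimnames = list(NULL, varied))
  cohort <- lapply(seq_len(n), function(i) {
    do.call(set_params, c(list(reference), as.list(design[i, ])))
  })
  attr(cohort, "design") <- design
  cohort
}

#' Response modes across a cohort
#'
#' Simulates every virtual patient at the given resection level and
#' classifies the response. Per-patient simulation errors are recorded as
#' mode `"error"` rather than aborting the sweep, so large cohort runs
#' always complete.
#'
#' @param cohort List of [hep_params] (e.g. from [sobol_cohort]).
#' @param resection_fraction Resection level applied to every patient.
#' @param horizon Simulation horizon in days (>= 912.5 for classification).
#' @param delta_flat Passed to [classify_response].
#' @return data.frame: `patient`, any varied-design columns, `mode`,
#'   `N_730`, `N_912.5`.
#' @export
sweep_modes <- function(cohort, resection_fraction, horizon = 912.5,
                        delta_flat = 0.01) {
  design <- attr(cohort, "design")
  rows <- lapply(seq_along(cohort), function(i) {
    res <- tryCatch({
      tr <- simulate_resection(cohort[[i]], resection_fraction,
                               horizon = horizon)
      cl <- classify_response(tr, delta_flat = delta_flat)
      list(mode = cl$label, n730 = cl$evidence[["N_730"]],
           n912 = cl$evidence[["N_912.5"]])
    }, error = function(e) list(mode = "error", n730 = NA_real_,
                                n912 = NA_real_))
    data.frame(patient = i, mode = res$mode, N_730 = res$n730,
               N_912.5 = res$n912)
  })
  out <- do.call(rbind, rows)
  if (!is.null(design)) out <- cbind(out[1], as.data.frame(design), out[-1])
  out
}

## parameters rescaled over a ten-fold span during calibration/sweeps;
## the remaining parameters use a two-fold span
tenfold_params <- c("M", "k_G", "theta_ap", "KM_ST3", "kappa_JAK")

#' Fold-range sweep bounds around a reference value
#'
#' A fold range f spans \[ref/f, ref*f\]. Parameters in the significantly
#' rescaled set get a ten-fold range, all others two-fold.
#'
#' @param name Parameter name.
#' @param reference Reference parameter set.
#' @export
sweep_bounds <- function(name, reference = id71_params()) {
  f <- if (name %in% tenfold_params) 10 else 2
  ref <- reference[[name]]
  c(ref / f, ref * f)
}

#' Directional influence of a single parameter
#'
#' Sweeps one parameter over `n_levels` equally spaced values in `bounds`
#' (others fixed at the reference), simulates the response to
#' `resection_fraction`, and classifies the parameter:
#' `outcome_class` is `"recovery-and-failure"` if any level fails, else
#' `"recovery-only"`; `sensitivity` is `"insensitive"` if the spread of
#' N(912.5 d) across non-failing levels stays below `delta_sens`, otherwise
#' `"sensitive-improves"`/`"sensitive-decelerates"` by the sign of the
#' correlation between the parameter and the long-term mass fraction (or
#' plain `"sensitive"` when both recovery and failure occur).
#'
#' @param name Parameter to sweep.
#' @param bounds `c(lower, upper)`; default [sweep_bounds].
#' @param n_levels Number of sweep levels (>= 5).
#' @param resection_fraction Resection level (default 2/3).
#' @param reference Reference parameter set.
#' @param delta_sens Sensitivity cut on the spread of N(912.5 d).
#' @param horizon Simulation horizon (days).
#' @return Object of class `hep_influence`: list with `parameter`,
#'   `outcome_class`, `sensitivity`, and the per-level sweep table.
#' @export
classify_parameter_influence <- function(name, bounds = NULL, n_levels = 11,
                                         resection_fraction = 2 / 3,
                                         reference = id71_params(),
                                         delta_sens = 0.05,
                                         horizon = 912.5) {
  if (n_levels < 5) stop("need at least 5 sweep levels")
  if (!name %in% hep_param_names) stop("unknown parameter: ", name)
  if (is.null(bounds)) bounds <- sweep_bounds(name, reference)
  levels <- seq(bounds[1], bounds[2], length.out = n_levels)
  sweep <- do.call(rbind, lapply(levels, function(v) {
    p <- do.call(set_params, setNames(list(reference, v), c("p", name)))
    tr <- simulate_resection(p, resection_fraction, horizon = horizon)
    cl <- classify_response(tr)
    data.frame(value = v, mode = cl$label,
               N_912.5 = cl$evidence[["N_912.5"]])
  }))
  any_fail <- any(sweep$mode == "failure")
  outcome <- if (any_fail) "recovery-and-failure" else "recovery-only"
  ok <- sweep$mode != "failure"
  spread <- if (any(ok)) diff(range(sweep$N_912.5[ok])) else 0
  sensitivity <-
    if (any_fail) {
      if (spread > delta_sens) "sensitive" else "insensitive"
    } else if (spread <= delta_sens) "insensitive"
    else if (cor(sweep$value[ok], sweep$N_912.5[ok]) > 0) "sensitive-improves"
    else "sensitive-decelerates"
  structure(list(parameter = name, outcome_class = outcome,
                 sensitivity = sensitivity, sweep = sweep),
            class = "hep_influence")
}

#' @export
print.hep_influence <- function(x, ...) {
  cat("<hep_influence>", x$parameter, ":", x$outcome_class, "/",
      x$sensitivity, "\n")
  invisible(x)
}

#' SVM decision boundary between normal growth and other response modes
#'
#' Fits a third-order polynomial-kernel support vector classifier to
#' (M, beta_ap) points labelled by response mode, with the box constraint
#' selected by 5-fold cross-validation over a log-spaced grid in \[1, 1e4\].
#'
#' @param points Two-column matrix or data.frame of (M, beta_ap) coordinates.
#' @param labels Response-mode labels (coerced to normal vs other).
#' @param costs Candidate box constraints.
#' @param seed Seed for the cross-validation folds.
#' @return Object of class `hep_boundary`: list with the fitted `svm`,
#'   chosen `cost`, and `decision(newpoints)` returning the signed decision
#'   value (positive inside the normal region).
#' @export
decision_boundary <- function(points, labels,
                              costs = 10^seq(0, 4, length.out = 9),
                              seed = 1) {
  points <- as.data.frame(points)
  if (ncol(points) != 2) stop("points must have two columns")
  names(points) <- c("x1", "x2")
  y <- factor(ifelse(labels == "normal", "normal", "other"),
              levels = c("normal", "other"))
  if (length(unique(y)) < 2)
    stop("need both normal and non-normal labels to fit a boundary")
  cv_err <- vapply(costs, function(cc) {
    with_seed(seed, e1071::svm(points, y, kernel = "polynomial", degree = 3,
                               cost = cc, cross = 5))$tot.accuracy
  }, numeric(1))
  cost <- costs[which.max(cv_err)]
  fit <- e1071::svm(points, y, kernel = "polynomial", degree = 3, cost = cost)
  dv0 <- attr(stats::predict(fit, points[1, , drop = FALSE],
                             decision.values = TRUE), "decision.values")
  sgn <- if (identical(colnames(dv0)[1], "normal/other")) 1 else -1
  decision <- function(newpoints) {
    newpoints <- as.data.frame(newpoints)
    names(newpoints) <- c("x1", "x2")
    sgn * attr(stats::predict(fit, newpoints, decision.values = TRUE),
               "decision.values")[, 1]
  }
  structure(list(fit = fit, cost = cost, decision = decision,
                 training_accuracy = mean(stats::predict(fit, points) == y)),
            class = "hep_boundary")
}

#' Fraction of parameter space giving full recovery
#'
#' Monte-Carlo estimate: the fraction of sampled virtual patients labelled
#' `normal` in a mode map (the sample being space-filling over the stated
#' bounds, the fraction estimates the normal region's relative area).
#'
#' @param mode_map data.frame from [sweep_modes] (needs a `mode` column).
#' @export
recovery_region_extent <- function(mode_map) {
  if (!nrow(mode_map)) stop("empty mode map")
  mean(mode_map$mode == "normal")
}

#' Threshold-of-failure map over metabolic load and cell death sensitivity
#'
#' Crosses a 1-D Sobol sample of `n_per_axis` metabolic-load values with a
#' 1-D Sobol sample of `n_per_axis` cell-death-sensitivity values (each value
#' of one axis paired with all values of the other) and computes the
#' threshold of failure per cell. Cells partition into a bistable zone with a
#' finite threshold and a monostable failure zone with no safe level.
#'
#' @param M_bounds,beta_bounds Axis bounds (defaults from
#'   [default_cohort_bounds]).
#' @param n_per_axis Points per axis (the full design is its square).
#' @param grid Resection grid per cell (passed to [threshold_of_failure]).
#' @param horizon Classification horizon per cell; default
#'   [attractor_horizon] so that near-separatrix cells resolve to their
#'   eventual fate.
#' @param reference Reference parameter set for the non-varied parameters.
#' @return Object of class `hep_threshold_map`: list with sorted `M_values`,
#'   `beta_values`, numeric matrix `threshold` (percent; `NA` where no safe
#'   level), character matrix `status`, and `reference`.
#' @export
threshold_map <- function(M_bounds = default_cohort_bounds()$M,
                          beta_bounds = default_cohort_bounds()$beta_ap,
                          n_per_axis = 50,
                          grid = seq(0.05, 0.90, by = 0.01),
                          horizon = attractor_horizon(),
                          reference = id71_params()) {
  if (n_per_axis < 2) stop("need at least 2 points per axis")
  u <- sobol_seq(n_per_axis, 2)
  Ms <- sort(M_bounds[1] + u[, 1] * diff(M_bounds))
  Bs <- sort(beta_bounds[1] + u[, 2] * diff(beta_bounds))
  thr <- matrix(NA_real_, n_per_axis, n_per_axis)
  status <- matrix(NA_character_, n_per_axis, n_per_axis)
  for (i in seq_along(Ms)) {
    for (j in seq_along(Bs)) {
      cell <- tryCatch({
        t <- threshold_of_failure(set_params(reference, M = Ms[i],
                                             beta_ap = Bs[j]),
                                  grid = grid, horizon = horizon)
        list(v = t$threshold_pct, s = t$status)
      }, error = function(e) list(v = NA_real_, s = "error"))
      thr[i, j] <- if (identical(cell$s, "threshold")) cell$v else NA_real_
      status[i, j] <- cell$s
    }
  }
  structure(list(M_values = Ms, beta_values = Bs, threshold = thr,
                 status = status, reference = reference),
            class = "hep_threshold_map")
}

#' @export
print.hep_threshold_map <- function(x, ...) {
  cat("<hep_threshold_map>", length(x$M_values), "x", length(x$beta_values),
      "cells;", sum(x$status == "none-safe", na.rm = TRUE), "none-safe\n")
  invisible(x)
}

#' Tidy view of a threshold map
#'
#' @param x A `hep_threshold_map`.
#' @param ... Unused.
#' @export
as.data.frame.hep_threshold_map <- function(x, ...) {
  expand.grid(M = x$M_values, beta_ap = x$beta_values,
              KEEP.OUT.ATTRS = FALSE) |>
    cbind(threshold_pct = as.vector(x$threshold),
          status = as.vector(x$status))
}
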