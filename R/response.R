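#' Classify a regeneration trajectory into a response mode
#'
#' Modes, applied in order:
#' \describe{
#'   \item{failure}{mass fraction below 0.1 at 2 years (730 d);}
#'   \item{unresponsive}{no material change from the post-surgery value
#'     (max deviation below `delta_flat`);}
#'   \item{normal}{mass fraction within \[0.9, 1.1\] at 2.5 years (912.5 d);}
#'   \item{suppressed}{everything else (recovering but short of normal).}
#' }
#'
#' @param tr A `hep_trajectory` spanning at least 912.5 days.
#' @param delta_flat Flat-trajectory tolerance (absolute mass fraction).
#' @return Object of class `hep_response`: list with `label` and `evidence`
#'   (N at 730 d, N at 912.5 d, max absolute deviation from N(0)).
#' @export
classify_response <- function(tr, delta_flat = 0.01) {
  stopifnot(inherits(tr, "hep_trajectory"))
  if (max(tr$time) < 912.5)
    stop("trajectory must span at least 912.5 days for mode classification")
  n730 <- regeneration_profile(tr, 730)
  n912 <- regeneration_profile(tr, 912.5)
  dmax <- max(abs(tr$N - tr$N[1]))
  label <-
    if (n730 < 0.1) "failure"
    else if (dmax < delta_flat) "unresponsive"
    else if (n912 >= 0.9 && n912 <= 1.1) "normal"
    else "suppressed"
  structure(list(label = label,
                 evidence = c(N_730 = n730, N_912.5 = n912, max_dN = dmax)),
            class = "hep_response")
}

#' @export
print.hep_response <- function(x, ...) {
  cat("<hep_response>", x$label, " (N730 =", signif(x$evidence[1], 4),
      ", N912.5 =", signif(x$evidence[2], 4), ")\n")
  invisible(x)
}

#' Threshold of failure for a parameterization
#'
#' Scans resection levels (ascending) and reports the smallest level whose
#' trajectory fails, i.e. the critical level at and above which resection
#' leads to liver failure. Failure at a level means mass fraction below 0.1
#' at the end of `horizon`. The default `horizon = 730` is the 2-year rule;
#' a long horizon (e.g. `attractor_horizon()`) classifies by eventual fate,
#' resolving slow near-separatrix transients into the failure basin.
#'
#' @param p A [hep_params] object.
#' @param grid Resection levels to scan, sorted ascending within
#'   \[0.05, 0.90\] by default at 1\% resolution.
#' @param horizon Classification horizon in days (>= 730).
#' @param rtol,atol Solver tolerances.
#' @return Object of class `hep_threshold`: list with `threshold_pct`
#'   (percent, or `NA`), `status` one of `"threshold"`, `"none-safe"`
#'   (smallest scanned level already fails), `"none-found"` (no failure up to
#'   the top of the grid, reported as > 100 * max(grid)), and the `grid`.
#' @export
threshold_of_failure <- function(p, grid = seq(0.05, 0.90, by = 0.01),
                                 horizon = 730, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "hep_params"))
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  if (horizon < 730) stop("horizon must be at least 730 days")
  for (i in seq_along(grid)) {
    tr <- tryCatch(
      simulate_resection(p, grid[i], horizon = horizon,
                         times = c(0, 730, horizon)[c(TRUE, 730 < horizon, TRUE)],
                         rtol = rtol, atol = atol),
      error = function(e) stop("simulation failed at resection level ",
                               grid[i], ": ", conditionMessage(e)))
    if (tr$N[nrow(tr)] < 0.1) {
      status <- if (i == 1) "none-safe" else "threshold"
      return(structure(list(threshold_pct = round(100 * grid[i], 6),
                            status = status, grid = grid),
                       class = "hep_threshold"))
    }
  }
  structure(list(threshold_pct = NA_real_, status = "none-found", grid = grid),
            class = "hep_threshold")
}

#' Horizon long enough to resolve basin membership
#'
#' 36500 days (100 years): trajectories hovering near the separatrix for
#' years are followed to their attractor, so classification reflects the
#' asymptotic fate rather than the 2-year snapshot.
#'
#' @export
attractor_horizon <- function() 36500

#' @export
print.hep_threshold <- function(x, ...) {
  cat("<hep_threshold>",
      if (x$status == "threshold") paste0(x$threshold_pct, "% resection")
      else x$status, "\n")
  invisible(x)
}

#' (Q, R) phase portrait across resection levels
#'
#' Projects trajectories for a set of resection levels onto the
#' quiescent/replicating plane and marks the critical level (smallest failing
#' level among `levels` at the given horizon). Below the critical level
#' curves terminate near the recovery attractor; at and above it, near the
#' failure attractor at the origin.
#'
#' @param p A [hep_params] object.
#' @param levels At least two resection levels, ascending.
#' @param horizon Integration horizon in days (long, to approach attractors).
#' @return Object of class `hep_portrait`: list with `curves` (data.frame:
#'   `resection`, `time`, `Q`, `R`, `N`), `critical_resection` (fraction or
#'   `NA`) and `status` from [threshold_of_failure] on the same levels.
#' @export
phase_portrait <- function(p, levels, horizon = 7300) {
  if (length(levels) < 2) stop("need at least two resection levels")
  levels <- sort(levels)
  curves <- do.call(rbind, lapply(levels, function(r) {
    tr <- simulate_resection(p, r, horizon = horizon)
    # tolerance-level solver negatives floored for the (Q, R) projection
    data.frame(resection = r, time = tr$time,
               Q = pmax(tr$Q, 0), R = pmax(tr$R, 0), N = tr$N)
  }))
  thr <- threshold_of_failure(p, grid = levels, horizon = horizon)
  structure(list(curves = curves,
                 critical_resection = if (is.na(thr$threshold_pct)) NA_real_
                                      else thr$threshold_pct / 100,
                 status = thr$status),
            class = "hep_portrait")
}

#' @export
print.hep_portrait <- function(x, ...) {
  cat("<hep_portrait>", length(unique(x$curves$resection)), "levels;",
      "critical resection:",
      if (is.na(x$critical_resection)) x$status else x$critical_resection,
      "\n")
  invisible(x)
}
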