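#' Synthetic liver-volume series for one patient
#'
#' Observations are the model's mass fraction at the requested times under
#' multiplicative lognormal noise:
#' `volume_i = N(t_i; truth) * exp(e_i)`, `e_i ~ N(0, noise_sd^2)` -
#' volumetry errors scale with volume. The generating truth is attached for
#' recovery scoring.
#'
#' @param truth Generating [hep_params].
#' @param resection_fraction Resection applied at t = 0.
#' @param times Observation times (days, increasing); default
#'   [clinical_sampling_times].
#' @param noise_sd Lognormal noise standard deviation (default 0.05).
#' @param seed Integer seed; the series is fully determined by it.
#' @param covariates Optional named list (e.g. `bmi`, `sex`, `height_m`).
#' @return A `hep_series`: data.frame `time_days`, `volume_fraction` with
#'   attributes `resection_fraction`, `truth`, `covariates`.
#' @export
generate_patient_series <- function(truth, resection_fraction,
                                    times = NULL, noise_sd = 0.05,
                                    seed = 1, covariates = NULL) {
  stopifnot(inherits(truth, "hep_params"))
  if (is.null(times)) times <- clinical_sampling_times(6)
  if (is.unsorted(times, strictly = TRUE) || any(times <= 0))
    stop("times must be strictly increasing and positive")
  tr <- simulate_resection(truth, resection_fraction, horizon = max(times),
                           times = c(0, times))
  N <- tr$N[match(times, tr$time)]
  eps <- with_seed(seed, rnorm(length(times), 0, noise_sd))
  structure(data.frame(time_days = times, volume_fraction = N * exp(eps)),
            class = c("hep_series", "data.frame"),
            resection_fraction = resection_fraction,
            truth = truth, covariates = covariates)
}

#' Log-spaced clinical follow-up times
#'
#' `n` observation times log-spaced over \[14, 912.5\] days: dense early
#' follow-up after surgery, sparse late volumetry, mimicking clinical
#' practice.
#'
#' @param n Number of observations.
#' @param t_min,t_max Range in days.
#' @export
clinical_sampling_times <- function(n, t_min = 14, t_max = 912.5) {
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Specification of a synthetic virtual-clinical cohort
#'
#' Defines the generating laws for a cohort of synthetic patients: the
#' reference truth and per-parameter log-uniform jitter folds, the
#' observation-time law (4-8 log-spaced times by default), multiplicative
#' noise level, resection distribution (uniform on \[0.30, 0.70\]), and the
#' covariate model (BMI ~ Normal(22.5, 3) truncated at 15, sex ~
#' Bernoulli(0.5), sex-specific heights 1.72/1.58 m).
#'
#' @param n_patients Cohort size (default 27, the tuning-set size emulated).
#' @param reference Reference truth parameters.
#' @param jitter_folds Named vector of fold ranges; each patient's truth
#'   multiplies the reference by `exp(U(-log sqrt(f), log sqrt(f)))`
#'   per jittered parameter.
#' @param n_times_range Range `c(min, max)` of observations per patient.
#' @param noise_sd Multiplicative lognormal noise sd.
#' @param resection_range Uniform resection-fraction range.
#' @param bmi_mean,bmi_sd,bmi_min Truncated-normal BMI model.
#' @return A `hep_cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(n_patients = 27,
                                  reference = id71_params(),
                                  jitter_folds = c(M = 2, k_G = 2,
                                                   beta_ap = 2),
                                  n_times_range = c(4, 8),
                                  noise_sd = 0.05,
                                  resection_range = c(0.30, 0.70),
                                  bmi_mean = 22.5, bmi_sd = 3,
                                  bmi_min = 15) {
  bad <- setdiff(names(jitter_folds), hep_param_names)
  if (length(bad)) stop("unknown jitter parameters: ",
                        paste(bad, collapse = ", "))
  stopifnot(n_patients >= 1, all(jitter_folds >= 1), noise_sd >= 0,
            resection_range[1] >= 0, resection_range[2] < 1)
  structure(list(n_patients = n_patients, reference = reference,
                 jitter_folds = jitter_folds, n_times_range = n_times_range,
                 noise_sd = noise_sd, resection_range = resection_range,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_min = bmi_min),
            class = "hep_cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient truths around the reference (independent log-uniform
#' jitter), observation schedules, resections and covariates from the spec's
#' laws, then generates each series via [generate_patient_series]. Patients
#' whose simulation fails are resampled (up to `retry_cap` attempts each).
#' Fully determined by `seed`.
#'
#' @param spec A [synthetic_cohort_spec].
#' @param seed Integer seed.
#' @param retry_cap Resampling attempts per patient.
#' @return List of `hep_series` (attributes carry truth and covariates).
#' @export
generate_cohort <- function(spec, seed = 1, retry_cap = 5) {
  stopifnot(inherits(spec, "hep_cohort_spec"))
  ref_v <- setNames(as.numeric(spec$reference), names(spec$reference))
  draws <- with_seed(seed, {
    lapply(seq_len(spec$n_patients), function(i) {
      list(
        jit = vapply(spec$jitter_folds, function(f)
          exp(runif(1, -log(sqrt(f)), log(sqrt(f)))), 0),
        n_t = {
          nn <- seq(spec$n_times_range[1], spec$n_times_range[2])
          nn[sample.int(length(nn), 1)]
        },
        resect = runif(1, spec$resection_range[1], spec$resection_range[2]),
        bmi = max(spec$bmi_min, rnorm(1, spec$bmi_mean, spec$bmi_sd)),
        sex = if (runif(1) < 0.5) "M" else "F",
        series_seed = sample.int(.Machine$integer.max, 1))
    })
  })
  lapply(seq_len(spec$n_patients), function(i) {
    d <- draws[[i]]
    v <- ref_v
    v[names(d$jit)] <- v[names(d$jit)] * d$jit
    truth <- hep_params(v, eps = attr(spec$reference, "eps"),
                        N_SS = attr(spec$reference, "N_SS"))
    cov <- list(bmi = d$bmi, sex = d$sex,
                height_m = if (d$sex == "M") 1.72 else 1.58)
    for (attempt in seq_len(retry_cap)) {
      s <- tryCatch(
        generate_patient_series(truth, d$resect,
                                times = clinical_sampling_times(d$n_t),
                                noise_sd = spec$noise_sd,
                                seed = d$series_seed + attempt - 1,
                                covariates = cov),
        error = function(e) NULL)
      if (!is.null(s)) return(s)
    }
    stop("patient ", i, ": simulation failed after ", retry_cap, " attempts")
  })
}

#' Full-recovery predicate
#'
#' Whether the final observed volume fraction lies inside `window`. Two
#' windows are in clinical use for "recovered fully": \[0.9, 1.0\] (fraction
#' of the preoperative volume, used when selecting tuning patients) and
#' \[0.9, 1.1\] (the normal-mode window); the default is the wider one.
#'
#' @param series A `hep_series`.
#' @param window Acceptance window on the final volume fraction.
#' @export
recovered_fully <- function(series, window = c(0.9, 1.1)) {
  v <- series$volume_fraction[nrow(series)]
  v >= window[1] && v <= window[2]
}

#' Read / write patient series CSV
#'
#' Dialect: columns `patient_id`, `time_days`, `volume_fraction`,
#' `resection_fraction`, `bmi`, `sex`. `write_patient_series` writes one or
#' more series to a single CSV; `read_patient_series` returns a list of
#' `hep_series`.
#'
#' @param series_list List of `hep_series` (or a single one).
#' @param path CSV path.
#' @export
write_patient_series <- function(series_list, path) {
  if (inherits(series_list, "hep_series")) series_list <- list(series_list)
  rows <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    cov <- attr(s, "covariates")
    data.frame(patient_id = i, time_days = s$time_days,
               volume_fraction = s$volume_fraction,
               resection_fraction = attr(s, "resection_fraction"),
               bmi = if (!is.null(cov$bmi)) cov$bmi else NA_real_,
               sex = if (!is.null(cov$sex)) cov$sex else NA_character_)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patient_series
#' @export
read_patient_series <- function(path) {
  df <- read.csv(path)
  need <- c("patient_id", "time_days", "volume_fraction",
            "resection_fraction")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$time_days), ]
    structure(data.frame(time_days = d$time_days,
                         volume_fraction = d$volume_fraction),
              class = c("hep_series", "data.frame"),
              resection_fraction = d$resection_fraction[1],
              truth = NULL,
              covariates = list(bmi = d$bmi[1], sex = d$sex[1]))
  })
}
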