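#' @useDynLib hepregen, .registration = TRUE
#' @importFrom stats approx optim rnorm runif setNames cor quantile median sd
#' @importFrom utils read.csv write.csv modifyList
NULL

#' Canonical names of the 33 tunable model parameters
#'
#' Order follows the reference parameter table: metabolic load first, then the
#' cytokine/JAK-STAT/SOCS3/immediate-early cascade constants, ECM and growth
#' factor turnover, cell-state transition rates, the two tanh switches
#' (re-quiescence and apoptosis), and the relative cell-mass growth constant.
#'
#' @format Character vector of length 33.
#' @export
hep_param_names <- c(
  "M", "k_IL6", "kappa_IL6", "V_JAK", "KM_JAK", "kappa_JAK",
  "proSTAT3", "V_ST3", "KM_ST3", "kappa_ST3",
  "V_SOCS3", "KM_SOCS3", "kappa_SOCS3", "KI_SOCS3",
  "V_IE", "KM_IE", "kappa_IE",
  "k_deg", "kappa_ECM", "k_GF", "kappa_GF", "k_up",
  "k_QP", "k_PR", "k_RQ", "k_prol",
  "k_req", "theta_req", "beta_req",
  "k_ap", "theta_ap", "beta_ap", "k_G"
)

#' Construct and validate a model parameter set
#'
#' A parameter set is a named numeric vector of the 33 tunable constants (per
#' day time base) plus two model constants carried as attributes: `eps`, the
#' senescent-but-functional cell fraction entering the load denominator
#' M/(N + eps), and `N_SS`, the pre-resection non-senescent mass. At baseline
#' `N_SS + eps = 1` so that total liver mass is normalized to the preoperative
#' organ.
#'
#' @param values Named numeric vector or list covering all 33 parameters in
#'   [hep_param_names] (any order; extra names are an error).
#' @param eps Senescent functional cell fraction (default 0.01).
#' @param N_SS Pre-resection non-senescent mass (default 0.99).
#' @return Object of class `hep_params`: named numeric vector (canonical
#'   order) with attributes `eps` and `N_SS`.
#' @export
hep_params <- function(values, eps = 0.01, N_SS = 0.99) {
  values <- unlist(values)
  if (!all(hep_param_names %in% names(values)))
    stop("missing parameters: ",
         paste(setdiff(hep_param_names, names(values)), collapse = ", "))
  extra <- setdiff(names(values), hep_param_names)
  if (length(extra))
    stop("unknown parameters: ", paste(extra, collapse = ", "))
  p <- values[hep_param_names]
  storage.mode(p) <- "double"
  if (any(!is.finite(p)))
    stop("non-finite parameter value: ",
         paste(names(p)[!is.finite(p)], collapse = ", "))
  if (any(p < 0))
    stop("negative parameter value: ", paste(names(p)[p < 0], collapse = ", "))
  if (p[["beta_ap"]] <= 0 || p[["beta_req"]] <= 0)
    stop("tanh slopes beta_ap and beta_req must be strictly positive")
  if (p[["M"]] <= 0) stop("metabolic load M must be strictly positive")
  if (!is.finite(eps) || eps < 0) stop("eps must be >= 0")
  if (!is.finite(N_SS) || N_SS + eps <= 0) stop("N_SS + eps must be positive")
  structure(p, eps = eps, N_SS = N_SS, class = "hep_params")
}

#' @export
print.hep_params <- function(x, ...) {
  cat("<hep_params> 33 parameters, eps =", attr(x, "eps"),
      ", N_SS =", attr(x, "N_SS"), "\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Override selected parameters
#'
#' Returns a copy of `p` with the named parameters replaced; validation is
#' re-run so invalid overrides fail immediately.
#'
#' @param p A [hep_params] object.
#' @param ... Named scalar overrides, e.g. `M = 4`.
#' @export
set_params <- function(p, ...) {
  ov <- list(...)
  if (length(ov) == 0) return(p)
  v <- as.list(setNames(as.numeric(p), names(p)))
  bad <- setdiff(names(ov), hep_param_names)
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  v[names(ov)] <- ov
  hep_params(v, eps = attr(p, "eps"), N_SS = attr(p, "N_SS"))
}

#' Read / write parameter sets as flat JSON
#'
#' Files are flat `name: value` JSON objects keyed by [hep_param_names]
#' (ASCII transliteration of the field's symbols: `kappa_IL6`, `KM_JAK`,
#' `theta_ap`, `beta_ap`, ...). Optional keys `eps` and `N_SS` override the
#' model-constant defaults.
#'
#' @param path File path.
#' @return `read_params`: a [hep_params] object.
#' @export
read_params <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- v[!startsWith(names(v), "__")]   # tolerate comment keys
  eps <- if (!is.null(v[["eps"]])) v[["eps"]] else 0.01
  nss <- if (!is.null(v[["N_SS"]])) v[["N_SS"]] else 0.99
  v <- v[setdiff(names(v), c("eps", "N_SS"))]
  hep_params(v, eps = eps, N_SS = nss)
}

#' @rdname read_params
#' @param p A [hep_params] object.
#' @export
write_params <- function(p, path) {
  x <- as.list(setNames(as.numeric(p), names(p)))
  x$eps <- attr(p, "eps")
  x$N_SS <- attr(p, "N_SS")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reference human-timescale parameterization
#'
#' The optimized 33-parameter vector for the reference patient used throughout
#' the cohort analyses (shipped as `extdata/id71_optimal.json`).
#'
#' @export
id71_params <- function() {
  read_params(system.file("extdata", "id71_optimal.json",
                          package = "hepregen", mustWork = TRUE))
}

#' Synthetic rodent-baseline parameterization
#'
#' A stand-in rodent baseline used only as the calibration initial guess. The
#' published rodent values are not redistributable here, so this fixture
#' back-scales the reference human vector in the directions reported for the
#' significantly rescaled parameters (higher metabolic load and cell-mass
#' growth rate, lower apoptosis threshold in the rodent). It is synthetic and
#' non-authoritative; any real baseline can be supplied via [read_params].
#'
#' @export
rat_baseline_params <- function() {
  read_params(system.file("extdata", "rat_baseline_synthetic.json",
                          package = "hepregen", mustWork = TRUE))
}
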