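#' Homeostatic flux constants
#'
#' The seven in/out-flux constants k1..k7 are defined so that every molecular
#' species has zero net rate at the pre-resection steady state (all species at
#' their baseline value 1, non-senescent mass at `N_SS`). They are fixed at
#' their baseline values and are not altered during regeneration.
#'
#' @param p A [hep_params] object.
#' @return Named numeric vector `k1`..`k7`.
#' @export
derived_constants <- function(p) {
  stopifnot(inherits(p, "hep_params"))
  eps <- attr(p, "eps"); nss <- attr(p, "N_SS")
  if (p[["KI_SOCS3"]] <= 0)
    stop("invalid parameter: the 1/K_I inhibition term is non-finite ",
         "for KI_SOCS3 <= 0")
  v <- as.list(setNames(as.numeric(p), names(p)))
  k <- with(v, c(
    k1 = V_JAK / (1 + KM_JAK) - k_IL6 * M / (nss + eps) + kappa_IL6,
    k2 = kappa_JAK - V_JAK / (1 + KM_JAK),
    k3 = -V_ST3 * proSTAT3^2 / (proSTAT3^2 + KM_ST3 * (1 + 1 / KI_SOCS3)) +
      V_IE / (1 + KM_IE) + V_SOCS3 / (1 + KM_SOCS3) + kappa_ST3,
    k4 = -V_SOCS3 / (1 + KM_SOCS3) + kappa_SOCS3,
    k5 = -V_IE / (1 + KM_IE) + kappa_IE,
    k6 = k_deg + kappa_ECM,
    k7 = -k_GF * M / (nss + eps) + k_up + kappa_GF
  ))
  if (any(!is.finite(k)))
    stop("non-finite homeostatic constant (check KI_SOCS3 and saturation ",
         "denominators): ", paste(names(k)[!is.finite(k)], collapse = ", "))
  k
}

tanh_clip <- function(x) tanh(pmin(50, pmax(-50, x)))

#' Apoptosis switch
#'
#' Smooth (tanh) switch on the per-cell metabolic reserve: apoptotic loss
#' turns on as functional mass per unit demand `(N + eps)/M` falls below the
#' threshold `theta_ap`, with sensitivity (inverse slope) `beta_ap`.
#'
#' @param N Non-senescent liver mass fraction.
#' @param p A [hep_params] object.
#' @return Value in \[0, 1\], decreasing in `N`, increasing in `M`.
#' @export
sigma_ap <- function(N, p) {
  eps <- attr(p, "eps")
  0.5 * (1 + tanh_clip((p[["theta_ap"]] - (N + eps) / p[["M"]]) / p[["beta_ap"]]))
}

#' Re-quiescence switch
#'
#' Primed hepatocytes return to quiescence when growth factor falls below
#' `theta_req`; slope set by `beta_req`.
#'
#' @param GF Growth factor level (baseline = 1).
#' @inheritParams sigma_ap
#' @return Value in \[0, 1\], decreasing in `GF`.
#' @export
sigma_req <- function(GF, p) {
  0.5 * (1 + tanh_clip((p[["theta_req"]] - GF) / p[["beta_req"]]))
}

#' Non-senescent liver mass fraction
#'
#' `N = Q + G (P + R)`: quiescent cells plus primed/replicating cells weighted
#' by relative cell mass G (hypertrophy).
#'
#' @param state Named numeric state vector (needs `Q`, `P`, `R`, `G`).
#' @export
total_mass <- function(state) {
  unname(state[["Q"]] + state[["G"]] * (state[["P"]] + state[["R"]]))
}

hep_state_names <- c("Q", "P", "R", "IL6", "JAK", "STAT3", "SOCS3",
                     "IE", "GF", "ECM", "G")

## parameter vector as passed to the compiled right-hand side
hep_pack_parms <- function(p, k = derived_constants(p)) {
  c(as.numeric(p), attr(p, "eps"), attr(p, "N_SS"), as.numeric(k))
}

#' Model right-hand side
#'
#' Time-derivatives of the 11 state variables: three hepatocyte functional
#' states (Q, P, R), seven molecular species relative to baseline (IL6, JAK,
#' STAT3, SOCS3, IE, GF, ECM) and relative cell mass G. Metabolic load per
#' functional cell is `M/(N + eps)` throughout; the baseline offsets of the
#' immediate-early and growth-factor drives are their initial values (1).
#' The system is autonomous; `t` is accepted for solver compatibility.
#'
#' @param t Time (days); unused.
#' @param state Named state vector (order of `hep_state_names`).
#' @param p A [hep_params] object.
#' @param k Derived constants from [derived_constants] (recomputed if omitted).
#' @return List with the named derivative vector (deSolve convention).
#' @export
liver_rhs <- function(t, state, p, k = derived_constants(p)) {
  if (any(!is.finite(state)))
    stop("non-finite state component: ",
         paste(hep_state_names[!is.finite(state)], collapse = ", "))
  eps <- attr(p, "eps")
  v <- as.list(setNames(as.numeric(p), names(p)))
  s <- as.list(setNames(as.numeric(state), hep_state_names))
  kk <- as.list(k)
  d <- with(c(v, s, kk), {
    N <- Q + G * (P + R)
    load <- M / (N + eps)
    sap <- 0.5 * (1 + tanh_clip((theta_ap - (N + eps) / M) / beta_ap))
    sreq <- 0.5 * (1 + tanh_clip((theta_req - GF) / beta_req))
    c(
      Q = -k_QP * (IE - 1) * Q + k_RQ * ECM * R + k_req * sreq * P - k_ap * sap * Q,
      P =  k_QP * (IE - 1) * Q - k_PR * (GF - 1) * P - k_req * sreq * P - k_ap * sap * P,
      R =  k_PR * (GF - 1) * P - k_RQ * ECM * R + k_prol * R - k_ap * sap * R,
      IL6 = k_IL6 * load - V_JAK * IL6 / (IL6 + KM_JAK) - kappa_IL6 * IL6 + k1,
      JAK = V_JAK * IL6 / (IL6 + KM_JAK) - kappa_JAK * JAK + k2,
      STAT3 = V_ST3 * JAK * proSTAT3^2 /
        (proSTAT3^2 + KM_ST3 * (1 + SOCS3 / KI_SOCS3)) -
        V_IE * STAT3 / (STAT3 + KM_IE) -
        V_SOCS3 * STAT3 / (STAT3 + KM_SOCS3) -
        kappa_ST3 * STAT3 + k3,
      SOCS3 = V_SOCS3 * STAT3 / (STAT3 + KM_SOCS3) - kappa_SOCS3 * SOCS3 + k4,
      IE = V_IE * STAT3 / (STAT3 + KM_IE) - kappa_IE * IE + k5,
      GF = k_GF * load - k_up * GF * ECM - kappa_GF * GF + k7,
      ECM = -k_deg * IL6 * ECM - kappa_ECM * ECM + k6,
      G = k_G * load - k_G * M
    )
  })
  list(d)
}

#' Pre-resection baseline state
#'
#' All molecular species at 1, `Q = N_SS`, `P = R = 0`, `G = 1`: the
#' steady state the homeostatic constants are constructed around.
#'
#' @inheritParams sigma_ap
#' @export
baseline_state <- function(p) {
  setNames(c(attr(p, "N_SS"), 0, 0, rep(1, 7), 1), hep_state_names)
}
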