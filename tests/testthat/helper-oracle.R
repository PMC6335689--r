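# Independent transcription of the model equations, written against the
# published equation set separately from the package implementation (indexed
# style, explicit intermediate fluxes). Used as the cross-check oracle.

oracle_derived <- function(pv, eps, nss) {
  den <- nss + eps
  jak_sat0 <- pv["V_JAK"] / (1 + pv["KM_JAK"])
  st3_num0 <- pv["V_ST3"] * pv["proSTAT3"]^2
  st3_den0 <- pv["proSTAT3"]^2 + pv["KM_ST3"] * (1 + 1 / pv["KI_SOCS3"])
  ie_sat0  <- pv["V_IE"] / (1 + pv["KM_IE"])
  so_sat0  <- pv["V_SOCS3"] / (1 + pv["KM_SOCS3"])
  unname(c(
    jak_sat0 - pv["k_IL6"] * pv["M"] / den + pv["kappa_IL6"],
    pv["kappa_JAK"] - jak_sat0,
    -st3_num0 / st3_den0 + ie_sat0 + so_sat0 + pv["kappa_ST3"],
    -so_sat0 + pv["kappa_SOCS3"],
    -ie_sat0 + pv["kappa_IE"],
    pv["k_deg"] + pv["kappa_ECM"],
    -pv["k_GF"] * pv["M"] / den + pv["k_up"] + pv["kappa_GF"]
  ))
}

oracle_rhs <- function(y, pv, eps = 0.01, nss = 0.99) {
  k <- oracle_derived(pv, eps, nss)
  Q <- y[1]; P <- y[2]; R <- y[3]
  IL6 <- y[4]; JAK <- y[5]; ST3 <- y[6]; SO <- y[7]
  IE <- y[8]; GF <- y[9]; ECM <- y[10]; G <- y[11]
  N <- Q + G * (P + R)
  percell <- (N + eps) / pv["M"]
  sap  <- (1 + tanh((pv["theta_ap"] - percell) / pv["beta_ap"])) / 2
  sreq <- (1 + tanh((pv["theta_req"] - GF) / pv["beta_req"])) / 2
  prime  <- pv["k_QP"] * (IE - 1) * Q
  repl   <- pv["k_PR"] * (GF - 1) * P
  requi  <- pv["k_req"] * sreq * P
  back   <- pv["k_RQ"] * ECM * R
  jakflx <- pv["V_JAK"] * IL6 / (IL6 + pv["KM_JAK"])
  st3flx <- pv["V_ST3"] * JAK * pv["proSTAT3"]^2 /
    (pv["proSTAT3"]^2 + pv["KM_ST3"] * (1 + SO / pv["KI_SOCS3"]))
  ieflx  <- pv["V_IE"] * ST3 / (ST3 + pv["KM_IE"])
  soflx  <- pv["V_SOCS3"] * ST3 / (ST3 + pv["KM_SOCS3"])
  unname(c(
    -prime + back + requi - pv["k_ap"] * sap * Q,
    prime - repl - requi - pv["k_ap"] * sap * P,
    repl - back + pv["k_prol"] * R - pv["k_ap"] * sap * R,
    pv["k_IL6"] * pv["M"] / (N + eps) - jakflx - pv["kappa_IL6"] * IL6 + k[1],
    jakflx - pv["kappa_JAK"] * JAK + k[2],
    st3flx - ieflx - soflx - pv["kappa_ST3"] * ST3 + k[3],
    soflx - pv["kappa_SOCS3"] * SO + k[4],
    ieflx - pv["kappa_IE"] * IE + k[5],
    pv["k_GF"] * pv["M"] / (N + eps) - pv["k_up"] * GF * ECM -
      pv["kappa_GF"] * GF + k[7],
    -pv["k_deg"] * IL6 * ECM - pv["kappa_ECM"] * ECM + k[6],
    pv["k_G"] * pv["M"] / (N + eps) - pv["k_G"] * pv["M"]
  ))
}

# reference parameter vector as a plain named vector
ref_param_vector <- function() {
  p <- id71_params()
  setNames(as.numeric(p), names(p))
}

# random baseline-viable parameter set: log-uniform two-fold jitter around the
# reference, redrawing the apoptosis switch until its baseline tail is
# negligible (the homeostatic constants cancel molecular fluxes only; a
# baseline-viable patient has essentially no apoptotic loss pre-resection)
random_viable_params <- function() {
  ref <- ref_param_vector()
  repeat {
    v <- ref * exp(runif(length(ref), -log(sqrt(2)), log(sqrt(2))))
    tail <- 0.5 * (1 + tanh((v[["theta_ap"]] - 1 / v[["M"]]) / v[["beta_ap"]]))
    if (tail < 1e-10) return(hep_params(v))
  }
}

# minimal trajectory container for classification-rule tests
fake_trajectory <- function(times, N, resection) {
  structure(data.frame(time = times, N = N),
            class = c("hep_trajectory", "data.frame"),
            resection_fraction = resection, params_id = "fake")
}
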