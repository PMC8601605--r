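#' Single-cell reaction kinetics
#'
#' The intracellular model tracks three state variables per cell:
#' cytosolic IP3 `p` (uM), cytosolic Ca2+ `c` (uM) and the fraction `r`
#' of IP3 receptors not yet inactivated by Ca2+. The ER Ca2+
#' concentration `s` is algebraically slaved to `c` through total-Ca2+
#' conservation (see [er_calcium]), so it is derived, never integrated.
#' All functions are vectorized over their state arguments.
#'
#' @name kinetics
NULL

#' PLC-mediated IP3 production rate
#'
#' Hill-type activation of phospholipase C by cytosolic Ca2+:
#' `v_plc * c^2 / (K_PLC^2 + c^2)`.
#'
#' @param c Cytosolic Ca2+ concentration, uM (non-negative).
#' @param v_plc Maximal IP3 production rate, uM/s (non-negative). This is
#'   the per-cell stimulation-strength control parameter.
#' @param params A [model_params] object.
#' @return IP3 production rate, uM/s, in `[0, v_plc)`.
#' @export
plc_production <- function(c, v_plc, params = model_params()) {
  if (any(c < 0)) stop("c must be non-negative", call. = FALSE)
  if (any(v_plc < 0)) stop("v_plc must be non-negative", call. = FALSE)
  v_plc * c^2 / (params$K_PLC^2 + c^2)
}

#' ER Ca2+ concentration from total-Ca2+ conservation
#'
#' `s = (c_tot - c) / beta`, the algebraic closure that eliminates the ER
#' pool as a dynamical variable; `c + beta * s = c_tot` holds identically.
#'
#' @inheritParams plc_production
#' @return ER Ca2+ concentration `s`, uM.
#' @export
er_calcium <- function(c, params = model_params()) {
  if (any(c < 0) || any(c > params$c_tot))
    stop("c must lie in [0, c_tot]", call. = FALSE)
  (params$c_tot - c) / params$beta
}

#' Time derivative of cytosolic Ca2+
#'
#' IP3R-gated release plus ER leak, both driven by the ER-cytosol
#' gradient, minus SERCA reuptake, plus any gap-junction flux `jc`:
#' `jc + [k1 (r c/(Ka+c) p/(Kp+p))^3 + k2] (s - c)
#'  - V_SERCA c^2/(c^2 + K_SERCA^2)`.
#'
#' @param p Cytosolic IP3, uM.
#' @param c Cytosolic Ca2+, uM, in `[0, c_tot]`.
#' @param r Fraction of non-inactivated IP3R, in `[0, 1]`.
#' @param jc Gap-junction Ca2+ flux into the cell, uM/s.
#' @param params A [model_params] object.
#' @return dc/dt, uM/s.
#' @export
calcium_rhs <- function(p, c, r, jc = 0, params = model_params()) {
  s <- er_calcium(c, params)
  gate <- (r * c / (params$Ka + c) * p / (params$Kp + p))^3
  jc + (params$k1 * gate + params$k2) * (s - c) -
    params$V_SERCA * c^2 / (c^2 + params$K_SERCA^2)
}

#' Time derivative of cytosolic IP3
#'
#' PLC production minus first-order dephosphorylation, plus any
#' gap-junction flux `jp`: `jp + plc_production(c, v_plc) - k5P * p`.
#'
#' @inheritParams calcium_rhs
#' @param v_plc Per-cell maximal PLC rate, uM/s.
#' @param jp Gap-junction IP3 flux into the cell, uM/s.
#' @return dp/dt, uM/s.
#' @export
ip3_rhs <- function(p, c, v_plc, jp = 0, params = model_params()) {
  jp + plc_production(c, v_plc, params) - params$k5P * p
}

#' Time derivative of the non-inactivated IP3R fraction
#'
#' Relaxation toward the nullcline `r = Kr/(Kr + c)`. With the default
#' `"modified"` variant the relaxation rate itself is Ca2+-dependent,
#' `(k_tau^4 + c^4)/(tau_max k_tau^4)`; with `"constant_tau"` it is the
#' fixed `1/tau_r`. The two coincide at `c = 0` when `tau_r = tau_max`.
#'
#' @inheritParams calcium_rhs
#' @return dr/dt, 1/s.
#' @export
receptor_rhs <- function(c, r, params = model_params()) {
  drive <- 1 - r * (params$Kr + c) / params$Kr
  if (identical(params$receptor_variant, "modified")) {
    (params$k_tau^4 + c^4) / (params$tau_max * params$k_tau^4) * drive
  } else {
    if (!is.numeric(params$tau_r) || is.na(params$tau_r))
      stop("receptor_variant = 'constant_tau' requires tau_r",
           call. = FALSE)
    drive / params$tau_r
  }
}

# full single-cell RHS, optionally with a linear reservoir leak
# leak: list(Fp, Fc, L, p_rest, c_rest) or NULL
cell_rhs <- function(p, c, r, v_plc, params, leak = NULL) {
  jp <- 0; jc <- 0
  if (!is.null(leak)) {
    jp <- -leak$Fp * leak$L * (p - leak$p_rest)
    jc <- -leak$Fc * leak$L * (c - leak$c_rest)
  }
  c(ip3_rhs(p, c, v_plc, jp, params),
    calcium_rhs(p, c, r, jc, params),
    receptor_rhs(c, r, params))
}

#' Resting state of an unstimulated cell
#'
#' Fixed point of the isolated single-cell model at `v_plc = 0`: IP3 is
#' zero, Ca2+ balances the ER leak against SERCA reuptake, and the
#' receptor pool sits on its nullcline. Used as the default initial
#' condition for all simulations.
#'
#' @param params A [model_params] object.
#' @return Named vector `c(p, c, r)`.
#' @export
resting_state <- function(params = model_params()) {
  g <- function(c) {
    params$k2 * (er_calcium(c, params) - c) -
      params$V_SERCA * c^2 / (c^2 + params$K_SERCA^2)
  }
  cr <- stats::uniroot(g, c(1e-9, params$c_tot - 1e-9), tol = 1e-14)$root
  c(p = 0, c = cr, r = params$Kr / (params$Kr + cr))
}
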