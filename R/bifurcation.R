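#' Numerical bifurcation analysis of the single-cell model
#'
#' Steady states, linear stability, Hopf threshold location and
#' limit-cycle summaries as the stimulation strength `V_PLC` varies.
#' An optional gap-junction "leak" models an isolated stimulated cell
#' whose neighbours are clamped at the unstimulated resting state: it
#' adds linear terms `-Fp*L*(p - p_rest)` and `-Fc*L*(c - c_rest)` with
#' total shared boundary `L`.
#'
#' @name bifurcation
NULL

#' Reservoir-leak specification
#'
#' @param Fp,Fc Gap-junction permeabilities toward the resting
#'   reservoir.
#' @param L Total shared boundary with the reservoir (default 6, a
#'   hexagonal cell with unit-length sides).
#' @param params Parameters used to locate the resting reservoir state.
#' @return A list with elements `Fp`, `Fc`, `L`, `p_rest`, `c_rest`.
#' @export
gj_leak <- function(Fp = 0, Fc = 0, L = 6, params = model_params()) {
  rest <- resting_state(params)
  list(Fp = Fp, Fc = Fc, L = L,
       p_rest = unname(rest["p"]), c_rest = unname(rest["c"]))
}

#' Steady state of the single-cell model
#'
#' Uses the algebraic closures `r* = Kr/(Kr + c*)` and
#' `p* = (plc_production(c*) + Fp*L*p_rest) / (k5P + Fp*L)` and solves
#' the remaining scalar Ca2+ balance by bracketed root finding on a fine
#' scan of `c` in `(0, c_tot)`. Where the balance has several roots (the
#' folded branch structure at high stimulation) the lowest-Ca2+ root is
#' returned, which is the branch on which the first Hopf point lives.
#'
#' @param v_plc Stimulation strength, uM/s (>= 0).
#' @param params A [model_params] object.
#' @param leak Optional [gj_leak] specification.
#' @return Named vector `c(p, c, r)` with attribute `residual` (the
#'   maximum absolute RHS component, < 1e-10).
#' @export
steady_state <- function(v_plc, params = model_params(), leak = NULL) {
  if (v_plc < 0) stop("v_plc must be non-negative", call. = FALSE)
  lp <- if (is.null(leak)) 0 else leak$Fp * leak$L
  lp_rest <- if (is.null(leak)) 0 else leak$Fp * leak$L * leak$p_rest
  p_of_c <- function(c) {
    (plc_production(c, v_plc, params) + lp_rest) / (params$k5P + lp)
  }
  g <- function(c) {
    r <- params$Kr / (params$Kr + c)
    jc <- if (is.null(leak)) 0 else -leak$Fc * leak$L * (c - leak$c_rest)
    calcium_rhs(p_of_c(c), c, r, jc, params)
  }
  cs <- seq(1e-8, params$c_tot - 1e-8, length.out = 2001)
  gv <- vapply(cs, g, 0)
  idx <- which(gv[-length(gv)] * gv[-1] <= 0)
  if (!length(idx))
    stop("no steady state found in c in (0, ", params$c_tot,
         "): scanned 2001 points", call. = FALSE)
  i <- idx[1]
  cr <- stats::uniroot(g, c(cs[i], cs[i + 1]), tol = 1e-14)$root
  st <- c(p = unname(p_of_c(cr)), c = cr,
          r = unname(params$Kr / (params$Kr + cr)))
  res <- max(abs(cell_rhs(st["p"], st["c"], st["r"], v_plc, params,
                          leak)))
  attr(st, "residual") <- res
  st
}

#' Analytic Jacobian of the single-cell model
#'
#' 3x3 matrix of partial derivatives of `(dp/dt, dc/dt, dr/dt)` with the
#' ER pool eliminated algebraically; the leak contributes
#' `-Fp*L` and `-Fc*L` on the diagonal.
#'
#' @param state Named or ordered vector `c(p, c, r)`.
#' @param v_plc Stimulation strength, uM/s.
#' @param params A [model_params] object.
#' @param leak Optional [gj_leak].
#' @return 3x3 numeric matrix, rows/cols ordered `(p, c, r)`.
#' @export
model_jacobian <- function(state, v_plc, params = model_params(),
                           leak = NULL) {
  p <- state[[1]]; c <- state[[2]]; r <- state[[3]]
  K2 <- params$K_PLC^2
  lp <- if (is.null(leak)) 0 else leak$Fp * leak$L
  lc <- if (is.null(leak)) 0 else leak$Fc * leak$L

  # dp/dt = v c^2/(K2+c^2) - k5P p - lp (p - p_rest)
  J11 <- -params$k5P - lp
  J12 <- v_plc * 2 * c * K2 / (K2 + c^2)^2
  J13 <- 0

  # dc/dt = (k1 A^3 + k2) S - V c^2/(c^2+Ks^2) - lc (c - c_rest)
  A <- r * c / (params$Ka + c) * p / (params$Kp + p)
  S <- er_calcium(c, params) - c
  dA_dp <- r * c / (params$Ka + c) * params$Kp / (params$Kp + p)^2
  dA_dc <- r * p / (params$Kp + p) * params$Ka / (params$Ka + c)^2
  dA_dr <- c / (params$Ka + c) * p / (params$Kp + p)
  rel <- params$k1 * A^3 + params$k2
  dS_dc <- -1 / params$beta - 1
  Ks2 <- params$K_SERCA^2
  dserca <- params$V_SERCA * 2 * c * Ks2 / (c^2 + Ks2)^2
  J21 <- 3 * params$k1 * A^2 * dA_dp * S
  J22 <- 3 * params$k1 * A^2 * dA_dc * S + rel * dS_dc - dserca - lc
  J23 <- 3 * params$k1 * A^2 * dA_dr * S

  # dr/dt = phi(c) (1 - r (Kr+c)/Kr)
  drive <- 1 - r * (params$Kr + c) / params$Kr
  if (identical(params$receptor_variant, "modified")) {
    kt4 <- params$k_tau^4
    phi <- (kt4 + c^4) / (params$tau_max * kt4)
    dphi <- 4 * c^3 / (params$tau_max * kt4)
  } else {
    phi <- 1 / params$tau_r
    dphi <- 0
  }
  J31 <- 0
  J32 <- dphi * drive - phi * r / params$Kr
  J33 <- -phi * (params$Kr + c) / params$Kr

  matrix(c(J11, J12, J13, J21, J22, J23, J31, J32, J33),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("p", "c", "r"), c("p", "c", "r")))
}

# stability indicator: real part of the oscillatory (complex) eigenvalue
# pair if one exists, otherwise the leading real eigenvalue
leading_eigen <- function(v_plc, params, leak) {
  st <- steady_state(v_plc, params, leak)
  ev <- eigen(model_jacobian(st, v_plc, params, leak),
              only.values = TRUE)$values
  cp <- ev[abs(Im(ev)) > 1e-10]
  list(value = if (length(cp)) max(Re(cp)) else max(Re(ev)),
       complex_pair = length(cp) > 0, eigenvalues = ev, state = st)
}

#' Locate the first Hopf bifurcation threshold
#'
#' Scans `V_PLC` over `scan`, finds the first sign change of the real
#' part of the oscillatory eigenvalue pair of the Jacobian at the fixed
#' point, and refines it by bisection to `tol`. If the destabilizing
#' eigenvalue at the crossing is real (a saddle-node, not a Hopf) the
#' function errors and says so.
#'
#' @param params A [model_params] object.
#' @param leak Optional [gj_leak].
#' @param scan Length-2 `V_PLC` interval to search.
#' @param tol Bisection tolerance on `V_PLC` (default 1e-4).
#' @param n_scan Grid points of the initial scan.
#' @return The threshold `V_PLC*`, with attribute `frequency` (imaginary
#'   part of the crossing pair, rad/s).
#' @examples
#' \donttest{hopf_threshold()}  # ~0.774 at baseline
#' @export
hopf_threshold <- function(params = model_params(), leak = NULL,
                           scan = c(0.1, 1.5), tol = 1e-4,
                           n_scan = 141) {
  vs <- seq(scan[1], scan[2], length.out = n_scan)
  f <- function(v) leading_eigen(v, params, leak)$value
  fv <- vapply(vs, f, 0)
  idx <- which(fv[-length(fv)] < 0 & fv[-1] >= 0)
  if (!length(idx))
    stop("no stability crossing in scan [", scan[1], ", ", scan[2],
         "]", call. = FALSE)
  lo <- vs[idx[1]]; hi <- vs[idx[1] + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  vstar <- (lo + hi) / 2
  le <- leading_eigen(hi, params, leak)
  if (!le$complex_pair)
    stop("destabilizing eigenvalue at V_PLC = ", signif(vstar, 6),
         " is real (saddle-node event, not a Hopf)", call. = FALSE)
  cp <- le$eigenvalues[abs(Im(le$eigenvalues)) > 1e-10]
  structure(vstar, frequency = abs(Im(cp[which.max(Re(cp))])))
}

#' Steady-state branch with stability and limit-cycle summaries
#'
#' For every grid value of `V_PLC`: the fixed point, the leading
#' eigenvalue real part, and, where the fixed point is unstable, the
#' limit-cycle Ca2+ maxima/minima and period measured from a long
#' integration (the first `transient` seconds are discarded and peaks
#' are read from the remainder). Unstable limit cycles are not tracked.
#'
#' @param params A [model_params] object.
#' @param v_plc_grid Ascending grid of stimulation strengths.
#' @param duration,transient Integration length and discarded transient,
#'   s.
#' @return A `data.frame` (class `ca_bifurcation`) with columns
#'   `v_plc, p_star, c_star, r_star, max_re_eig, stable, c_max, c_min,
#'   period`.
#' @export
bifurcation_diagram <- function(params = model_params(),
                                v_plc_grid = seq(0.1, 1.5, by = 0.025),
                                duration = 3600, transient = 1200) {
  if (is.unsorted(v_plc_grid))
    stop("v_plc_grid must be ascending", call. = FALSE)
  rows <- lapply(v_plc_grid, function(v) {
    le <- leading_eigen(v, params, leak = NULL)
    st <- le$state
    out <- data.frame(v_plc = v, p_star = st[["p"]], c_star = st[["c"]],
                      r_star = st[["r"]],
                      max_re_eig = max(Re(le$eigenvalues)),
                      stable = max(Re(le$eigenvalues)) < 0,
                      c_max = NA_real_, c_min = NA_real_,
                      period = NA_real_)
    if (!out$stable) {
      cyc <- limit_cycle_summary(v, params, duration, transient)
      out$c_max <- cyc["c_max"]; out$c_min <- cyc["c_min"]
      out$period <- cyc["period"]
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ca_bifurcation", "data.frame")
  out
}

# integrate past the transient and summarize the stable cycle; slow
# cycles near onset get one retry at three times the window
limit_cycle_summary <- function(v_plc, params, duration = 3600,
                                transient = 1200, retry = TRUE) {
  cfg <- sim_config(duration = duration, sample_interval = 1,
                    rtol = 1e-8, atol = 1e-11)
  out <- simulate_cell(v_plc, params, cfg)
  keep <- out[, "time"] >= transient
  x <- out[keep, "c"]; t <- out[keep, "time"]
  pk <- local_maxima(x)
  amp <- max(x) - min(x)
  pk <- pk[x[pk] > min(x) + 0.25 * amp]
  if (length(pk) < 2 || amp < 1e-4) {
    if (retry)
      return(limit_cycle_summary(v_plc, params, 3 * duration,
                                 transient, retry = FALSE))
    return(c(c_max = NA_real_, c_min = NA_real_, period = NA_real_))
  }
  c(c_max = mean(x[pk]),
    c_min = min(x),
    period = mean(diff(t[pk])))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}
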