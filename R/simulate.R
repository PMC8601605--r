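#' Simulation configuration
#'
#' @param duration Simulated time, s (default 3600: the 1 h imaging
#'   window the model mirrors).
#' @param sample_interval Sampling interval, s (default 10, the movie
#'   frame interval).
#' @param settle Equilibration window, s (default 0): the system is
#'   integrated for `settle + duration` seconds and the first `settle`
#'   seconds are discarded before reporting, with times rebased to 0.
#'   Used by scenarios that compare equilibrated activity, where the
#'   transient caused by switching stimulation on at t = 0 is an
#'   artifact of the initial condition.
#' @param rtol,atol Relative / absolute solver tolerances.
#' @param ic_mode `"resting"` starts every cell at the unstimulated
#'   fixed point; `"custom"` uses `y0`.
#' @param y0 Custom initial state, length `3 * n_cells`
#'   (`p` then `c` then `r` blocks), when `ic_mode = "custom"`.
#' @param perturb_c Relative amplitude of a seeded, reproducible random
#'   perturbation applied to the initial Ca2+ of each cell (default 0;
#'   useful to break symmetry in homogeneous tissues).
#' @param seed Seed for the perturbation.
#' @return A `ca_sim_config` object.
#' @export
sim_config <- function(duration = 3600, sample_interval = 10,
                       rtol = 1e-6, atol = 1e-9,
                       ic_mode = c("resting", "custom"), y0 = NULL,
                       perturb_c = 0, seed = NULL, settle = 0) {
  ic_mode <- match.arg(ic_mode)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (sample_interval <= 0 || sample_interval > duration)
    stop("sample_interval must lie in (0, duration]", call. = FALSE)
  if (settle < 0) stop("settle must be non-negative", call. = FALSE)
  if (identical(ic_mode, "custom") && is.null(y0))
    stop("ic_mode = 'custom' requires y0", call. = FALSE)
  structure(list(duration = duration, sample_interval = sample_interval,
                 rtol = rtol, atol = atol, ic_mode = ic_mode, y0 = y0,
                 perturb_c = perturb_c, seed = seed, settle = settle),
            class = "ca_sim_config")
}

#' Gap-junction exchange flux
#'
#' Discrete graph-Laplacian exchange over the adjacency graph:
#' `J_i = F * sum_{j in N_i} l_ij (x_j - x_i)`. Pairwise antisymmetric,
#' so the tissue total is conserved exactly and a uniform field produces
#' zero flux.
#'
#' @param values Per-cell concentration vector (length `n_cells`).
#' @param tissue A `ca_tissue`.
#' @param F Permeability (non-negative scalar).
#' @return Per-cell flux vector.
#' @export
gj_flux <- function(values, tissue, F) {
  if (length(values) != tissue$n_cells)
    stop("values must have one entry per cell", call. = FALSE)
  if (F < 0) stop("permeability must be non-negative", call. = FALSE)
  J <- numeric(tissue$n_cells)
  e <- tissue$edges
  if (nrow(e)) {
    d <- e$l * (values[e$j] - values[e$i])
    J <- J + F * (tabulate_sum(e$i, d, tissue$n_cells) -
                    tabulate_sum(e$j, d, tissue$n_cells))
  }
  J
}

tabulate_sum <- function(idx, w, n) {
  out <- numeric(n)
  agg <- tapply(w, idx, sum)
  out[as.integer(names(agg))] <- agg
  out
}

# pack the parameter vector consumed by the C right-hand side
pack_parms <- function(tissue, v_plc, params, reactions = TRUE,
                       Fp = params$Fp, Fc = params$Fc) {
  variant <- if (identical(params$receptor_variant, "modified")) 1 else 2
  tau_r <- if (is.na(params$tau_r)) 1 else params$tau_r
  e <- tissue$edges
  c(tissue$n_cells, nrow(e), as.numeric(reactions),
    params$k5P, params$K_PLC, params$beta, params$V_SERCA,
    params$K_SERCA, params$k1, params$k2, params$Ka, params$Kr,
    params$Kp, params$tau_max, params$k_tau, Fp, Fc, params$c_tot,
    variant, tau_r,
    v_plc, e$i, e$j, e$l)
}

#' Simulate the coupled tissue
#'
#' Integrates the `3 * n_cells` coupled system (IP3, Ca2+, IP3R fraction
#' per cell, gap-junction exchange of IP3 and Ca2+ across shared
#' boundaries) with the stiff sparse solver `lsodes`; the right-hand
#' side is compiled code and the Jacobian sparsity follows the adjacency
#' graph. The tissue boundary is no-flux: cells exchange only across
#' listed edges.
#'
#' @param tissue A `ca_tissue`.
#' @param vplc_field A `ca_vplc` for the same tissue.
#' @param params A [model_params] object.
#' @param config A [sim_config].
#' @param reactions Internal switch: `FALSE` integrates pure
#'   gap-junction diffusion with all reaction terms off (used by
#'   conservation checks).
#' @return A `ca_trajectory`: sample times plus `n_times x n_cells`
#'   matrices `p`, `c`, `r`, carrying references to the inputs.
#' @examples
#' tis <- generate_tissue(30, seed = 1)
#' fld <- assign_vplc(tis, 1, c(1.4, 1.5), c(0.1, 0.5), seed = 2)
#' tr <- simulate_tissue(tis, fld, config = sim_config(duration = 300))
#' dim(tr$c)
#' @export
simulate_tissue <- function(tissue, vplc_field, params = model_params(),
                            config = sim_config(), reactions = TRUE) {
  validate_params(params)
  if (length(vplc_field$v_plc) != tissue$n_cells)
    stop("vplc_field does not match tissue size", call. = FALSE)
  if (identical(params$receptor_variant, "constant_tau") &&
      (is.na(params$tau_r) || params$tau_r <= 0))
    stop("receptor_variant = 'constant_tau' requires tau_r",
         call. = FALSE)
  n <- tissue$n_cells
  y0 <- initial_state(n, params, config)
  parms <- pack_parms(tissue, vplc_field$v_plc, params, reactions)
  settle <- if (is.null(config$settle)) 0 else config$settle
  times <- seq(0, settle + config$duration,
               by = config$sample_interval)
  if (times[length(times)] < settle + config$duration)
    times <- c(times, settle + config$duration)
  out <- run_lsodes(y0, times, parms, config)
  if (settle > 0) {
    out <- out[out[, 1] >= settle, , drop = FALSE]
    out[, 1] <- out[, 1] - settle
  }
  traj <- list(times = out[, 1],
               p = out[, 1 + seq_len(n), drop = FALSE],
               c = out[, 1 + n + seq_len(n), drop = FALSE],
               r = out[, 1 + 2 * n + seq_len(n), drop = FALSE],
               tissue = tissue, vplc = vplc_field, params = params,
               config = config)
  dimnames(traj$p) <- dimnames(traj$c) <- dimnames(traj$r) <- NULL
  class(traj) <- "ca_trajectory"
  traj
}

initial_state <- function(n, params, config) {
  if (identical(config$ic_mode, "custom")) {
    if (length(config$y0) != 3 * n)
      stop("custom y0 must have length 3 * n_cells", call. = FALSE)
    return(as.numeric(config$y0))
  }
  rest <- resting_state(params)
  y0 <- c(rep(rest["p"], n), rep(rest["c"], n), rep(rest["r"], n))
  if (config$perturb_c > 0) {
    eps <- with_seed(config$seed,
                     stats::runif(n, -config$perturb_c, config$perturb_c))
    y0[n + seq_len(n)] <- y0[n + seq_len(n)] * (1 + eps)
  }
  y0
}

run_lsodes <- function(y0, times, parms, config) {
  .C("capouch_alloc", as.integer(length(parms)), PACKAGE = "capouch")
  out <- deSolve::ode(y = y0, times = times, func = "capouch_derivs",
                      parms = parms, dllname = "capouch",
                      initfunc = "capouch_init", method = "lsodes",
                      rtol = config$rtol, atol = config$atol,
                      maxsteps = 100000)
  if (nrow(out) < length(times)) {
    t_fail <- out[nrow(out), 1]
    stop("solver failed to converge at t = ", signif(t_fail, 6), " s",
         call. = FALSE)
  }
  out
}

#' Simulate an isolated single cell
#'
#' Integrates one uncoupled cell at a fixed `v_plc` with the same solver
#' and tolerances as the tissue simulator.
#'
#' @param v_plc Maximal PLC rate, uM/s.
#' @param params A [model_params] object.
#' @param config A [sim_config].
#' @param y0 Optional initial `c(p, c, r)`; defaults to the resting
#'   state.
#' @return A matrix with columns `time, p, c, r`.
#' @export
simulate_cell <- function(v_plc, params = model_params(),
                          config = sim_config(), y0 = NULL) {
  validate_params(params)
  if (is.null(y0)) y0 <- resting_state(params)
  parms <- c(1, 0, 1,
             params$k5P, params$K_PLC, params$beta, params$V_SERCA,
             params$K_SERCA, params$k1, params$k2, params$Ka, params$Kr,
             params$Kp, params$tau_max, params$k_tau, 0, 0,
             params$c_tot,
             if (identical(params$receptor_variant, "modified")) 1 else 2,
             if (is.na(params$tau_r)) 1 else params$tau_r,
             v_plc)
  times <- seq(0, config$duration, by = config$sample_interval)
  out <- run_lsodes(as.numeric(y0), times, parms, config)
  colnames(out) <- c("time", "p", "c", "r")
  out
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat("Ca2+ trajectory:", ncol(x$c), "cells x", nrow(x$c),
      "samples (", x$times[length(x$times)], "s, every",
      x$config$sample_interval, "s)\n")
  cat("  c range [", signif(min(x$c), 4), ",", signif(max(x$c), 4),
      "] uM\n")
  invisible(x)
}

#' Check the state-box invariants of a trajectory
#'
#' Verifies `p >= 0`, `c` in `[0, c_tot]`, `r` in `[0, 1]` at every
#' sample, up to a numerical tolerance.
#'
#' @param traj A `ca_trajectory`.
#' @param tol Permitted numerical overshoot.
#' @return `TRUE` (invisibly) or an error.
#' @export
check_state_box <- function(traj, tol = 1e-6) {
  ctot <- traj$params$c_tot
  if (min(traj$p) < -tol) stop("negative IP3 encountered", call. = FALSE)
  if (min(traj$c) < -tol || max(traj$c) > ctot + tol)
    stop("Ca2+ left [0, c_tot]", call. = FALSE)
  if (min(traj$r) < -tol || max(traj$r) > 1 + tol)
    stop("receptor fraction left [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Write a trajectory to per-variable CSV files
#'
#' Writes `t.csv` (sample times, s), and `p.csv`, `c.csv`, `r.csv`
#' (samples x cells, uM or dimensionless), into `dir`.
#'
#' @param traj A `ca_trajectory`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_trajectory_csv <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(time_s = traj$times),
                   file.path(dir, "t.csv"), row.names = FALSE)
  for (v in c("p", "c", "r")) {
    m <- traj[[v]]
    colnames(m) <- paste0("cell_", seq_len(ncol(m)) - 1L)
    utils::write.csv(m, file.path(dir, paste0(v, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
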