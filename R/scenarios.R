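#' Scenario runners
#'
#' Canned simulation setups reproducing the published in-silico
#' experiments: the four pattern classes, the gap-junction block
#' comparison, the two developmental scaling laws, and single-parameter
#' sensitivity sweeps.
#'
#' @name scenarios
NULL

pattern_standby_ranges <- list(
  spikes     = c(0.10, 0.50),
  ICT        = c(0.25, 0.60),
  ICW        = c(0.40, 0.80),
  fluttering = c(1.40, 1.50)
)

#' Simulate one of the four pattern-class scenarios
#'
#' Builds a tissue, assigns initiators (`V_PLC` in `[1.4, 1.5]`, 2% of
#' cells, at least one) and standby cells with the class-specific range
#' — spikes `[0.1, 0.5]`, ICT `[0.25, 0.60]`, ICW `[0.4, 0.8]`,
#' fluttering `[1.4, 1.5]` (for fluttering every cell sits above the
#' Hopf threshold, so initiators and standby cells coincide) — then
#' simulates 1 h at baseline parameters.
#'
#' @param class_name One of `"spikes"`, `"ICT"`, `"ICW"`,
#'   `"fluttering"`.
#' @param n_cells Tissue size (default 200).
#' @param seed Integer seed controlling geometry and V_PLC assignment.
#' @param params,config Overrides for parameters and simulation
#'   settings.
#' @param tissue Optional pre-built tissue (skips generation).
#' @return A `ca_trajectory`.
#' @export
pattern_scenario <- function(class_name = c("spikes", "ICT", "ICW",
                                            "fluttering"),
                             n_cells = 200, seed = NULL,
                             params = model_params(),
                             config = sim_config(), tissue = NULL) {
  class_name <- match.arg(class_name)
  if (is.null(tissue))
    tissue <- generate_tissue(n_cells, seed = seed)
  fld <- assign_vplc(tissue, default_initiator_count(tissue$n_cells),
                     c(1.4, 1.5), pattern_standby_ranges[[class_name]],
                     seed = if (is.null(seed)) NULL else seed + 1L)
  simulate_tissue(tissue, fld, params, config)
}

#' Gap-junction block scenario
#'
#' Initiator cells are pinned exactly at the single-cell Hopf threshold
#' (`V_PLC = 0.774`) and standby cells draw from `[0.1, 0.5]`. With gap
#' junctions enabled (baseline permeabilities) the sub-threshold
#' neighbourhood drains the initiators and no activity arises; with
#' `blocked = TRUE` (`Fp = Fc = 0`) the isolated initiators spike.
#' Because this comparison concerns the *equilibrated* tissue, the
#' default config discards a 1200 s settle window before the measured
#' hour, excluding the one-off transient caused by switching
#' stimulation on at t = 0 (see [sim_config]).
#'
#' @param n_cells Tissue size.
#' @param blocked Set permeabilities to zero?
#' @param seed Integer seed.
#' @param n_initiators Number of initiator cells (default 2% of the
#'   tissue).
#' @param params,config Overrides.
#' @param tissue Optional pre-built tissue.
#' @return A `ca_trajectory`.
#' @export
gj_block_scenario <- function(n_cells = 200, blocked = FALSE,
                              seed = NULL,
                              n_initiators =
                                default_initiator_count(n_cells),
                              params = model_params(),
                              config = sim_config(settle = 1200),
                              tissue = NULL) {
  if (is.null(tissue))
    tissue <- generate_tissue(n_cells, seed = seed)
  fld <- assign_vplc(tissue, n_initiators, c(0.774, 0.774),
                     c(0.1, 0.5),
                     seed = if (is.null(seed)) NULL else seed + 1L)
  if (blocked) { params$Fp <- 0; params$Fc <- 0 }
  simulate_tissue(tissue, fld, params, config)
}

#' Initiator-count rule of the first developmental scaling law
#'
#' `N_init = round(8000 * N_cells^-0.8)`, floored at 1 and clamped at
#' `N_cells` (with a warning) — fewer initiators as the tissue grows,
#' at constant gap-junction permeability.
#'
#' @param n_cells Tissue size.
#' @return Integer initiator count.
#' @export
initiator_scaling_count <- function(n_cells) {
  n <- max(1, round(8000 * n_cells^-0.8))
  if (n > n_cells) {
    warning("initiator count ", n, " exceeds tissue size ", n_cells,
            "; clamped", call. = FALSE)
    n <- n_cells
  }
  as.integer(n)
}

#' Permeability rule of the second developmental scaling law
#'
#' `Fp = 800 * N_cells^-1.8` with `Fc = 0.1 * Fp` — weaker gap-junction
#' coupling as the tissue grows, at a constant initiator count.
#'
#' @param n_cells Tissue size.
#' @return Named vector `c(Fp, Fc)`.
#' @export
permeability_scaling <- function(n_cells) {
  fp <- 800 * n_cells^-1.8
  c(Fp = fp, Fc = 0.1 * fp)
}

#' Developmental scaling scenarios
#'
#' Simulates a series of tissue sizes under one of the two scaling
#' hypotheses for the developmental decline of integrated Ca2+
#' activity. Mode `"initiator_scaling"` varies the initiator count by
#' [initiator_scaling_count] at baseline permeability; mode
#' `"permeability_scaling"` varies the permeabilities by
#' [permeability_scaling] with the initiator count held at
#' `n_init_fixed` (clamped to the tissue size where needed). In both
#' modes standby cells sit at `V_PLC = 0.40` and initiators draw from
#' `[1.3, 1.5]`. The default config discards a 1200 s settle window:
#' the scaling comparison concerns equilibrated, unstimulated tissue.
#'
#' @param mode `"initiator_scaling"` or `"permeability_scaling"`.
#' @param n_cells_list Vector of tissue sizes.
#' @param seed Integer seed; each size draws independently from a
#'   stream derived from it.
#' @param n_init_fixed Constant initiator count of the permeability
#'   mode (default 65).
#' @param params,config Overrides.
#' @return A list of `ca_trajectory`, one per size, with the applied
#'   initiator count and permeabilities in each trajectory's
#'   `scenario` attribute.
#' @export
scaling_scenario <- function(mode = c("initiator_scaling",
                                      "permeability_scaling"),
                             n_cells_list = c(100, 200, 400, 800),
                             seed = NULL, n_init_fixed = 65,
                             params = model_params(),
                             config = sim_config(settle = 1200)) {
  mode <- match.arg(mode)
  if (any(n_cells_list < 1)) stop("all n_cells must be >= 1",
                                  call. = FALSE)
  lapply(seq_along(n_cells_list), function(k) {
    n <- n_cells_list[k]
    sk <- if (is.null(seed)) NULL else seed + 101L * k
    pars <- params
    if (identical(mode, "initiator_scaling")) {
      n_init <- initiator_scaling_count(n)
    } else {
      n_init <- n_init_fixed
      if (n_init > n) {
        warning("initiator count ", n_init, " exceeds tissue size ", n,
                "; clamped", call. = FALSE)
        n_init <- n
      }
      fpfc <- permeability_scaling(n)
      pars$Fp <- fpfc[["Fp"]]; pars$Fc <- fpfc[["Fc"]]
    }
    tissue <- generate_tissue(n, seed = sk)
    fld <- assign_vplc(tissue, n_init, c(1.3, 1.5), c(0.40, 0.40),
                       seed = if (is.null(sk)) NULL else sk + 1L)
    tr <- simulate_tissue(tissue, fld, pars, config)
    attr(tr, "scenario") <- list(mode = mode, n_cells = n,
                                 n_initiators = n_init,
                                 Fp = pars$Fp, Fc = pars$Fc)
    tr
  })
}

#' Single-parameter sensitivity sweep
#'
#' Re-simulates one frozen intercellular-wave setup (standby `V_PLC`
#' uniform in `[0.7, 1.0]`, initiators in `[1.4, 1.5]`) while scaling a
#' single model parameter across `percentages` of its baseline value
#' (`"Fp_Fc_joint"` co-scales both permeabilities). The V_PLC field and
#' the geometry are identical across sweep points so differences are
#' attributable to the parameter alone. The default config discards a
#' 1200 s settle window so that metrics describe the established
#' oscillatory state, not the stimulation-onset transient.
#'
#' @param parameter_name A numeric field of [model_params], or
#'   `"Fp_Fc_joint"`.
#' @param percentages Positive percentages of the baseline value
#'   (100 = baseline).
#' @param n_cells Tissue size of the frozen scenario.
#' @param seed Integer seed fixing the frozen field.
#' @param params,config Baseline parameters and simulation settings.
#' @return A `data.frame` with one row per sweep point: the applied
#'   value, mean frequency, mean WHM, propagation extent (largest event
#'   as a tissue fraction) and class label; trajectories in the
#'   `trajectories` attribute.
#' @export
sensitivity_sweep <- function(parameter_name, percentages = c(50, 100,
                                                              150),
                              n_cells = 200, seed = NULL,
                              params = model_params(),
                              config = sim_config(settle = 1200)) {
  numeric_pars <- c("k5P", "K_PLC", "beta", "V_SERCA", "K_SERCA", "k1",
                    "k2", "Ka", "Kr", "Kp", "tau_max", "k_tau", "Fp",
                    "Fc", "c_tot")
  if (!parameter_name %in% c(numeric_pars, "Fp_Fc_joint"))
    stop("unknown parameter: ", parameter_name, call. = FALSE)
  if (any(percentages <= 0)) stop("percentages must be positive",
                                  call. = FALSE)
  tissue <- generate_tissue(n_cells, seed = seed)
  fld <- assign_vplc(tissue, default_initiator_count(n_cells),
                     c(1.4, 1.5), c(0.7, 1.0),
                     seed = if (is.null(seed)) NULL else seed + 1L)
  trajs <- list()
  rows <- lapply(seq_along(percentages), function(k) {
    pct <- percentages[k]
    pars <- params
    if (identical(parameter_name, "Fp_Fc_joint")) {
      pars$Fp <- params$Fp * pct / 100
      pars$Fc <- params$Fc * pct / 100
      val <- pars$Fp
    } else {
      pars[[parameter_name]] <- params[[parameter_name]] * pct / 100
      val <- pars[[parameter_name]]
    }
    tr <- simulate_tissue(tissue, fld, pars, config)
    trajs[[k]] <<- tr
    met <- sweep_metrics(tr)
    data.frame(parameter = parameter_name, percent = pct, value = val,
               frequency = met$frequency, whm_s = met$whm_s,
               propagation = met$propagation, class = met$class)
  })
  out <- do.call(rbind, rows)
  attr(out, "trajectories") <- trajs
  out
}

# mean over active cells of per-cell frequency/WHM + largest event extent
sweep_metrics <- function(traj) {
  n <- ncol(traj$c)
  per <- lapply(seq_len(n), function(i)
    oscillation_metrics(traj$c[, i], traj$times))
  fr <- vapply(per, `[[`, 0, "frequency")
  wh <- vapply(per, `[[`, 0, "whm_s")
  pat <- classify_pattern(traj)
  list(frequency = if (any(!is.na(fr))) mean(fr, na.rm = TRUE)
       else NA_real_,
       whm_s = if (any(!is.na(wh))) mean(wh, na.rm = TRUE)
       else NA_real_,
       propagation = if (nrow(pat$events))
         max(pat$events$cells) / n else 0,
       class = pat$class)
}
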