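#' Model parameters for the single-cell IP3/Ca2+/IP3R kinetics
#'
#' Constructs the baseline parameter set of the intracellular model.
#' The defaults are the published baseline values; any subset can be
#' overridden by name. The maximal PLC rate `V_PLC` is deliberately *not*
#' a member: it is the spatially heterogeneous control parameter, carried
#' per cell by a V_PLC field (see [assign_vplc]).
#'
#' @param k5P IP3 dephosphorylation rate constant, 1/s.
#' @param K_PLC Half-activation of PLC by Ca2+, uM.
#' @param beta Ratio of effective ER to cytosolic volume, dimensionless,
#'   in (0, 1).
#' @param V_SERCA Maximum SERCA pump rate, uM/s.
#' @param K_SERCA SERCA half-activation constant, uM.
#' @param k1 Maximum IP3R-mediated Ca2+ release rate, 1/s.
#' @param k2 ER leak rate, 1/s.
#' @param Ka Ca2+ binding to the activating IP3R site, uM.
#' @param Kr Ca2+ binding to the inactivating IP3R site, uM.
#' @param Kp IP3 binding to the IP3R, uM.
#' @param tau_max Maximum time constant of IP3R inactivation, s. (Some
#'   published tables print this with units of 1/s; a time *constant* in
#'   1/s is dimensionally inconsistent with the receptor equation, so it
#'   is interpreted in seconds here.)
#' @param k_tau Ca2+ scale of the Ca2+-dependent IP3R inactivation rate, uM.
#' @param Fp Gap-junction permeability for IP3, per unit shared-boundary
#'   length (lengths are expressed in mean cell diameters, see
#'   [generate_tissue]).
#' @param Fc Gap-junction permeability for Ca2+, same units as `Fp`.
#' @param c_tot Total Ca2+ (cytosolic + volume-scaled ER), uM.
#' @param receptor_variant Which IP3R inactivation equation to use:
#'   `"modified"` (default) scales the inactivation rate by
#'   `(k_tau^4 + c^4)/k_tau^4`; `"constant_tau"` uses a fixed time
#'   constant `tau_r`.
#' @param tau_r Characteristic IP3R inactivation time, s. Only consulted
#'   when `receptor_variant = "constant_tau"`.
#'
#' @return An object of class `ca_params`: a validated named list.
#' @examples
#' p <- model_params()
#' p$k1
#' model_params(k_tau = 0.75)  # halved Ca2+ scale of receptor recovery
#' @export
model_params <- function(k5P = 0.66, K_PLC = 0.2, beta = 0.185,
                         V_SERCA = 0.9, K_SERCA = 0.1, k1 = 1.11,
                         k2 = 0.0203, Ka = 0.08, Kr = 0.4, Kp = 0.13,
                         tau_max = 800, k_tau = 1.5, Fp = 0.005,
                         Fc = 0.0005, c_tot = 2.0,
                         receptor_variant = c("modified", "constant_tau"),
                         tau_r = NA_real_) {
  receptor_variant <- match.arg(receptor_variant)
  p <- list(k5P = k5P, K_PLC = K_PLC, beta = beta, V_SERCA = V_SERCA,
            K_SERCA = K_SERCA, k1 = k1, k2 = k2, Ka = Ka, Kr = Kr,
            Kp = Kp, tau_max = tau_max, k_tau = k_tau, Fp = Fp, Fc = Fc,
            c_tot = c_tot, receptor_variant = receptor_variant,
            tau_r = tau_r)
  class(p) <- "ca_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  num <- c("k5P", "K_PLC", "beta", "V_SERCA", "K_SERCA", "k1", "k2",
           "Ka", "Kr", "Kp", "tau_max", "k_tau", "c_tot")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  for (nm in c("Fp", "Fc")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", nm, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (p$beta >= 1)
    stop("beta must lie in (0, 1)", call. = FALSE)
  if (!p$receptor_variant %in% c("modified", "constant_tau"))
    stop("unknown receptor_variant: ", p$receptor_variant, call. = FALSE)
  if (identical(p$receptor_variant, "constant_tau") &&
      (!is.numeric(p$tau_r) || is.na(p$tau_r) || p$tau_r <= 0))
    stop("receptor_variant = 'constant_tau' requires a positive tau_r",
         call. = FALSE)
  invisible(p)
}

#' @export
print.ca_params <- function(x, ...) {
  cat("Single-cell Ca2+ model parameters (uM, s)\n")
  num <- vapply(x[setdiff(names(x), "receptor_variant")], as.numeric, 0)
  print(num)
  cat("receptor_variant:", x$receptor_variant, "\n")
  invisible(x)
}

#' Read and write parameter sets
#'
#' Parameters serialize to a flat key-value map (JSON or YAML, chosen by
#' the file extension) whose keys are the parameter symbols themselves,
#' so configuration files read like the published parameter table.
#'
#' @param params A `ca_params` object.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_params` returns a `ca_params` object; `write_params`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  x <- unclass(params)
  if (is.na(x$tau_r)) x$tau_r <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else stop("unsupported parameter file extension: ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else stop("unsupported parameter file extension: ", path, call. = FALSE)
  known <- names(formals(model_params))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown parameter keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(model_params, x)
}

# run expr with a transient, restorable RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
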