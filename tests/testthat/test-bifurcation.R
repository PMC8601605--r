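test_that("the unstimulated steady state matches the scalar balance", {
  p <- baseline
  st <- steady_state(0)
  expect_equal(st[["p"]], 0, tolerance = 1e-12)
  # independent one-dimensional oracle: leak/SERCA balance
  g <- function(c) p$k2 * ((p$c_tot - c) / p$beta - c) -
    p$V_SERCA * c^2 / (c^2 + p$K_SERCA^2)
  c_oracle <- uniroot(g, c(1e-9, p$c_tot - 1e-9), tol = 1e-14)$root
  expect_equal(st[["c"]], c_oracle, tolerance = 1e-10)
  expect_equal(st[["r"]], p$Kr / (p$Kr + c_oracle), tolerance = 1e-10)
  expect_lt(attr(st, "residual"), 1e-10)
})

test_that("fixed points are independent of the receptor time scales", {
  a <- steady_state(0.9, model_params())
  b <- steady_state(0.9, model_params(tau_max = 100, k_tau = 0.4))
  d <- steady_state(0.9, model_params(receptor_variant = "constant_tau",
                                      tau_r = 5))
  expect_equal(a, b, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(a, d, tolerance = 1e-10, ignore_attr = TRUE)
  # residual of the full RHS vanishes at the returned point
  expect_lt(max(abs(capouch:::cell_rhs(a[["p"]], a[["c"]], a[["r"]],
                                       0.9, baseline))), 1e-10)
})

test_that("the analytic Jacobian agrees with finite differences", {
  set.seed(20)
  for (k in 1:20) {
    st <- c(runif(1, 0.05, 1.5), runif(1, 0.05, 1.5),
            runif(1, 0.1, 0.9))
    v <- runif(1, 0, 1.5)
    leak <- if (k %% 2 == 0) gj_leak(Fp = 0.005, Fc = 0.0005) else NULL
    J <- model_jacobian(st, v, baseline, leak)
    Jn <- num_jacobian(st, v, baseline, leak)
    expect_equal(J, Jn, tolerance = 1e-6, ignore_attr = TRUE)
  }
  # the IP3 row is linear: exact diagonal entry
  leak <- gj_leak(Fp = 0.01, L = 6)
  J <- model_jacobian(c(0.3, 0.2, 0.5), 0.8, baseline, leak)
  expect_equal(J[1, 1], -baseline$k5P - 0.01 * 6)
  J0 <- model_jacobian(c(0.3, 0.2, 0.5), 0.8, baseline)
  expect_equal(J0[1, 1], -baseline$k5P)
})

test_that("the Hopf threshold sits near 0.774 and is found by bisection", {
  thr <- hopf_threshold(tol = 1e-5)
  expect_equal(as.numeric(thr), 0.774, tolerance = 0.005)
  expect_gt(attr(thr, "frequency"), 0)
  expect_error(hopf_threshold(scan = c(0.1, 0.5)), "no stability")
  # the leak-free threshold is the isolated-cell threshold
  thr0 <- hopf_threshold(leak = gj_leak(Fp = 0, Fc = 0), tol = 1e-5)
  expect_equal(as.numeric(thr0), as.numeric(thr), tolerance = 1e-4)
})

test_that("the threshold responds to tau_max but not k_tau at rest", {
  # the fixed point sits at c* ~ 0.07 where the Ca2+-dependent receptor
  # factor is ~1 + 6e-6, so halving k_tau cannot move the local
  # linearization; halving tau_max doubles the receptor rate and does
  thr <- as.numeric(hopf_threshold(tol = 1e-6))
  thr_kt <- as.numeric(hopf_threshold(model_params(k_tau = 0.75),
                                      tol = 1e-6))
  thr_tm <- as.numeric(hopf_threshold(model_params(tau_max = 400),
                                      tol = 1e-6))
  expect_lt(abs(thr_kt - thr), 1e-5)
  expect_gt(abs(thr_tm - thr), 1e-5)
})

test_that("eigenvalues vary continuously along the branch", {
  grid <- seq(0.3, 0.75, by = 0.025)
  vals <- vapply(grid, function(v)
    capouch:::leading_eigen(v, baseline, NULL)$value, 0)
  expect_true(all(abs(diff(vals)) < 0.05))
  expect_true(all(vals < 0))
})

test_that("below threshold the cell settles back onto the fixed point", {
  st <- steady_state(0.5)
  y0 <- st * c(1, 1.01, 1)
  out <- simulate_cell(0.5, baseline,
                       sim_config(duration = 3600, rtol = 1e-10,
                                  atol = 1e-13), y0 = y0)
  expect_lt(max(abs(out[nrow(out), c("p", "c", "r")] - st)), 1e-6)
})

test_that("the branch records stability and slowing periods", {
  low <- bifurcation_diagram(v_plc_grid = c(0.3, 0.5, 0.7))
  expect_true(all(low$stable))
  expect_true(all(is.na(low$period)))
  hi <- bifurcation_diagram(v_plc_grid = c(0.8, 0.9, 1.0, 1.2))
  expect_true(all(!hi$stable))
  expect_true(all(hi$period > 0))
  # period decreases with stimulation strength (relaxation-oscillation
  # regime; matches the published period-vs-V_PLC inset)
  expect_true(all(diff(hi$period) < 0))
  # the cycle is full-amplitude right above onset (the published
  # diagram shows a subcritical structure with unstable cycles)
  expect_gt(hi$c_max[1] - hi$c_min[1], 1)
  expect_error(bifurcation_diagram(v_plc_grid = c(1, 0.5)), "ascending")
})

test_that("single-cell and tissue frequencies agree when uncoupled", {
  bd <- bifurcation_diagram(v_plc_grid = 1.0)
  tis <- generate_tissue(4, seed = 21)
  fld <- assign_vplc(tis, 0, c(0, 0), c(1.0, 1.0), seed = 22)
  tr <- simulate_tissue(tis, fld, uncoupled(),
                        sim_config(duration = 3600,
                                   sample_interval = 2))
  m <- oscillation_metrics(tr$c[tr$times >= 1200, 1],
                           tr$times[tr$times >= 1200])
  expect_equal(1 / m$frequency, bd$period, tolerance = 0.02)
})
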