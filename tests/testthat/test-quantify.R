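test_that("baseline normalization is robust and scale-invariant", {
  expect_equal(normalize_trace(rep(2.5, 100)), rep(1, 100))
  # one sample at three times baseline maps to ~3
  x <- rep(0.1, 200); x[100] <- 0.3
  expect_equal(max(normalize_trace(x)), 3, tolerance = 1e-12)
  y <- runif(50, 0.5, 2)
  expect_equal(normalize_trace(7 * y), normalize_trace(y))
  expect_error(normalize_trace(numeric(0)), "empty")
  expect_error(normalize_trace(rep(0, 50)), "baseline")
  expect_error(normalize_trace(c(-1, 1)), "non-negative")
})

test_that("spike detection finds constructed events", {
  t <- seq(0, 900, by = 1)
  expect_equal(nrow(detect_spikes(rep(1, length(t)), t)), 0)
  # two Gaussian bumps 300 s apart
  y <- 1 + 2 * exp(-(t - 250)^2 / (2 * 15^2)) +
    2 * exp(-(t - 550)^2 / (2 * 15^2))
  ev <- detect_spikes(y, t, threshold = 1.5)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$t_peak, c(250, 550), tolerance = 1)
  # detection is invariant to uniform scaling of the raw trace
  ev2 <- detect_spikes(100 * y, t, threshold = 1.5)
  expect_equal(ev2, ev)
  expect_error(detect_spikes(y, t, threshold = 0.9), "exceed 1")
})

test_that("triangular pulse width at half maximum is exact", {
  t <- seq(0, 200, by = 1)
  y <- rep(1, length(t))
  # isosceles triangle: base 20 s, apex 2.0, centred at t = 100
  ramp <- pmax(0, 1 - abs(t - 100) / 10)
  y <- y + ramp
  ev <- detect_spikes(y, t, threshold = 1.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$whm_s, 10, tolerance = 1e-9)
  expect_equal(ev$amplitude, 2, tolerance = 1e-9)
})

test_that("nearby excursions merge by separation", {
  t <- seq(0, 600, by = 1)
  bump <- function(t0) 2 * exp(-(t - t0)^2 / (2 * 3^2))
  y <- 1 + bump(300) + bump(315)
  expect_equal(nrow(detect_spikes(y, t, min_separation = 20)), 1)
  expect_equal(nrow(detect_spikes(y, t, min_separation = 1)), 2)
})

test_that("oscillation metrics recover a constructed period", {
  t <- seq(0, 1200, by = 2)
  y <- 1 + pmax(0, sin(2 * pi * t / 120))^4
  m <- oscillation_metrics(y, t)
  expect_equal(1 / m$frequency, 120, tolerance = 2)
  # fewer than two events: frequency absent, not zero
  y1 <- 1 + 2 * exp(-(t - 600)^2 / (2 * 10^2))
  m1 <- oscillation_metrics(y1, t)
  expect_true(is.na(m1$frequency))
  expect_equal(m1$n_events, 1L)
})

test_that("single-cell frequency rises with stimulation and recovery rate", {
  cfg <- sim_config(duration = 3600, sample_interval = 2)
  f_of <- function(v, params = baseline) {
    out <- simulate_cell(v, params, cfg)
    keep <- out[, "time"] >= 1200
    oscillation_metrics(out[keep, "c"], out[keep, "time"])$frequency
  }
  expect_gt(f_of(1.3), f_of(1.0))
  expect_gt(f_of(1.0, model_params(k_tau = 0.75)), f_of(1.0))
})

test_that("kymographs order intersected cells along the line", {
  tis <- generate_tissue(60, seed = 30)
  fld <- assign_vplc(tis, 1, c(1.4, 1.5), c(0.1, 0.5), seed = 31)
  tr <- simulate_tissue(tis, fld, config = sim_config(duration = 600))
  xr <- range(tis$centroids[, 1])
  ky <- make_kymograph(tr, rbind(c(xr[1], 0), c(xr[2], 0)))
  expect_true(all(diff(ky$positions) >= 0))
  expect_equal(dim(ky$intensity),
               c(length(ky$cells), length(tr$times)))
  # roughly one cell per diameter across the long axis
  expect_gt(length(ky$cells), floor(diff(xr) / 2))
  expect_error(make_kymograph(tr, rbind(c(100, 100), c(101, 101))),
               "intersect")
})

test_that("a quiescent trajectory is classed none with zero activity", {
  tis <- generate_tissue(30, seed = 32)
  fld <- assign_vplc(tis, 0, c(0, 0), c(0.1, 0.4), seed = 33)
  tr <- simulate_tissue(tis, fld, config = sim_config(duration = 1800))
  pat <- classify_pattern(tr)
  expect_equal(pat$class, "none")
  expect_equal(pat$n_events, 0)
  rep <- activity_report(tr)
  expect_equal(rep$n_spikes, 0)
  expect_equal(rep$class, "none")
  # a truly resting tissue (zero stimulation) has zero integrated
  # activity; the sub-threshold field above has a finite but tiny value
  # from its settling drift
  fld0 <- assign_vplc(tis, 0, c(0, 0), c(0, 0), seed = 33)
  tr0 <- simulate_tissue(tis, fld0,
                         config = sim_config(duration = 1800))
  expect_equal(integrated_activity(tr0), 0, tolerance = 1e-6)
  expect_lt(integrated_activity(tr),
            0.01 * integrated_activity(pattern_scenario("ICW", 30,
                                                        seed = 33)))
})

test_that("an everywhere-active constructed trajectory is fluttering", {
  tis <- generate_tissue(30, seed = 34)
  nt <- 121
  cmat <- matrix(0.05, nt, 30)
  cmat[30:90, ] <- 1.2   # the whole tissue elevated for half the run
  traj <- structure(list(times = seq(0, 1200, by = 10), c = cmat,
                         p = cmat * 0, r = cmat * 0 + 0.5,
                         tissue = tis, params = baseline,
                         config = sim_config(duration = 1200)),
                    class = "ca_trajectory")
  expect_equal(classify_pattern(traj)$class, "fluttering")
})

test_that("classification is deterministic and permutation-equivariant", {
  tr <- pattern_scenario("ICW", 100, seed = 35)
  a <- classify_pattern(tr)
  b <- classify_pattern(tr)
  expect_identical(a$class, b$class)
  expect_identical(a$n_events, b$n_events)
  # relabeling the cells leaves the class unchanged
  set.seed(36)
  perm <- sample(100)
  tis2 <- permute_tissue(tr$tissue, perm)
  tr2 <- tr
  tr2$tissue <- tis2
  tr2$c <- tr$c[, order(perm)]
  tr2$p <- tr$p[, order(perm)]
  tr2$r <- tr$r[, order(perm)]
  p2 <- classify_pattern(tr2)
  expect_identical(p2$class, a$class)
  expect_identical(p2$n_events, a$n_events)
})

test_that("integrated activity is additive over repeated episodes", {
  tis <- generate_tissue(10, seed = 37)
  mk <- function(reps) {
    block <- c(rep(0.05, 50), rep(0.5, 10), rep(0.05, 60))
    cm <- matrix(rep(rep(block, reps), 10), ncol = 10)
    structure(list(times = seq(0, by = 10,
                               length.out = nrow(cm)),
                   c = cm, p = cm * 0, r = cm * 0 + 0.5, tissue = tis,
                   params = baseline,
                   config = sim_config(duration = 10 * nrow(cm))),
              class = "ca_trajectory")
  }
  one <- integrated_activity(mk(1))
  two <- integrated_activity(mk(2))
  expect_gt(one, 0)
  expect_equal(two / one, 2, tolerance = 0.1)
})
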