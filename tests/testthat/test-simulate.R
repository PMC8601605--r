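test_that("gap-junction flux is a weighted graph Laplacian", {
  two <- toy_tissue(2, data.frame(i = 1L, j = 2L, l = 1))
  expect_equal(gj_flux(c(1, 0), two, 0.005), c(-0.005, 0.005))
  # uniform concentration: no flux
  tis <- generate_tissue(40, seed = 1)
  expect_equal(gj_flux(rep(0.7, 40), tis, 0.005), rep(0, 40))
  # antisymmetry: tissue total conserved on random fields
  set.seed(1)
  for (k in 1:5) {
    J <- gj_flux(runif(40, 0, 2), tis, 0.005)
    expect_lt(abs(sum(J)), 1e-12)
  }
  expect_error(gj_flux(runif(40), tis, -1), "non-negative")
  expect_error(gj_flux(runif(10), tis, 1), "per cell")
})

test_that("an unstimulated tissue rests at the fixed point", {
  tis <- generate_tissue(25, seed = 2)
  fld <- assign_vplc(tis, 0, c(0, 0), c(0, 0), seed = 3)
  tr <- simulate_tissue(tis, fld, config = sim_config(duration = 1800))
  rest <- resting_state()
  expect_lt(max(abs(tr$c - rest["c"])), 1e-6)
  expect_lt(max(abs(tr$p - rest["p"])), 1e-6)
  expect_lt(max(abs(tr$r - rest["r"])), 1e-6)
})

test_that("uncoupled tissue cells match isolated integrations", {
  tis <- generate_tissue(12, seed = 4)
  fld <- assign_vplc(tis, 1, c(1.4, 1.5), c(0.1, 1.0), seed = 5)
  cfg <- sim_config(duration = 1200, rtol = 1e-11, atol = 1e-14)
  tr <- simulate_tissue(tis, fld, uncoupled(), cfg)
  for (i in seq_len(12)) {
    sc <- simulate_cell(fld$v_plc[i], baseline, cfg)
    for (v in c("p", "c", "r")) {
      rel <- max(abs(tr[[v]][, i] - sc[, v])) /
        max(1, max(abs(sc[, v])))
      expect_lt(rel, 1e-6)
    }
  }
})

test_that("pure gap-junction diffusion conserves tissue totals", {
  tis <- generate_tissue(30, seed = 6)
  fld <- assign_vplc(tis, 2, c(1.4, 1.5), c(0.1, 0.5), seed = 7)
  set.seed(8)
  y0 <- c(runif(30, 0, 1), runif(30, 0, 2), runif(30, 0, 1))
  cfg <- sim_config(duration = 900, ic_mode = "custom", y0 = y0)
  tr <- simulate_tissue(tis, fld, config = cfg, reactions = FALSE)
  expect_lt(max(abs(rowSums(tr$p) - sum(y0[1:30]))), 1e-8)
  expect_lt(max(abs(rowSums(tr$c) - sum(y0[31:60]))), 1e-8)
  # r has no exchange term and no reactions: frozen
  expect_equal(tr$r[nrow(tr$r), ], y0[61:90], tolerance = 1e-12)
  # diffusion relaxes toward the uniform state
  expect_lt(diff(range(tr$p[nrow(tr$p), ])), diff(range(y0[1:30])))
})

test_that("relabeling cells permutes the trajectory identically", {
  tis <- generate_tissue(20, seed = 9)
  fld <- assign_vplc(tis, 2, c(1.4, 1.5), c(0.4, 0.8), seed = 10)
  set.seed(11)
  perm <- sample(20)
  tis2 <- permute_tissue(tis, perm)
  fld2 <- fld
  fld2$v_plc[perm] <- fld$v_plc
  fld2$is_initiator[perm] <- fld$is_initiator
  cfg <- sim_config(duration = 1200, rtol = 1e-9, atol = 1e-12)
  a <- simulate_tissue(tis, fld, config = cfg)
  b <- simulate_tissue(tis2, fld2, config = cfg)
  for (v in c("p", "c", "r"))
    expect_equal(b[[v]][, perm], a[[v]], tolerance = 1e-6)
})

test_that("halving solver tolerances barely moves the solution", {
  tis <- generate_tissue(30, seed = 12)
  fld <- assign_vplc(tis, 2, c(1.4, 1.5), c(0.4, 0.8), seed = 13)
  a <- simulate_tissue(tis, fld,
                       config = sim_config(duration = 900,
                                           rtol = 1e-8, atol = 1e-11))
  b <- simulate_tissue(tis, fld,
                       config = sim_config(duration = 900,
                                           rtol = 5e-9, atol = 5e-12))
  rel <- max(abs(a$c - b$c)) / max(abs(b$c))
  expect_lt(rel, 1e-4)
})

test_that("sampled states satisfy the physical box invariants", {
  tr <- pattern_scenario("ICW", 80, seed = 14,
                         config = sim_config(duration = 1800))
  expect_true(check_state_box(tr))
  # conservation identity holds at every sample by construction
  s <- er_calcium(tr$c, tr$params)
  expect_equal(tr$c + tr$params$beta * s,
               matrix(tr$params$c_tot, nrow(tr$c), ncol(tr$c)),
               tolerance = 1e-14)
})

test_that("a settle window is discarded and times rebased", {
  tis <- generate_tissue(15, seed = 15)
  fld <- assign_vplc(tis, 1, c(1.4, 1.5), c(0.1, 0.5), seed = 16)
  cfg <- sim_config(duration = 600, settle = 300)
  tr <- simulate_tissue(tis, fld, config = cfg)
  expect_equal(tr$times[1], 0)
  expect_equal(tr$times[length(tr$times)], 600)
  # the settled run equals the tail of an equivalent long run
  cfg2 <- sim_config(duration = 900)
  tr2 <- simulate_tissue(tis, fld, config = cfg2)
  keep <- tr2$times >= 300
  expect_equal(tr$c, tr2$c[keep, ], tolerance = 1e-12)
})

test_that("configuration errors are caught", {
  expect_error(sim_config(duration = -1), "positive")
  expect_error(sim_config(sample_interval = 0), "sample_interval")
  expect_error(sim_config(ic_mode = "custom"), "y0")
  tis <- generate_tissue(5, seed = 1)
  fld <- assign_vplc(tis, 0, c(0, 0), c(0.1, 0.5), seed = 1)
  expect_error(
    simulate_tissue(tis, fld,
                    config = sim_config(ic_mode = "custom",
                                        y0 = rep(0.1, 7))),
    "3 \\* n_cells")
  bad <- assign_vplc(generate_tissue(6, seed = 2), 0, c(0, 0),
                     c(0.1, 0.5), seed = 1)
  expect_error(simulate_tissue(tis, bad), "match")
})

test_that("trajectory CSV export writes consistent matrices", {
  tis <- generate_tissue(8, seed = 17)
  fld <- assign_vplc(tis, 1, c(1.4, 1.5), c(0.1, 0.5), seed = 18)
  tr <- simulate_tissue(tis, fld, config = sim_config(duration = 300))
  d <- tempfile()
  write_trajectory_csv(tr, d)
  cc <- utils::read.csv(file.path(d, "c.csv"))
  expect_equal(dim(cc), dim(tr$c))
  expect_equal(as.matrix(cc), tr$c, ignore_attr = TRUE,
               tolerance = 1e-10)
  unlink(d, recursive = TRUE)
})
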