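test_that("zero planted effect leaves the groups identical", {
  sim_cfg <- simulation_config(n_sz = 2, n_hc = 2, C_fmri = 6, C_meg = 5,
                               T_fmri = 40, T_meg = 40, bands = "theta",
                               effect_pairs = data.frame(source = character(0),
                                                         i = integer(0),
                                                         j = integer(0),
                                                         dr = numeric(0)),
                               n_states = 2, seed = 5)
  model <- build_group_model(sim_cfg)
  for (src in names(model$sources)) {
    expect_equal(model$sources[[src]]$static$HC, model$sources[[src]]$static$SZ)
  }
})

test_that("planting perturbs only the target pair up to SPD-projection leakage", {
  ep <- data.frame(source = "fmri", i = 1, j = 2, dr = 0.4)
  sim_cfg <- simulation_config(n_sz = 2, n_hc = 2, C_fmri = 8, C_meg = 5,
                               T_fmri = 40, T_meg = 40, bands = character(0),
                               effect_pairs = ep, n_states = 1,
                               base_strength = 0.2, seed = 7)
  m <- build_group_model(sim_cfg)
  hc <- m$sources$fmri$static$HC
  sz <- m$sources$fmri$static$SZ
  diff <- abs(sz - hc)
  expect_gt(diff[1, 2], 0.35)
  diff[1, 2] <- diff[2, 1] <- 0
  expect_lt(max(diff), 0.02)
})

test_that("default effect layout plants nothing in theta and gamma", {
  ep <- default_effect_pairs()
  expect_setequal(unique(ep$source), c("fmri", "delta", "alpha", "beta"))
  counts <- table(ep$source)
  expect_equal(unname(counts[c("fmri", "delta", "alpha", "beta")]),
               c(12L, 9L, 4L, 22L), ignore_attr = TRUE)
})

test_that("an overlarge effect is rejected with advice", {
  ep <- data.frame(source = "fmri", i = 1, j = 2, dr = 1.9)
  sim_cfg <- simulation_config(n_sz = 2, n_hc = 2, C_fmri = 5, C_meg = 5,
                               T_fmri = 40, T_meg = 40, bands = character(0),
                               effect_pairs = ep, n_states = 1, seed = 1)
  expect_error(build_group_model(sim_cfg), "smaller dr")
})

test_that("subject simulation is deterministic in its seed", {
  sim_cfg <- simulation_config(n_sz = 2, n_hc = 2, C_fmri = 5, C_meg = 4,
                               T_fmri = 50, T_meg = 60, bands = "delta",
                               effect_pairs = data.frame(source = character(0),
                                                         i = integer(0), j = integer(0),
                                                         dr = numeric(0)),
                               n_states = 3, seed = 2)
  m <- build_group_model(sim_cfg)
  a <- simulate_subject(m, "HC", "x", seed = 99)
  b <- simulate_subject(m, "HC", "x", seed = 99)
  expect_identical(a$tcs$fmri$data, b$tcs$fmri$data)
  expect_identical(a$states, b$states)
})

test_that("dwell = 1 makes the state sequence constant", {
  sim_cfg <- simulation_config(n_sz = 1, n_hc = 1, C_fmri = 4, C_meg = 4,
                               T_fmri = 200, T_meg = 40, bands = character(0),
                               effect_pairs = data.frame(source = character(0),
                                                         i = integer(0), j = integer(0),
                                                         dr = numeric(0)),
                               n_states = 4, dwell = 1.0, seed = 3)
  m <- build_group_model(sim_cfg)
  s <- simulate_subject(m, "SZ", "x", seed = 5)$states$fmri
  expect_equal(length(unique(s)), 1L)
})

test_that("long-run sample correlation converges to the planted target", {
  ep <- data.frame(source = "fmri", i = 1, j = 2, dr = 0.5)
  sim_cfg <- simulation_config(n_sz = 1, n_hc = 1, C_fmri = 4, C_meg = 4,
                               T_fmri = 5000, T_meg = 64, bands = character(0),
                               effect_pairs = ep, n_states = 1,
                               state_strength = 0, base_strength = 0, seed = 4)
  sim <- simulate_study(sim_cfg)
  sz_id <- names(sim$dataset$groups)[sim$dataset$groups == "SZ"][1]
  X <- sim$dataset$subjects[[sz_id]]$tcs$fmri$data
  target <- sim$truth$static$fmri$SZ[1, 2]
  expect_lt(abs(cor(X[, 1], X[, 2]) - target), 0.05)
})

test_that("state occupancy matches the uniform stationary distribution", {
  sim_cfg <- simulation_config(n_sz = 1, n_hc = 1, C_fmri = 4, C_meg = 4,
                               T_fmri = 5000, T_meg = 64, bands = character(0),
                               effect_pairs = data.frame(source = character(0),
                                                         i = integer(0), j = integer(0),
                                                         dr = numeric(0)),
                               n_states = 3, dwell = 0.8, seed = 5)
  m <- build_group_model(sim_cfg)
  s <- simulate_subject(m, "HC", "x", seed = 77)$states$fmri
  occ <- as.numeric(table(factor(s, levels = 1:3))) / length(s)
  expect_true(all(abs(occ - 1 / 3) < 0.05))
})

test_that("group-difference tests on a null cohort reject at about alpha", {
  # calibration on ~200 replicate pairs: 10 cohorts x 21 pairs, no effects
  rej <- unlist(lapply(1:10, function(r) {
    sim <- tiny_cohort(n_per_group = 10, C = 7, T_n = 60, seed = 100 + r)
    Z <- t(vapply(sim$dataset$subjects,
                  function(s) static_fnc(s$tcs$fmri)$pairs, numeric(21)))
    tests <- pairwise_group_test(Z, sim$dataset$groups)
    tests$p < 0.05
  }))
  expect_gt(length(rej), 200)
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("a default study has 91 subjects with 6 sources each", {
  sim_cfg <- simulation_config()
  expect_equal(sim_cfg$n_sz + sim_cfg$n_hc, 91L)
  expect_equal(sim_cfg$T_fmri, 149L)
  expect_equal(sim_cfg$T_meg, 300L)
  # smoke-scale shape check: sources = fmri + requested bands
  sim <- tiny_cohort(n_per_group = 2, C = 5, T_n = 40, seed = 9)
  expect_length(sim$dataset$subjects, 4L)
  expect_equal(sim$dataset$sources, "fmri")
  sim2 <- simulate_study(simulation_config(
    n_sz = 2, n_hc = 2, C_fmri = 5, C_meg = 4, T_fmri = 40, T_meg = 40,
    bands = c("delta", "gamma"),
    effect_pairs = data.frame(source = character(0), i = integer(0),
                              j = integer(0), dr = numeric(0)),
    n_states = 1, seed = 8))
  expect_setequal(sim2$dataset$sources, c("fmri", "delta", "gamma"))
})

test_that("different seeds give different data of identical shape", {
  a <- tiny_cohort(n_per_group = 2, C = 4, T_n = 30, seed = 1)
  b <- tiny_cohort(n_per_group = 2, C = 4, T_n = 30, seed = 2)
  xa <- a$dataset$subjects[[1]]$tcs$fmri$data
  xb <- b$dataset$subjects[[1]]$tcs$fmri$data
  expect_equal(dim(xa), dim(xb))
  expect_false(isTRUE(all.equal(xa, xb)))
})
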