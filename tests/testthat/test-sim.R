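test_that("Hill factors obey their limits and monotonicity", {
  expect_equal(f_lambda(0, 2, 2), 1)
  expect_equal(f_delta(0, 2, 2), 1)
  expect_equal(f_lambda(1e8, 3, 2), 3, tolerance = 1e-6)
  expect_equal(f_delta(1e8, 4, 2), 1 / 4, tolerance = 1e-6)
  # g_lambda = 1 collapses the modulation
  w <- seq(0, 5, by = 0.1)
  expect_equal(f_lambda(w, 1, 2), rep(1, length(w)))
  set.seed(3)
  for (i in 1:10) {
    g <- runif(1, 1, 6)
    h <- runif(1, 0.5, 4)
    w <- sort(runif(50, 0, 10))
    expect_true(all(diff(f_lambda(w, g, h)) >= 0))
    expect_true(all(diff(f_delta(w, g, h)) <= 0))
  }
})

test_that("rate normalisation conserves population averages exactly", {
  set.seed(4)
  for (sc in c("lung", "lung_no_decay", "lymph_node")) {
    cfg <- sim_config(scenario = sc)
    for (i in 1:20) {
      w <- runif(sample(10:500, 1), 0, 4)
      t <- runif(1, cfg$T_g, cfg$T_end)
      r <- cell_rates(w, cfg, t)
      l0 <- effective_lambda0(cfg, t)
      l0_cap <- if (sc == "lymph_node") cfg$alpha_LN * cfg$lambda0 else cfg$lambda0
      cap <- (l0_cap - cfg$delta0) * length(w) / cfg$C
      expect_lt(abs(mean(r$lambda) - l0), 1e-9)
      expect_lt(abs(mean(r$delta) - cap - cfg$delta0), 1e-9)
    }
  }
})

test_that("homogeneous populations and M = C reproduce the closed forms", {
  cfg <- sim_config(scenario = "lung")
  w <- rep(0.7, 100)
  r <- cell_rates(w, cfg, t = 6)
  expect_equal(r$lambda, rep(cfg$lambda0, 100))
  expect_equal(r$delta,
               rep(cfg$delta0 + (cfg$lambda0 - cfg$delta0) * 100 / cfg$C, 100))
  # at carrying capacity the net growth of a homogeneous population is zero
  wC <- rep(0.3, cfg$C)
  rC <- cell_rates(wC, cfg, t = 6)
  expect_equal(unique(rC$delta), cfg$lambda0)
})

test_that("fitness mutation has the stated moments and zero clamp", {
  expect_equal(mutate_fitness(rep(0.4, 10), 0), rep(0.4, 10))
  set.seed(6)
  D <- 0.02
  dw <- mutate_fitness(rep(10, 1e5), D) - 10   # far from the clamp
  expect_lt(abs(mean(dw)), 4 * sqrt(2 * D / 1e5))
  expect_equal(var(dw), 2 * D, tolerance = 0.02)
  set.seed(7)
  low <- mutate_fitness(rep(0.01, 1e4), 0.5)
  expect_true(all(low >= 0))
  expect_gt(mean(low == 0), 0.1)  # the clamp is exercised
})

test_that("identical configs and seeds give identical event logs", {
  cfg <- sim_config(scenario = "lymph_node", n_founders = 10, C = 150,
                    T_end = 7, seed = 123, log_events = TRUE)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$event_log, r2$event_log)
  expect_identical(r1$timeline, r2$timeline)
  expect_gt(nrow(r1$event_log), 0L)
})

test_that("the neutral process matches the branching-process mean", {
  # M << C: E[M(t)] = n0 * exp((lambda0 - delta0) t)
  n_runs <- 200
  Ms <- vapply(seq_len(n_runs), function(i) {
    cfg <- sim_config(scenario = "no_selection", n_founders = 20,
                      C = 1e7, T_g = 2, T_end = 2, record_dt = 2,
                      seed = 1000L + i)
    r <- run_simulation(cfg)
    r$timeline$M[nrow(r$timeline)]
  }, numeric(1))
  expected <- 20 * exp((2 - 0.5) * 2)
  se <- stats::sd(Ms) / sqrt(n_runs)
  expect_lt(abs(mean(Ms) - expected), 4 * se)
})

test_that("the decayed growth rate is continuous and bounded below by delta0", {
  cfg <- sim_config(scenario = "lung")
  eps <- 1e-9
  expect_equal(effective_lambda0(cfg, cfg$T_dec),
               effective_lambda0(cfg, cfg$T_dec + eps), tolerance = 1e-6)
  expect_equal(effective_lambda0(cfg, 1e6), cfg$delta0, tolerance = 1e-6)
  expect_true(all(vapply(seq(0, 50, 0.5), function(t) {
    effective_lambda0(cfg, t) >= cfg$delta0
  }, logical(1))))
})

test_that("extinction ends the trajectory early with a flag", {
  cfg <- sim_config(scenario = "no_selection", lambda0 = 0.6, delta0 = 0.5,
                    n_founders = 2, C = 50, T_end = 40, seed = 11)
  r <- run_simulation(cfg)
  expect_true(r$extinct)
  expect_equal(r$timeline$M[nrow(r$timeline)], 0L)
})

test_that("equal shuttling rates give 50% dark-zone occupancy", {
  occ <- simulate_shuttling(6, 6, t_end = 2000, seed = 42)
  expect_lt(abs(occ - 0.5), 0.02)
  # asymmetric rates: occupancy k_LZDZ / (k_DZLZ + k_LZDZ)
  occ2 <- simulate_shuttling(9, 3, t_end = 2000, seed = 43)
  expect_lt(abs(occ2 - 0.25), 0.02)
})

test_that("ensembles aggregate run statistics with SEM", {
  cfg <- sim_config(scenario = "lung", n_founders = 10, C = 150,
                    T_end = 7, seed = 5)
  e1 <- ensemble(cfg, 1)
  r1 <- run_simulation(sim_config(scenario = "lung", n_founders = 10,
                                  C = 150, T_end = 7, seed = 6))
  expect_equal(e1$runs$M, glance(r1)$M)
  e <- ensemble(cfg, 5)
  expect_equal(nrow(e$runs), 5L)
  expect_true(all(c("mean_clone_size_mean", "mean_clone_size_sem") %in%
                  names(e$timeline)))
  g <- glance(e)
  expect_equal(g$n_runs, 5)
})
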