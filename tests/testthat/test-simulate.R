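test_that("parameter invariants are enforced with the violation named", {
  expect_error(circuit_params(basal = 1.5), "basal")
  expect_error(circuit_params(hill_R = 0.5), "hill_R")
  expect_error(circuit_params(N_mean = 0), "N_mean")
  expect_error(circuit_params(alpha = -1), "alpha")
  expect_error(measurement_params(debris_fraction = 1), "debris_fraction")
  expect_error(measurement_params(maturation_fraction = 2), "maturation")
})

test_that("no production means exactly zero reporter", {
  pop <- simulate_population(circuit_params(alpha = 0), inducer = 10,
                             n_cells = 500, seed = 1)
  expect_identical(pop$reporter, rep(0, 500))
})

test_that("constitutive deterministic limit matches the closed form", {
  # saturating repression: R0 * rho >> K_R, so activity = basal exactly in
  # the hill_R -> large sense; here computed against the hand-evaluated
  # Hill activity instead of the approximation
  p <- det_constitutive(alpha = 2000, basal = 0.1, K_R = 30, hill_R = 2,
                        R0 = 3e4, Kd_I = 10, hill_I = 2, N_mean = 7)
  rho <- 1 / (1 + (5 / 10)^2)
  a <- 0.1 + 0.9 / (1 + (3e4 * rho / 30)^2)
  pop <- simulate_population(p, inducer = 5, n_cells = 100, seed = 3)
  expect_equal(pop$reporter, rep(7 * 2000 * a, 100), tolerance = 1e-12)
  # and the strong-repression value is within rounding of N*alpha*basal
  expect_equal(unique(pop$reporter), 7 * 2000 * 0.1, tolerance = 1e-3)
})

test_that("autoregulated fixed point matches bisection and the sqrt law", {
  p <- circuit_params(mode = "autoregulated", alpha = 1e4, basal = 0,
                      hill_R = 1, K_R = 10, r_ratio = 1, burst = 0,
                      size_cv2 = 0, N_disp = 0)
  for (N in c(1, 4, 10, 40)) {
    g <- steady_state_reporter(p, 0, N)
    expect_equal(g, bisect_fixed_point(p, 0, N), tolerance = 1e-8)
    # exact root of G (1 + G/K_R) = N alpha with basal = 0, hill = 1
    g_exact <- (sqrt(1 + 4 * N * 1e4 / 10) - 1) * 10 / 2
    expect_equal(g, g_exact, tolerance = 1e-8)
    # strong repression: G ~ sqrt(N alpha K_R / r), exact as N grows
    if (N >= 4) expect_equal(g, sqrt(N * 1e4 * 10), tolerance = 0.02)
  }
  # elasticity d log G / d log N ~ 1/2 under the sqrt law
  el <- log(steady_state_reporter(p, 0, 20) /
              steady_state_reporter(p, 0, 10)) / log(2)
  expect_equal(el, 0.5, tolerance = 0.01)
})

test_that("fixed-point solver agrees with bisection over a parameter sweep", {
  set.seed(42)
  for (i in 1:100) {
    p <- circuit_params(mode = "autoregulated",
                        alpha = 10^runif(1, 1, 5),
                        basal = runif(1, 0, 0.2),
                        K_R = 10^runif(1, 0, 3),
                        hill_R = runif(1, 1, 4),
                        Kd_I = 10^runif(1, 0, 3),
                        hill_I = runif(1, 1, 3),
                        r_ratio = 10^runif(1, -1, 1))
    inducer <- 10^runif(1, -1, 4)
    N <- sample(1:40, 1)
    expect_equal(steady_state_reporter(p, inducer, N),
                 bisect_fixed_point(p, inducer, N),
                 tolerance = 1e-8)
  }
})

test_that("population mean approaches G_det as noise terms vanish", {
  p <- circuit_params(mode = "autoregulated", burst = 0.01, size_cv2 = 1e-6,
                      N_disp = 0)
  g_det <- steady_state_reporter(p, 25, 10)
  pop <- simulate_population(p, inducer = 25, n_cells = 20000, seed = 7)
  expect_equal(mean(pop$reporter), g_det, tolerance = 1e-3)
})

test_that("populations and event tables are reproducible and seed-sensitive", {
  p <- tetr_circuit()
  pop1 <- simulate_population(p, 25, 2000, seed = 11)
  pop2 <- simulate_population(p, 25, 2000, seed = 11)
  pop3 <- simulate_population(p, 25, 2000, seed = 12)
  expect_identical(pop1$reporter, pop2$reporter)
  expect_identical(pop1$copy_number, pop2$copy_number)
  expect_false(identical(pop1$reporter, pop3$reporter))
  m <- measurement_params()
  ev1 <- simulate_flow_sample(pop1, m, n_events = 3000, seed = 5)
  ev2 <- simulate_flow_sample(pop1, m, n_events = 3000, seed = 5)
  expect_identical(ev1, ev2)
})

test_that("monotone dose response in the deterministic limit, both modes", {
  ladder <- c(0, 2, 4.5, 10, 22.4, 50, 111.8, 250, 559, 1250)
  for (mode in c("autoregulated", "constitutive_repressor")) {
    p <- circuit_params(mode = mode, Kd_I = 50, hill_I = 1.3, burst = 0,
                        size_cv2 = 0, N_disp = 0)
    g <- vapply(ladder, function(d) steady_state_reporter(p, d, 10),
                numeric(1))
    expect_false(is.unsorted(g))
  }
})

test_that("dosage compensation: feedback elasticity < 1, constitutive = 1", {
  auto <- circuit_params(mode = "autoregulated", basal = 0, burst = 0,
                         size_cv2 = 0)
  cons <- circuit_params(mode = "constitutive_repressor", burst = 0,
                         size_cv2 = 0)
  el <- function(p) {
    log(steady_state_reporter(p, 5, 20) / steady_state_reporter(p, 5, 10)) /
      log(2)
  }
  expect_lt(el(auto), 1)
  expect_equal(el(cons), 1, tolerance = 1e-6)
  # halving copy number drops the mean less with feedback than without
  drop_auto <- 1 - steady_state_reporter(auto, 5, 5) /
    steady_state_reporter(auto, 5, 10)
  drop_cons <- 1 - steady_state_reporter(cons, 5, 5) /
    steady_state_reporter(cons, 5, 10)
  expect_lt(drop_auto, drop_cons)
})

test_that("flow samples have the requested size and exact identity measurement", {
  pop <- gamma_population(k = 10, n_cells = 5000, seed = 2)
  ev <- simulate_flow_sample(pop, measurement_params(), seed = 3)
  expect_identical(nrow(ev), 30000L)

  m0 <- noise_free_meas()
  ev0 <- simulate_flow_sample(pop, m0, n_events = 1000, seed = 4)
  # identity measurement: fl1 equals the sampled G values exactly
  set.seed(4L)
  idx <- sample.int(5000, 1000)
  expect_identical(ev0$fl1_area, pop$reporter[idx])
  expect_true(all(c("fsc_area", "ssc_height", "fl1_area") %in% names(ev0)))
})

test_that("two-channel populations carry an fl2 column sharing cell size", {
  pop <- simulate_population(tetr_circuit(), 25, 2000, seed = 1,
                             params2 = laci_circuit(), inducer2 = 100)
  expect_length(pop$reporter2, 2000)
  ev <- simulate_flow_sample(pop, measurement_params(), n_events = 1000,
                             seed = 2)
  expect_true("fl2_area" %in% names(ev))
})

test_that("debris events appear at the configured binomial rate", {
  pop <- gamma_population(k = 10, n_cells = 1000, seed = 1)
  m <- measurement_params(debris_fraction = 0.05)
  counts <- vapply(1:100, function(s) {
    ev <- simulate_flow_sample(pop, m, n_events = 30000, seed = s)
    sum(attr(ev, "is_debris"))
  }, numeric(1))
  expected <- 0.05 * 30000
  se <- sqrt(30000 * 0.05 * 0.95 / 100)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("control samples are flagged and contain only background", {
  m0 <- measurement_params(autofluorescence = 0, instrument_cv = 0,
                           debris_fraction = 0)
  ctrl <- simulate_control_sample(m0, n_events = 500, seed = 9)
  expect_true(all(ctrl$is_control))
  expect_identical(ctrl$fl1_area, rep(0, 500))

  # autofluorescence 50 AU/size with E[s] = 1: mean fl1 ~ 50
  m <- measurement_params(autofluorescence = 50, instrument_cv = 0,
                          debris_fraction = 0)
  means <- vapply(1:20, function(s) {
    mean(simulate_control_sample(m, n_events = 2000, seed = s,
                                 size_cv2 = 0.05)$fl1_area)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 50), 3 * se + 0.5)
})

test_that("empty populations and invalid event counts are rejected", {
  pop <- gamma_population(k = 10, n_cells = 100, seed = 1)
  expect_error(simulate_flow_sample(pop, measurement_params(), n_events = 0,
                                    seed = 1), "n_events")
})
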