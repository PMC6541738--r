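test_that("compute_cv2 follows its definition and flags nonpositive means", {
  expect_identical(compute_cv2(1, 0), 0)
  expect_identical(compute_cv2(100, 1000), 0.1)
  expect_true(is.na(compute_cv2(0, 5)))
  expect_true(is.na(compute_cv2(-2, 5)))
  # fitted gamma: CV^2 = 1/k
  set.seed(1)
  f <- fit_sample_gamma(rgamma(2e4, 10, scale = 100))
  expect_equal(compute_cv2(f$mean, f$variance), 1 / f$shape,
               tolerance = 1e-12)
})

test_that("summarizing a control against its own background flags cv2", {
  m <- measurement_params(debris_fraction = 0)
  ctrl <- simulate_control_sample(m, n_events = 10000, seed = 1)
  cm <- control_mean_from_events(ctrl)
  s <- summarize_sample(ctrl, control_mean = cm)
  # self-subtraction: residual mean within a few fitted SEs of zero
  expect_lt(abs(s$mean_bgsub), 3 * sqrt(s$variance / s$n_gated) + 1)
  ctrl2 <- simulate_control_sample(m, n_events = 10000, seed = 2)
  s2 <- summarize_sample(ctrl2, control_mean = cm * 1.5)
  expect_false(s2$cv2_defined)
  expect_true(is.na(s2$cv2))
})

test_that("pipeline recovers a known gamma concentration law over background", {
  k <- 10
  mean_G <- 10000
  m <- measurement_params(autofluorescence = 100, instrument_cv = 0.02,
                          debris_fraction = 0.02)
  cv2s <- means <- numeric(3)
  for (i in 1:3) {
    pop <- gamma_population(k = k, mean_G = mean_G, n_cells = 30000,
                            seed = 100 + i)
    ev <- simulate_flow_sample(pop, m, seed = 200 + i)
    ctrl <- simulate_control_sample(m, seed = 300 + i, size_cv2 = 0)
    s <- summarize_sample(ev, control_mean_from_events(ctrl))
    means[i] <- s$mean_bgsub
    cv2s[i] <- s$cv2
  }
  mat <- measurement_params()$maturation_fraction
  expect_equal(mean(means), mean_G * mat, tolerance = 0.05)
  expect_equal(mean(cv2s), 1 / k, tolerance = 0.1)
})

test_that("dose response aggregates replicates, ranges and monotonicity", {
  mk <- function(iptg, rep, mean_bgsub) {
    data.frame(sample_id = "s", condition_atc_nM = NA_real_,
               condition_iptg_uM = iptg, replicate = rep,
               channel = "fl1_area", n_gated = 100L,
               mean_raw = mean_bgsub + 10, control_mean = 10,
               mean_bgsub = mean_bgsub, variance = mean_bgsub,
               cv2 = 1 / mean_bgsub, cv2_defined = TRUE,
               fit_converged = TRUE)
  }
  one <- mk(10, 1, 50)
  expect_identical(dose_response(one)$dynamic_range, 1)

  two <- rbind(mk(2, 1, 10), mk(1250, 1, 500))
  dr <- dose_response(two)
  expect_identical(dr$dynamic_range, 50)
  expect_true(dr$monotone)

  withzero <- rbind(mk(0, 1, 2), mk(2, 1, 10), mk(1250, 1, 500))
  dr0 <- dose_response(withzero)
  expect_identical(dr0$dynamic_range, 50)  # zero dose excluded from range
  expect_identical(dr0$zero_condition$inducer, 0)

  expect_error(dose_response(rbind(one, one)), "duplicate")
})

test_that("near-deterministic dose response over the IPTG ladder is monotone", {
  ladder <- c(0, 2, 4.5, 10, 22.4, 50, 111.8, 250, 559, 1250)
  p <- laci_circuit(burst = 2, size_cv2 = 0.01, N_disp = 0)
  m0 <- noise_free_meas(2000L)
  rows <- lapply(seq_along(ladder), function(i) {
    pop <- simulate_population(p, ladder[i], 2000, seed = i)
    ev <- simulate_flow_sample(pop, m0, n_events = 2000, seed = 50 + i,
                               iptg_uM = ladder[i])
    summarize_sample(ev, control_mean = 0, gate_fraction = 1)
  })
  dr <- dose_response(do.call(rbind, rows))
  expect_true(dr$monotone)
  expect_gt(dr$dynamic_range, 1)
})

test_that("backbone comparison handles identity, zero and mismatch cases", {
  mk <- function(atc, rep, mean_bgsub) {
    data.frame(condition_atc_nM = atc, condition_iptg_uM = NA_real_,
               replicate = rep, mean_bgsub = mean_bgsub)
  }
  a <- rbind(mk(5, 1, 100), mk(25, 1, 500))
  expect_equal(compare_backbones(a, a)$drop_pct, 0)
  z <- rbind(mk(5, 1, 0), mk(25, 1, 0))
  expect_equal(compare_backbones(a, z)$drop_pct, 100)
  b <- mk(125, 1, 100)
  expect_error(compare_backbones(a, b), "unmatched")
})

test_that("crosstalk is zero for constant channels and one for a doubling", {
  mk <- function(atc, iptg, ch, mean_bgsub) {
    data.frame(condition_atc_nM = atc, condition_iptg_uM = iptg,
               channel = ch, replicate = 1L, mean_bgsub = mean_bgsub)
  }
  grid <- expand.grid(atc = c(5, 125), iptg = c(50, 1250))
  const <- do.call(rbind, lapply(seq_len(4), function(i) {
    rbind(mk(grid$atc[i], grid$iptg[i], "fl1_area", 100 * (grid$atc[i] / 5)),
          mk(grid$atc[i], grid$iptg[i], "fl2_area", 40 * (grid$iptg[i] / 50)))
  }))
  ct <- crosstalk(const)
  expect_equal(ct$per_channel$crosstalk, c(0, 0), tolerance = 1e-12)
  expect_true(ct$independent)

  # inject dependence: channel-1 mean doubled at high IPTG
  dep <- const
  sel <- dep$channel == "fl1_area" & dep$condition_iptg_uM == 1250
  dep$mean_bgsub[sel] <- 2 * dep$mean_bgsub[sel]
  ct2 <- crosstalk(dep)
  x1 <- ct2$per_channel$crosstalk[ct2$per_channel$channel == "fl1_area"]
  expect_equal(x1, 1, tolerance = 1e-12)  # (2m - m) / m
  expect_false(ct2$independent)

  expect_error(crosstalk(const[-1, ]), "incomplete grid")
})

test_that("CV^2 is invariant under common rescaling of fluorescence and control", {
  pop <- gamma_population(k = 10, n_cells = 20000, seed = 42)
  m <- measurement_params(debris_fraction = 0)
  ev <- simulate_flow_sample(pop, m, n_events = 20000, seed = 43)
  ctrl <- simulate_control_sample(m, n_events = 20000, seed = 44,
                                  size_cv2 = 0)
  cm <- control_mean_from_events(ctrl)
  s1 <- summarize_sample(ev, cm)
  for (c in c(0.1, 100)) {
    evc <- ev
    evc$fl1_area <- c * evc$fl1_area
    sc <- summarize_sample(evc, c * cm)
    expect_equal(sc$cv2, s1$cv2, tolerance = 1e-3)
  }
})

test_that("feedback reduces the backbone drop for the same copy-number ratio", {
  # deterministic-limit means through the identity pipeline, N 10 -> 4
  run_means <- function(p, N) {
    vapply(c(5, 25, 125), function(d) {
      pcopy <- p
      pcopy$N_mean <- N
      steady_state_reporter(pcopy, d, N)
    }, numeric(1))
  }
  auto <- circuit_params(mode = "autoregulated", basal = 0)
  cons <- circuit_params(mode = "constitutive_repressor")
  mk <- function(means) {
    data.frame(condition_atc_nM = c(5, 25, 125),
               condition_iptg_uM = NA_real_, replicate = 1L,
               mean_bgsub = means)
  }
  drop_auto <- compare_backbones(mk(run_means(auto, 10)),
                                 mk(run_means(auto, 4)))$drop_pct
  drop_cons <- compare_backbones(mk(run_means(cons, 10)),
                                 mk(run_means(cons, 4)))$drop_pct
  expect_lt(drop_auto, drop_cons)
  expect_equal(drop_cons, 60, tolerance = 1e-9)  # 1 - 4/10
})
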