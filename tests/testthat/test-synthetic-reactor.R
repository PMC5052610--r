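test_that("single stirred tank reproduces the exponential impulse response", {
  cfg <- reactor_config(n_compartments = 1, total_volume = 17.88, feed_split = 1)
  ex <- tracer_experiment(injected_mass = 10, sampling_interval = 6)
  curve <- simulate_tracer_pulse(cfg, ex)
  theta <- curve$times / cfg$nominal_hrt
  expected <- (10 / 17.88) * exp(-theta)
  expect_lt(max(abs(curve$concentrations - expected) / expected), 1e-6)
})

test_that("six equal tanks fed upstream give the Erlang-6 normalized moments", {
  cfg <- reactor_config()  # feed_split defaults to all-first-compartment
  curve <- dense_tracer_curve(cfg, duration_multiple = 10)
  m <- curve_moments(normalize_curve(curve))
  expect_equal(m$mean_theta, 1, tolerance = 0.01)
  expect_equal(m$variance_theta, 1 / 6, tolerance = 0.01)
})

test_that("split-feed effluent equals the per-path superposition closed form", {
  # two equal tanks, half the feed (and tracer) into each
  cfg2 <- reactor_config(n_compartments = 2, total_volume = 2,
                         total_flow = 1, feed_split = c(0.5, 0.5))
  ex <- tracer_experiment(injected_mass = 5, sampling_interval = 0.05,
                          duration_multiple = 5)
  curve <- simulate_tracer_pulse(cfg2, ex)
  oracle <- superposition_effluent(cfg2, 5, curve$times)
  expect_equal(curve$concentrations, oracle, tolerance = 1e-6)

  # the closed-form mixture: 0.5 x (chain through both tanks, rates Q/2V
  # then Q/V) + 0.5 x (single tank under the full flow)
  analytic <- 0.5 * hypoexp_effluent(cfg2, 1, 5, curve$times) +
    0.5 * hypoexp_effluent(cfg2, 2, 5, curve$times)
  expect_equal(curve$concentrations, analytic, tolerance = 1e-6)

  # six-compartment reactor with the 6:3:1 feed split
  cfg6 <- reactor_config(feed_split = c(0.6, 0, 0.3, 0, 0.1, 0))
  ex6 <- tracer_experiment(injected_mass = 10, sampling_interval = 2,
                           duration_multiple = 4)
  curve6 <- simulate_tracer_pulse(cfg6, ex6)
  oracle6 <- superposition_effluent(cfg6, 10, curve6$times)
  expect_equal(curve6$concentrations, oracle6, tolerance = 1e-6)
})

test_that("tracer mass is conserved across feeding strategies", {
  splits <- list(c(1, 0, 0, 0, 0, 0),
                 c(0.6, 0, 0.3, 0, 0.1, 0),
                 c(0.6, 0, 0.2, 0, 0.2, 0))
  for (fs in splits) {
    cfg <- reactor_config(feed_split = fs)
    curve <- dense_tracer_curve(cfg, duration_multiple = 12)
    recovered <- cfg$total_flow * trapz_manual(curve$times, curve$concentrations)
    expect_equal(recovered, 10, tolerance = 0.005)
  }
})

test_that("feed placement changes spread, not the mean residence time", {
  # For a fully flowed-through chain the RTD mean is V/Q regardless of the
  # split (sum_i V_i/Q_i * Q_i/Q = V/Q): feeding downstream broadens the
  # response (mixture of short and long paths) without moving its centroid.
  cfg_up <- reactor_config()
  cfg_split <- reactor_config(feed_split = c(0.6, 0, 0.3, 0, 0.1, 0))
  m_up <- curve_moments(normalize_curve(dense_tracer_curve(cfg_up, 14)))
  m_split <- curve_moments(normalize_curve(dense_tracer_curve(cfg_split, 14)))
  expect_equal(m_up$mean_theta, 1, tolerance = 1e-3)
  expect_equal(m_split$mean_theta, 1, tolerance = 1e-3)
  expect_gt(m_split$variance_theta, m_up$variance_theta)
})

test_that("a square pulse converges to the impulse response as it narrows", {
  cfg <- reactor_config(n_compartments = 2, total_volume = 2, total_flow = 1,
                        feed_split = c(1, 0))
  imp <- simulate_tracer_pulse(cfg, tracer_experiment(4, sampling_interval = 0.25,
                                                      duration_multiple = 4))
  pul <- simulate_tracer_pulse(cfg, tracer_experiment(4, sampling_interval = 0.25,
                                                      duration_multiple = 4,
                                                      pulse_duration = 0.01))
  expect_equal(pul$concentrations[-1], imp$concentrations[-1], tolerance = 0.01)
})

test_that("steady-state COD profile honours mixing, kinetics and limits", {
  cfg <- reactor_config(feed_split = c(0.6, 0, 0.3, 0, 0.1, 0))

  # no degradation: everything passes through unchanged
  none <- simulate_cod_steady_state(cfg, cod_scenario(4250, rep(0, 6)))
  expect_equal(none$effluent_mg_L[6], 4250)

  # flow-weighted merge oracle
  expect_equal(compartment_influent(0.222, 1000, 0.111, 4250),
               (0.222 * 1000 + 0.111 * 4250) / 0.333)
  expect_equal(compartment_influent(0.222, 1000, 0.111, 4250), 2083.3,
               tolerance = 1e-4)

  # huge rate in the only fed compartment removes essentially everything
  cfg1 <- reactor_config(feed_split = c(1, 0, 0, 0, 0, 0))
  hot <- simulate_cod_steady_state(cfg1, cod_scenario(4250, c(1e9, 0, 0, 0, 0, 0)))
  expect_lt(hot$effluent_mg_L[1], 1e-3)
  expect_lt(hot$effluent_mg_L[6], 1e-3)

  # steady-state mass balance closes: in = out + removed
  sc <- cod_scenario(4250, c(0.08, 0.05, 0.04, 0.03, 0.05, 0.01))
  tab <- simulate_cod_steady_state(cfg, sc)
  q_feed <- cfg$feed_split * cfg$total_flow
  mass_in <- sum(q_feed * 4250)
  mass_out <- tab$flow_L_h[6] * tab$effluent_mg_L[6]
  removed <- sum(tab$flow_L_h * (tab$influent_mg_L - tab$effluent_mg_L))
  expect_equal(mass_in, mass_out + removed, tolerance = 1e-9)
})

test_that("observation noise is multiplicative, seeded and well calibrated", {
  cfg <- reactor_config()
  curve <- simulate_tracer_pulse(cfg, tracer_experiment(10, sampling_interval = 6))

  expect_identical(add_observation_noise(curve, 0), curve)
  n1 <- add_observation_noise(curve, 0.05, rng_seed = 7)
  n2 <- add_observation_noise(curve, 0.05, rng_seed = 7)
  expect_identical(n1$concentrations, n2$concentrations)
  expect_false(identical(n1$concentrations, curve$concentrations))

  # Monte-Carlo calibration of the noise generator on one point
  point <- ccurve(c(0, 1), c(1, 1), c0 = 1, nominal_hrt = 1)
  draws <- vapply(seq_len(10000), function(s)
    add_observation_noise(point, 0.05, rng_seed = s)$concentrations[2],
    numeric(1))
  cv_hat <- sd(draws) / mean(draws)
  expect_equal(cv_hat, 0.05, tolerance = 0.1)
  expect_equal(mean(draws), 1, tolerance = 0.01)
})

test_that("invalid configurations and experiments are rejected", {
  expect_error(reactor_config(feed_split = c(0.5, 0.4, 0, 0, 0, 0)), "sum to 1")
  expect_error(reactor_config(compartment_volumes = c(1, 0, 1, 1, 1, 1)),
               "positive")
  expect_error(reactor_config(total_flow = 0), "positive")
  expect_error(tracer_experiment(0), "positive")
  expect_error(tracer_experiment(10, noise_cv = 0.1), "rng_seed")
  expect_error(cod_scenario(4250, c(-0.1, 0, 0, 0, 0, 0)), "non-negative")
  cfg <- reactor_config()
  expect_error(simulate_tracer_pulse(cfg, tracer_experiment(10, injection = 9L)),
               "exceeds")
})
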