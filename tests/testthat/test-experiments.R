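test_that("forgetting starts at the learning increment and decays to zero", {
  sp <- default_spec()
  lp <- learning_params(mu = 1)
  A <- 1000
  fc <- forgetting_experiment(sp, lp, A = A, t_max = 1e5)
  d_net <- sp$x[1] * sp$x[2] * sp$y[1] * lp$mu * A / (sp$S - 1)
  expect_equal(fc$strength[fc$t == 0], d_net, tolerance = 1e-10)
  expect_true(all(fc$strength >= 0))
  expect_lt(fc$strength[nrow(fc)], 1e-3 * d_net)
  # nothing learned, nothing to forget
  fc0 <- forgetting_experiment(sp, learning_params(mu = 0), A = A, t_max = 100)
  expect_true(all(abs(fc0$strength) < 1e-12))
})

test_that("late-time forgetting rate equals the spectral gap", {
  sp <- default_spec()
  fc <- forgetting_experiment(sp, learning_params(mu = 1), t_max = 2e5)
  sh <- classify_curve_shape(fc)
  lambda2 <- spectral_summary(build_transition_matrix(sp), sp$x)$lambda2
  expect_equal(sh$exp_rate, log(lambda2), tolerance = 0.01)
})

test_that("simulated forgetting decreases recall toward the background level", {
  sp <- default_spec()
  lp <- learning_params(mu = 1)
  fc <- forgetting_experiment(sp, lp, A = 1e5, times = c(0, 5, 50),
                              metric = "simulated", B = 60, seed = 4)
  expect_gt(fc$strength[1], 0.9)             # fresh trace retrieved
  expect_true(all(fc$strength <= fc$strength[1]))
  expect_lt(fc$strength[3], 0.5)             # largely lost by t = 50
})

test_that("shape classifier recovers pure synthetic curves", {
  tt <- unique(round(exp(seq(0, log(5000), length.out = 50))))
  exp_curve <- data.frame(t = tt, strength = 3 * 0.995^tt)
  sh_e <- classify_curve_shape(exp_curve)
  expect_gt(sh_e$late_exp_r2, 0.999)
  expect_equal(sh_e$exp_rate, log(0.995), tolerance = 0.01)
  pow_curve <- data.frame(t = tt, strength = 5 * tt^-0.7)
  sh_p <- classify_curve_shape(pow_curve)
  expect_gt(sh_p$early_power_r2, 0.999)
  expect_equal(sh_p$power_exponent, -0.7, tolerance = 0.01)
  expect_error(classify_curve_shape(data.frame(t = tt, strength = 1)),
               "degenerate|constant")
})

test_that("forgetting is power-like early and exponential-like late", {
  sp <- default_spec()
  fc <- forgetting_experiment(sp, learning_params(mu = 1), t_max = 2e5)
  sh <- classify_curve_shape(fc)
  expect_gt(sh$early_power_r2, sh$early_exp_r2)
  expect_gt(sh$late_exp_r2, sh$late_power_r2)
})

test_that("equal-strength traces of age zero behave identically", {
  sp <- default_spec()
  lp <- learning_params(mu = 0.8)
  jd <- jost_decay_experiment(sp, lp, age_old = 0, t_probe = c(5, 50))
  expect_true(jd$feasible)
  expect_equal(jd$mu_young, 0.8, tolerance = 1e-7)
  expect_equal(jd$probes$strength_old, jd$probes$strength_young,
               tolerance = 1e-6)
  jl <- jost_learning_experiment(sp, lp, age_old = 0)
  expect_equal(jl$increment_old, jl$increment_young, tolerance = 1e-6)
})

test_that("the older of two equal-strength traces decays slower", {
  sp <- default_spec()
  jd <- jost_decay_experiment(sp, learning_params(mu = 1), age_old = 200,
                              t_probe = c(10, 50, 200))
  expect_true(jd$feasible)
  # calibration contract: strengths matched at probe time 0
  fresh <- jost_decay_experiment(sp, learning_params(mu = 1), age_old = 200,
                                 t_probe = 0)
  expect_equal(fresh$probes$strength_old, fresh$probes$strength_young,
               tolerance = 1e-8)
  expect_true(all(jd$probes$strength_old > jd$probes$strength_young))
})

test_that("the older trace gains more from identical relearning", {
  sp <- default_spec()
  jl <- jost_learning_experiment(sp, learning_params(mu = 1), age_old = 200)
  expect_true(jl$feasible)
  expect_gt(jl$state1_old, jl$state1_young)
  expect_gt(jl$increment_old, jl$increment_young)
  # increment equals current state-1 mass * p12 * mu * A / (S-1)
  p12 <- sp$x[2] * sp$y[1]
  expect_equal(jl$increment_old,
               jl$state1_old * p12 * 1 * 1000 / (sp$S - 1), tolerance = 1e-10)
  expect_equal(jl$increment_young,
               jl$state1_young * p12 * 1 * 1000 / (sp$S - 1), tolerance = 1e-10)
})

test_that("spaced learning outlasts strength-matched massed learning", {
  sp <- default_spec()
  lp <- learning_params(mu = 0.5)
  # gap 0 makes the schedules identical
  sp0 <- spacing_experiment(sp, lp, k_episodes = 5, gap = 0, t_probe = c(50))
  expect_true(sp0$feasible)
  expect_equal(sp0$mu_massed, 0.5, tolerance = 1e-7)
  expect_equal(sp0$probes$strength_spaced, sp0$probes$strength_massed,
               tolerance = 1e-6)
  spx <- spacing_experiment(sp, lp, k_episodes = 5, gap = 50,
                            t_probe = c(50, 500))
  expect_true(spx$feasible)
  expect_true(all(spx$probes$strength_spaced > spx$probes$strength_massed))
  # mechanism: the spaced trace holds strictly more mass in states >= 3
  expect_gt(sum(spx$deviation_spaced[3:sp$S]),
            sum(spx$deviation_massed[3:sp$S]))
})

test_that("lesion models enforce decreasing vulnerability with strength", {
  expect_error(lesion_model(c(0.1, 0.5, 0.2)), "q\\[1\\]")
  expect_error(lesion_model(c(0, 0.2, 0.5)), "non-increasing")
  lm5 <- lesion_model_power(5, q_base = 0.8, gamma = 1)
  expect_equal(lm5$q, c(0, 0.6, 0.4, 0.2, 0))
  expect_equal(lesion_model_power(5, 0.5, 0)$q, c(0, rep(0.5, 4)))
})

test_that("lesioning a distribution conserves mass and commutes with expectation", {
  sp <- default_spec()
  les <- lesion_model_power(5, 0.8, 1)
  v <- learn_distribution(sp$x, sp, learning_params(mu = 1))
  vl <- apply_lesion(v, les)
  expect_equal(sum(vl), 1, tolerance = 1e-14)
  expect_true(all(vl >= 0))
  # ensemble-level lesion mean matches the distribution-level result
  ens <- new_ensemble(sp, A = 400, B = 250, seed = 17)
  occ0 <- tabulate(ens$states, nbins = 5) / length(ens$states)
  ensl <- apply_lesion_ensemble(ens, les, seed = 18)
  occ1 <- tabulate(ensl$states, nbins = 5) / length(ensl$states)
  pred <- apply_lesion(occ0, les)
  se <- sqrt(pmax(pred * (1 - pred), 1e-12) / length(ens$states))
  expect_true(all(abs(occ1 - pred) < 4 * se))
})

test_that("Ribot gradient: recent traces are hit hardest by diffuse lesions", {
  sp <- default_spec()
  lp <- learning_params(mu = 1)
  ages <- c(10, 100, 1000, 5000)
  # no lesion: groups identical, relative gradient flat at 1
  rb0 <- lesion_experiment(sp, lp, lesion_model(rep(0, 5)), ages)
  expect_equal(rb0$relative, rep(1, 4), tolerance = 1e-12)
  # total lesion of present connections: no post-lesion strength at any age
  rb1 <- lesion_experiment(sp, lp, lesion_model(c(0, rep(1, 4))), ages)
  expect_true(all(abs(rb1$strength_post) < 1e-12))
  # graded lesion: retained-strength ratio strictly increases with age
  rb <- lesion_experiment(sp, lp, lesion_model_power(5, 0.8, 1), ages)
  expect_true(all(diff(rb$strength_post / rb$strength_pre) > 0))
  expect_true(all(rb$relative >= rb$relative[length(ages)] - 1e-9))
  expect_gt(rb$relative[1], 1)
})
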