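test_that("state weights are affine in state index with fixed endpoints", {
  expect_equal(state_weight(1, 7), 0)
  expect_equal(state_weight(7, 7), 1)
  expect_equal(state_weight(3, 5), 0.5)
  expect_equal(state_weight(4, 5, alpha = 2), 1.5)
  w <- state_weight(1:6, 6)
  expect_equal(diff(w), rep(1 / 5, 5))
  expect_error(state_weight(0, 5), "out of range")
  expect_error(state_weight(6, 5), "out of range")
})

test_that("distribution-level learning moves mass only from state 1 to 2", {
  sp <- spec3()
  v <- sp$x
  lp <- learning_params(mu = 1)
  expect_identical(learn_distribution(v, sp, learning_params(mu = 0)), v)
  v1 <- learn_distribution(v, sp, lp, 1)
  expect_equal(v1, c(0.47, 0.33, 0.2), tolerance = 1e-12)
  expect_equal(sum(v1), 1, tolerance = 1e-14)
  # only states 1 and 2 change, by opposite amounts
  v5 <- learn_distribution(v, sp, learning_params(mu = 0.3), 5)
  expect_equal(v5[3], v[3])
  expect_equal(v5[1] - v[1], -(v5[2] - v[2]), tolerance = 1e-14)
})

test_that("ensemble learning matches the binomial prediction in expectation", {
  sp <- spec3()   # p12 = 0.06
  lp <- learning_params(mu = 1)
  A <- 100
  # empty brain: promotions per output neuron ~ Binomial(A, p12 * mu), mean 6
  promoted <- unlist(lapply(1:4, function(s) {
    ens <- new_ensemble(sp, A = A, B = 250, init = "empty")
    colSums(learn_ensemble(ens, sp, lp, seed = s)$states == 2L)
  }))
  se <- stats::sd(promoted) / sqrt(length(promoted))
  expect_lt(abs(mean(promoted) - A * 0.06), 3 * se)
  # at equilibrium the expected number of new connections is x1 * p12 * mu * A
  newly <- unlist(lapply(1:4, function(s) {
    ens <- new_ensemble(sp, A = A, B = 250, init = "equilibrium", seed = 50 + s)
    before <- colSums(ens$states == 1L)
    after <- colSums(learn_ensemble(ens, sp, lp, seed = s)$states == 1L)
    before - after
  }))
  se2 <- stats::sd(newly) / sqrt(length(newly))
  expect_lt(abs(mean(newly) - sp$x[1] * 0.06 * A), 3 * se2)
  # mu = 0 leaves the ensemble untouched
  ens <- new_ensemble(sp, 20, 20, seed = 3)
  expect_identical(learn_ensemble(ens, sp, learning_params(mu = 0))$states,
                   ens$states)
})

test_that("expected net input is the weighted occupancy sum", {
  expect_equal(expected_net_input(c(1, 0, 0, 0, 0), 50, 5), 0)
  expect_equal(expected_net_input(c(0, 0, 0, 0, 1), 50, 5), 50)
  expect_equal(expected_net_input(c(0.6, 0.2, 0.1, 0.06, 0.04), 20, 5), 3.7)
})

test_that("feedforward inhibition sits half a learning increment above baseline", {
  spF <- chain_spec(x = c(0.6, 0.2, 0.1, 0.06, 0.04),
                    y = c(0.1, 0.05, 0.03, 0.01))   # p12 = 0.02
  expect_equal(feedforward_inhibition(20, spF, learning_params(mu = 0.5)),
               3.715, tolerance = 1e-12)
  expect_equal(feedforward_inhibition(0, spF, learning_params(mu = 0.5)), 0)
  # with mu = 0 the threshold equals the equilibrium net input exactly
  expect_equal(feedforward_inhibition(20, spF, learning_params(mu = 0)),
               expected_net_input(spF$x, 20, 5), tolerance = 1e-12)
  # linear in the active-input count
  F1 <- feedforward_inhibition(7, spF, learning_params(mu = 0.5))
  F2 <- feedforward_inhibition(14, spF, learning_params(mu = 0.5))
  expect_equal(F2, 2 * F1, tolerance = 1e-12)
  # alternative policy: threshold above the equilibrium net input
  Fs <- feedforward_inhibition(20, spF,
                               learning_params(mu = 0.5, inhibition = "two_sigma"))
  expect_gt(Fs, expected_net_input(spF$x, 20, 5))
})

test_that("retrieval margin is +/- half the learning increment around threshold", {
  sp <- default_spec()
  lp <- learning_params(mu = 1)
  A <- 500
  d_net <- sp$x[1] * sp$x[2] * sp$y[1] * lp$mu * A / (sp$S - 1)
  Fb <- feedforward_inhibition(A, sp, lp)
  net_pre <- expected_net_input(sp$x, A, sp$S)
  net_post <- expected_net_input(learn_distribution(sp$x, sp, lp), A, sp$S)
  expect_equal(net_pre - Fb, -d_net / 2, tolerance = 1e-10)
  expect_equal(net_post - Fb, d_net / 2, tolerance = 1e-10)
})

test_that("threshold retrieval separates learned from unlearned patterns", {
  sp <- default_spec()
  lp <- learning_params(mu = 1)
  # all connections absent: zero net never crosses the positive threshold
  empty <- new_ensemble(sp, 100, 20, init = "empty")
  expect_equal(retrieve(empty, 1, sp, lp)$fraction_active, 0)
  expect_error(retrieve(empty, 0, sp, lp), "cue_fraction")
  # unlearned equilibrium ensembles fire under half the time on average
  fa_eq <- vapply(1:10, function(s) {
    ens <- new_ensemble(sp, A = 500, B = 50, seed = s)
    retrieve(ens, 1, sp, lp, seed = s)$fraction_active
  }, numeric(1))
  expect_lt(mean(fa_eq), 0.5)
  # with a large input population the learned increment clears the noise
  fa_learned <- vapply(1:2, function(s) {
    ens <- new_ensemble(sp, A = 1e5, B = 30, seed = s)
    ens <- learn_ensemble(ens, sp, lp, seed = s + 100)
    retrieve(ens, 1, sp, lp, seed = s)$fraction_active
  }, numeric(1))
  expect_gt(mean(fa_learned), 0.95)
})

test_that("rescaling alpha leaves activations invariant", {
  sp <- default_spec()
  ens <- new_ensemble(sp, 200, 40, seed = 5)
  ens <- learn_ensemble(ens, sp, learning_params(mu = 1), seed = 6)
  r1 <- retrieve(ens, 0.8, sp, learning_params(mu = 1, alpha = 1), seed = 9)
  r2 <- retrieve(ens, 0.8, sp, learning_params(mu = 1, alpha = 2.5), seed = 9)
  expect_identical(r1$act, r2$act)
  expect_equal(r2$net, 2.5 * r1$net, tolerance = 1e-12)
  expect_equal(r2$F, 2.5 * r1$F, tolerance = 1e-12)
})

test_that("closed-form learning curve is exponential with the stated asymptote", {
  sp <- spec3()   # f = mu * x2 * y1 = 0.06
  lp <- learning_params(mu = 1)
  lc <- learning_curve(sp, lp, A = 100, t = 0:60)
  expect_equal(lc$state1[1], 50)
  expect_equal(lc$state2[1], 30)
  expect_equal(lc$state1[2], 47)   # 50 * 0.94
  # asymptote A(x1 + x2) = 80, reached to machine precision far out
  expect_equal(learning_curve(sp, lp, 100, 500)$state2, 80, tolerance = 1e-9)
  expect_true(all(diff(lc$state2) > 0))
  expect_true(all(diff(diff(lc$state2)) < 0))  # negatively accelerated
})

test_that("ensemble learning reproduces the closed-form learning curve", {
  sp <- spec3()
  lp <- learning_params(mu = 1)
  A <- 200; B <- 400; t_units <- 8
  ens <- new_ensemble(sp, A, B, init = "equilibrium", seed = 31)
  ens <- learn_ensemble(ens, sp, lp, units = t_units, seed = 32)
  counts1 <- colSums(ens$states == 1L)
  pred <- learning_curve(sp, lp, A, t_units)
  se <- stats::sd(counts1) / sqrt(B)
  expect_lt(abs(mean(counts1) - pred$state1), 4 * se)
})
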