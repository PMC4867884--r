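test_that("constrained EM traces are monotone for several events", {
  set.seed(401)
  des <- simulation_design(N = 300L)
  sim <- simulate_hmm(des, seed = 41)
  init <- hmm(rep(1 / 3, 3), rand_stochastic(3),
              emission_gaussian(c(-1, 0, 1), rep(2, 3)))
  for (ev in list(event_at_most(3), event_exactly(5), event_at_most(12))) {
    fit <- constrained_em(init, sim$observations, event = ev, max_iter = 40)
    expect_true(all(diff(fit$trace) >= -1e-8))
  }
})

test_that("a vacuous constraint reproduces the unconstrained EM iterates", {
  set.seed(402)
  inst <- rand_instance(2L, 80L)
  init <- rand_hmm(2L)
  plain <- em_fit(init, inst$y, max_iter = 25)
  vac <- constrained_em(init, inst$y, event = event_at_most(80),
                        max_iter = 25)
  expect_equal(vac$trace, plain$trace, tolerance = 1e-9)
  expect_equal(vac$model$A, plain$model$A, tolerance = 1e-9)
  expect_equal(vac$model$emission$mean, plain$model$emission$mean,
               tolerance = 1e-9)
})

test_that("a one-segment constraint drives the transition matrix to identity", {
  des <- simulation_design()
  sim <- simulate_hmm(des, seed = 43)
  y <- sim$observations
  init <- hmm(rep(1 / 3, 3),
              matrix(1 / 12, 3, 3) + diag(3) * 0.75,
              emission_gaussian(seq(min(y) / 2, max(y) / 2, length.out = 3),
                                rep(var(y), 3)))
  fit <- constrained_em(init, y, event = event_at_most(1), max_iter = 200)
  offdiag <- fit$model$A - diag(diag(fit$model$A))
  expect_lt(sum(abs(offdiag)), 1e-6)
})

test_that("prospective fitting never trails the retrospective evaluation", {
  des <- simulation_design(N = 400L)
  sim <- simulate_hmm(des, seed = 44)
  y <- sim$observations
  init <- hmm(rep(1 / 3, 3),
              matrix(1 / 12, 3, 3) + diag(3) * 0.75,
              emission_gaussian(seq(min(y) / 2, max(y) / 2, length.out = 3),
                                rep(var(y), 3)))
  plain <- em_fit(init, y, tol = 1e-9, max_iter = 400)
  tab <- prospective_vs_retrospective(y, init, k_grid = c(2L, 5L, 10L, 400L),
                                      max_iter = 60, unconstrained = plain)
  expect_true(all(tab$gain >= -1e-8))
  # vacuous constraint: retrospective value is the unconstrained likelihood
  # and there is (numerically) nothing left to gain
  expect_equal(tab$retrospective[tab$k == 400L],
               as.numeric(logLik(plain)), tolerance = 1e-9)
  expect_lt(tab$gain[tab$k == 400L], 1e-3)
})

test_that("transition-matrix sparsity grows with the constraint level", {
  des <- simulation_design()
  sim <- simulate_hmm(des, seed = 45)
  y <- sim$observations
  init <- hmm(rep(1 / 3, 3),
              matrix(1 / 12, 3, 3) + diag(3) * 0.75,
              emission_gaussian(seq(min(y) / 2, max(y) / 2, length.out = 3),
                                rep(var(y), 3)))
  nnz <- vapply(c(1L, 5L, 20L, 50L), function(k) {
    fit <- constrained_em(init, y, event = event_at_most(k), max_iter = 80)
    sum(fit$model$A > 0.01)
  }, numeric(1))
  expect_true(all(diff(nnz) >= 0))
})

test_that("constrained Gibbs respects the event and is reproducible", {
  set.seed(406)
  inst <- rand_instance(2L, 30L)
  init <- rand_hmm(2L)
  ev <- event_at_most(4)
  g1 <- constrained_gibbs(inst$y, spec = counting_standard(), event = ev,
                          init = init, n_iter = 30, seed = 7, burnin = 5)
  g2 <- constrained_gibbs(inst$y, spec = counting_standard(), event = ev,
                          init = init, n_iter = 30, seed = 7, burnin = 5)
  expect_true(all(apply(g1$paths, 1, count_segments) <= 4L))
  expect_identical(g1$paths, g2$paths)
  expect_equal(g1$theta[[3]]$A, g2$theta[[3]]$A)
})

test_that("single-state Gibbs matches the conjugate posterior moments", {
  set.seed(407)
  y <- rnorm(150, mean = 2, sd = 1.5)
  init <- hmm(1, matrix(1), emission_gaussian(0, 1))
  pr <- prior_spec(m0 = 0, kappa0 = 0.01, a0 = 2, b0 = 2)
  g <- constrained_gibbs(y, prior = pr, event = event_at_most(1), init = init,
                         n_iter = 4000, seed = 8, burnin = 500)
  means <- vapply(g$theta, function(t) t$mean, numeric(1))
  vars <- vapply(g$theta, function(t) t$var, numeric(1))
  n <- length(y)
  kn <- pr$kappa0 + n
  mn <- (pr$kappa0 * pr$m0 + sum(y)) / kn
  an <- pr$a0 + n / 2
  bn <- pr$b0 + sum((y - mean(y))^2) / 2 +
    pr$kappa0 * n * (mean(y) - pr$m0)^2 / (2 * kn)
  expect_equal(mean(means), mn, tolerance = 0.02)
  expect_equal(mean(vars), bn / (an - 1), tolerance = 0.05)
})

test_that("an event impossible under the initial model is reported", {
  m <- hmm(c(1, 0), diag(2), emission_gaussian(c(0, 1), c(1, 1)))
  expect_error(constrained_em(m, rnorm(6), event = event_greater_than(3)),
               "zero probability")
})

test_that("constrained EM is robust to an uninformative transition init", {
  # with a uniform transition-matrix initialization, fitting under the true
  # segment count protects segmental classification relative to plain EM +
  # Viterbi on most replicates
  des <- simulation_design(N = 500L)
  wins <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    sim <- simulate_hmm(des, seed = 600 + r)
    y <- sim$observations
    k_true <- count_segments(sim$states)
    init <- hmm(rep(1 / 3, 3), matrix(1 / 3, 3, 3),
                emission_gaussian(seq(min(y) / 2, max(y) / 2, length.out = 3),
                                  rep(var(y), 3)))
    plain <- em_fit(init, y, max_iter = 60)
    err_plain <- classification_error(viterbi(plain$model, y)$path, sim$states)
    con <- constrained_em(init, y, event = event_at_most(k_true), max_iter = 60)
    path_con <- kseg_viterbi(con$model, y,
                             event = event_at_most(k_true))$path
    err_con <- classification_error(path_con, sim$states)
    if (err_con <= err_plain + 1e-12) wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.6)
})
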