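test_that("uniform model with shared emissions gives the exact count posterior", {
  m <- hmm(c(0.5, 0.5), matrix(0.5, 2, 2), emission_gaussian(c(0, 0), c(1, 1)))
  kf <- kseg_forward(m, c(0.3, -1, 2), k_max = 3)
  # 8 equiprobable paths: 2 constant, 4 with two segments, 2 alternating
  expect_equal(kf$p, c(0.25, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(kf$tail, 0)
  expect_equal(sum(kf$p) + kf$tail, 1, tolerance = 1e-12)
})

test_that("count posteriors match enumeration for all counting variants", {
  set.seed(301)
  especs <- list(standard = counting_standard(),
                 excursion = counting_excursion(1L),
                 restricted = counting_excursion(1L, restricted = TRUE))
  for (rep in 1:4) {
    inst <- rand_instance(3L, 8L)
    gmu <- as.integer(runif(3) < 0.5)
    gC <- matrix(as.integer(runif(9) < 0.5), 3, 3); diag(gC) <- 0L
    specs <- c(especs, list(generalized = counting_generalized(gmu, gC)))
    for (spec in specs) {
      en <- enumerate_posterior(inst$model, inst$y, spec)
      kf <- kseg_forward(inst$model, inst$y, spec, k_max = 8)
      want <- vapply(kf$k, function(k) {
        nm <- as.character(k)
        if (nm %in% names(en$count_posterior)) en$count_posterior[[nm]] else 0
      }, numeric(1))
      expect_equal(kf$p, want, tolerance = 1e-10)
      expect_equal(sum(kf$p) + kf$tail, 1, tolerance = 1e-10)
    }
  }
})

test_that("constrained MAP matches enumerated argmax for every event type", {
  set.seed(302)
  for (rep in 1:3) {
    inst <- rand_instance(2L, 8L)
    en <- enumerate_posterior(inst$model, inst$y)
    events <- c(lapply(1:8, event_exactly),
                list(event_at_most(2), event_between(2, 4),
                     event_greater_than(3), event_greater_than(6)))
    for (ev in events) {
      want <- enum_event_map(en, ev)
      got <- kseg_viterbi(inst$model, inst$y, event = ev)
      expect_equal(got$path, want$path)
      expect_equal(got$log_score, want$log_score, tolerance = 1e-10)
      expect_true(event_holds(ev, got$count))
    }
  }
})

test_that("constrained MAP under excursion counting matches enumeration", {
  set.seed(303)
  inst <- rand_instance(3L, 7L)
  for (spec in list(counting_excursion(1:2),
                    counting_excursion(3L, restricted = TRUE))) {
    en <- enumerate_posterior(inst$model, inst$y, spec)
    for (k in 0:2) {
      ev <- event_exactly(k)
      want <- enum_event_map(en, ev)
      if (is.null(want)) {
        expect_error(kseg_viterbi(inst$model, inst$y, spec, ev),
                     class = "ksegment_infeasible")
      } else {
        got <- kseg_viterbi(inst$model, inst$y, spec, ev)
        expect_equal(got$path, want$path)
        expect_equal(got$log_score, want$log_score, tolerance = 1e-10)
      }
    }
  }
})

test_that("one-segment and N-segment constraints have forced structure", {
  set.seed(304)
  inst <- rand_instance(3L, 9L)
  m <- inst$model; y <- inst$y
  # {c=1}: best constant path, closed form over M candidates
  logB <- ksegment:::log_emissions(m, y)
  const_scores <- vapply(1:3, function(s)
    log(m$pi0[s]) + 8 * log(m$A[s, s]) + sum(logB[, s]), numeric(1))
  got <- kseg_viterbi(m, y, event = event_exactly(1))
  expect_equal(got$path, rep(which.max(const_scores), 9L))
  expect_equal(got$log_score, max(const_scores), tolerance = 1e-10)
  # {c=N}: strictly alternating path
  gotN <- kseg_viterbi(m, y, event = event_exactly(9))
  expect_true(all(diff(gotN$path) != 0))
  # no off-diagonal transitions at all -> alternation impossible
  frozen <- hmm(m$pi0, diag(3), m$emission)
  expect_error(kseg_viterbi(frozen, y, event = event_exactly(9)),
               class = "ksegment_infeasible")
})

test_that("the summary contains the Viterbi path and is self-consistent", {
  set.seed(305)
  score_of <- function(m, y, path) {
    logB <- ksegment:::log_emissions(m, y)
    s <- log(m$pi0[path[1]]) + logB[1, path[1]]
    for (n in 2:length(path))
      s <- s + log(m$A[path[n - 1], path[n]]) + logB[n, path[n]]
    s
  }
  for (rep in 1:4) {
    inst <- rand_instance(3L, 30L)
    sm <- kseg_summary(inst$model, inst$y, k_max = 6)
    vt <- viterbi(inst$model, inst$y)
    vc <- count_segments(vt$path)
    entry <- if (vc <= 6) sm$paths[which(sm$k == vc), ] else sm$absorbing_path
    expect_equal(as.integer(entry), vt$path)
    for (i in seq_along(sm$k)) {
      if (!is.finite(sm$scores[i])) next
      p <- as.integer(sm$paths[i, ])
      expect_identical(count_segments(p), as.integer(sm$k[i]))
      expect_equal(score_of(inst$model, inst$y, p), sm$scores[i],
                   tolerance = 1e-10)
      # constrained scores never beat the unconstrained optimum
      expect_lte(sm$scores[i], vt$log_score + 1e-12)
    }
  }
})

test_that("summary entries match the event-constrained enumeration argmax", {
  set.seed(306)
  inst <- rand_instance(2L, 8L)
  en <- enumerate_posterior(inst$model, inst$y)
  sm <- kseg_summary(inst$model, inst$y, k_max = 5)
  for (i in seq_along(sm$k)) {
    want <- enum_event_map(en, event_exactly(sm$k[i]))
    expect_equal(as.integer(sm$paths[i, ]), want$path)
    expect_equal(sm$scores[i], want$log_score, tolerance = 1e-10)
  }
  wantA <- enum_event_map(en, event_greater_than(5))
  expect_equal(sm$absorbing_path, wantA$path)
  expect_equal(sm$absorbing_score, wantA$log_score, tolerance = 1e-10)
})

test_that("consecutive summary paths are not always nested splits", {
  # coarse-to-fine segmentations are each globally optimal for their own k;
  # unlike recursive binary splitting, the k+1-segment path need not refine
  # the k-segment one -- exhibit a random instance where it does not
  set.seed(307)
  found <- FALSE
  for (trial in 1:200) {
    inst <- rand_instance(3L, 25L)
    sm <- kseg_summary(inst$model, inst$y, k_max = 6)
    for (i in seq_len(length(sm$k) - 1L)) {
      if (!is.finite(sm$scores[i]) || !is.finite(sm$scores[i + 1L])) next
      a <- path_to_segments(sm$paths[i, ])
      b <- path_to_segments(sm$paths[i + 1L, ])
      # nested split: every boundary of a is a boundary of b
      if (!all(a$end %in% b$end)) { found <- TRUE; break }
    }
    if (found) break
  }
  expect_true(found)
})

test_that("constrained sampling draws from the event-conditioned posterior", {
  set.seed(308)
  inst <- rand_instance(2L, 4L)
  en <- enumerate_posterior(inst$model, inst$y)
  ev <- event_exactly(2)
  draws <- kseg_sample(inst$model, inst$y, event = ev, n_samples = 20000,
                       seed = 5)
  expect_true(all(apply(draws, 1, count_segments) == 2L))
  cond <- enum_event_posterior(en, ev)
  obs <- table(factor(path_key(draws), levels = path_key(cond$paths)))
  expect_equal(sum(obs), 20000L)  # nothing outside the event
  chi <- suppressWarnings(chisq.test(as.numeric(obs), p = cond$prob))
  expect_gt(chi$p.value, 0.001)
  # identical seeds give identical streams
  expect_identical(draws,
                   kseg_sample(inst$model, inst$y, event = ev,
                               n_samples = 20000, seed = 5))
})

test_that("a vacuous constraint reproduces unconstrained inference", {
  set.seed(309)
  inst <- rand_instance(3L, 10L)
  fb <- forward_backward(inst$model, inst$y)
  cm <- constrained_marginals(inst$model, inst$y, event = event_at_most(10))
  expect_lt(max(abs(cm$site - fb$marginals)), 1e-10)
  expect_equal(cm$log_evidence_event, fb$log_evidence, tolerance = 1e-10)
  # vacuous-range sampling matches the enumerated unconstrained posterior
  inst <- rand_instance(2L, 5L)
  en <- enumerate_posterior(inst$model, inst$y)
  draws <- kseg_sample(inst$model, inst$y, event = event_between(1, 5),
                       n_samples = 20000, seed = 9)
  obs <- table(factor(path_key(draws), levels = path_key(en$paths)))
  p <- exp(en$log_joint - en$log_evidence)
  keep <- p > 1e-9
  chi <- suppressWarnings(
    chisq.test(as.numeric(obs[keep]), p = p[keep] / sum(p[keep])))
  expect_gt(chi$p.value, 0.001)
})

test_that("constrained marginals match enumeration and are consistent", {
  set.seed(310)
  inst <- rand_instance(2L, 6L)
  en <- enumerate_posterior(inst$model, inst$y)
  ev <- event_at_most(2)
  cm <- constrained_marginals(inst$model, inst$y, event = ev)
  cond <- enum_event_posterior(en, ev)
  site <- vapply(1:2, function(m) colSums(cond$prob * (cond$paths == m)),
                 numeric(6))
  expect_lt(max(abs(cm$site - site)), 1e-10)
  for (n in 2:6) {
    pairn <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2)
      pairn[i, j] <- sum(cond$prob[cond$paths[, n - 1] == i & cond$paths[, n] == j])
    expect_lt(max(abs(cm$pair[n - 1, , ] - pairn)), 1e-10)
    # both margins of the pairwise table agree with the site marginals
    expect_equal(colSums(cm$pair[n - 1, , ]), cm$site[n, ], tolerance = 1e-10)
    expect_equal(rowSums(cm$pair[n - 1, , ]), cm$site[n - 1, ], tolerance = 1e-10)
  }
})

test_that("infeasible events raise a typed error, not a silent fallback", {
  m <- hmm(c(1, 0), diag(2), emission_gaussian(c(0, 1), c(1, 1)))
  y <- rnorm(5)
  expect_error(kseg_viterbi(m, y, event = event_exactly(2)),
               class = "ksegment_infeasible")
  expect_error(kseg_sample(m, y, event = event_exactly(2), n_samples = 1,
                           seed = 1),
               class = "ksegment_infeasible")
  expect_error(constrained_marginals(m, y, event = event_greater_than(1)),
               class = "ksegment_infeasible")
  # k = 0 only makes sense for counting variants that can start at zero
  expect_error(kseg_viterbi(m, y, event = event_exactly(0)), "infeasible")
  gspec <- counting_generalized(c(0, 1), matrix(c(0, 1, 0, 0), 2, byrow = TRUE))
  got <- kseg_viterbi(m, y, spec = gspec, event = event_exactly(0))
  expect_identical(got$count, 0L)
})

test_that("mixture decomposition: count-resolved evidence sums to p(y)", {
  set.seed(311)
  for (rep in 1:3) {
    inst <- rand_instance(3L, 200L)
    kf <- kseg_forward(inst$model, inst$y, k_max = 200)
    fb <- forward_backward(inst$model, inst$y)
    expect_equal(ksegment:::logsumexp(kf$log_joint), fb$log_evidence,
                 tolerance = 1e-8)
    expect_equal(kf$tail, 0)
  }
})
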