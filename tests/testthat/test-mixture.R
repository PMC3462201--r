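test_that("component weights follow pi * (1-p)^x * p^(m-x) without underflow", {
  # the no-hit weight that justifies truncating absent entries
  expect_equal(signif(component_weight(0, 35, 1, 0.02), 2), 3.4e-60)
  expect_equal(component_weight(0, 35, 1, 0.02), 0.02^35, tolerance = 1e-12)
  # error-free perfect match carries exactly the prior
  expect_equal(component_weight(100, 100, 0.4, 0), 0.4)
  # zero prior kills the component whatever the alignment
  expect_equal(component_weight(50, 60, 0, 0.05), 0)
  # a long perfect read must not underflow to zero
  expect_gt(component_weight(500, 500, 1e-3, 0.01), 0)
  expect_error(component_weight(101, 100, 0.5, 0.05), "x <= m")
})

test_that("log-likelihood matches a brute-force dense summation", {
  # K = 1, all perfect matches, p = 0: every read has probability 1
  M1 <- scoring_matrix(make_hits(c("r1", "r2"), c("g1", "g1"),
                                 c(50, 70), c(50, 70)))
  expect_equal(mixture_loglik(M1, 1, 0), 0)

  # two symmetric genomes: per-read probability is (1-p)^x p^(m-x)
  M2 <- scoring_matrix(make_hits(rep(c("r1", "r2"), each = 2),
                                 rep(c("g1", "g2"), 2),
                                 rep(40L, 4), rep(38L, 4)))
  p <- 0.03
  expect_equal(mixture_loglik(M2, c(0.5, 0.5), p),
               2 * (38 * log(1 - p) + 2 * log(p)))

  # random toy matrices against the entry-by-entry oracle
  set.seed(21)
  for (rep in 1:5) {
    h <- random_instance(8, 3)
    M <- scoring_matrix(h)
    pi <- c(0.2, 0.5, 0.3)
    expect_equal(mixture_loglik(M, pi, 0.04), brute_loglik(M, pi, 0.04),
                 tolerance = 1e-10)
  }
})

test_that("E-step responsibilities normalise correctly", {
  # a single-hit read gets posterior 1
  M <- scoring_matrix(make_hits("r1", "g1", 100, 95))
  es <- taxmix:::.e_step_core(M$i, M$j, M$x, M$m, 1L, 1, 0.05)
  expect_equal(es$z, 1)

  # symmetric hits split 50/50
  M2 <- scoring_matrix(make_hits(c("r1", "r1"), c("g1", "g2"),
                                 c(100, 100), c(95, 95)))
  es2 <- taxmix:::.e_step_core(M2$i, M2$j, M2$x, M2$m, 1L, c(0.5, 0.5), 0.05)
  expect_equal(es2$z, c(0.5, 0.5))

  # hand-computed ratio: x = (97, 90), m = 100, p = 0.02 ->
  # w1/w2 = (0.98/0.02)^7, z1 = 1 / (1 + (0.02/0.98)^7)
  M3 <- scoring_matrix(make_hits(c("r1", "r1"), c("g1", "g2"),
                                 c(100, 100), c(97, 90)))
  es3 <- taxmix:::.e_step_core(M3$i, M3$j, M3$x, M3$m, 1L, c(0.5, 0.5), 0.02)
  r <- (0.02 / 0.98)^7                     # w2/w1 after the common factors cancel
  expect_equal(es3$z, c(1 / (1 + r), r / (1 + r)), tolerance = 1e-12)

  # rows always sum to one on random instances
  set.seed(5)
  h <- random_instance(20, 4)
  M4 <- scoring_matrix(h)
  es4 <- taxmix:::.e_step_core(M4$i, M4$j, M4$x, M4$m, length(M4$reads),
                               rep(0.25, 4), 0.03)
  expect_equal(unname(rowsum(es4$z, M4$i)[, 1]), rep(1, length(M4$reads)),
               tolerance = 1e-9)
})

test_that("M-step recovers the closed-form maximisers", {
  M <- scoring_matrix(make_hits(c("r1", "r1", "r2", "r2"),
                                c("g1", "g2", "g1", "g2"),
                                c(100, 100, 80, 80), c(95, 90, 78, 70)))
  # all responsibility on genome 1
  ms <- taxmix:::.m_step_core(M$i, M$j, M$x, M$m, c(1, 0, 1, 0), 2L, 2L)
  expect_equal(ms$pi, c(1, 0))
  # weighted mismatch fraction, by hand: z = (.8,.2,.6,.4)
  z <- c(0.8, 0.2, 0.6, 0.4)
  ms2 <- taxmix:::.m_step_core(M$i, M$j, M$x, M$m, z, 2L, 2L)
  num <- 0.8 * (100 - 95) + 0.2 * (100 - 90) + 0.6 * (80 - 78) + 0.4 * (80 - 70)
  den <- 0.8 * 100 + 0.2 * 100 + 0.6 * 80 + 0.4 * 80
  expect_equal(ms2$p, num / den)
  expect_equal(ms2$pi, c((0.8 + 0.6) / 2, (0.2 + 0.4) / 2))
  # perfect matches give p = 0
  Mp <- scoring_matrix(make_hits(c("r1", "r2"), c("g1", "g1"),
                                 c(60, 70), c(60, 70)))
  msp <- taxmix:::.m_step_core(Mp$i, Mp$j, Mp$x, Mp$m, c(1, 1), 2L, 1L)
  expect_equal(msp$p, 0)
})

test_that("EM solves degenerate and unambiguous cases in closed form", {
  # single genome: pi = 1, p = pooled mismatch fraction
  M <- scoring_matrix(make_hits(c("r1", "r2", "r3"), "g1",
                                c(100, 100, 100), c(95, 97, 96)))
  fit <- taxmix(M)
  expect_equal(unname(fit$pi), 1)
  expect_equal(fit$p, (5 + 3 + 4) / 300, tolerance = 1e-8)
  expect_true(fit$converged)

  # two genomes, each read hits exactly one: pi = hit fractions
  M2 <- scoring_matrix(make_hits(sprintf("r%d", 1:10),
                                 rep(c("g1", "g2"), c(7, 3)),
                                 rep(100L, 10), rep(96L, 10)))
  fit2 <- taxmix(M2)
  expect_equal(unname(fit2$pi), c(0.7, 0.3), tolerance = 1e-6)
  expect_equal(fit2$p, 0.04, tolerance = 1e-6)
})

test_that("EM attains the grid-search maximum of the likelihood", {
  set.seed(31)
  for (K in 2:3) {
    h <- random_instance(30, K, p = 0.04)
    M <- scoring_matrix(h)
    fit <- taxmix(M)
    grid_best <- grid_search_loglik(M, pi_step = if (K == 2) 0.01 else 0.02)
    expect_gte(fit$loglik, grid_best - 1e-6)
  }
})

test_that("the log-likelihood trace never decreases", {
  set.seed(17)
  for (rep in 1:20) {
    h <- random_instance(sample(10:30, 1), sample(2:4, 1), p = runif(1, 0.01, 0.1))
    fit <- suppressWarnings(taxmix(scoring_matrix(h)))
    expect_true(all(diff(fit$trace) >= -1e-8))
  }
})

test_that("sparse and dense EM agree to near machine precision", {
  set.seed(23)
  for (rep in 1:5) {
    h <- random_instance(25, 3)
    M <- scoring_matrix(h)
    fit <- taxmix(M)
    ora <- dense_em(M)
    expect_equal(unname(fit$pi), ora$pi, tolerance = 1e-10)
    expect_equal(fit$p, ora$p, tolerance = 1e-10)
  }
})

test_that("permuting genome order permutes pi and leaves p unchanged", {
  set.seed(41)
  h <- random_instance(40, 3)
  M <- scoring_matrix(h)
  fit <- taxmix(M)
  # reverse first-appearance order by reversing hit rows
  h_rev <- h[rev(seq_len(nrow(h))), ]
  fit_rev <- taxmix(scoring_matrix(h_rev))
  expect_equal(fit_rev$pi[names(fit$pi)], fit$pi, tolerance = 1e-8)
  expect_equal(fit_rev$p, fit$p, tolerance = 1e-10)
})

test_that("EM recovers generating parameters on model-simulated data", {
  cfg <- community_config(genomes = 4, pi = c(0.4, 0.3, 0.2, 0.1), p = 0.03,
                          n_reads = 8000, cross_hit_prob = 0.1,
                          cross_hit_penalty = 5, no_hit_prob = 0.02, seed = 3)
  sim <- simulate_hits(cfg)
  fit <- taxmix(scoring_matrix(sim$hits))
  expect_lt(max(abs(fit$pi[cfg$genomes] - cfg$pi)), 0.02)
  expect_lt(abs(fit$p - cfg$p), 0.005)
})

test_that("pathological parameter starts are caught, not silently wrong", {
  M <- scoring_matrix(make_hits(c("r1", "r2"), c("g1", "g1"),
                                c(50, 60), c(48, 55)))
  # p = 0 with imperfect matches leaves every component at zero probability
  expect_error(mixture_loglik(M, 1, 0), "zero probability")
  expect_error(taxmix(M, epsilon = 0), "epsilon")
  expect_error(taxmix(M, pi0 = c(0.5, 0.5)), "proportions")
})

test_that("an iteration cap returns an unconverged fit with a warning", {
  set.seed(2)
  h <- random_instance(30, 3)
  M <- scoring_matrix(h)
  expect_warning(fit <- taxmix(M, max_iter = 2L), "without converging")
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 2L)
  expect_error(assign_reads(fit), "accept_unconverged")
})

test_that("fit methods expose coefficients, likelihood and serialisation", {
  set.seed(8)
  M <- scoring_matrix(random_instance(20, 2))
  fit <- taxmix(M)
  co <- coef(fit)
  expect_named(co, c(paste0("pi.", names(fit$pi)), "p"))
  expect_equal(unname(co[["p"]]), fit$p)
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), fit$loglik)
  s <- summary(fit)
  expect_true(all(s$table$detected == (s$table$pi >= 1 / (10 * 20))))
  f <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$pi, unname(fit$pi), tolerance = 1e-12)
  expect_equal(back$p, fit$p, tolerance = 1e-12)
  # responsibilities from predict() match the stored fit
  pr <- predict(fit)
  expect_equal(pr$z, fit$z)
})
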