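test_that("PCM category probabilities match direct evaluation", {
  # hand case: m = 2, delta = (-1, 1), theta = 0
  expect_equal(drop(pcm_prob(0, c(-1, 1))),
               oracle_pcm_prob(0, c(-1, 1)), tolerance = 1e-12)
  # dichotomous PCM is the Rasch/logistic model everywhere
  th <- seq(-6, 6, by = 0.5)
  expect_equal(pcm_prob(th, 0.7)[, 2], plogis(th - 0.7), tolerance = 1e-12)
  # random cases: agreement with the oracle and exact normalisation
  set.seed(1)
  for (i in 1:20) {
    m <- sample(1:5, 1)
    d <- rnorm(m); t0 <- rnorm(1, sd = 3)
    expect_equal(drop(pcm_prob(t0, d)), oracle_pcm_prob(t0, d),
                 tolerance = 1e-10)
    expect_equal(sum(pcm_prob(t0, d)), 1, tolerance = 1e-12)
  }
  # numerically stable far out in the tails
  expect_equal(sum(pcm_prob(40, c(-1, 1))), 1, tolerance = 1e-12)
  expect_equal(sum(pcm_prob(-40, c(-1, 1))), 1, tolerance = 1e-12)
})

test_that("expected score has the right limits and is increasing", {
  d <- c(-1, 0.2, 1.3)
  expect_equal(pcm_expected(-40, d), 0, tolerance = 1e-10)
  expect_equal(pcm_expected(40, d), 3, tolerance = 1e-10)
  expect_equal(pcm_expected(0, 0), 0.5, tolerance = 1e-12)
  th <- seq(-8, 8, length.out = 100)
  expect_true(all(diff(pcm_expected(th, d)) > 0))
})

test_that("pcm_draw frequencies match the model distribution", {
  set.seed(2)
  y <- pcm_draw(rep(0, 10000), 0)   # m = 1, delta = 0: P(Y=1) = 0.5
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(y) - 0.5), 3 * se)
})

test_that("pairwise conditional likelihood equals brute-force enumeration", {
  toy <- matrix(c(0, 1, 1, 1, 2, 0, 1, 2), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("i1", "i2")))
  d <- list(i1 = c(-0.5, 0.2), i2 = c(0.1, 0.6))
  expect_equal(pce_loglik(d, toy), oracle_pce_loglik(d, toy),
               tolerance = 1e-12)
  # with a missing entry the affected pair drops out
  toy_na <- toy; toy_na[2, 1] <- NA
  expect_equal(pce_loglik(d, toy_na), oracle_pce_loglik(d, toy_na),
               tolerance = 1e-12)
})

test_that("PCE on symmetric dichotomous data gives mirrored thresholds", {
  y <- matrix(c(0, 1, 1, 0, 0, 0, 1, 1), ncol = 2, byrow = FALSE)
  y <- y[rep(1:4, 25), ]
  colnames(y) <- c("p", "q")
  fit <- pce_fit(y)
  expect_equal(fit$delta$p, -fit$delta$q, tolerance = 1e-6)
  expect_equal(sum(unlist(fit$delta)), 0, tolerance = 1e-8)
})

test_that("PCE recovers thresholds and respects the sum-zero constraint", {
  set.seed(3)
  bank <- bank4()
  th <- rnorm(2000, 0, 1.2)
  yy <- draw_matrix(th, bank)
  fit <- pce_fit(yy)
  expect_equal(fit$convergence, 0L)
  expect_equal(sum(unlist(fit$delta)), 0, tolerance = 1e-8)
  truth <- unlist(center_bank(bank)$delta)
  expect_lt(sqrt(mean((unlist(fit$delta) - truth)^2)), 0.15)
})

test_that("PCE is consistent under ignorable (MCAR) missingness", {
  set.seed(4)
  bank <- bank4()
  th <- rnorm(4000, 0, 1.2)
  yy <- draw_matrix(th, bank)
  y_mcar <- yy
  y_mcar[matrix(runif(length(yy)) < 0.2, nrow(yy))] <- NA
  full <- pce_fit(yy)
  part <- pce_fit(y_mcar)
  expect_lt(max(abs(item_locations(full) - item_locations(part))), 0.1)
})

test_that("unobserved categories are collapsed with a warning", {
  set.seed(5)
  y <- cbind(a = sample(c(0L, 1L, 3L), 200, TRUE),  # category 2 unseen
             b = sample(0:2, 200, TRUE),
             c = sample(0:2, 200, TRUE))
  expect_warning(fit <- pce_fit(y, m = c(a = 3L, b = 2L, c = 2L)),
                 "collapsed")
  expect_named(fit$collapse_maps, "a")
  expect_length(fit$delta$a, 2L)   # 3 observed categories -> m = 2
})

test_that("EAP estimates behave and are quadrature-stable", {
  bank <- bank4()
  y <- rbind(rep(0, 5), rep(3, 5), rep(NA, 5), c(1, 2, NA, 0, 3))
  colnames(y) <- names(bank$delta)
  e <- eap_estimate(y, bank, 0, 1.5)
  expect_true(is.na(e$eap[3]))
  expect_lt(e$eap[1], e$eap[2])
  e2 <- eap_estimate(y, bank, 0, 1.5, nodes = 121L)
  expect_equal(e$eap[-3], e2$eap[-3], tolerance = 1e-6)
})
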