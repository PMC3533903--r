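test_that("tau reproduces the published explained-variance rates", {
  pub <- published_sf36_estimates()
  f <- pub$footers
  taus <- mapply(tau_explained, f$sigma2_0, f$k0, f$sigma2, f$k, f$n)
  expect_equal(round(100 * taus), c(13, 27, 5), ignore_attr = TRUE)
  expect_equal(tau_explained(1.5, 10, 1.5, 10, 1000), 0)
  expect_error(tau_explained(-1, 10, 1.5, 10, 1000), "positive")
})

test_that("marginal-ML calibration recovers thresholds and variance", {
  set.seed(41)
  bank <- bank4()
  th <- rnorm(4000, 0, sqrt(1.5))
  y <- draw_matrix(th, bank)
  cal <- calibrate_pcm(y)
  expect_equal(cal$convergence, 0L)
  expect_lt(abs(cal$sigma2 - 1.5), 0.15)
  expect_lt(max(abs(unlist(cal$bank$delta) - unlist(bank$delta))), 0.2)
  expect_equal(cal$AIC, 2 * cal$k - 2 * cal$logL, tolerance = 1e-10)
  # cross-estimator agreement: PCE (relative) vs marginal ML, compared on
  # the sum-zero scale
  pce <- pce_fit(y)
  cal_c <- unlist(center_bank(cal$bank)$delta)
  expect_lt(max(abs(cal_c - unlist(pce$delta))), 0.1)
})

test_that("degenerate calibrations are rejected", {
  y <- cbind(a = rep(0:1, 50))
  expect_error(calibrate_pcm(y), "unidentifiable")
})

test_that("the latent regression nests the calibration model", {
  set.seed(42)
  bank <- bank4()
  th <- rnorm(1500, 0, 1.1)
  y <- draw_matrix(th, bank)
  d <- data.frame(g = factor(sample(c("A", "B"), 1500, TRUE)))
  m0 <- lrpcm(y, d, mean = ~ 1, var = ~ 1, bank = bank, hessian = FALSE)
  expect_lt(abs(m0$beta[[1]]), 3 * 1.1 / sqrt(1500))
  m1 <- lrpcm(y, d, mean = ~ g, var = ~ 1, bank = bank, hessian = FALSE)
  expect_gte(m1$logL, m0$logL - 1e-6)   # logL never drops with a covariate
  expect_equal(m1$AIC, 2 * m1$k - 2 * m1$logL, tolerance = 1e-10)
})

test_that("the marginal likelihood is stable under node refinement", {
  set.seed(43)
  bank <- bank4()
  d <- data.frame(g = factor(sample(c("A", "B"), 800, TRUE)))
  th <- rnorm(800, 0.3 - 0.5 * (d$g == "B"), 1)
  y <- draw_matrix(th, bank)
  f41 <- lrpcm(y, d, mean = ~ g, var = ~ g, bank = bank, nodes = 41L,
               hessian = FALSE)
  f82 <- lrpcm(y, d, mean = ~ g, var = ~ g, bank = bank, nodes = 82L,
               hessian = FALSE)
  expect_lt(abs(f41$logL - f82$logL), 1e-4)
  expect_equal(coef(f41), coef(f82), tolerance = 1e-4)
  # the default order trades a ~1e-3 absolute logL offset for speed but
  # leaves the estimates essentially unchanged
  f21 <- lrpcm(y, d, mean = ~ g, var = ~ g, bank = bank, nodes = 21L,
               hessian = FALSE)
  expect_equal(coef(f21), coef(f82), tolerance = 2e-3)
})

test_that("heteroscedastic effects are recovered with sane Wald errors", {
  set.seed(44)
  bank <- bank4()
  N <- 4000
  d <- data.frame(g = factor(sample(c("A", "B"), N, TRUE)))
  th <- rnorm(N, 0.3 - 0.5 * (d$g == "B"), sqrt(1.4 - 0.4 * (d$g == "B")))
  y <- draw_matrix(th, bank)
  fit <- lrpcm(y, d, mean = ~ g, var = ~ g, bank = bank)
  expect_lt(abs(fit$beta[["gB"]] + 0.5), 3 * fit$se[["gB"]])
  expect_lt(abs(fit$gamma[["gB"]] + 0.4), 3 * fit$se[["gB"]])
  s <- summary(fit)
  expect_true(all(c("section", "term", "estimate", "se", "z", "p") %in%
                    names(s$coefficients)))
  expect_lt(s$coefficients$p[s$coefficients$term == "gB" &
                               s$coefficients$section == "mean"], 0.001)
})

test_that("simulate/predict/residuals methods are coherent", {
  set.seed(45)
  bank <- bank4()
  d <- data.frame(g = factor(rep(c("A", "B"), each = 300)))
  th <- rnorm(600, 0.4 - 0.6 * (d$g == "B"), 1)
  y <- draw_matrix(th, bank)
  fit <- lrpcm(y, d, mean = ~ g, var = ~ 1, bank = bank, hessian = FALSE)
  mu <- predict(fit, type = "mean")
  expect_equal(unique(round(diff(range(mu)), 6)),
               round(abs(fit$beta[["gB"]]), 6))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_equal(dim(sims[[1]]), dim(y))
  expect_false(identical(sims[[1]], sims[[2]]))
  r <- residuals(fit)
  expect_lt(abs(mean(r)), 0.1)
})

test_that("backward selection drops noise and keeps real effects", {
  set.seed(46)
  bank <- bank4()
  N <- 2500
  d <- data.frame(g = factor(sample(c("A", "B"), N, TRUE)),
                  noise = factor(sample(c("u", "v"), N, TRUE)))
  th <- rnorm(N, 0.3 - 0.5 * (d$g == "B"), 1.1)
  y <- draw_matrix(th, bank)
  sel <- backward_select(y, d, bank, mean_terms = c("g", "noise"),
                         var_terms = "noise")
  expect_true("g" %in% sel$mean_terms)
  expect_false("noise" %in% sel$mean_terms)
  expect_length(sel$var_terms, 0L)
  expect_true(all(c("phase", "term", "p") %in% names(sel$removed)))
  # no candidates: intercept-only fit returned unchanged
  sel0 <- backward_select(y, d, bank, mean_terms = character())
  expect_length(sel0$mean_terms, 0L)
  expect_equal(sel0$fit$k, 2L)
})

test_that("interactions must leave before their main effects", {
  terms <- c("a", "b", "a:b")
  rem <- pcmreg:::hierarchy_removable(terms)
  expect_equal(rem, c(FALSE, FALSE, TRUE))
  expect_true(all(pcmreg:::hierarchy_removable(c("a", "b"))))
})

test_that("quantitative age recoding extracts integer score ratios", {
  r1 <- recode_age_quantitative(c(0, -0.6, -1.2, -2.4, -3.6, -4.8, -6.0))
  expect_equal(unname(r1$scores), c(0, 1, 2, 4, 6, 8, 10))
  expect_equal(r1$slope, -0.6, tolerance = 1e-9)
  r2 <- recode_age_quantitative(c(0, -1, -2, -3))
  expect_equal(unname(r2$scores), 0:3)
  expect_error(recode_age_quantitative(c(0, 0, 0)), "refused")
  expect_warning(recode_age_quantitative(c(0, -0.5, -0.2, -1)),
                 "not monotone")
  # survey-style series needing a doubled base unit
  gh <- c(0, -0.07, -0.42, -0.59, -0.84, -1.12, -1.40)
  expect_equal(unname(recode_age_quantitative(gh)$scores),
               c(0, 2, 12, 17, 24, 32, 40))
})

test_that("profile deviations combine main effects and interactions", {
  co <- c(Ager = -0.596, Women = -1.1154, `Women:Ager` = 0.0667)
  expect_equal(profile_deviation(co, list(Ager = 5), list(Ager = 5)), 0)
  expect_equal(profile_deviation(co, list(Ager = 10), list(Ager = 0)),
               -5.96)
  expect_equal(
    profile_deviation(co, list(Ager = 10, Women = 1),
                      list(Ager = 0, Women = 1)),
    (-0.596 + 0.0667) * 10)
  # the lrpcm method agrees with the design-based prediction
  set.seed(47)
  bank <- bank4()
  d <- data.frame(q = sample(0:3, 600, TRUE))
  th <- rnorm(600, -0.3 * d$q, 1)
  y <- draw_matrix(th, bank)
  fit <- lrpcm(y, d, mean = ~ q, var = ~ 1, bank = bank, hessian = FALSE)
  expect_equal(profile_deviation(fit, data.frame(q = 3), data.frame(q = 0)),
               3 * fit$beta[["q"]], tolerance = 1e-10)
})
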