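small_config <- function(N = 1000, ...) {
  sim_config(N = N, bank = bank4(),
             covariate_levels = list(
               gender = c(Men = 0.5, Women = 0.5),
               age_band = c(young = 0.4, mid = 0.35, old = 0.25)),
             transform = function(d) { d$ager <- (as.integer(d$age_band) - 1);
                                       d },
             mean_formula = ~ gender + ager, var_formula = ~ gender,
             beta = c(genderWomen = -0.4, ager = -0.3),
             gamma = c(genderWomen = -0.3),
             mu_star = 0.2, sigma2_star = 1.2, ...)
}

test_that("covariate simulation hits the requested frequencies", {
  cfg <- small_config(N = 20000, seed = 11)
  set.seed(cfg$seed)
  cov <- simulate_covariates(cfg)
  se <- sqrt(0.25 / 20000)
  expect_lt(abs(mean(cov$gender == "Men") - 0.5), 3 * se)
  se_y <- sqrt(0.4 * 0.6 / 20000)
  expect_lt(abs(mean(cov$age_band == "young") - 0.4), 3 * se_y)
  expect_equal(nrow(simulate_covariates(small_config(N = 0))), 0L)
  deg <- small_config(N = 50)
  deg$covariate_levels$gender <- c(Men = 1, Women = 0)
  set.seed(1)
  expect_true(all(simulate_covariates(deg)$gender == "Men"))
})

test_that("latent traits follow the configured mean/variance structure", {
  cfg <- small_config(N = 20000, seed = 12)
  cfg$beta <- c(genderWomen = 0.5, ager = 0)
  cfg$gamma <- c(genderWomen = 0)
  cfg$mu_star <- 0; cfg$sigma2_star <- 1
  set.seed(cfg$seed)
  cov <- simulate_covariates(cfg)
  lat <- simulate_latent(cfg, cov)
  w <- cov$gender == "Women"
  se_diff <- sqrt(1 / sum(w) + 1 / sum(!w))
  expect_lt(abs((mean(lat$theta[w]) - mean(lat$theta[!w])) - 0.5),
            3 * se_diff)
  expect_lt(abs(mean(lat$theta[!w])), 3 / sqrt(sum(!w)))
  expect_lt(abs(var(lat$theta[!w]) - 1), 3 * sqrt(2 / sum(!w)))
})

test_that("non-positive latent variances are rejected", {
  cfg <- small_config(N = 200, seed = 13)
  cfg$gamma <- c(genderWomen = -1.3)   # 1.2 - 1.3 < 0 for women
  set.seed(cfg$seed)
  cov <- simulate_covariates(cfg)
  expect_error(simulate_latent(cfg, cov), "non-positive")
})

test_that("responses follow the PCM, including DIF offsets", {
  cfg <- small_config(N = 10000, seed = 14)
  set.seed(cfg$seed)
  cov <- simulate_covariates(cfg)
  th <- rep(0, cfg$N)
  cfg1 <- cfg
  cfg1$bank <- item_bank(list(v = 0))   # single dichotomous item, delta 0
  y <- simulate_responses(cfg1, th, cov)
  expect_lt(abs(mean(y[, "v"]) - 0.5), 3 * sqrt(0.25 / cfg$N))
  # extreme trait pins the top category
  expect_true(all(simulate_responses(cfg, rep(40, cfg$N), cov) == 3L))
  # a positive threshold shift lowers the item mean for the shifted group,
  # by about the exact PCM expectation difference
  cfg2 <- cfg
  cfg2$dif_offsets <- list(list(item = "v", factor = "gender",
                                levels = "Women", offset = 0.5))
  y2 <- simulate_responses(cfg2, th, cov)
  w <- cov$gender == "Women"
  gap_model <- pcm_expected(0, cfg$bank$delta$v) -
    pcm_expected(0, cfg$bank$delta$v + 0.5)
  gap_emp <- mean(y2[!w, "v"]) - mean(y2[w, "v"])
  expect_gt(gap_emp, 0)
  expect_lt(abs(gap_emp - gap_model), 3 * 1.2 / sqrt(sum(w)))
})

test_that("missingness mechanisms behave as configured", {
  cfg <- small_config(N = 5000, seed = 15)
  set.seed(cfg$seed)
  cov <- simulate_covariates(cfg)
  lat <- simulate_latent(cfg, cov)
  y <- simulate_responses(cfg, lat$theta, cov)
  expect_identical(apply_missingness(y, lat$theta, list(type = "none")), y)
  ym <- apply_missingness(y, lat$theta, list(type = "mcar", rate = 0.1))
  ncell <- length(ym)
  expect_lt(abs(mean(is.na(ym)) - 0.1), 3 * sqrt(0.09 / ncell))
  expect_error(apply_missingness(y, lat$theta,
                                 list(type = "mcar", rate = 1.2)), "rate")
  # informative missingness: heavy missingness marks low-trait persons
  yi <- apply_missingness(y, lat$theta,
                          list(type = "informative", rate = 0.15,
                               slope = 1.5))
  expect_lt(abs(mean(is.na(yi)) - 0.15), 0.02)
  many <- rowSums(is.na(yi)) >= 3
  expect_gt(sum(many), 20)
  expect_lt(mean(lat$theta[many]), mean(lat$theta[rowSums(is.na(yi)) == 0]))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_config(N = 300, seed = 16)
  a <- simulate_qol(cfg)
  b <- simulate_qol(cfg)
  expect_identical(a$responses, b$responses)
  expect_identical(a$covariates, b$covariates)
  cfg2 <- small_config(N = 300, seed = 17)
  expect_false(identical(simulate_qol(cfg2)$responses, a$responses))
})

test_that("simulated datasets round-trip through the CSV schemas", {
  cfg <- small_config(N = 120, seed = 18)
  dir <- withr::local_tempdir()
  paths <- simulate_dataset(cfg, dir)
  y <- read_responses(paths$responses)
  cov <- read_covariates(paths$covariates)
  dat <- simulate_qol(cfg)
  expect_equal(unname(y), unname(dat$responses))
  expect_equal(nrow(cov), 120L)
  expect_match(readLines(paths$responses, n = 1L), "seed=18")
})

test_that("YAML configurations build equivalent generators", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "N: 150", "seed: 9", "mu_star: 0.1", "sigma2_star: 1.1",
    "items:", "  a: [-1.0, 0.5]", "  b: [-0.4, 0.9]",
    "covariate_levels:", "  gender:", "    Men: 0.5", "    Women: 0.5",
    "mean_formula: '~ gender'", "var_formula: '~ 1'",
    "beta:", "  genderWomen: -0.3",
    "missingness:", "  type: mcar", "  rate: 0.05"), path)
  cfg <- sim_config_from_yaml(path)
  cfg$gamma <- numeric(); cfg$transform <- NULL
  expect_equal(cfg$N, 150)
  expect_equal(cfg$bank$delta$b, c(-0.4, 0.9))
  dat <- simulate_qol(cfg)
  expect_equal(dim(dat$responses), c(150L, 2L))
  expect_gt(mean(is.na(dat$responses)), 0)
})

test_that("the default configuration matches the survey frequencies", {
  cfg <- sim_config()
  expect_equal(cfg$N, 26388L)
  expect_equal(sum(cfg$covariate_levels$region), 1)
  expect_equal(unname(cfg$covariate_levels$year["1995"]), 0.139)
  expect_equal(length(cfg$covariate_levels$age_band), 7L)
})
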