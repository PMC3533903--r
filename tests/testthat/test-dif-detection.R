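# build a location table directly (strata x items), bypassing PCE
make_table <- function(loc, strata, sizes) {
  structure(list(locations = loc, sizes = sizes, strata = strata),
            class = "location_table")
}

test_that("stratification produces the expected strata counts", {
  cfg <- sim_config(N = 12000, seed = 31)
  dat <- simulate_qol(cfg)
  tab <- fit_strata_locations(dat$responses, dat$covariates,
                              c("gender", "age_band", "year"),
                              min_stratum = 25L)
  expect_equal(nrow(tab$locations), 28L)   # 2 x 7 x 2
  tab2 <- fit_strata_locations(dat$responses, dat$covariates,
                               c("region", "year"), min_stratum = 25L)
  expect_equal(nrow(tab2$locations), 18L)  # 9 x 2
  # single-factor stratification with one level
  one <- fit_strata_locations(dat$responses[dat$covariates$year == "2003", ],
                              droplevels(dat$covariates[
                                dat$covariates$year == "2003", ]),
                              "year", min_stratum = 25L)
  expect_equal(nrow(one$locations), 1L)
})

test_that("constant locations give p near 1 and no flags", {
  strata <- expand.grid(gender = c("M", "W"), age = c("y", "m", "o"))
  loc <- matrix(0.3, 6, 2, dimnames = list(NULL, c("i1", "i2")))
  tab <- make_table(loc, strata, rep(500L, 6))
  rep <- weighted_anova_dif(tab, factors = c("gender", "age"),
                            ordered_factors = "age")
  expect_true(all(rep$p == 1))
  expect_false(any(rep$flag))
})

test_that("the flag rule is the conjunction of p-value and difference", {
  set.seed(32)
  strata <- expand.grid(gender = c("M", "W"), age = c("y", "m", "o"),
                        rep = 1:4)[, 1:2]
  n_str <- nrow(strata)
  noise <- function(s) rnorm(n_str, 0, s)
  # +0.5 shift for women on item i1: flagged
  loc <- cbind(i1 = 0.5 * (strata$gender == "W") + noise(0.02),
               i2 = noise(0.02))
  tab <- make_table(loc, strata, rep(1000L, n_str))
  rep <- weighted_anova_dif(tab, factors = c("gender", "age"),
                            ordered_factors = "age")
  r1 <- rep[rep$item == "i1" & rep$factor == "gender", ]
  expect_true(r1$flag)
  expect_gt(r1$diff, 0.4)
  # significant but tiny (0.05 < 0.1) difference: NOT flagged
  loc2 <- cbind(i1 = 0.05 * (strata$gender == "W") + noise(0.002),
                i2 = noise(0.002))
  tab2 <- make_table(loc2, strata, rep(10000L, n_str))
  rep2 <- weighted_anova_dif(tab2, factors = c("gender", "age"),
                             ordered_factors = "age")
  r2 <- rep2[rep2$item == "i1" & rep2$factor == "gender", ]
  expect_lt(r2$p, 0.05)
  expect_false(r2$flag)
})

test_that("level collapsing follows the greedy 0.1-spread rule", {
  m <- c(a = 0.0, b = 0.02, c = 0.5, d = 0.52)
  expect_equal(collapse_levels(m, ordered = TRUE),
               list(c("a", "b"), c("c", "d")))
  expect_length(collapse_levels(c(a = 0, b = 0.05, c = 0.09)), 1L)
  expect_length(collapse_levels(c(a = 0, b = 0.2, c = 0.4)), 3L)
  # unordered factors are sorted by location first
  expect_equal(collapse_levels(c(a = 0.5, b = 0.0, c = 0.52),
                               ordered = FALSE),
               list("b", c("a", "c")))
})

test_that("a flagged report converts into a pseudo-item specification", {
  rep <- data.frame(item = c("i1", "i2"), factor = c("age", "gender"),
                    diff = c(0.5, 0.02), p = c(0.001, 0.8),
                    flag = c(TRUE, FALSE),
                    grouping = c("y+m / o", ""))
  spec <- dif_report_to_spec(rep)
  expect_length(spec, 1L)
  expect_equal(spec[[1]]$item, "i1")
  expect_equal(spec[[1]]$groups, list(c("y", "m"), "o"))
})

test_that("stage 2 flags year DIF but not mean-only region impact", {
  set.seed(33)
  bank <- bank4()
  N <- 9000
  cov <- data.frame(
    gender = factor(sample(c("Men", "Women"), N, TRUE)),
    age_band = factor(sample(c("18-44", "45-64", "65-84"), N, TRUE)),
    region = factor(sample(paste0("R", 1:9), N, TRUE)),
    year = factor(sample(c("1995", "2003"), N, TRUE)))
  # impact only through region and age on the MEAN of the trait
  mu <- -0.4 * (cov$region %in% c("R2", "R3")) +
    0.5 * (cov$region == "R7") - 0.3 * (cov$age_band == "65-84")
  th <- rnorm(N, mu, 1)
  y <- draw_matrix(th, bank)
  # true year DIF: uniform +0.4 shift on item x in 2003
  sel <- cov$year == "2003"
  y[sel, "x"] <- pcm_draw(th[sel], bank$delta$x + 0.4)
  stage1 <- dif_scan(y, cov, c("gender", "age_band"),
                     min_stratum = 50L)
  items <- item_specs_from_bank(bank)
  stage2 <- second_stage_region_year(y, cov, stage1, items,
                                     min_stratum = 50L)
  r <- stage2$report
  expect_true(r$flag[r$item == "x" & r$factor == "year"])
  expect_false(any(r$flag[r$factor == "region"]))
})
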