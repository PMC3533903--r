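gh_matrix <- function(n = 6) {
  m <- matrix(rep(c(0L, 2L, 4L, 1L, 3L), n), n, 5, byrow = TRUE)
  colnames(m) <- vapply(sf36_items("GH"), `[[`, character(1), "item_id")
  m
}

test_that("reverse coding reflects endpoints, fixes midpoints, involutes", {
  items <- sf36_items("GH")
  m <- gh_matrix()
  m[1, "GH1"] <- 0; m[2, "GH1"] <- 2; m[3, "GH1"] <- NA
  r <- reverse_code(m, items)
  expect_equal(unname(r[1, "GH1"]), 4)        # endpoint reflection, m_j = 4
  expect_equal(unname(r[2, "GH1"]), 2)        # midpoint fixed
  expect_true(is.na(r[3, "GH1"]))     # missing stays missing
  expect_equal(r[, "GH11a"], m[, "GH11a"])  # unflagged item untouched
  expect_equal(reverse_code(r, items), m)   # involution
})

test_that("out-of-range codes are rejected with the item identified", {
  items <- sf36_items("GH")
  m <- gh_matrix()
  m[2, "GH11b"] <- 7
  expect_error(validate_responses(m, items), "GH11b")
})

test_that("super-items sum component codes and propagate missingness", {
  items <- sf36_items("PF")
  m <- matrix(1L, 4, 10,
              dimnames = list(NULL, vapply(items, `[[`, character(1),
                                           "item_id")))
  m[1, "PF1"] <- 1L; m[1, "PF2"] <- 2L
  m[2, "PF7"] <- NA
  out <- build_super_items(m, sf36_pf_groups(), items)
  expect_equal(ncol(out$responses), 6L)   # 10 PF items -> 6 scored items
  expect_setequal(colnames(out$responses),
                  c("PF12", "PF3", "PF45", "PF6", "PF789", "PF10"))
  expect_equal(unname(out$responses[1, "PF12"]), 3)        # 1 + 2 on a 0-4 scale
  expect_equal(out$items$PF12$n_categories, 5L)
  expect_equal(out$items$PF789$n_categories, 7L)   # 0-6 scale
  expect_true(is.na(out$responses[2, "PF789"]))    # any-missing rule
  # raw-score preservation for fully observed persons
  expect_equal(rowSums(out$responses[3:4, ]), rowSums(m[3:4, ]))
  expect_error(build_super_items(m, list(A = c("PF1", "PF2"),
                                         B = c("PF2", "PF3")), items),
               "overlap")
})

test_that("pseudo-item expansion reproduces the survey item counts", {
  set.seed(6)
  n <- 40
  gh <- gh_matrix(n)
  cov <- data.frame(age_band = factor(
    sample(c("18-24", "35-44", "55-64", "75-84"), n, TRUE)))
  spec <- dif_spec(
    dif_split("GH1", "age_band",
              list(c("18-24", "35-44"), c("55-64"), c("75-84"))),
    dif_split("GH11a", "age_band",
              list(c("18-24"), c("35-44", "55-64"), c("75-84"))))
  out <- expand_pseudo_items(gh, cov, spec, sf36_items("GH"))
  expect_equal(ncol(out$responses), 9L)   # 2 items split in 3 + 3 unsplit
  # per-person observed responses are preserved as a multiset
  for (i in c(1L, 17L, n)) {
    expect_equal(sort(out$responses[i, !is.na(out$responses[i, ])]),
                 sort(gh[i, !is.na(gh[i, ])]), ignore_attr = TRUE)
  }
  # a pseudo-item is missing outside its group
  sel <- cov$age_band == "75-84"
  expect_true(all(is.na(out$responses[!sel, "GH1@age_band:75-84"])))
  expect_equal(out$responses[sel, "GH1@age_band:75-84"], gh[sel, "GH1"])
})

test_that("MH-style split into five groups gives nine pseudo-items", {
  n <- 30
  mh <- matrix(3L, n, 5,
               dimnames = list(NULL, paste0("MH", 1:5)))
  bands <- c("18-44", "45-54", "55-64", "65-74", "75-84")
  cov <- data.frame(age_band = factor(rep(bands, length.out = n)))
  spec <- dif_spec(dif_split("MH1", "age_band", as.list(bands)))
  out <- expand_pseudo_items(mh, cov, spec, sf36_items("MH"))
  expect_equal(ncol(out$responses), 9L)
})

test_that("empty DIF spec is the identity and bad levels are rejected", {
  gh <- gh_matrix()
  cov <- data.frame(age_band = factor(rep(c("18-24", "75-84"), 3)))
  out <- expand_pseudo_items(gh, cov, dif_spec(), sf36_items("GH"))
  expect_identical(out$responses, gh)
  spec <- dif_spec(dif_split("GH1", "age_band", list(c("18-24"))))
  expect_error(expand_pseudo_items(gh, cov, spec, sf36_items("GH")),
               "outside")
})

test_that("double splits give one pseudo-item set per factor by default", {
  n <- 20
  pf <- matrix(1L, n, 2, dimnames = list(NULL, c("PF3", "PF10")))
  items <- list(item_spec("PF3", 3L), item_spec("PF10", 3L))
  cov <- data.frame(gender = factor(rep(c("Men", "Women"), n / 2)),
                    year = factor(rep(c("1995", "2003"), each = n / 2)))
  spec <- dif_spec(
    dif_split("PF3", "gender", list("Men", "Women")),
    dif_split("PF3", "year", list("1995", "2003")))
  ind <- expand_pseudo_items(pf, cov, spec, items)
  expect_equal(ncol(ind$responses), 5L)   # 2 + 2 pseudo + PF10
  cross <- expand_pseudo_items(pf, cov, spec, items, cross_product = TRUE)
  expect_equal(ncol(cross$responses), 5L) # 2 x 2 pseudo + PF10
  expect_true(any(grepl("gender.*year", colnames(cross$responses))))
})

test_that("item bank CSV round-trips at full precision", {
  bank <- bank4()
  path <- withr::local_tempfile(fileext = ".csv")
  write_item_bank(bank, path)
  back <- read_item_bank(path)
  expect_equal(back$delta, bank$delta, tolerance = 1e-11)
})

test_that("response/covariate CSVs round-trip with metadata header", {
  set.seed(7)
  y <- draw_matrix(rnorm(20), bank4())
  y[3, 2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(y, path, comment = "seed=7")
  expect_match(readLines(path, n = 1L), "^# seed=7")
  back <- read_responses(path)
  expect_equal(unname(back), unname(y))
})
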