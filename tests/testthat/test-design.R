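# Contrast codings and design-matrix construction.

schemes <- c("treatment", "simple", "sum", "backward_difference", "helmert")

test_that("coding matrices have the right shape and zero-sum structure", {
  for (scheme in schemes) {
    for (k in 2:5) {
      cm <- coding_matrix(scheme, LETTERS[1:k])
      expect_identical(dim(unclass(cm)), c(k, k - 1L))
      expect_identical(qr(unclass(cm))$rank, k - 1L)
      if (scheme != "treatment") {
        expect_equal(colSums(unclass(cm)), rep(0, k - 1),
                     ignore_attr = TRUE, tolerance = 1e-12)
      }
    }
  }
  expect_error(coding_matrix("treatment", "A"), "at least 2 levels")
  expect_error(coding_matrix("fancy", c("A", "B")))
})

as_plain <- function(cm) {
  matrix(as.numeric(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
}

test_that("treatment coding of two levels is plain dummy coding", {
  cm <- coding_matrix("treatment", c("A", "B"))
  expect_equal(as_plain(cm), matrix(c(0, 1), 2, 1,
                                    dimnames = list(c("A", "B"), "B-A")))
})

test_that("fitted coefficients on balanced data match each scheme's estimand", {
  m_sets <- list(c(10, 12), c(10, 12, 14), c(3, -1, 4, 1), c(2, 7, 1, 8, 2.5))
  for (m in m_sets) {
    dat <- balanced_oneway(m)
    for (scheme in schemes) {
      cm <- coding_matrix(scheme, levels(dat$g))
      X <- cbind("(Intercept)" = 1, encode_factor(dat$g, cm))
      beta <- oracle_ols(X, dat$y)$coefficients
      expect_equal(unname(beta[-1]), unname(expected_contrasts(scheme, m)),
                   tolerance = 1e-10,
                   label = sprintf("%s k=%d", scheme, length(m)))
      expected_icpt <- if (scheme == "treatment") m[1] else mean(m)
      expect_equal(unname(beta[1]), expected_icpt, tolerance = 1e-10)
    }
  }
})

test_that("the documented worked examples hold (sum, backward difference, helmert)", {
  dat <- balanced_oneway(c(10, 12, 14))
  fit_with <- function(scheme) {
    X <- cbind("(Intercept)" = 1,
               encode_factor(dat$g, coding_matrix(scheme, levels(dat$g))))
    unname(fit_ols(X, dat$y)$coefficients[-1])
  }
  expect_equal(fit_with("sum"), c(-2, 0), tolerance = 1e-10)
  expect_equal(fit_with("backward_difference"), c(2, 2), tolerance = 1e-10)
  cm <- coding_matrix("sum", c("A", "B", "C"))
  expect_equal(unname(as_plain(cm)), rbind(c(1, 0), c(0, 1), c(-1, -1)))
  dat2 <- balanced_oneway(c(10, 12))
  X2 <- cbind("(Intercept)" = 1,
              encode_factor(dat2$g, coding_matrix("helmert", c("A", "B"))))
  expect_equal(unname(fit_ols(X2, dat2$y)$coefficients[-1]), 2,
               tolerance = 1e-10)
})

test_that("encode_factor applies coding rows and rejects unseen levels", {
  cm <- coding_matrix("treatment", c("A", "B"))
  expect_equal(unname(encode_factor(c("A", "B", "A"), cm)[, 1]), c(0, 1, 0))
  cm3 <- coding_matrix("sum", c("A", "B", "C"))
  expect_equal(unname(encode_factor(c("A", "B", "C", "B"), cm3)),
               rbind(c(1, 0), c(0, 1), c(-1, -1), c(0, 1)))
  expect_error(encode_factor(c("A", "Z"), cm), "'Z' is not among")
})

test_that("build_design assembles intercept, codings, and interaction products", {
  docs <- generate_multisite(
    list(site_config("s1", 40, list(
      site_var("group", "categorical", levels = c("a", "b", "c"),
               local_name = "group", element_id = "grp01"),
      site_var("age", "numeric", range = c(20, 60))))),
    truth_record(10, effects = list(age = 0.5, group = c(b = 1, c = 2)),
                 noise_sd = 0),
    seed = 5)
  tab <- extract_table(docs, c("fs_000008", "group", "age"))
  spec <- model_spec("fs_000008 = group + age + age*group")
  des <- build_design(tab, spec)
  expect_identical(ncol(des$X), 1L + 2L + 1L + 2L)
  expect_identical(des$term_map, list(group = 2:3, age = 4L, `age*group` = 5:6))
  # interaction columns are exact elementwise products of their parents
  expect_equal(des$X[, 5], des$X[, 4] * des$X[, 2], tolerance = 0)
  expect_equal(des$X[, 6], des$X[, 4] * des$X[, 3], tolerance = 0)
  expect_true(all(des$X[, 1] == 1))
})

test_that("numeric-only models produce intercept plus one column per factor", {
  docs <- generate_multisite(seed = 2)
  age <- "http://uri.interlex.org/ilx_0100400"
  tab <- extract_table(docs, c("fs_000008", "PIQ", age))
  des <- build_design(tab, model_spec(paste("fs_000008 = PIQ +", age)))
  expect_identical(dim(des$X), c(100L, 3L))
})

test_that("any two codings of the same factor give identical fitted values", {
  dat <- balanced_oneway(c(5, 9, 4, 7), reps = 4L)
  y <- dat$y + rep(c(0.3, -0.2, 0.1, -0.4), times = 4)
  fits <- lapply(schemes, function(scheme) {
    X <- cbind("(Intercept)" = 1,
               encode_factor(dat$g, coding_matrix(scheme, levels(dat$g))))
    fit_ols(X, y)$fitted
  })
  for (f in fits[-1]) expect_equal(f, fits[[1]], tolerance = 1e-10)
})

test_that("a categorical response and rank-deficient designs are hard errors", {
  tab <- extract_table(tiny_study(), c("fs_000008", "DX_GROUP", "age"))
  expect_error(build_design(tab, model_spec("DX_GROUP = age")),
               "categorical.*must be numeric")
  # duplicate the age column through an interaction with itself via two terms
  docs <- generate_multisite(seed = 3)
  age <- "http://uri.interlex.org/ilx_0100400"
  tb <- extract_table(docs, c("fs_000008", age, "PIQ"))
  tb2 <- tb
  tb2$PIQ <- tb2[[age]]   # perfectly collinear with age
  attr(tb2, "column_info") <- attr(tb, "column_info")
  expect_error(build_design(tb2, model_spec(paste("fs_000008 =", age, "+ PIQ"))),
               "rank deficient")
})

test_that("contrast variables use the requested scheme, others treatment", {
  docs <- generate_multisite(
    list(site_config("s1", 60, list(
      site_var("group", "categorical", levels = c("a", "b", "c")),
      site_var("sex", "categorical", levels = c("F", "M")),
      site_var("age", "numeric", range = c(10, 20))))),
    truth_record(1, effects = list(age = 1), noise_sd = 0), seed = 9)
  tab <- extract_table(docs, c("fs_000008", "group", "sex", "age"))
  spec <- model_spec("fs_000008 = group + sex + age", contrast = "group",
                     coding = "helmert")
  des <- build_design(tab, spec)
  expect_identical(attr(des$factor_codings[["group"]], "scheme"), "helmert")
  expect_identical(attr(des$factor_codings[["sex"]], "scheme"), "treatment")
})
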