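test_that("Pearson test matches its closed form", {
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 1.9, 3.2, 3.8)
  res <- pearson_test(x, y)
  # independent closed-form evaluation
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((4 - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = 2, lower.tail = FALSE)
  expect_equal(res$estimate, r, tolerance = 1e-10)
  expect_equal(res$statistic, tstat, tolerance = 1e-10)
  expect_equal(res$p, p, tolerance = 1e-10)
  expect_equal(res$df, 2)

  expect_equal(pearson_test(x, x)$estimate, 1)
  expect_lt(pearson_test(x, x)$p, 1e-12)
  expect_equal(pearson_test(x, -x)$estimate, -1)
  # affine invariance (sign-aware)
  z <- c(0.4, -1, 2, 0.3)
  expect_equal(pearson_test(3 * x - 2, z)$estimate,
               pearson_test(x, z)$estimate, tolerance = 1e-12)
  expect_equal(pearson_test(-2 * x, z)$estimate,
               -pearson_test(x, z)$estimate, tolerance = 1e-12)
  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_test(1:2, 1:2), "length >= 3")
})

test_that("two-sample tests behave at their reference points", {
  x <- c(1, 2, 3, 4, 5)
  for (f in list(welch_test, student_test)) {
    res <- f(x, x)
    expect_equal(res$statistic, 0)
    expect_equal(res$p, 1)
  }
  expect_error(welch_test(1, c(1, 2)), "at least 2")
  expect_error(student_test(c(2, 2), c(2, 2)), "identical")
  # Student pools df; Welch uses Satterthwaite
  y <- c(10, 11, 14, 20, 30, 28)
  expect_equal(student_test(x, y)$df, length(x) + length(y) - 2)
  expect_lt(welch_test(x, y)$df, student_test(x, y)$df)
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.01, 3)), rep(0.03, 3))
  p <- c(0.001, 0.2, 0.04, 0.9)
  expect_true(all(holm_adjust(p) >= p))
  expect_true(all(diff(holm_adjust(sort(p))) >= 0))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("AUC equals the exhaustive pairwise U-statistic", {
  res <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(res$auc, 0.75)
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  # complement identity holds exactly, ties get half credit
  set.seed(15)
  for (i in 1:20) {
    s <- sample(0:5, 30, replace = TRUE)
    l <- sample(c(0, 1), 30, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(l)) < 2) next
    a <- roc_auc(s, l)$auc
    pairwise <- mean(outer(s[l == 1], s[l == 0],
                           function(p, n) (p > n) + 0.5 * (p == n)))
    expect_equal(a, pairwise, tolerance = 1e-12)
    expect_equal(a + roc_auc(-s, l)$auc, 1, tolerance = 1e-12)
  }
  # shuffled labels give chance AUC on average
  set.seed(16)
  s <- stats::rnorm(60)
  l <- rep(c(0, 1), 30)
  nulls <- replicate(200, roc_auc(s, sample(l))$auc)
  expect_lt(abs(mean(nulls) - 0.5), 0.03)
  expect_error(roc_auc(s, rep(1, 60)), "both classes")

  skip_if_not_installed("pROC")
  set.seed(17)
  s <- stats::rnorm(80)
  l <- stats::rbinom(80, 1, stats::plogis(s))
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE)))
  expect_equal(roc_auc(s, l)$auc, ref, tolerance = 1e-12)
})

test_that("bootstrap CI brackets the point AUC reproducibly", {
  set.seed(18)
  s <- c(stats::rnorm(40), stats::rnorm(40, 1.5))
  l <- rep(c(0, 1), each = 40)
  a <- roc_auc(s, l, ci = TRUE, n_boot = 500, seed = 4)
  b <- roc_auc(s, l, ci = TRUE, n_boot = 500, seed = 4)
  expect_identical(a, b)
  expect_lt(a$ci_low, a$auc)
  expect_gt(a$ci_high, a$auc)
})

test_that("IRLS logistic fit matches an independent Newton-Raphson oracle", {
  set.seed(20)
  n <- 200
  dat <- tibble::tibble(
    neutrophil_pct = stats::rnorm(n, 60, 8),
    monocyte_pct = stats::rnorm(n, 8, 2),
    age = stats::rnorm(n, 70, 9),
    sex = stats::rbinom(n, 1, 0.5)
  )
  zn <- scale(dat$neutrophil_pct)[, 1]
  zm <- scale(dat$monocyte_pct)[, 1]
  za <- scale(dat$age)[, 1]
  eta <- -0.3 + 0.7 * zn - 0.4 * zm - 0.5 * zn * zm + 0.2 * za
  dat$shock <- stats::runif(n) < stats::plogis(eta)
  fit <- logistic_irls(dat)
  X <- cbind(1, zn, zm, zn * zm, za, dat$sex)
  oracle <- logit_newton_oracle(X, as.numeric(dat$shock))
  expect_equal(fit$coefficients$estimate, unname(oracle$beta),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$coefficients$std_error, unname(oracle$se),
               tolerance = 1e-6, ignore_attr = TRUE)
  # intercept-only closed form: logit of the prevalence
  fit0 <- logistic_irls(dat, exposure = NULL, modifier = NULL,
                        adjust = character())
  expect_equal(fit0$coefficients$estimate[1],
               stats::qlogis(mean(dat$shock)), tolerance = 1e-8)
  expect_error(logistic_irls(dat[1:30, ]), "parameters")
  expect_error(logistic_irls(dplyr::mutate(dat, shock = shock + 1)), "binary")
})

test_that("separation is reported as an explicit error", {
  set.seed(22)
  n <- 120
  dat <- tibble::tibble(
    neutrophil_pct = c(stats::rnorm(n / 2, 40, 2), stats::rnorm(n / 2, 80, 2)),
    monocyte_pct = stats::rnorm(n, 8, 2),
    age = stats::rnorm(n, 70, 9),
    sex = stats::rbinom(n, 1, 0.5),
    shock = rep(c(FALSE, TRUE), each = n / 2)
  )
  expect_error(logistic_irls(dat), "separation|converge")
})

test_that("effect-modification curves reflect the interaction sign", {
  set.seed(23)
  n <- 2500
  dat <- tibble::tibble(
    neutrophil_pct = stats::rnorm(n, 60, 8),
    monocyte_pct = stats::rnorm(n, 8, 2),
    age = stats::rnorm(n, 70, 9),
    sex = stats::rbinom(n, 1, 0.5)
  )
  zn <- scale(dat$neutrophil_pct)[, 1]
  zm <- scale(dat$monocyte_pct)[, 1]
  mk_fit <- function(b_int) {
    d <- dat
    d$shock <- stats::runif(n) < stats::plogis(0.8 * zn - 0.4 * zm +
                                                 b_int * zn * zm)
    logistic_irls(d)
  }
  # an exactly-zero interaction coefficient makes the strata curves
  # horizontal translations on the logit scale (model algebra, checked by
  # zeroing the fitted coefficient)
  fit0 <- mk_fit(0)
  fit0$coefficients$estimate[
    fit0$coefficients$term == "neutrophil_pct:monocyte_pct"] <- 0
  cv <- stratified_effect_curve(fit0, exposure_grid = c(50, 60, 70))
  logit <- function(p) log(p / (1 - p))
  shifts <- tapply(logit(cv$probability), cv$modifier_quantile, diff)
  expect_equal(shifts[[1]], shifts[[2]], tolerance = 1e-9)
  expect_equal(shifts[[2]], shifts[[3]], tolerance = 1e-9)
  expect_true(all(cv$probability > 0 & cv$probability < 1))
  # planted negative interaction: exposure slope decreases across strata
  fitn <- mk_fit(-0.6)
  cvn <- stratified_effect_curve(fitn, exposure_grid = c(50, 60, 70))
  slopes <- tapply(logit(cvn$probability), cvn$modifier_quantile,
                   function(p) (p[3] - p[1]) / 20)
  expect_true(all(diff(unname(slopes)) < 0))
  expect_warning(stratified_effect_curve(fitn, exposure_grid = c(0, 200)),
                 "outside")
})
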