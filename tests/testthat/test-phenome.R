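test_that("phenotype change encoding follows the sign rules", {
  ids <- sprintf("p%d", 1:6)
  meta <- tibble::tibble(
    id = c("smoker", "score", "grade", "home"),
    domain = "lifestyle",
    var_type = c("binary", "continuous", "ordered", "unordered"))
  v1 <- tibble::tibble(participant_id = ids,
                       smoker = c(0, 1, 0, 1, 0, 0),
                       score = c(10, 12, 9, 11, 10, 13),
                       grade = c(1, 3, 2, 4, 1, 2),
                       home = c("own", "rent", "own", "own", "rent", "own"))
  v2 <- tibble::tibble(participant_id = ids,
                       smoker = c(1, 1, 0, 0, 0, 1),   # gained / kept / lost
                       score = c(12, 12, 10, 10, 10, 15),
                       grade = c(3, 1, 2, 4, 2, 1),
                       home = c("rent", "rent", "own", "own", "own", "own"))
  enc <- encode_phenotype_changes(v1, v2, meta)
  # non-smoker who smokes at visit 2 -> +1; quitting -> -1; unchanged -> 0
  expect_equal(enc$smoker, c(1, 0, 0, -1, 0, 1))
  # ordered multi-level moves collapse to their sign
  expect_equal(enc$grade, c(1, -1, 0, 0, 1, -1))
  # continuous changes standardized over non-missing
  expect_equal(mean(enc$score), 0, tolerance = 1e-12)
  expect_equal(sd(enc$score), 1, tolerance = 1e-12)
  # unordered expansion to per-level indicators in {-1, 0, 1}
  expect_true(all(c("home.own", "home.rent") %in% names(enc)))
  expect_equal(enc$home.own, c(-1, 0, 0, 0, 1, 0))
  expect_true(all(unlist(enc[c("home.own", "home.rent")]) %in% c(-1, 0, 1)))
})

test_that("low response-rate phenotypes are dropped with a log entry", {
  n <- 100
  ids <- sprintf("p%d", 1:n)
  meta <- tibble::tibble(id = c("rare", "common"), domain = "lifestyle",
                         var_type = "continuous")
  v1 <- tibble::tibble(participant_id = ids, rare = rnorm(n),
                       common = rnorm(n))
  v2 <- v1
  v2$rare[10:100] <- NA  # 9% response at visit 2
  expect_message(enc <- encode_phenotype_changes(v1, v2, meta), "dropped")
  expect_false("rare" %in% names(enc))
  expect_true("common" %in% names(enc))
  expect_equal(attr(enc, "dropped")$id, "rare")
})

test_that("adjusted R^2 closed forms hold in both variants", {
  expect_equal(adjusted_r2(0.5, 101, 50), 0)
  expect_equal(adjusted_r2(0.5, 101, 50, as_printed = TRUE), 1)
  expect_equal(adjusted_r2(1, 50, 10), 1)
  expect_equal(adjusted_r2(0.3, 40, 0), 0.3)
  expect_equal(adjusted_r2(0.3, 40, 0, as_printed = TRUE), 0.3)
  expect_error(adjusted_r2(0.5, 11, 10), "n > d")
  # standard form is strictly below R0^2 for d >= 1 and R0^2 < 1
  for (r0 in c(0, 0.2, 0.8)) {
    for (d in c(1, 5, 20)) {
      expect_lt(adjusted_r2(r0, 100, d), r0 + 1e-12)
    }
  }
})

test_that("ridge regression matches OLS at lambda 0 and shrinks to zero", {
  set.seed(21)
  n <- 200
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- drop(x %*% c(1, -0.5, 0, 0.2)) + rnorm(n, sd = 0.5)
  fit0 <- ridge_regression(y, x, lambda = 0)
  xs <- scale(x)
  ols <- coef(lm(y ~ xs))
  expect_equal(unname(fit0$beta), unname(ols[-1]), tolerance = 1e-8)
  expect_equal(fit0$r0_sq, summary(lm(y ~ x))$r.squared, tolerance = 1e-10)
  # huge penalty drives coefficients and R0^2 to zero
  fit_inf <- ridge_regression(y, x, lambda = 1e9)
  expect_lt(max(abs(fit_inf$beta)), 1e-5)
  expect_lt(fit_inf$r0_sq, 1e-4)
  expect_error(ridge_regression(rep(1, n), x), "constant")
})

test_that("domain regression flags the planted phenotype as strongest", {
  set.seed(22)
  n <- 1500
  demo <- tibble::tibble(age = rnorm(n, 60, 7), sex = rbinom(n, 1, 0.5))
  demo <- tibble::tibble(demo, age2 = demo$age^2, age_sex = demo$age * demo$sex,
                         age2_sex = demo$age^2 * demo$sex,
                         delta_t = rnorm(n, 830, 40))
  domain <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  target <- 0.5 * domain$b + rnorm(n)
  res <- domain_regression(target, domain, demo)
  expect_equal(res$top_feature, "b")
  expect_gt(res$adj_r2, res$baseline_adj_r2)
  expect_error(domain_regression(target, domain[0], demo), "empty domain")
})

test_that("behaviour-change regression calibrates its permutation null", {
  set.seed(23)
  n <- 2000
  lbac <- matrix(rnorm(n * 3), n, 3)
  ch <- changes_from_lbac(lbac)
  demo <- tibble::tibble(age = rnorm(n, 60, 7), sex = rbinom(n, 1, 0.5))
  demo <- tibble::tibble(demo, age2 = demo$age^2, age_sex = demo$age * demo$sex,
                         age2_sex = demo$age^2 * demo$sex, delta_t = 830)
  # planted: dPhi follows pattern-2 LBAC
  dphi <- lbac[, 2] + rnorm(n, sd = 0.4)
  res <- behaviour_change_regression(dphi, ch, demo, n_perm = 30, seed = 7)
  expect_equal(res$attribution_category, "lbac")
  expect_equal(res$attribution_feature, "lbac_pattern_02")
  expect_gt(res$gain, 0.3)
  # independent dPhi: gain within 3 permutation sds of zero
  dphi0 <- rnorm(n)
  res0 <- behaviour_change_regression(dphi0, ch, demo, n_perm = 30, seed = 7)
  expect_lt(abs(res0$gain), 3 * res0$null_sd + 1e-3)
})

test_that("volume-change prediction picks the generating model", {
  set.seed(24)
  b <- small_bundle()
  res <- small_pipeline()
  ch <- res$changes
  n <- nrow(ch$lbac)
  # synthetic target built from LBACs: the LBAC model must win out of sample
  lbacs <- hemishift:::tbl_to_matrix(ch$lbac)
  demo <- b$demographics
  y_lbac <- drop(lbacs %*% rnorm(ncol(lbacs))) + rnorm(n, sd = 0.3)
  y_age <- 0.8 * scale(demo$age)[, 1] + rnorm(n, sd = 0.3)
  cv_r2 <- function(y, x, folds) {
    pred <- rep(NA_real_, length(y))
    for (f in unique(folds)) {
      fit <- ridge_regression(y[folds != f], x[folds != f, , drop = FALSE],
                              lambda = 1)
      pred[folds == f] <- hemishift:::predict_ridge(fit, x[folds == f, ,
                                                           drop = FALSE])
    }
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  folds <- rep_len(1:5, n)
  ages <- cbind(age = demo$age, sex = demo$sex, age2 = demo$age^2,
                age_sex = demo$age * demo$sex,
                age2_sex = demo$age^2 * demo$sex)
  expect_gt(cv_r2(y_lbac, lbacs, folds), cv_r2(y_lbac, ages, folds))
  expect_gt(cv_r2(y_age, ages, folds), cv_r2(y_age, lbacs, folds))
  # package-level wrapper returns one row per model and is reproducible
  vp <- volume_change_prediction(ch, b, tissue = "grey", seed = 3)
  expect_setequal(vp$model, c("lbac", "mbac", "age_sex"))
  vp2 <- volume_change_prediction(ch, b, tissue = "grey", seed = 3)
  expect_equal(vp, vp2)
  expect_error(volume_change_prediction(ch, b, tissue = "csf"),
               "unknown tissue")
  # constant target: no explainable variance, no model scores above zero
  b0 <- simulate_cohort(cohort_config(n_participants = 40, seed = 2,
                                      n_latent_patterns = 3, noise_sd = 0,
                                      drift_sd = 0, drift_mean = rep(0, 3),
                                      atrophy_rate = 0, atrophy_sd = 0))
  res0 <- suppressWarnings(asymmetry_pipeline(b0, k = 3))
  vp0 <- volume_change_prediction(res0$changes, b0, tissue = "grey")
  expect_true(all(vp0$r2_cv <= 0))
})

test_that("coefficient PCA recovers planted motifs and handles degeneracy", {
  set.seed(25)
  f <- 10
  m1 <- c(rep(1, 5), rep(0, 5)); m1 <- m1 / sqrt(sum(m1^2))
  m2 <- c(rep(0, 5), rep(1, 5)); m2 <- m2 / sqrt(sum(m2^2))
  coefs <- rbind(
    t(sapply(rnorm(20, sd = 2), function(s) s * m1)),
    t(sapply(rnorm(20, sd = 1), function(s) s * m2))
  ) + matrix(rnorm(40 * f, sd = 0.01), 40, f)
  pc <- coefficient_pca(coefs, n_components = 2)
  expect_equal(pc$n_components, 2)
  ang <- acos(pmin(abs(c(sum(pc$loadings[, 1] * m1),
                         sum(pc$loadings[, 2] * m2))), 1))
  expect_true(all(ang < 0.1))
  # sign convention: largest |loading| positive
  expect_true(all(apply(pc$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  # identical models -> no components, warning
  expect_warning(pc0 <- coefficient_pca(matrix(1, 5, 3)), "no variance")
  expect_equal(pc0$n_components, 0L)
  expect_error(coefficient_pca(matrix(1, 1, 3)), "at least 2")
})

test_that("phenome domain scan covers the 20-group layout", {
  b <- small_bundle()
  res <- small_pipeline()
  scan <- suppressWarnings(phenome_domain_scan(res$changes, b))
  expect_equal(length(unique(scan$domain[scan$domain_kind == "baseline"])), 11)
  expect_equal(length(unique(scan$domain[scan$domain_kind == "change"])), 9)
  # 20 fits per target (2 measures x 6 patterns)
  expect_equal(nrow(scan), 20 * 2 * 6)
  expect_true(all(scan$r0_sq >= 0 & scan$r0_sq <= 1))
})
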