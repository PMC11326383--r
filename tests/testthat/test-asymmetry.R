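test_that("lateralization index matches its closed form and boundaries", {
  expect_equal(compute_li(2, 2), 0)
  expect_equal(compute_li(3, 1), 1)
  expect_equal(compute_li(0, 4), -2)
  expect_equal(compute_li(4, 0), 2)
  expect_error(compute_li(-1, 2), "negative")
  expect_warning(out <- compute_li(c(0, 1), c(0, 1)), "both homologs zero")
  expect_true(is.na(out[1]))
  expect_equal(out[2], 0)
})

test_that("deconfounding recovers a planted confound coefficient and matches OLS", {
  set.seed(71)
  n <- 2000
  conf <- tibble::tibble(participant_id = sprintf("p%04d", 1:n),
                         headsize = rnorm(n))
  li_vals <- 0.5 * conf$headsize + rnorm(n, sd = 0.1)
  li <- tibble::tibble(participant_id = conf$participant_id, feat_a = li_vals,
                       feat_b = rnorm(n))
  model <- fit_deconfound(li, conf)
  beta <- model$coefficients["headsize", "feat_a"]
  expect_gt(beta, 0.45)
  expect_lt(beta, 0.55)
  # independent oracle: lm()
  ols <- unname(coef(lm(li_vals ~ conf$headsize))[2])
  expect_equal(unname(beta), ols, tolerance = 1e-10)
})

test_that("deconfound model guards degenerate fits and collinearity", {
  n <- 50
  conf <- tibble::tibble(participant_id = sprintf("p%03d", 1:n),
                         a = rnorm(n))
  conf$b <- 2 * conf$a  # collinear
  li <- tibble::tibble(participant_id = conf$participant_id, f1 = rnorm(n))
  expect_error(fit_deconfound(li, conf), "collinear")
  # exactly linear LI -> zero residual sd triggers the guard
  conf2 <- conf[c("participant_id", "a")]
  li2 <- tibble::tibble(participant_id = conf$participant_id, f1 = 3 * conf$a)
  expect_error(fit_deconfound(li2, conf2), "zero residual sd")
})

test_that("applying a deconfound model standardizes fit data but not new data", {
  set.seed(5)
  n <- 300
  conf <- tibble::tibble(participant_id = sprintf("p%04d", 1:n),
                         c1 = rnorm(n), c2 = rnorm(n))
  li1 <- tibble::tibble(participant_id = conf$participant_id,
                        f1 = 0.3 * conf$c1 + rnorm(n),
                        f2 = rnorm(n))
  model <- fit_deconfound(li1, conf)
  a1 <- apply_deconfound(li1, model, conf)
  m1 <- hemishift:::tbl_to_matrix(a1)
  expect_true(all(abs(colMeans(m1)) < 1e-6))
  expect_equal(unname(apply(m1, 2, sd)), c(1, 1), tolerance = 1e-6)
  # a shifted second visit keeps its shift: no re-centering
  li2 <- li1
  li2$f1 <- li2$f1 + 1
  a2 <- apply_deconfound(li2, model, conf)
  expect_gt(mean(a2$f1), 0.5)
  # missing confound column errors
  expect_error(apply_deconfound(li1, model, conf["participant_id"]),
               "missing confound")
  # identity model leaves input untouched
  id_model <- structure(list(
    coefficients = matrix(0, 3, 2,
                          dimnames = list(c("(Intercept)", "c1", "c2"),
                                          c("f1", "f2"))),
    mean = c(f1 = 0, f2 = 0), sd = c(f1 = 1, f2 = 1),
    confound_names = c("c1", "c2"),
    fit_ids = conf$participant_id), class = "deconfound_model")
  a_id <- apply_deconfound(li1, id_model, conf)
  expect_equal(a_id$f1, li1$f1, tolerance = 1e-12)
})

test_that("pattern basis recovers a planted subspace and is orthonormal", {
  set.seed(31)
  n <- 200; f <- 12; k <- 3
  w <- qr.Q(qr(matrix(rnorm(f * k), f, k)))
  z <- matrix(rnorm(n * k), n, k) %*% diag(c(3, 2, 1))
  a <- z %*% t(w)
  tb <- hemishift:::matrix_to_tbl(a, sprintf("p%03d", 1:n))
  colnames(a) <- names(tb)[-1]
  basis <- fit_pattern_basis(tb, k)
  # subspace recovery: principal angles ~ 0
  sv <- svd(t(w) %*% basis$v)$d
  expect_true(all(acos(pmin(sv, 1)) < 1e-6))
  # orthonormality
  expect_equal(crossprod(basis$v), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  # row permutation invariance
  perm <- sample(n)
  basis2 <- fit_pattern_basis(tb[perm, ], k)
  expect_equal(basis$v, basis2$v, tolerance = 1e-8)
  # k beyond rank errors
  expect_error(fit_pattern_basis(tb, 7), "rank")
})

test_that("full-rank basis is a complete orthogonal transform", {
  set.seed(32)
  n <- 60; f <- 8
  tb <- hemishift:::matrix_to_tbl(matrix(rnorm(n * f), n, f),
                                  sprintf("p%03d", 1:n))
  basis <- fit_pattern_basis(tb, f)
  expect_equal(basis$v %*% t(basis$v), diag(f), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("pattern projection is the plain linear map P = A V", {
  set.seed(33)
  f <- 6; k <- 3
  v <- qr.Q(qr(matrix(rnorm(f * k), f, k)))
  v <- hemishift:::fix_column_signs(v)
  rownames(v) <- sprintf("feat%02d", 1:f)
  colnames(v) <- hemishift:::pattern_labels(k)
  basis <- structure(list(v = v, k = k,
                          sign_flips = setNames(rep(1, k), colnames(v)),
                          provenance = "supplied"),
                     class = "pattern_basis")
  # single row equal to the first basis column projects to e1
  a1 <- hemishift:::matrix_to_tbl(matrix(v[, 1], 1,
                                         dimnames = list(NULL, rownames(v))),
                                  "p1")
  p <- project_patterns(a1, basis)
  expect_equal(unname(unlist(p[-1])), c(1, 0, 0), tolerance = 1e-10)
  # zero input -> zero output
  a0 <- hemishift:::matrix_to_tbl(matrix(0, 2, f,
                                         dimnames = list(NULL, rownames(v))),
                                  c("p1", "p2"))
  expect_true(all(unlist(project_patterns(a0, basis)[-1]) == 0))
  # orthonormal projection contracts the Frobenius norm
  am <- matrix(rnorm(5 * f), 5, f, dimnames = list(NULL, rownames(v)))
  a <- hemishift:::matrix_to_tbl(am, sprintf("p%d", 1:5))
  pm <- hemishift:::tbl_to_matrix(project_patterns(a, basis))
  expect_lte(norm(pm, "F"), norm(am, "F") + 1e-12)
  # dimension mismatch errors
  expect_error(project_patterns(a[, 1:3], basis), "dimension mismatch")
})

test_that("change rates follow the closed form with a 365-day year", {
  mk <- function(vals) tibble::tibble(participant_id = "p1", pattern_01 = vals)
  ch <- compute_changes(mk(0.5), mk(1.5), 365)
  expect_equal(ch$lbac$pattern_01, 1)
  expect_equal(ch$mbac$pattern_01, 1)
  ch2 <- compute_changes(mk(1.5), mk(0.5), 730)
  expect_equal(ch2$lbac$pattern_01, -0.5)
  expect_equal(ch2$mbac$pattern_01, 0.5)
  ch3 <- compute_changes(mk(0.7), mk(0.7), 400)
  expect_equal(ch3$lbac$pattern_01, 0)
  expect_error(compute_changes(mk(1), mk(2), 0), "positive")
})

test_that("grey-matter reference has the documented sign convention", {
  atlas <- atlas_spec(cortical = 1, subcortical = 0, tract = 0, cerebellar = 0)
  mk <- function(l, r) tibble::tibble(participant_id = "p1",
                                      L_ctx_01 = l, R_ctx_01 = r)
  # right 100 -> 90, left 100 -> 80 over one year: dG_delta = +10 mm3/yr
  ref <- compute_grey_reference(mk(100, 100), mk(80, 90), atlas, 365)
  expect_equal(ref$dG_R, -10)
  expect_equal(ref$dG_L, -20)
  expect_equal(ref$dG_delta, 10)
  # identical hemispheric change cancels
  ref0 <- compute_grey_reference(mk(100, 100), mk(95, 95), atlas, 365)
  expect_equal(ref0$dG_delta, 0)
  # left declining faster -> positive reference
  expect_gt(ref$dG_delta, 0)
  expect_error(compute_grey_reference(mk(1, 1)[-2], mk(1, 1), atlas, 365),
               "missing cortical")
})

test_that("LBAC sign alignment enforces non-negative correlation with the reference", {
  set.seed(44)
  n <- 5000
  ref_vals <- rnorm(n)
  ids <- sprintf("p%05d", 1:n)
  ref <- tibble::tibble(participant_id = ids, dG_R = ref_vals, dG_L = 0,
                        dG_delta = ref_vals)
  lbac <- cbind(-ref_vals, ref_vals, rnorm(n))
  ch <- changes_from_lbac(lbac, ids)
  aligned <- align_lbac_signs(ch, ref)
  m <- hemishift:::tbl_to_matrix(aligned$lbac)
  expect_equal(cor(m[, 1], ref_vals), 1)
  expect_equal(unname(aligned$sign_flips[1:2]), c(-1, 1))
  expect_equal(cor(m[, 2], ref_vals), 1)
  # independent column: |r| small, flip recorded either way, post r >= 0
  expect_gte(cor(m[, 3], ref_vals), 0)
  expect_lt(abs(cor(m[, 3], ref_vals)), 0.05)
  # mbac untouched by alignment
  expect_equal(aligned$mbac, ch$mbac)
  # zero-variance column warns and keeps +1
  ch0 <- changes_from_lbac(cbind(rep(0, 10)), ids[1:10])
  expect_warning(al0 <- align_lbac_signs(ch0, ref[1:10, ]), "zero-variance")
  expect_equal(unname(al0$sign_flips), 1)
})

test_that("homolog change correlations behave at both extremes", {
  atlas <- atlas_spec(cortical = 2, subcortical = 1, tract = 0, cerebellar = 0)
  set.seed(55)
  n <- 5000
  ids <- sprintf("p%05d", 1:n)
  base <- matrix(1000, n, 6)
  colnames(base) <- c("L_ctx_01", "R_ctx_01", "L_ctx_02", "R_ctx_02",
                      "L_sub_01", "R_sub_01")
  v1 <- hemishift:::matrix_to_tbl(base, ids)
  # perfectly coupled changes
  shared <- rnorm(n)
  coupled <- base + cbind(shared, shared, 2 * shared, 2 * shared,
                          shared, shared)
  v2 <- hemishift:::matrix_to_tbl(coupled, ids)
  hc <- homolog_change_correlation(v1, v2, atlas)
  expect_equal(nrow(hc), 3)
  expect_equal(hc$r, rep(1, 3), tolerance = 1e-12)
  # independent changes: null correlations
  indep <- base + matrix(rnorm(n * 6), n, 6)
  hc0 <- homolog_change_correlation(v1, hemishift:::matrix_to_tbl(indep, ids),
                                    atlas)
  expect_lt(mean(abs(hc0$r)), 0.05)
  # default atlas returns all 55 grey-matter pairs
  b <- small_bundle()
  hc55 <- homolog_change_correlation(b$bilateral_v1, b$bilateral_v2, b$atlas)
  expect_equal(nrow(hc55), 55)
})

test_that("pipeline output matches a direct transcription of the formulas", {
  # oracle: recompute P, LBAC, MBAC from scratch on a 5 x 6 instance
  set.seed(66)
  n <- 5; f <- 6
  ids <- sprintf("p%d", 1:n)
  a1m <- matrix(rnorm(n * f), n, f, dimnames = list(NULL, sprintf("f%d", 1:f)))
  a2m <- a1m + matrix(rnorm(n * f, sd = 0.3), n, f)
  dt <- c(700, 750, 800, 850, 900)
  k <- 2
  basis <- fit_pattern_basis(hemishift:::matrix_to_tbl(a1m, ids), k)
  p1 <- project_patterns(hemishift:::matrix_to_tbl(a1m, ids), basis)
  p2 <- project_patterns(hemishift:::matrix_to_tbl(a2m, ids), basis)
  ch <- compute_changes(p1, p2, dt)
  # direct re-implementation
  v <- svd(a1m)$v[, 1:k]
  for (j in 1:k) if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  p1o <- a1m %*% v; p2o <- a2m %*% v
  lbac_o <- (p2o - p1o) / dt * 365
  expect_equal(unname(hemishift:::tbl_to_matrix(p1)), unname(p1o),
               tolerance = 1e-10)
  expect_equal(unname(hemishift:::tbl_to_matrix(ch$lbac)), unname(lbac_o),
               tolerance = 1e-10)
  expect_equal(unname(hemishift:::tbl_to_matrix(ch$mbac)), unname(abs(lbac_o)),
               tolerance = 1e-10)
})

test_that("visit-1 pattern expressions from a fitted basis are uncorrelated", {
  res <- small_pipeline()
  p1 <- hemishift:::tbl_to_matrix(res$p1)
  cc <- cor(p1)
  diag(cc) <- 0
  expect_lt(max(abs(cc)), 1e-8)
})

test_that("mbac equals |lbac| across a realistic pipeline run", {
  res <- small_pipeline()
  expect_equal(hemishift:::tbl_to_matrix(res$changes$mbac),
               abs(hemishift:::tbl_to_matrix(res$changes$lbac)),
               tolerance = 1e-12)
  # post-alignment correlations with the grey reference are non-negative
  ref <- res$changes$grey_reference$dG_delta
  l <- hemishift:::tbl_to_matrix(res$changes$lbac)
  expect_true(all(apply(l, 2, function(x) cor(x, ref)) >= 0))
})
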