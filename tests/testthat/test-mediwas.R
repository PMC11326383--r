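synthetic_map <- function() {
  tibble::tibble(
    icd_code = c("A01.1", "A01.2", "A02.1", "B01.1", "B02.1", "001.1"),
    icd_version = c(10L, 10L, 10L, 10L, 10L, 9L),
    phecode = c("PH1", "PH1", "PH2", "PH3", "PH4", "PH4"),
    disease_class = c("ClassA", "ClassA", "ClassA", "ClassB", "ClassB",
                      "ClassB"))
}

test_that("ICD records binarize into phecodes with class bookkeeping", {
  map <- synthetic_map()
  rec <- tibble::tibble(
    participant_id = c("p1", "p1", "p2", "p3", "p3"),
    icd_code = c("A01.1", "A01.2", "B01.1", "001.1", "ZZZ"),
    icd_version = c(10L, 10L, 10L, 9L, 10L))
  expect_message(pm <- map_icd_to_phecodes(rec, map,
                                           participants = c("p1", "p2", "p3", "p4")),
                 "absent from the map")
  expect_equal(attr(pm, "n_unmapped"), 1)
  # two codes for one phecode still give 1, not 2
  expect_equal(pm$PH1[pm$participant_id == "p1"], 1)
  # participant with no diagnoses keeps an all-zero row
  expect_equal(sum(unlist(pm[pm$participant_id == "p4", -1])), 0)
  expect_true(all(unlist(pm[-1]) %in% c(0, 1)))
  # class partition follows the map
  cls <- attr(pm, "classes")
  expect_equal(sort(cls$disease_class[match(c("PH1", "PH3"), cls$phecode)]),
               c("ClassA", "ClassB"))
  expect_error(map_icd_to_phecodes(tibble::tibble(participant_id = "p1",
                                                  icd_code = "",
                                                  icd_version = 10L), map),
               "malformed")
  dup <- map; dup$disease_class[2] <- "ClassB"  # PH1 now in two classes
  expect_error(map_icd_to_phecodes(rec, dup), "more than one disease class")
})

test_that("per-class phecode counts in the simulated cohort match the plant", {
  b <- small_bundle()
  pm <- map_icd_to_phecodes(b$icd_records, b$phecode_map,
                            participants = b$demographics$participant_id)
  cls <- attr(pm, "classes")
  planted <- b$config$disease_class_spec
  observed <- table(cls$disease_class)
  # every observed class respects its planted column budget
  for (cl in names(observed)) {
    expect_lte(observed[[cl]],
               planted$n_phecodes[planted$disease_class == cl])
  }
})

test_that("permutation retention keeps correlated structure and drops noise", {
  set.seed(41)
  n <- 2000
  # planted one-factor block: exactly the structure retention should find
  u <- rnorm(n)
  block <- (0.6 * u + sqrt(1 - 0.36) * matrix(rnorm(n * 6), n, 6)) >
    qnorm(0.9)
  ret <- pca_retention(block * 1, n_perm = 5, seed = 1)
  expect_gte(ret$n_retained, 1)
  # duplicated column pair: first component always survives
  dupe <- cbind(a = rbinom(n, 1, 0.2))
  dupe <- cbind(dupe, b = dupe[, 1], c = rbinom(n, 1, 0.2))
  ret2 <- pca_retention(dupe, n_perm = 5, seed = 1)
  expect_gte(ret2$n_retained, 1)
  # column-order invariance of the retained count
  ret3 <- pca_retention(dupe[, c(3, 1, 2)], n_perm = 5, seed = 1)
  expect_equal(ret3$n_retained, ret2$n_retained)
  expect_error(pca_retention(matrix(1, 10, 3)), "constant block")
  expect_error(pca_retention(matrix(rnorm(4), 2, 2)), ">= 2 columns and >= 3 rows")
})

test_that("connectivity reduction is a deterministic centered PCA", {
  set.seed(42)
  x <- matrix(rnorm(100 * 30), 100, 30)
  expect_warning(sc <- reduce_fmri_block(x, 100), "keeping all")
  expect_equal(ncol(sc), 30)
  sc2 <- suppressWarnings(reduce_fmri_block(x, 100))
  expect_identical(sc, sc2)
  # rank-5 input keeps only 5 informative components
  low <- matrix(rnorm(100 * 5), 100, 5) %*% matrix(rnorm(5 * 30), 5, 30)
  expect_warning(scl <- reduce_fmri_block(low, 20), "rank-deficient")
  expect_equal(ncol(scl), 5)
  # scores span the centered input subspace up to rotation
  q <- qr.Q(qr(matrix(rnorm(100 * 10), 100, 10)))
  scq <- reduce_fmri_block(q, 10)
  expect_true(all(cancor(scale(q, scale = FALSE), scq)$cor > 1 - 1e-8))
})

test_that("CCA and PLS-C variates behave at the fixed points", {
  set.seed(43)
  n <- 500
  x <- matrix(rnorm(n * 4), n, 4)
  # identical blocks: first canonical correlation is 1
  cp <- cca_plsc_clusters(x, x, 2, ridge = 1e-8)
  expect_gt(cp$cca$correlations[1], 0.999)
  # planted shared factor across distinct blocks is recovered
  shared <- rnorm(n)
  xb <- 0.8 * shared + matrix(rnorm(n * 5, sd = 0.6), n, 5)
  yb <- -0.7 * shared + matrix(rnorm(n * 8, sd = 0.6), n, 8)
  cp2 <- cca_plsc_clusters(xb, yb, 1, ridge = 1e-3)
  expect_gt(abs(cor(cp2$cca$scores[, 1], shared)), 0.8)
  expect_gt(abs(cor(cp2$plsc$scores[, 1], shared)), 0.8)
  # independent blocks: first canonical correlation stays below the
  # permutation 95th percentile
  x0 <- matrix(rnorm(n * 4), n, 4)
  y0 <- matrix(rnorm(n * 6), n, 6)
  c_obs <- cca_plsc_clusters(x0, y0, 1, ridge = 1e-3)$cca$correlations[1]
  c_perm <- replicate(40, {
    cca_plsc_clusters(x0[sample(n), ], y0, 1, ridge = 1e-3)$cca$correlations[1]
  })
  expect_lt(c_obs, quantile(c_perm, 0.95) + 0.05)
  expect_error(cca_plsc_clusters(x, x, 10), "rank bound")
})

test_that("CCA agrees with the stats::cancor reference when unregularized", {
  set.seed(44)
  n <- 400
  x <- matrix(rnorm(n * 3), n, 3)
  y <- x %*% matrix(rnorm(9), 3, 3) + matrix(rnorm(n * 3, sd = 2), n, 3)
  ours <- cca_plsc_clusters(x, y, 3, ridge = 1e-10)
  ref <- cancor(x, y)
  expect_equal(ours$cca$correlations, ref$cor, tolerance = 1e-6)
})

test_that("cluster bookkeeping ties totals to retained components", {
  b <- small_bundle()
  pm <- map_icd_to_phecodes(b$icd_records, b$phecode_map,
                            participants = b$demographics$participant_id)
  cl <- suppressWarnings(build_disease_clusters(pm, b$fmri, seed = 4))
  expect_equal(ncol(cl$scores), 3 * sum(cl$retained_per_class))
  expect_true(all(cl$meta$technique %in% c("PCA", "CCA", "PLSC")))
  counts <- table(cl$meta$technique)
  if (length(counts)) expect_true(all(counts == counts[1]))
})

test_that("association scan controls multiplicity as configured", {
  set.seed(45)
  n <- 300
  ids <- sprintf("s%04d", 1:n)
  lbac <- matrix(rnorm(n * 2), n, 2)
  ch <- changes_from_lbac(lbac, ids)
  scores <- matrix(rnorm(n * 10), n, 10)
  scores[, 1] <- lbac[, 1]  # cluster identical to an LBAC column
  cl <- clusters_from_scores(scores, ids)
  scan <- mediwas_scan(ch, cl, alpha = 0.05, fdr_q = 0.05)
  expect_equal(attr(scan, "bonferroni_threshold"), 0.05 / 10)
  hit <- dplyr::filter(scan, cluster_id == "cluster_001", measure == "lbac",
                       pattern == 1)
  expect_equal(hit$r, 1, tolerance = 1e-12)
  expect_true(hit$passes_bonferroni && hit$passes_fdr)
  # BH-passing set contains the Bonferroni-passing set family by family
  expect_true(all(!scan$passes_bonferroni | scan$passes_fdr))
  # bonferroni flag is consistent with the threshold
  expect_equal(scan$passes_bonferroni,
               scan$p < attr(scan, "bonferroni_threshold"))
  # zero-variance cluster column errors
  bad <- clusters_from_scores(cbind(rep(1, n)), ids)
  expect_error(mediwas_scan(ch, bad), "zero-variance|constant")
})
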