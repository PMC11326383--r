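#' Encode between-visit behavioural phenotype changes
#'
#' Builds the change score dPhi = Phi2 - Phi1 per phenotype. Binary and
#' categorical phenotypes are encoded in \{-1, 0, +1\} (behaviour lost /
#' unchanged / gained; multi-level ordered moves are collapsed to their
#' sign). Unordered-categorical phenotypes are expanded to one binary
#' indicator per visit-1 level before differencing. Continuous changes are
#' standardized to mean 0, sd 1 over non-missing values. Per-visit values
#' are never re-standardized before differencing. Phenotypes with a
#' non-missing response rate below 10% at either visit are dropped and
#' logged.
#'
#' @param phenotypes_v1,phenotypes_v2 Phenotype tibbles (participant_id +
#'   one column per phenotype) for the two visits.
#' @param meta Tibble `id`, `domain`, `var_type`
#'   (`continuous`/`binary`/`ordered`/`unordered`) and optionally
#'   `has_change` (phenotypes with `has_change = FALSE` are skipped).
#' @param min_response Minimum response rate (default 0.1).
#' @return Tibble `participant_id` + encoded dPhi columns; attributes
#'   `meta` (encoded-column metadata) and `dropped` (tibble of dropped
#'   phenotypes with reasons).
#' @export
encode_phenotype_changes <- function(phenotypes_v1, phenotypes_v2, meta,
                                     min_response = 0.1) {
  stopifnot(identical(phenotypes_v1$participant_id,
                      phenotypes_v2$participant_id))
  if ("has_change" %in% names(meta)) meta <- meta[meta$has_change, ]
  n <- nrow(phenotypes_v1)
  out <- list()
  out_meta <- list()
  dropped <- tibble(id = character(), reason = character())
  for (i in seq_len(nrow(meta))) {
    id <- meta$id[i]; vt <- meta$var_type[i]
    v1 <- phenotypes_v1[[id]]; v2 <- phenotypes_v2[[id]]
    if (is.null(v1) || is.null(v2)) {
      dropped <- dplyr::bind_rows(dropped, tibble(id = id, reason = "absent at a visit"))
      next
    }
    rr1 <- mean(!is.na(v1)); rr2 <- mean(!is.na(v2))
    if (n == 0 || rr1 < min_response || rr2 < min_response) {
      dropped <- dplyr::bind_rows(dropped, tibble(
        id = id, reason = sprintf("response rate below %g%% (v1 %.1f%%, v2 %.1f%%)",
                                  100 * min_response, 100 * rr1, 100 * rr2)))
      next
    }
    if (vt == "unordered") {
      if (!is.character(v1)) v1 <- as.character(v1)
      if (!is.character(v2)) {
        warn(paste0("phenotype ", id, ": visit-2 encoding recoded to visit-1 rule"))
        v2 <- as.character(v2)
      }
      for (lev in sort(unique(v1[!is.na(v1)]))) {
        d <- as.numeric(v2 == lev) - as.numeric(v1 == lev)
        out[[paste0(id, ".", lev)]] <- d
        out_meta[[paste0(id, ".", lev)]] <- tibble(
          id = paste0(id, ".", lev), source_id = id,
          domain = meta$domain[i], var_type = "indicator")
      }
    } else if (vt == "continuous") {
      if (!is.numeric(v2)) {
        warn(paste0("phenotype ", id, ": visit-2 encoding recoded to visit-1 rule"))
        v2 <- suppressWarnings(as.numeric(v2))
      }
      d <- v2 - v1
      s <- sd(d, na.rm = TRUE)
      d <- if (is.finite(s) && s > 0) (d - mean(d, na.rm = TRUE)) / s else d * 0
      out[[id]] <- d
      out_meta[[id]] <- tibble(id = id, source_id = id,
                               domain = meta$domain[i], var_type = "continuous")
    } else {  # binary or ordered-categorical
      if (!is.numeric(v2)) {
        warn(paste0("phenotype ", id, ": visit-2 encoding recoded to visit-1 rule"))
        v2 <- suppressWarnings(as.numeric(v2))
      }
      out[[id]] <- sign(v2 - v1)
      out_meta[[id]] <- tibble(id = id, source_id = id,
                               domain = meta$domain[i], var_type = vt)
    }
  }
  res <- tibble::add_column(as_tibble(out),
                            participant_id = phenotypes_v1$participant_id,
                            .before = 1)
  attr(res, "meta") <- if (length(out_meta)) dplyr::bind_rows(out_meta) else
    tibble(id = character(), source_id = character(), domain = character(),
           var_type = character())
  attr(res, "dropped") <- dropped
  if (nrow(dropped)) {
    inform(paste0("dropped ", nrow(dropped), " phenotype(s): ",
                  paste(dropped$id, collapse = ", ")))
  }
  res
}

#' Encode baseline phenotypes for regression
#'
#' Numeric phenotypes pass through; unordered-categorical phenotypes are
#' expanded to one indicator per level.
#'
#' @inheritParams encode_phenotype_changes
#' @param phenotypes Phenotype tibble for one visit.
#' @return Tibble `participant_id` + numeric columns; attribute `meta` maps
#'   encoded columns to source phenotypes and domains.
#' @export
encode_baseline_phenotypes <- function(phenotypes, meta) {
  out <- list(); out_meta <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$id[i]; vt <- meta$var_type[i]
    v <- phenotypes[[id]]
    if (is.null(v)) next
    if (vt == "unordered") {
      v <- as.character(v)
      for (lev in sort(unique(v[!is.na(v)]))) {
        out[[paste0(id, ".", lev)]] <- as.numeric(v == lev)
        out_meta[[paste0(id, ".", lev)]] <- tibble(
          id = paste0(id, ".", lev), source_id = id,
          domain = meta$domain[i], var_type = "indicator")
      }
    } else {
      out[[id]] <- as.numeric(v)
      out_meta[[id]] <- tibble(id = id, source_id = id,
                               domain = meta$domain[i], var_type = vt)
    }
  }
  res <- tibble::add_column(as_tibble(out),
                            participant_id = phenotypes$participant_id,
                            .before = 1)
  attr(res, "meta") <- dplyr::bind_rows(out_meta)
  res
}

#' Demographic covariate set
#'
#' The six demographic regressors included in every phenome model: age at
#' first visit, sex, age^2, age x sex, age^2 x sex, and days between visits.
#' Derived columns are exact functions of age and sex.
#'
#' @param demographics Tibble with `participant_id`, `age` (years), `sex`
#'   (0/1) and `delta_t_days`.
#' @return Tibble `participant_id` + the 6 covariate columns.
#' @export
demographic_covariates <- function(demographics) {
  tibble(
    participant_id = demographics$participant_id,
    age = demographics$age,
    sex = demographics$sex,
    age2 = demographics$age^2,
    age_sex = demographics$age * demographics$sex,
    age2_sex = demographics$age^2 * demographics$sex,
    delta_t = demographics$delta_t_days
  )
}

#' Adjusted coefficient of determination
#'
#' Standard form (default): 1 - (1 - R0^2) (n - 1) / (n - d - 1).
#' `as_printed = TRUE` instead computes R0^2 (n - 1) / (n - d - 1) — a
#' variant that can exceed 1 and is provided for exact comparability with
#' analyses that used it; both forms coincide at d = 0.
#'
#' @param r0_sq Unadjusted in-sample R^2.
#' @param n Number of observations.
#' @param d Number of non-intercept regressors.
#' @param as_printed Use the multiplicative variant.
#' @return Adjusted R^2 (can be negative in the standard form).
#' @export
adjusted_r2 <- function(r0_sq, n, d, as_printed = FALSE) {
  if (any(n <= d + 1)) abort("adjusted R^2 requires n > d + 1")
  if (as_printed) r0_sq * (n - 1) / (n - d - 1)
  else 1 - (1 - r0_sq) * (n - 1) / (n - d - 1)
}

#' L2-penalized (ridge) linear regression
#'
#' Features are standardized (mean 0, sd 1) before penalization; the
#' intercept is unpenalized. Coefficients solve
#' (X'X + lambda I) beta = X'y on the standardized scale, so `lambda = 0`
#' reproduces ordinary least squares exactly on full-rank designs.
#'
#' @param y Response vector.
#' @param x Feature matrix or tibble (no intercept column).
#' @param lambda Ridge penalty on standardized features (default 1).
#' @return A `ridge_fit`: standardized-scale `beta`, `intercept`, fitted
#'   values, `r0_sq`, `n`, `d`.
#' @export
ridge_regression <- function(y, x, lambda = 1) {
  x <- as.matrix(x)
  keep <- !is.na(y) & complete.cases(x)
  y <- y[keep]; x <- x[keep, , drop = FALSE]
  n <- length(y)
  if (n < 3) abort("too few complete cases")
  if (sd(y) == 0) abort("target is constant")
  std <- standardize_columns(x)
  xs <- std$x
  yc <- y - mean(y)
  d <- ncol(xs)
  beta <- solve(crossprod(xs) + diag(lambda, d), crossprod(xs, yc))
  fitted <- drop(xs %*% beta) + mean(y)
  r0 <- 1 - sum((y - fitted)^2) / sum(yc^2)
  structure(list(beta = setNames(drop(beta), colnames(x)),
                 intercept = mean(y),
                 feature_mean = std$mean, feature_sd = std$sd,
                 fitted = fitted, r0_sq = r0, n = n, d = d,
                 lambda = lambda, kept = keep),
            class = "ridge_fit")
}

predict_ridge <- function(fit, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, fit$feature_mean, "-"), 2, fit$feature_sd, "/")
  drop(xs %*% fit$beta) + fit$intercept
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat("<ridge_fit> n =", x$n, " d =", x$d, " lambda =", x$lambda,
      " R0^2 =", signif(x$r0_sq, 4), "\n")
  invisible(x)
}

#' Domain regression of one asymmetry-change target
#'
#' Ridge fit of a single LBAC or MBAC column on one phenotype-domain block
#' plus the six demographic covariates, reported with the adjusted R^2 (d =
#' demographic + domain feature count) and a demographics-only baseline fit
#' for comparison. Complete-case rows below 10 x (d + 1) trigger a warning.
#'
#' @param target Numeric target vector (one pattern's LBAC or MBAC).
#' @param domain_block Tibble/matrix of domain phenotype features.
#' @param demo Demographic covariate tibble from [demographic_covariates()]
#'   (`participant_id` dropped if present).
#' @param lambda Ridge penalty.
#' @param as_printed Passed to [adjusted_r2()].
#' @return List: `fit`, `baseline_fit` (`ridge_fit`s), `adj_r2`,
#'   `baseline_adj_r2`, `top_feature`, `top_beta`.
#' @export
domain_regression <- function(target, domain_block, demo, lambda = 1,
                              as_printed = FALSE) {
  demo <- as.matrix(demo[setdiff(colnames(demo), "participant_id")])
  domain_block <- as.matrix(domain_block[setdiff(colnames(domain_block),
                                                 "participant_id")])
  if (ncol(domain_block) == 0) abort("empty domain block")
  x <- cbind(demo, domain_block)
  nc <- sum(!is.na(target) & complete.cases(x))
  if (nc < 10 * (ncol(x) + 1)) {
    warn(sprintf("only %d complete cases for %d features (< 10 per feature)",
                 nc, ncol(x)))
  }
  fit <- ridge_regression(target, x, lambda)
  base <- ridge_regression(target, demo, lambda)
  dom_beta <- fit$beta[colnames(domain_block)]
  top <- which.max(abs(dom_beta))
  list(fit = fit, baseline_fit = base,
       adj_r2 = adjusted_r2(fit$r0_sq, fit$n, fit$d, as_printed),
       baseline_adj_r2 = adjusted_r2(base$r0_sq, base$n, base$d, as_printed),
       top_feature = names(dom_beta)[top], top_beta = unname(dom_beta[top]))
}

#' Phenome-wide domain scan over all asymmetry-change targets
#'
#' Runs [domain_regression()] for every (measure, pattern) target against
#' every baseline phenotype domain and every change domain: with 11 baseline
#' and 9 change domains this is the 20-group analysis layout.
#'
#' @param changes An `asym_changes` object.
#' @param bundle A `cohort_bundle` (phenotype tables, metadata,
#'   demographics).
#' @param lambda Ridge penalty.
#' @return Long tibble: target `measure`/`pattern`, `domain`,
#'   `domain_kind` (`baseline`/`change`), `n`, `d`, `r0_sq`, `adj_r2`,
#'   `baseline_adj_r2`, `top_feature`, `top_beta`.
#' @export
phenome_domain_scan <- function(changes, bundle, lambda = 1) {
  ids <- changes$lbac$participant_id
  demo <- demographic_covariates(bundle$demographics)
  demo <- demo[match(ids, demo$participant_id), ]
  base_enc <- encode_baseline_phenotypes(bundle$phenotypes_v1,
                                         bundle$phenotype_meta)
  base_enc <- base_enc[match(ids, base_enc$participant_id), ]
  chg_enc <- encode_phenotype_changes(bundle$phenotypes_v1,
                                      bundle$phenotypes_v2,
                                      bundle$phenotype_meta)
  chg_enc <- chg_enc[match(ids, chg_enc$participant_id), ]
  blocks <- c(
    purrr::map(split(attr(base_enc, "meta")$id,
                     attr(base_enc, "meta")$domain),
               ~ list(kind = "baseline", cols = .x, enc = base_enc)),
    purrr::map(split(attr(chg_enc, "meta")$id,
                     attr(chg_enc, "meta")$domain),
               ~ list(kind = "change", cols = .x, enc = chg_enc))
  )
  purrr::map_dfr(c(lbac = "lbac", mbac = "mbac"), function(meas) {
    m <- tbl_to_matrix(changes[[meas]])
    purrr::map_dfr(seq_len(ncol(m)), function(j) {
      purrr::imap_dfr(blocks, function(bl, dom) {
        res <- domain_regression(m[, j], bl$enc[bl$cols], demo, lambda)
        tibble(measure = meas, pattern = j, domain = dom,
               domain_kind = bl$kind, n = res$fit$n, d = res$fit$d,
               r0_sq = res$fit$r0_sq, adj_r2 = res$adj_r2,
               baseline_adj_r2 = res$baseline_adj_r2,
               top_feature = res$top_feature, top_beta = res$top_beta)
      })
    })
  })
}

#' Behavioural-change regression with permuted-label null
#'
#' Ridge fit of one encoded behavioural change dPhi on the six demographic
#' covariates plus all K LBACs and K MBACs. The permutation null refits
#' after jointly row-shuffling the brain-change block only (demographics
#' intact); the reported gain is the adjusted R^2 minus the mean null
#' adjusted R^2. Attribution is the category (lbac / mbac / demographic) and
#' name of the largest-|beta| standardized feature.
#'
#' @param dphi Encoded behavioural-change vector.
#' @param changes An `asym_changes` object.
#' @param demo Demographic covariates (rows matched to `changes`).
#' @param lambda Ridge penalty.
#' @param n_perm Number of label permutations (default 100).
#' @param seed Seed for the permutation stream.
#' @return List: `fit`, `adj_r2`, `null_adj_r2` (mean), `null_sd`, `gain`,
#'   `attribution_category`, `attribution_feature`.
#' @export
behaviour_change_regression <- function(dphi, changes, demo, lambda = 1,
                                        n_perm = 100, seed = 1) {
  demo_m <- as.matrix(demo[setdiff(colnames(demo), "participant_id")])
  l <- tbl_to_matrix(changes$lbac); m <- tbl_to_matrix(changes$mbac)
  colnames(l) <- paste0("lbac_", colnames(l))
  colnames(m) <- paste0("mbac_", colnames(m))
  brain <- cbind(l, m)
  fit <- ridge_regression(dphi, cbind(demo_m, brain), lambda)
  adj <- adjusted_r2(fit$r0_sq, fit$n, fit$d)
  nulls <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- sample(nrow(brain))
    f <- ridge_regression(dphi, cbind(demo_m, brain[perm, , drop = FALSE]),
                          lambda)
    adjusted_r2(f$r0_sq, f$n, f$d)
  }, numeric(1)))
  top <- which.max(abs(fit$beta))
  nm <- names(fit$beta)[top]
  cat_ <- if (startsWith(nm, "lbac_")) "lbac"
          else if (startsWith(nm, "mbac_")) "mbac" else "demographic"
  list(fit = fit, adj_r2 = adj,
       null_adj_r2 = mean(nulls), null_sd = sd(nulls),
       gain = adj - mean(nulls),
       attribution_category = cat_, attribution_feature = nm)
}

#' Scan all behavioural changes against brain asymmetry changes
#'
#' @param changes An `asym_changes` object.
#' @param bundle A `cohort_bundle`.
#' @param lambda Ridge penalty.
#' @param n_perm Permutations per model.
#' @param seed Seed for the permutation streams.
#' @return Long tibble: `phenotype`, `domain`, `n`, `adj_r2`, `null_adj_r2`,
#'   `gain`, `attribution_category`, `attribution_feature`.
#' @export
behaviour_change_scan <- function(changes, bundle, lambda = 1, n_perm = 100,
                                  seed = 1) {
  ids <- changes$lbac$participant_id
  demo <- demographic_covariates(bundle$demographics)
  demo <- demo[match(ids, demo$participant_id), ]
  enc <- encode_phenotype_changes(bundle$phenotypes_v1, bundle$phenotypes_v2,
                                  bundle$phenotype_meta)
  enc <- enc[match(ids, enc$participant_id), ]
  meta <- attr(enc, "meta")
  purrr::map_dfr(seq_len(nrow(meta)), function(i) {
    id <- meta$id[i]
    y <- enc[[id]]
    if (is.na(sd(y, na.rm = TRUE)) || sd(y, na.rm = TRUE) == 0) {
      return(tibble(phenotype = id, domain = meta$domain[i], n = NA_integer_,
                    adj_r2 = NA_real_, null_adj_r2 = NA_real_,
                    gain = NA_real_, attribution_category = NA_character_,
                    attribution_feature = NA_character_))
    }
    res <- behaviour_change_regression(y, changes, demo, lambda, n_perm,
                                       seed = substream_seed(seed, id))
    tibble(phenotype = id, domain = meta$domain[i], n = res$fit$n,
           adj_r2 = res$adj_r2, null_adj_r2 = res$null_adj_r2,
           gain = res$gain, attribution_category = res$attribution_category,
           attribution_feature = res$attribution_feature)
  })
}

# Total bilateral volume per tissue class per visit.
tissue_totals <- function(bilateral, atlas, tissue) {
  cls <- switch(tissue,
                grey = c("cortical", "subcortical", "cerebellar"),
                white = "tract",
                grey_white = c("cortical", "subcortical", "cerebellar", "tract"),
                abort(paste0("unknown tissue class: ", tissue)))
  pairs <- atlas$pair[atlas$class %in% cls]
  if (!length(pairs)) abort(paste0("tissue class absent from atlas: ", tissue))
  rowSums(bilateral[paste0("L_", pairs)]) + rowSums(bilateral[paste0("R_", pairs)])
}

#' Predict total brain-volume change from asymmetry changes
#'
#' Competing L2-penalized models of the yearly total-volume change for a
#' tissue class: asymmetry features (all LBACs, or all MBACs) versus an
#' age-sex baseline (age, sex, age^2, age x sex, age^2 x sex), scored by
#' k-fold cross-validated out-of-sample R^2. With `target = "baseline"` the
#' same machinery predicts the visit-1 total volume instead of its change.
#'
#' @param changes An `asym_changes` object.
#' @param bundle A `cohort_bundle`.
#' @param tissue One of `"grey"`, `"white"`, `"grey_white"`.
#' @param target `"change"` (yearly total-volume change) or `"baseline"`
#'   (visit-1 total volume).
#' @param lambda Ridge penalty.
#' @param k_folds Cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @return Tibble: `tissue`, `target`, `model`
#'   (`lbac`/`mbac`/`age_sex`), `r2_cv`.
#' @export
volume_change_prediction <- function(changes, bundle, tissue = "grey",
                                     target = c("change", "baseline"),
                                     lambda = 1, k_folds = 5, seed = 1) {
  target <- match.arg(target)
  ids <- changes$lbac$participant_id
  b1 <- bundle$bilateral_v1[match(ids, bundle$bilateral_v1$participant_id), ]
  b2 <- bundle$bilateral_v2[match(ids, bundle$bilateral_v2$participant_id), ]
  demo <- bundle$demographics[match(ids, bundle$demographics$participant_id), ]
  t1 <- tissue_totals(b1, bundle$atlas, tissue)
  y <- if (target == "change") {
    (tissue_totals(b2, bundle$atlas, tissue) - t1) / demo$delta_t_days * 365
  } else t1
  feats <- list(
    lbac = tbl_to_matrix(changes$lbac),
    mbac = tbl_to_matrix(changes$mbac),
    age_sex = cbind(age = demo$age, sex = demo$sex, age2 = demo$age^2,
                    age_sex = demo$age * demo$sex,
                    age2_sex = demo$age^2 * demo$sex)
  )
  if (sd(y) == 0) {
    # a constant target carries no explainable variance: every model scores 0
    return(purrr::imap_dfr(feats, function(x, model) {
      tibble(tissue = tissue, target = target, model = model, r2_cv = 0)
    }))
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), length(y))))
  purrr::imap_dfr(feats, function(x, model) {
    pred <- rep(NA_real_, length(y))
    for (f in seq_len(k_folds)) {
      test <- folds == f
      fit <- ridge_regression(y[!test], x[!test, , drop = FALSE], lambda)
      pred[test] <- predict_ridge(fit, x[test, , drop = FALSE])
    }
    r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    tibble(tissue = tissue, target = target, model = model, r2_cv = r2)
  })
}

#' PCA summary of a coefficient matrix
#'
#' Centered principal component analysis of a (models x phenotype-features)
#' coefficient matrix, used to summarize recurring phenotype motifs across
#' the per-pattern, per-domain regression fits. Missing feature columns
#' should be zero-filled before calling. Loading signs follow the
#' largest-|loading|-positive convention. If the centered matrix is zero
#' (all models identical) no components are returned, with a warning.
#'
#' @param coef_matrix Numeric matrix, rows = models, columns = features.
#' @param n_components Maximum number of components to return.
#' @return List: `loadings` (features x components), `scores`,
#'   `explained_variance` (proportions), `n_components`.
#' @export
coefficient_pca <- function(coef_matrix, n_components = 5) {
  coef_matrix <- as.matrix(coef_matrix)
  if (nrow(coef_matrix) < 2) abort("need at least 2 models")
  centered <- scale(coef_matrix, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) {
    warn("coefficient matrix has no variance across models: no components")
    return(list(loadings = NULL, scores = NULL,
                explained_variance = numeric(0), n_components = 0L))
  }
  pc <- prcomp(coef_matrix, center = TRUE, scale. = FALSE)
  nz <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  k <- min(n_components, nz, nrow(coef_matrix) - 1, ncol(coef_matrix))
  load <- fix_column_signs(pc$rotation[, seq_len(k), drop = FALSE])
  scores <- centered %*% load
  list(loadings = load, scores = scores,
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       n_components = as.integer(k))
}
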