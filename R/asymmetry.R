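#' Lateralization index of a homologous feature pair
#'
#' LI = (R - L) / (0.5 * (R + L)): a bounded, size-normalized left-right
#' imbalance. Positive values indicate a larger right homolog. Both homologs
#' must be non-negative; where both are zero the index is undefined and a
#' missing value is emitted (with a warning).
#'
#' @param right,left Non-negative measurement vectors (volumes or FA).
#' @return Numeric vector of LIs in \[-2, 2\].
#' @examples
#' compute_li(3, 1)  # 1
#' compute_li(2, 2)  # 0
#' compute_li(0, 4)  # -2
#' @export
compute_li <- function(right, left) {
  if (any(right < 0, na.rm = TRUE) || any(left < 0, na.rm = TRUE)) {
    abort("negative homolog measurements: volumes and FA cannot be negative")
  }
  both_zero <- !is.na(right) & !is.na(left) & right == 0 & left == 0
  if (any(both_zero)) {
    warn(sprintf("%d pair(s) with both homologs zero: LI undefined, set NA",
                 sum(both_zero)))
  }
  li <- (right - left) / (0.5 * (right + left))
  li[both_zero] <- NA_real_
  li
}

#' Lateralization-index table from a bilateral measurement table
#'
#' @param bilateral Tibble with `participant_id` and `L_<pair>` / `R_<pair>`
#'   columns for every pair of `atlas`.
#' @param atlas Atlas tibble from [atlas_spec()].
#' @return Tibble `participant_id` + one raw-LI column per pair, with
#'   attribute `stage = "raw"`.
#' @export
bilateral_to_li <- function(bilateral, atlas) {
  bc <- bilateral_cols(atlas)
  missing <- setdiff(c(bc$left, bc$right), names(bilateral))
  if (length(missing)) {
    abort(paste0("bilateral table is missing columns: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  li <- compute_li(as.matrix(bilateral[bc$right]), as.matrix(bilateral[bc$left]))
  colnames(li) <- atlas$pair
  out <- matrix_to_tbl(li, bilateral$participant_id)
  attr(out, "stage") <- "raw"
  out
}

#' Fit the technical deconfounding and standardization model
#'
#' Per-feature ordinary least squares of raw LIs on the technical confound
#' columns (plus intercept), fitted on visit-1 data only. Standardization
#' mean and sd are computed on the residuals. The model is then frozen and
#' applied unchanged to both visits, so visit-2 values are expressed on the
#' visit-1 scale.
#'
#' @param li Raw LI tibble from [bilateral_to_li()], visit 1.
#' @param confounds Tibble with `participant_id` and numeric confound
#'   columns (a `visit` column, if present, is dropped).
#' @return A `deconfound_model`: coefficients (confounds + intercept, per
#'   feature), residual mean/sd per feature, confound names, fit ids.
#' @export
fit_deconfound <- function(li, confounds) {
  confounds <- confounds[setdiff(names(confounds), "visit")]
  confounds <- confounds[match(li$participant_id, confounds$participant_id), ]
  x <- tbl_to_matrix(confounds)
  y <- tbl_to_matrix(li)
  keep <- complete.cases(x) & complete.cases(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  design <- cbind(`(Intercept)` = 1, x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    abort(paste0("rank-deficient confound matrix; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrd, y)
  resid <- y - design %*% beta
  mu <- colMeans(resid)
  sdev <- apply(resid, 2, sd)
  if (any(sdev <= sqrt(.Machine$double.eps))) {
    abort(paste0("zero residual sd after deconfounding for feature(s): ",
                 paste(colnames(y)[sdev <= sqrt(.Machine$double.eps)],
                       collapse = ", ")))
  }
  structure(list(coefficients = beta, mean = mu, sd = sdev,
                 confound_names = colnames(x),
                 fit_ids = li$participant_id[keep]),
            class = "deconfound_model")
}

#' Apply a frozen deconfounding model
#'
#' Output is `(LI - confounds %*% beta - mean) / sd` using the stored
#' parameters. Applied to its own fit data every column has mean 0 and sd 1;
#' applied to another visit no re-centering occurs.
#'
#' @param li Raw LI tibble.
#' @param model A `deconfound_model` from [fit_deconfound()].
#' @param confounds Confound table matching the visit of `li`.
#' @return Deconfounded-standardized LI tibble (attribute
#'   `stage = "deconfounded-standardized"`).
#' @export
apply_deconfound <- function(li, model, confounds) {
  stopifnot(inherits(model, "deconfound_model"))
  confounds <- confounds[setdiff(names(confounds), "visit")]
  missing <- setdiff(model$confound_names, names(confounds))
  if (length(missing)) {
    abort(paste0("missing confound column(s): ", paste(missing, collapse = ", ")))
  }
  confounds <- confounds[match(li$participant_id, confounds$participant_id), ]
  x <- cbind(`(Intercept)` = 1,
             as.matrix(confounds[model$confound_names]))
  y <- tbl_to_matrix(li)
  feats <- colnames(model$coefficients)
  stopifnot(identical(colnames(y), feats))
  resid <- y - x %*% model$coefficients
  out <- sweep(sweep(resid, 2, model$mean, "-"), 2, model$sd, "/")
  out <- matrix_to_tbl(out, li$participant_id)
  attr(out, "stage") <- "deconfounded-standardized"
  out
}

#' Fit an orthonormal asymmetry-pattern basis by SVD
#'
#' The basis columns are the top-k right singular vectors of the
#' deconfounded-standardized visit-1 LI matrix. Column signs follow a
#' deterministic convention (largest-absolute loading positive); sign flips
#' from grey-reference alignment are stored on the basis afterwards.
#'
#' @param a1 Deconfounded-standardized LI tibble (visit 1).
#' @param k Number of patterns to retain; must not exceed the matrix rank.
#' @return A `pattern_basis`: loading matrix `v` (features x k),
#'   `sign_flips` (+1/-1 per pattern), singular values, provenance.
#' @export
fit_pattern_basis <- function(a1, k) {
  a <- tbl_to_matrix(a1)
  a <- a[complete.cases(a), , drop = FALSE]
  if (k > min(dim(a))) abort("`k` exceeds the rank bound of the LI matrix")
  dec <- svd(a, nu = 0, nv = k)
  if (k > sum(dec$d > dec$d[1] * 1e-10)) {
    abort("`k` exceeds the numerical rank of the LI matrix")
  }
  v <- fix_column_signs(dec$v)
  rownames(v) <- colnames(a)
  colnames(v) <- pattern_labels(k)
  structure(list(v = v, k = as.integer(k),
                 sign_flips = setNames(rep(1, k), colnames(v)),
                 singular_values = dec$d[seq_len(k)],
                 provenance = "fitted"),
            class = "pattern_basis")
}

#' @export
print.pattern_basis <- function(x, ...) {
  cat("<pattern_basis> ", nrow(x$v), " features x ", x$k, " patterns (",
      x$provenance, ")\n", sep = "")
  cat("  sign flips applied:", sum(x$sign_flips < 0), "\n")
  invisible(x)
}

#' Project LIs onto an asymmetry-pattern basis
#'
#' Pattern expression is the linear projection P = A V, with the basis'
#' recorded sign flips applied.
#'
#' @param a Deconfounded-standardized LI tibble.
#' @param basis A `pattern_basis`.
#' @return Tibble `participant_id` + one pattern-expression column per
#'   pattern.
#' @export
project_patterns <- function(a, basis) {
  stopifnot(inherits(basis, "pattern_basis"))
  m <- tbl_to_matrix(a)
  if (ncol(m) != nrow(basis$v)) {
    abort(sprintf("dimension mismatch: %d LI features vs %d basis rows",
                  ncol(m), nrow(basis$v)))
  }
  p <- m %*% sweep(basis$v, 2, basis$sign_flips, "*")
  matrix_to_tbl(p, a$participant_id)
}

#' Lateralized and magnitude asymmetry-change rates
#'
#' LBAC_k = (P_k2 - P_k1) / delta_t_days * 365 (pattern-units/year, signed);
#' MBAC_k = |LBAC_k|. A year is 365 days exactly.
#'
#' @param p1,p2 Pattern-expression tibbles for visits 1 and 2 (matched
#'   participants and patterns).
#' @param delta_t_days Days between visits per participant (> 0), in the
#'   order of `p1`.
#' @return An `asym_changes` object: tibbles `lbac` and `mbac`,
#'   `delta_t_days`, and (once computed) the grey-matter reference and sign
#'   flips.
#' @export
compute_changes <- function(p1, p2, delta_t_days) {
  if (!identical(p1$participant_id, p2$participant_id)) {
    abort("visit-1 and visit-2 pattern tables must have matched participants")
  }
  if (!identical(names(p1), names(p2))) abort("pattern columns must match")
  if (any(delta_t_days <= 0)) abort("delta_t_days must be positive")
  stopifnot(length(delta_t_days) == nrow(p1))
  m1 <- tbl_to_matrix(p1); m2 <- tbl_to_matrix(p2)
  lbac <- (m2 - m1) / delta_t_days * 365
  structure(list(
    lbac = matrix_to_tbl(lbac, p1$participant_id),
    mbac = matrix_to_tbl(abs(lbac), p1$participant_id),
    delta_t_days = delta_t_days,
    grey_reference = NULL,
    sign_flips = setNames(rep(1, ncol(m1)), colnames(m1))
  ), class = "asym_changes")
}

#' @export
print.asym_changes <- function(x, ...) {
  cat("<asym_changes> ", nrow(x$lbac), " participants x ",
      ncol(x$lbac) - 1, " patterns\n", sep = "")
  cat("  grey reference:", if (is.null(x$grey_reference)) "absent" else "present",
      "| aligned flips:", sum(x$sign_flips < 0), "\n")
  invisible(x)
}

#' Hemispheric cortical grey-matter change reference
#'
#' Sums the cortical grey-matter volumes per hemisphere and visit, takes the
#' per-hemisphere yearly change, and returns the right-minus-left difference
#' dG_delta = (dG_R - dG_L) / delta_t_days * 365 in mm^3/year. Positive
#' values mean the left cortex declines faster (or grows slower) than the
#' right.
#'
#' @param bilateral_v1,bilateral_v2 Bilateral tables for both visits.
#' @param atlas Atlas tibble; all cortical pairs must be present.
#' @param delta_t_days Days between visits per participant.
#' @return Tibble `participant_id`, `dG_R`, `dG_L` (mm^3/yr per hemisphere),
#'   `dG_delta`.
#' @export
compute_grey_reference <- function(bilateral_v1, bilateral_v2, atlas,
                                   delta_t_days) {
  ctx <- cortical_pairs(atlas)
  need <- c(paste0("L_", ctx), paste0("R_", ctx))
  for (tb in list(bilateral_v1, bilateral_v2)) {
    missing <- setdiff(need, names(tb))
    if (length(missing)) {
      abort(paste0("missing cortical feature column(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  stopifnot(identical(bilateral_v1$participant_id, bilateral_v2$participant_id))
  gr1 <- rowSums(bilateral_v1[paste0("R_", ctx)])
  gl1 <- rowSums(bilateral_v1[paste0("L_", ctx)])
  gr2 <- rowSums(bilateral_v2[paste0("R_", ctx)])
  gl2 <- rowSums(bilateral_v2[paste0("L_", ctx)])
  dgr <- (gr2 - gr1) / delta_t_days * 365
  dgl <- (gl2 - gl1) / delta_t_days * 365
  tibble(participant_id = bilateral_v1$participant_id,
         dG_R = dgr, dG_L = dgl, dG_delta = dgr - dgl)
}

#' Align LBAC signs to the grey-matter change reference
#'
#' For each pattern, if the Pearson correlation between its LBAC column and
#' dG_delta is negative the column is flipped, so that after alignment
#' positive LBACs correspond to the left cortex declining faster than the
#' right. Flips are recorded on the object (and should be copied onto the
#' basis for future projections). MBACs are unchanged. A zero-variance or
#' exactly tied column keeps +1 with a warning.
#'
#' @param changes An `asym_changes` object.
#' @param grey_reference Tibble from [compute_grey_reference()] (matched
#'   participants).
#' @return The `asym_changes` object with aligned `lbac`, recorded
#'   `sign_flips` and the `grey_reference` attached.
#' @export
align_lbac_signs <- function(changes, grey_reference) {
  stopifnot(inherits(changes, "asym_changes"))
  stopifnot(identical(changes$lbac$participant_id,
                      grey_reference$participant_id))
  ref <- grey_reference$dG_delta
  m <- tbl_to_matrix(changes$lbac)
  flips <- setNames(rep(1, ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    if (sd(m[, j]) == 0) {
      warn(paste0("zero-variance LBAC column ", colnames(m)[j],
                  ": sign flip undefined, keeping +1"))
      next
    }
    r <- cor(m[, j], ref)
    if (is.finite(r) && r < 0) {
      m[, j] <- -m[, j]
      flips[j] <- -1
    }
  }
  changes$lbac <- matrix_to_tbl(m, changes$lbac$participant_id)
  changes$sign_flips <- flips
  changes$grey_reference <- grey_reference
  changes
}

#' Per-pair correlation of left and right homolog volume change
#'
#' For every grey-matter pair, the Pearson correlation across participants
#' between the left homolog's volume change and the right homolog's volume
#' change. Perfectly coupled hemispheres give r = 1 for every pair; values
#' below 1 quantify hemisphere-specific rates of longitudinal change.
#'
#' @param bilateral_v1,bilateral_v2 Bilateral tables for both visits.
#' @param atlas Atlas tibble; grey-matter (cortical + subcortical) pairs are
#'   used.
#' @return Tibble `pair`, `class`, `r`, with a `summary` attribute holding
#'   mean/min/max.
#' @export
homolog_change_correlation <- function(bilateral_v1, bilateral_v2, atlas) {
  pairs <- grey_pairs(atlas)
  stopifnot(identical(bilateral_v1$participant_id, bilateral_v2$participant_id))
  r <- vapply(pairs, function(p) {
    dl <- bilateral_v2[[paste0("L_", p)]] - bilateral_v1[[paste0("L_", p)]]
    dr <- bilateral_v2[[paste0("R_", p)]] - bilateral_v1[[paste0("R_", p)]]
    if (sd(dl) == 0 || sd(dr) == 0) {
      abort(paste0("zero-variance change vector for pair ", p))
    }
    cor(dl, dr)
  }, numeric(1))
  out <- tibble(pair = pairs,
                class = atlas$class[match(pairs, atlas$pair)],
                r = unname(r))
  attr(out, "summary") <- tibble(mean_r = mean(r), min_r = min(r),
                                 max_r = max(r), n_pairs = length(r))
  out
}

#' Run the full asymmetry-change stage on a cohort bundle
#'
#' Convenience wrapper chaining [bilateral_to_li()], [fit_deconfound()] /
#' [apply_deconfound()] (fitted on visit 1, frozen for visit 2),
#' [fit_pattern_basis()], [project_patterns()], [compute_changes()],
#' [compute_grey_reference()] and [align_lbac_signs()].
#'
#' @param bundle A `cohort_bundle` (or any list with the same tables).
#' @param k Number of asymmetry patterns to fit.
#' @return List: `changes` (`asym_changes`), `basis` (`pattern_basis`, with
#'   alignment flips folded in), `deconfound` model, pattern-expression
#'   tibbles `p1`/`p2`, and the homolog change-correlation table.
#' @export
asymmetry_pipeline <- function(bundle, k = bundle$config$n_latent_patterns %||% 33) {
  atlas <- bundle$atlas
  li1 <- bilateral_to_li(bundle$bilateral_v1, atlas)
  li2 <- bilateral_to_li(bundle$bilateral_v2, atlas)
  conf <- bundle$confounds
  conf1 <- if ("visit" %in% names(conf)) dplyr::filter(conf, .data$visit == 1) else conf
  conf2 <- if ("visit" %in% names(conf)) dplyr::filter(conf, .data$visit == 2) else conf
  model <- fit_deconfound(li1, conf1)
  a1 <- apply_deconfound(li1, model, conf1)
  a2 <- apply_deconfound(li2, model, conf2)
  basis <- fit_pattern_basis(a1, k)
  p1 <- project_patterns(a1, basis)
  p2 <- project_patterns(a2, basis)
  dt <- bundle$demographics$delta_t_days[
    match(p1$participant_id, bundle$demographics$participant_id)]
  changes <- compute_changes(p1, p2, dt)
  greyref <- compute_grey_reference(bundle$bilateral_v1, bundle$bilateral_v2,
                                    atlas, dt)
  changes <- align_lbac_signs(changes, greyref)
  basis$sign_flips <- basis$sign_flips * changes$sign_flips
  homolog <- tryCatch(
    homolog_change_correlation(bundle$bilateral_v1, bundle$bilateral_v2, atlas),
    error = function(e) {
      warn(paste0("homolog change correlations unavailable: ",
                  conditionMessage(e)))
      NULL
    })
  list(changes = changes, basis = basis, deconfound = model,
       p1 = p1, p2 = p2, homolog_correlations = homolog)
}

#' Match fitted patterns to the generator's planted patterns
#'
#' Greedy maximum-|correlation| matching between fitted basis loadings and
#' the ground-truth loading matrix of a synthetic bundle. Useful for
#' planted-effect recovery checks, where the fitted pattern order need not
#' equal the planted order.
#'
#' @param basis A fitted `pattern_basis`.
#' @param true_loadings Feature x pattern matrix of planted loadings
#'   (`bundle$ground_truth$loadings`).
#' @return Tibble `true_pattern`, `fitted_pattern`, `alignment` (absolute
#'   loading correlation).
#' @export
match_patterns <- function(basis, true_loadings) {
  v <- basis$v
  cc <- abs(cor(true_loadings, v))
  out <- tibble(true_pattern = integer(), fitted_pattern = integer(),
                alignment = numeric())
  avail <- seq_len(ncol(v))
  for (i in seq_len(ncol(true_loadings))) {
    j <- avail[which.max(cc[i, avail])]
    out <- dplyr::bind_rows(out, tibble(
      true_pattern = i, fitted_pattern = j, alignment = cc[i, j]))
    avail <- setdiff(avail, j)
    if (!length(avail)) break
  }
  out
}
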