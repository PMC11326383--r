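#' Cohen's d between two groups
#'
#' Pooled-standard-deviation Cohen's d, (mean_A - mean_B) / s_pooled with
#' s_pooled^2 = ((n_A-1) s_A^2 + (n_B-1) s_B^2) / (n_A + n_B - 2). No small-
#' sample (Hedges) correction is applied.
#'
#' @param a,b Numeric value vectors for groups A and B (n >= 2 each, with
#'   variance in at least one group).
#' @return Scalar d; its sign equals the sign of `mean(a) - mean(b)`.
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))  # -2
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort("both groups need at least 2 observations")
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) abort("pooled standard deviation is zero: d undefined")
  (mean(a) - mean(b)) / sp
}

# One contrast over every pattern x measure of an asym_changes object.
contrast_block <- function(changes, mask_a, mask_b, contrast, label_a, label_b) {
  purrr::map_dfr(c(lbac = "lbac", mbac = "mbac"), function(meas) {
    m <- tbl_to_matrix(changes[[meas]])
    purrr::map_dfr(seq_len(ncol(m)), function(j) {
      a <- m[mask_a, j]; b <- m[mask_b, j]
      tibble(measure = meas, pattern = j, contrast = contrast,
             group_a = label_a, group_b = label_b,
             n_a = sum(mask_a), n_b = sum(mask_b),
             mean_a = mean(a), mean_b = mean(b),
             d = cohens_d(a, b))
    })
  })
}

#' Sex contrast of asymmetry changes
#'
#' Cohen's d (male - female) per pattern for both LBAC and MBAC.
#'
#' @param changes An `asym_changes` object.
#' @param sex Numeric/logical vector, 1 = male, 0 = female, ordered as the
#'   change tables.
#' @return Long tibble: `measure`, `pattern`, `contrast`, group labels and
#'   sizes, means, `d`.
#' @export
sex_contrast <- function(changes, sex) {
  stopifnot(length(sex) == nrow(changes$lbac))
  contrast_block(changes, sex == 1, sex == 0, "sex", "male", "female")
}

#' Baseline-age quartile contrast of asymmetry changes
#'
#' Contrasts the oldest 25% of participants at baseline against the youngest
#' 25% (oldest - youngest). Quartile cuts use the empirical 25th/75th
#' percentiles; values equal to a cut are included in the extreme group.
#'
#' @param changes An `asym_changes` object.
#' @param ages Baseline ages, ordered as the change tables.
#' @return Long contrast tibble as in [sex_contrast()].
#' @export
age_quartile_contrast <- function(changes, ages) {
  stopifnot(length(ages) == nrow(changes$lbac))
  if (length(ages) < 8) abort("need at least 8 participants for quartile contrast")
  q <- quantile(ages, c(0.25, 0.75), names = FALSE)
  contrast_block(changes, ages >= q[2], ages <= q[1],
                 "age_quartile", "oldest_25pct", "youngest_25pct")
}

#' Employment-status contrasts of asymmetry changes
#'
#' Three Cohen's d contrasts per pattern and measure: employed - retired,
#' retiring - retired, retiring - employed. The three-state employment
#' trajectory is expected to be precomputed (employed at both visits,
#' retired at both visits, or transitioning in between); other trajectories
#' should already be excluded.
#'
#' @param changes An `asym_changes` object.
#' @param employment Character vector in
#'   `c("employed", "retiring", "retired")` (NA rows are dropped from every
#'   contrast), ordered as the change tables.
#' @return Long contrast tibble.
#' @export
employment_contrasts <- function(changes, employment) {
  stopifnot(length(employment) == nrow(changes$lbac))
  states <- c("employed", "retiring", "retired")
  bad <- setdiff(unique(employment[!is.na(employment)]), states)
  if (length(bad)) {
    abort(paste0("unknown employment state(s): ", paste(bad, collapse = ", ")))
  }
  for (s in states) {
    if (sum(employment == s, na.rm = TRUE) < 2) {
      abort(paste0("employment group '", s, "' is empty or has < 2 members"))
    }
  }
  specs <- list(c("employed", "retired"), c("retiring", "retired"),
                c("retiring", "employed"))
  purrr::map_dfr(specs, function(sp) {
    contrast_block(changes,
                   !is.na(employment) & employment == sp[1],
                   !is.na(employment) & employment == sp[2],
                   paste0(sp[1], "_vs_", sp[2]), sp[1], sp[2])
  })
}

#' Derive the three-group employment trajectory from per-visit status
#'
#' employed at both visits -> "employed"; retired at both -> "retired";
#' employed then retired -> "retiring"; any other trajectory -> NA
#' (excluded).
#'
#' @param v1,v2 Per-visit status strings.
#' @return Character vector with NA for excluded trajectories.
#' @export
employment_trajectory <- function(v1, v2) {
  dplyr::case_when(
    v1 == "employed" & v2 == "employed" ~ "employed",
    v1 == "retired" & v2 == "retired" ~ "retired",
    v1 == "employed" & v2 == "retired" ~ "retiring",
    TRUE ~ NA_character_
  )
}

#' Cross-pattern correlation structure of asymmetry changes
#'
#' Pearson correlation blocks among LBAC columns, among MBAC columns, and
#' between LBACs and MBACs, with off-diagonal summaries and the
#' matched-pattern LBAC-MBAC diagonal reported separately.
#'
#' @param changes An `asym_changes` object with at least 3 participants.
#' @return A `change_correlations` object: matrices `lbac_lbac`,
#'   `mbac_mbac`, `lbac_mbac`, a `summary` tibble (mean |r|, sd, max
#'   off-diagonal with index pair, per block) and `matched_diagonal`.
#' @export
change_correlations <- function(changes) {
  l <- tbl_to_matrix(changes$lbac)
  m <- tbl_to_matrix(changes$mbac)
  if (nrow(l) < 3) abort("need at least 3 participants")
  zero_var <- c(colnames(l)[apply(l, 2, sd) == 0],
                paste0("mbac ", colnames(m)[apply(m, 2, sd) == 0],
                       recycle0 = TRUE))
  if (length(zero_var)) {
    abort(paste0("zero-variance change column(s): ",
                 paste(zero_var, collapse = ", ")))
  }
  ll <- cor(l); mm <- cor(m); lm_ <- cor(l, m)
  summarize_block <- function(mat, block, off_only = TRUE) {
    vals <- mat
    if (off_only && block != "lbac_mbac") diag(vals) <- NA
    if (block == "lbac_mbac") diag(vals) <- NA  # matched pairs reported apart
    v <- abs(vals[!is.na(vals)])
    if (!length(v)) {
      return(tibble(block = block, mean_abs_r = NA_real_, sd_abs_r = NA_real_,
                    max_abs_r = NA_real_, max_i = NA_integer_,
                    max_j = NA_integer_))
    }
    idx <- which(abs(vals) == max(v, na.rm = TRUE), arr.ind = TRUE)[1, ]
    tibble(block = block, mean_abs_r = mean(v), sd_abs_r = sd(v),
           max_abs_r = max(v), max_i = unname(idx[1]), max_j = unname(idx[2]))
  }
  structure(list(
    lbac_lbac = ll, mbac_mbac = mm, lbac_mbac = lm_,
    matched_diagonal = setNames(diag(lm_), colnames(l)),
    summary = dplyr::bind_rows(
      summarize_block(ll, "lbac_lbac"),
      summarize_block(mm, "mbac_mbac"),
      summarize_block(lm_, "lbac_mbac"))
  ), class = "change_correlations")
}

#' @export
print.change_correlations <- function(x, ...) {
  cat("<change_correlations> ", nrow(x$lbac_lbac), " patterns\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Run all group contrasts of a cohort
#'
#' @param changes An `asym_changes` object.
#' @param demographics Demographics tibble with `sex`, `age`,
#'   `employment_v1`, `employment_v2` (rows matched to the change tables by
#'   `participant_id`).
#' @return Long tibble with all sex, age-quartile and employment contrasts.
#' @export
group_contrasts <- function(changes, demographics) {
  demo <- demographics[match(changes$lbac$participant_id,
                             demographics$participant_id), ]
  traj <- employment_trajectory(demo$employment_v1, demo$employment_v2)
  dplyr::bind_rows(
    sex_contrast(changes, demo$sex),
    age_quartile_contrast(changes, demo$age),
    employment_contrasts(changes, traj)
  )
}
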