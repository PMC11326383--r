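# Shared fixtures, built in code. Heavy simulations are cached per session so
# several test files can reuse one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small all-defaults cohort for structural checks.
small_bundle <- function() {
  cached("small_bundle", simulate_cohort(
    cohort_config(n_participants = 150, seed = 42, n_latent_patterns = 6)))
}

small_pipeline <- function() {
  cached("small_pipeline", asymmetry_pipeline(small_bundle(), k = 6))
}

# The planted-effect recovery run at study scale (n = 4000, K = 33).
recovery_effects <- function() {
  dplyr::bind_rows(
    planted_effect("lbac", 1, "sex", 0.5),
    planted_effect("mbac", 2, "sex", 0.3),
    planted_effect("lbac", 3, "employment", 0.4),
    planted_effect("lbac", 5, "age", 0.3),
    planted_effect("lbac", 6, "phenotype_change:lifestyle_01", 0.6),
    planted_effect("lbac", 4, "disease:Mental Disorders", 0.35)
  )
}

recovery_bundle <- function() {
  cached("recovery_bundle", simulate_cohort(cohort_config(
    n_participants = 4000, seed = 2024, n_latent_patterns = 33,
    planted_effects = recovery_effects())))
}

recovery_run <- function() {
  cached("recovery_run", {
    b <- recovery_bundle()
    res <- asymmetry_pipeline(b, k = 33)
    res$match <- match_patterns(res$basis, b$ground_truth$loadings)
    res
  })
}

# Build an asym_changes object directly from LBAC values (Delta t = 365 days
# so pattern-expression differences equal yearly rates).
changes_from_lbac <- function(lbac, ids = sprintf("s%04d", seq_len(nrow(lbac)))) {
  lbac <- as.matrix(lbac)
  colnames(lbac) <- sprintf("pattern_%02d", seq_len(ncol(lbac)))
  p1 <- lbac * 0
  mk <- function(m) {
    tb <- tibble::as_tibble(as.data.frame(m))
    tibble::add_column(tb, participant_id = ids, .before = 1)
  }
  compute_changes(mk(p1), mk(lbac), rep(365, nrow(lbac)))
}

# Minimal disease_clusters object from a score matrix.
clusters_from_scores <- function(scores, ids = rownames(scores),
                                 technique = "PCA", class = "Synthetic") {
  colnames(scores) <- colnames(scores) %||%
    sprintf("cluster_%03d", seq_len(ncol(scores)))
  rownames(scores) <- ids
  structure(list(
    scores = scores,
    meta = tibble::tibble(cluster_id = colnames(scores),
                          disease_class = class, technique = technique,
                          rank = seq_len(ncol(scores)),
                          explained_variance = NA_real_),
    retained_per_class = stats::setNames(ncol(scores), class)),
    class = "disease_clusters")
}

`%||%` <- rlang::`%||%`
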