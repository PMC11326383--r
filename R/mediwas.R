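#' Aggregate ICD diagnosis records into a binary phecode matrix
#'
#' Maps long-format ICD-9/ICD-10 records through a phecode map and binarizes
#' to ever-diagnosed status. Unmapped codes are tolerated, counted and
#' logged. Only phecodes with at least one case appear as columns.
#'
#' @param records Tibble `participant_id`, `icd_code`, `icd_version`.
#' @param map Phecode map tibble `icd_code`, `icd_version`, `phecode`,
#'   `disease_class` (each phecode in exactly one class).
#' @param participants Optional character vector fixing the row universe
#'   (participants without diagnoses get all-zero rows); defaults to the
#'   participants present in `records`.
#' @return Tibble `participant_id` + one 0/1 column per phecode, with
#'   attributes `classes` (tibble `phecode`, `disease_class`) and
#'   `n_unmapped`.
#' @export
map_icd_to_phecodes <- function(records, map, participants = NULL) {
  chk <- dplyr::distinct(map, .data$phecode, .data$disease_class)
  if (anyDuplicated(chk$phecode)) {
    abort("phecode map assigns some phecode to more than one disease class")
  }
  if (any(is.na(records$icd_code)) || any(!nzchar(records$icd_code))) {
    abort("malformed (empty) ICD code strings in records")
  }
  key <- paste(records$icd_code, records$icd_version)
  map_key <- paste(map$icd_code, map$icd_version)
  hit <- match(key, map_key)
  n_unmapped <- sum(is.na(hit))
  if (n_unmapped) {
    inform(paste0(n_unmapped, " record(s) with ICD codes absent from the map"))
  }
  mapped <- tibble(participant_id = records$participant_id[!is.na(hit)],
                   phecode = map$phecode[hit[!is.na(hit)]])
  if (is.null(participants)) participants <- sort(unique(records$participant_id))
  phecodes <- sort(unique(mapped$phecode))
  m <- matrix(0, length(participants), length(phecodes),
              dimnames = list(participants, phecodes))
  if (nrow(mapped)) {
    i <- match(mapped$participant_id, participants)
    j <- match(mapped$phecode, phecodes)
    ok <- !is.na(i)
    m[cbind(i[ok], j[ok])] <- 1
  }
  out <- matrix_to_tbl(m, participants)
  attr(out, "classes") <- chk[chk$phecode %in% phecodes, ]
  attr(out, "n_unmapped") <- n_unmapped
  out
}

# Explained-variance profile of a centered (optionally scaled) PCA.
pca_evar <- function(x, scale. = FALSE) {
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  list(evar = pc$sdev^2 / sum(pc$sdev^2), pc = pc)
}

#' Permutation-calibrated principal component retention
#'
#' PCA of one disease class' centered phecode block. The null
#' explained-variance per rank is the mean over `n_perm` runs in which each
#' column is independently row-shuffled (breaking inter-phecode links while
#' preserving prevalence). Ranks whose true explained variance exceeds the
#' null mean at the same rank are retained; zero retained components is a
#' valid outcome.
#'
#' @param block Numeric matrix/tibble of one class' phecode columns
#'   (>= 2 columns, >= 3 rows).
#' @param n_perm Number of permutations (default 5).
#' @param seed Seed for the permutation stream.
#' @param scale. Also variance-scale columns before PCA (default FALSE:
#'   centering only, so components are prevalence-weighted).
#' @param stop_at_first_failure Require retained ranks to be contiguous from
#'   rank 1 (default FALSE: rank-by-rank comparison).
#' @return List: `n_retained`, `scores` (rows x retained), `loadings`,
#'   `explained_variance`, `null_explained_variance`.
#' @export
pca_retention <- function(block, n_perm = 5, seed = 1, scale. = FALSE,
                          stop_at_first_failure = FALSE) {
  x <- as.matrix(block)
  if (ncol(x) < 2 || nrow(x) < 3) abort("block needs >= 2 columns and >= 3 rows")
  if (all(apply(x, 2, sd) == 0)) abort("constant block: PCA undefined")
  true <- pca_evar(x, scale.)
  null_evar <- with_seed(seed, {
    acc <- matrix(0, n_perm, length(true$evar))
    for (p in seq_len(n_perm)) {
      xp <- apply(x, 2, sample)
      acc[p, ] <- pca_evar(xp, scale.)$evar
    }
    colMeans(acc)
  })
  keep <- true$evar > null_evar
  if (stop_at_first_failure) keep <- cumprod(keep) > 0
  k <- sum(keep)
  idx <- which(keep)
  load <- fix_column_signs(true$pc$rotation[, idx, drop = FALSE])
  scores <- scale(x, center = TRUE, scale = if (scale.) apply(x, 2, sd) else FALSE) %*% load
  list(n_retained = as.integer(k),
       scores = scores, loadings = load,
       explained_variance = true$evar[idx],
       null_explained_variance = null_evar,
       true_explained_variance = true$evar)
}

#' Reduce a connectivity-feature block to its top principal components
#'
#' Centered PCA scores of the rs-fMRI connectivity block, truncated to
#' `n_components` (default 100). If fewer input columns are available all
#' are kept, with a warning; rank-deficient inputs yield only the
#' nonzero-variance components, with a warning.
#'
#' @param fmri Tibble `participant_id` + numeric connectivity features, or a
#'   plain matrix.
#' @param n_components Target component count.
#' @return Matrix of PC scores (rownames = participant ids when available).
#' @export
reduce_fmri_block <- function(fmri, n_components = 100) {
  x <- if (is.data.frame(fmri)) tbl_to_matrix(fmri) else as.matrix(fmri)
  if (nrow(x) < 2) abort("need at least 2 rows")
  if (ncol(x) < n_components) {
    warn(sprintf("only %d connectivity features (< %d): keeping all",
                 ncol(x), n_components))
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  nz <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  k <- min(n_components, ncol(x), nz)
  if (k < min(n_components, ncol(x))) {
    warn(sprintf("rank-deficient block: only %d nonzero-variance components", nz))
  }
  pc$x[, seq_len(k), drop = FALSE]
}

# Inverse square root of a symmetric positive-definite matrix.
sym_inv_sqrt <- function(s) {
  e <- eigen(s, symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

#' Disease-side CCA and PLS-C variates for one disease class
#'
#' Two-block latent decompositions of one class' phecode block against the
#' reduced connectivity block. CCA maximizes correlation between block
#' variates (with a small ridge on both covariance matrices for numerical
#' stability); PLS-C maximizes cross-block covariance (SVD of the
#' cross-covariance). The top `k_class` disease-side variates per technique
#' are returned, standardized, with the deterministic
#' largest-|loading|-positive sign convention.
#'
#' @param phecode_block Matrix/tibble of one class' phecode columns.
#' @param fmri_block Matrix of reduced connectivity features (same row
#'   order).
#' @param k_class Number of variates per technique (the class' retained PCA
#'   count).
#' @param ridge Ridge added to both block covariances for CCA (default
#'   1e-3).
#' @return List with `cca` and `plsc`, each holding `scores`
#'   (rows x k_class, standardized), `loadings` (disease side) and, for CCA,
#'   `correlations`.
#' @export
cca_plsc_clusters <- function(phecode_block, fmri_block, k_class,
                              ridge = 1e-3) {
  x <- as.matrix(phecode_block); y <- as.matrix(fmri_block)
  stopifnot(nrow(x) == nrow(y))
  if (k_class < 1) abort("k_class must be >= 1")
  if (k_class > min(ncol(x), ncol(y))) {
    abort("k_class exceeds the rank bound of the blocks")
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  n <- nrow(xc)
  cxx <- crossprod(xc) / (n - 1) + diag(ridge, ncol(xc))
  cyy <- crossprod(yc) / (n - 1) + diag(ridge, ncol(yc))
  cxy <- crossprod(xc, yc) / (n - 1)
  wx <- sym_inv_sqrt(cxx); wy <- sym_inv_sqrt(cyy)
  dec <- svd(wx %*% cxy %*% wy, nu = k_class, nv = 0)
  a <- wx %*% dec$u                      # disease-side canonical weights
  a <- fix_column_signs(a)
  cca_scores <- scale(xc %*% a)
  pls <- svd(cxy, nu = k_class, nv = 0)
  u <- fix_column_signs(pls$u[, seq_len(k_class), drop = FALSE])
  pls_scores <- scale(xc %*% u)
  list(
    cca = list(scores = cca_scores, loadings = a,
               correlations = dec$d[seq_len(k_class)]),
    plsc = list(scores = pls_scores, loadings = u)
  )
}

#' Build the composite disease clusters
#'
#' For each disease class: permutation-calibrated PCA retention on the
#' class' phecode block, then the same number of disease-side CCA and PLS-C
#' variates against the reduced connectivity block. Classes retaining zero
#' PCA components contribute no clusters. The total cluster count is
#' 3 x (sum of retained PCA counts).
#'
#' @param phecode_matrix Tibble from [map_icd_to_phecodes()] (carries the
#'   class partition attribute), or a plain matrix plus `classes`.
#' @param fmri Connectivity tibble/matrix (rows matched by participant id
#'   where available).
#' @param classes Optional tibble `phecode`, `disease_class` overriding the
#'   attribute.
#' @param n_perm Permutations for PCA retention (default 5).
#' @param n_fmri_components Connectivity PCs (default 100).
#' @param seed Seed.
#' @param ridge CCA covariance ridge.
#' @return A `disease_clusters` object: `scores` (participants x clusters,
#'   standardized), `meta` tibble (`cluster_id`, `disease_class`,
#'   `technique`, `rank`, `explained_variance` for PCA),
#'   `retained_per_class`.
#' @export
build_disease_clusters <- function(phecode_matrix, fmri, classes = NULL,
                                   n_perm = 5, n_fmri_components = 100,
                                   seed = 1, ridge = 1e-3) {
  classes <- classes %||% attr(phecode_matrix, "classes")
  if (is.null(classes)) abort("no phecode class partition supplied")
  ids <- phecode_matrix$participant_id
  pm <- tbl_to_matrix(phecode_matrix)
  if (is.data.frame(fmri)) {
    fmri <- fmri[match(ids, fmri$participant_id), ]
    stopifnot(!anyNA(fmri$participant_id))
  }
  fred <- reduce_fmri_block(fmri, n_fmri_components)
  score_list <- list(); meta <- list()
  retained <- setNames(integer(0), character(0))
  for (cls in unique(classes$disease_class)) {
    cols <- intersect(classes$phecode[classes$disease_class == cls],
                      colnames(pm))
    if (length(cols) < 2) {
      retained[cls] <- 0L
      next
    }
    block <- pm[, cols, drop = FALSE]
    ret <- pca_retention(block, n_perm = n_perm,
                         seed = substream_seed(seed, cls))
    retained[cls] <- ret$n_retained
    if (ret$n_retained == 0) next
    k <- ret$n_retained
    cp <- cca_plsc_clusters(block, fred, k, ridge)
    add <- function(scores, technique, evar = rep(NA_real_, k)) {
      for (r in seq_len(k)) {
        cid <- paste0(gsub("[^A-Za-z0-9]+", "_", cls), "_", technique, "_", r)
        score_list[[cid]] <<- scores[, r]
        meta[[cid]] <<- tibble(cluster_id = cid, disease_class = cls,
                               technique = technique, rank = r,
                               explained_variance = evar[r])
      }
    }
    add(scale(ret$scores), "PCA", ret$explained_variance)
    add(cp$cca$scores, "CCA")
    add(cp$plsc$scores, "PLSC")
  }
  scores <- if (length(score_list)) {
    m <- do.call(cbind, score_list)
    rownames(m) <- ids
    m
  } else matrix(numeric(0), length(ids), 0, dimnames = list(ids, NULL))
  structure(list(scores = scores,
                 meta = if (length(meta)) dplyr::bind_rows(meta) else
                   tibble(cluster_id = character(), disease_class = character(),
                          technique = character(), rank = integer(),
                          explained_variance = numeric()),
                 retained_per_class = retained),
            class = "disease_clusters")
}

#' @export
print.disease_clusters <- function(x, ...) {
  cat("<disease_clusters> ", ncol(x$scores), " clusters over ",
      length(x$retained_per_class), " classes (3 x ",
      sum(x$retained_per_class), " retained components)\n", sep = "")
  invisible(x)
}

#' Diagnosis-wide association scan
#'
#' Pearson correlation (two-sided test) between every composite disease
#' cluster and every asymmetry-change column (both measures, all patterns).
#' Bonferroni control uses threshold `alpha / n_clusters`;
#' Benjamini-Hochberg FDR at `fdr_q` is applied within each
#' (measure x pattern) family of `n_clusters` tests.
#'
#' @param changes An `asym_changes` object.
#' @param clusters A `disease_clusters` object (rows matched by participant
#'   id).
#' @param alpha Family-wise error target (default 0.05).
#' @param fdr_q FDR target (default 0.05).
#' @return A `mediwas_scan` tibble: `cluster_id`, `disease_class`,
#'   `technique`, `rank`, `measure`, `pattern`, `r`, `p`,
#'   `passes_bonferroni`, `passes_fdr`, `neg_log10_p`; attributes
#'   `bonferroni_threshold` and `n_clusters`.
#' @export
mediwas_scan <- function(changes, clusters, alpha = 0.05, fdr_q = 0.05) {
  stopifnot(inherits(clusters, "disease_clusters"))
  ids <- changes$lbac$participant_id
  sc <- clusters$scores[match(ids, rownames(clusters$scores)), , drop = FALSE]
  if (nrow(sc) < 3) abort("need at least 3 shared participants")
  if (ncol(sc) == 0) abort("no composite disease clusters to test")
  if (any(apply(sc, 2, sd) == 0)) abort("zero-variance cluster score column")
  n_clusters <- ncol(sc)
  bon <- alpha / n_clusters
  out <- purrr::map_dfr(c(lbac = "lbac", mbac = "mbac"), function(meas) {
    m <- tbl_to_matrix(changes[[meas]])
    purrr::map_dfr(seq_len(ncol(m)), function(j) {
      rows <- purrr::map_dfr(seq_len(n_clusters), function(ci) {
        ct <- cor.test(m[, j], sc[, ci])
        tibble(cluster_id = colnames(sc)[ci], measure = meas, pattern = j,
               r = unname(ct$estimate), p = ct$p.value)
      })
      rows$passes_fdr <- p.adjust(rows$p, method = "BH") < fdr_q
      rows
    })
  })
  out$passes_bonferroni <- out$p < bon
  out <- dplyr::left_join(out, clusters$meta, by = "cluster_id")
  out$neg_log10_p <- -log10(out$p)
  out <- out[c("cluster_id", "disease_class", "technique", "rank",
               "measure", "pattern", "r", "p",
               "passes_bonferroni", "passes_fdr", "neg_log10_p")]
  attr(out, "bonferroni_threshold") <- bon
  attr(out, "n_clusters") <- n_clusters
  class(out) <- c("mediwas_scan", class(out))
  out
}

#' Run the full diagnosis-wide stage on a cohort bundle
#'
#' Chains [map_icd_to_phecodes()], [build_disease_clusters()] and
#' [mediwas_scan()].
#'
#' @param changes An `asym_changes` object.
#' @param bundle A `cohort_bundle`.
#' @param alpha,fdr_q Multiple-testing targets.
#' @param n_perm PCA-retention permutations.
#' @param n_fmri_components Connectivity PCs.
#' @param seed Seed.
#' @return List: `scan` (`mediwas_scan`), `clusters`, `phecode_matrix`.
#' @export
mediwas_pipeline <- function(changes, bundle, alpha = 0.05, fdr_q = 0.05,
                             n_perm = 5, n_fmri_components = 100, seed = 1) {
  ids <- changes$lbac$participant_id
  pm <- map_icd_to_phecodes(bundle$icd_records, bundle$phecode_map,
                            participants = ids)
  clusters <- build_disease_clusters(pm, bundle$fmri, n_perm = n_perm,
                                     n_fmri_components = n_fmri_components,
                                     seed = seed)
  scan <- mediwas_scan(changes, clusters, alpha, fdr_q)
  list(scan = scan, clusters = clusters, phecode_matrix = pm)
}
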