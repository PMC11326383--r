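# Table schemas for the bundle files: character columns per table; all
# remaining columns are read as double.
bundle_files <- function() {
  list(
    demographics = c("participant_id", "employment", "employment_v1",
                     "employment_v2"),
    confounds = "participant_id",
    bilateral_v1 = "participant_id",
    bilateral_v2 = "participant_id",
    phenotypes_v1 = "participant_id",
    phenotypes_v2 = "participant_id",
    phenotype_meta = c("id", "domain", "var_type"),
    icd_records = c("participant_id", "icd_code"),
    phecode_map = c("icd_code", "phecode", "disease_class"),
    fmri = "participant_id",
    atlas = c("pair", "class", "measure")
  )
}

read_bundle_csv <- function(path, char_cols, sniff_chars = FALSE) {
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  if (sniff_chars) {
    # some columns (e.g. unordered phenotypes) carry character level codes
    peek <- suppressWarnings(readr::read_csv(
      path, n_max = 100, col_types = readr::cols(), show_col_types = FALSE,
      progress = FALSE))
    char_cols <- union(char_cols,
                       names(which(vapply(peek, is.character, logical(1)))))
  }
  char_cols <- intersect(char_cols, hdr)
  spec <- do.call(readr::cols, c(
    setNames(rep(list(readr::col_character()), length(char_cols)), char_cols),
    list(.default = readr::col_double())
  ))
  tb <- readr::read_csv(path, col_types = spec, show_col_types = FALSE,
                        progress = FALSE)
  attr(tb, "spec") <- NULL
  attr(tb, "problems") <- NULL
  class(tb) <- c("tbl_df", "tbl", "data.frame")
  tb
}

#' Write a cohort bundle to a directory of CSV files
#'
#' One UTF-8, comma-delimited file with header row per table (missing
#' values as empty fields), plus a ground-truth JSON sidecar and CSVs for
#' the planted loading and drift-rate matrices. Tables round-trip losslessly
#' through [read_bundle()].
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(bundle_files())) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(bundle[[nm]], p, na = "")
    paths[nm] <- p
  }
  gt <- bundle$ground_truth
  gt_json <- list(
    planted_effects = gt$planted_effects,
    latent_scales = gt$latent_scales,
    seed = bundle$config$seed,
    n_participants = bundle$config$n_participants,
    n_latent_patterns = bundle$config$n_latent_patterns
  )
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt_json, p, auto_unbox = TRUE, digits = NA, na = "null")
  paths["ground_truth"] <- p
  p <- file.path(dir, "ground_truth_loadings.csv")
  readr::write_csv(matrix_to_tbl(gt$loadings, rownames(gt$loadings), "pair"), p)
  paths["ground_truth_loadings"] <- p
  p <- file.path(dir, "ground_truth_drift.csv")
  drift <- gt$drift_rates
  colnames(drift) <- pattern_labels(ncol(drift))
  readr::write_csv(matrix_to_tbl(drift, bundle$demographics$participant_id), p)
  paths["ground_truth_drift"] <- p
  invisible(paths)
}

#' Read a cohort bundle from a directory written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return A `cohort_bundle` list (without the full simulation config; the
#'   ground truth carries planted effects, loadings and drift rates).
#' @export
read_bundle <- function(dir) {
  files <- bundle_files()
  out <- purrr::imap(files, function(char_cols, nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) abort(paste0("missing bundle file: ", p))
    if (nm == "phenotype_meta") {
      tb <- readr::read_csv(p, col_types = readr::cols(
        id = readr::col_character(), domain = readr::col_character(),
        var_type = readr::col_character(),
        has_change = readr::col_logical()), show_col_types = FALSE,
        progress = FALSE)
      attr(tb, "spec") <- NULL
      attr(tb, "problems") <- NULL
      class(tb) <- c("tbl_df", "tbl", "data.frame")
      tb
    } else {
      read_bundle_csv(p, char_cols,
                      sniff_chars = nm %in% c("phenotypes_v1", "phenotypes_v2"))
    }
  })
  if ("icd_version" %in% names(out$icd_records)) {
    out$icd_records$icd_version <- as.integer(out$icd_records$icd_version)
  }
  out$phecode_map$icd_version <- as.integer(out$phecode_map$icd_version)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    lpath <- file.path(dir, "ground_truth_loadings.csv")
    if (file.exists(lpath)) {
      lt <- read_bundle_csv(lpath, "pair")
      gt$loadings <- tbl_to_matrix(lt, "pair")
    }
    dpath <- file.path(dir, "ground_truth_drift.csv")
    if (file.exists(dpath)) {
      gt$drift_rates <- tbl_to_matrix(read_bundle_csv(dpath, "participant_id"))
    }
    out$ground_truth <- gt
  }
  structure(out, class = "cohort_bundle")
}

#' Validate the schemas of a cohort bundle
#'
#' Checks each table for required columns, non-negative bilateral
#' measurements, positive inter-visit intervals, probabilities/codes in
#' range, and cross-table participant consistency. Reports the first 10
#' violations per table.
#'
#' @param bundle A `cohort_bundle` (from [simulate_cohort()] or
#'   [read_bundle()]).
#' @return Tibble `table`, `check`, `ok`, `detail`; overall validity in
#'   attribute `ok`.
#' @export
validate_bundle <- function(bundle) {
  checks <- list()
  add <- function(table, check, ok, detail = "") {
    checks[[length(checks) + 1]] <<- tibble(
      table = table, check = check, ok = ok, detail = detail)
  }
  first_rows <- function(idx) paste(head(which(idx), 10), collapse = ", ")
  atlas <- bundle$atlas
  add("atlas", "unique pair names", !anyDuplicated(atlas$pair))
  bc <- bilateral_cols(atlas)
  for (nm in c("bilateral_v1", "bilateral_v2")) {
    tb <- bundle[[nm]]
    missing <- setdiff(c("participant_id", bc$left, bc$right), names(tb))
    add(nm, "required columns", length(missing) == 0,
        paste(head(missing, 10), collapse = ", "))
    if (!length(missing)) {
      vals <- as.matrix(tb[c(bc$left, bc$right)])
      neg <- rowSums(vals < 0, na.rm = TRUE) > 0
      add(nm, "non-negative measurements", !any(neg), first_rows(neg))
    }
  }
  demo <- bundle$demographics
  need <- c("participant_id", "age", "sex", "delta_t_days")
  missing <- setdiff(need, names(demo))
  add("demographics", "required columns", length(missing) == 0,
      paste(missing, collapse = ", "))
  if (!length(missing)) {
    bad <- !is.na(demo$delta_t_days) & demo$delta_t_days <= 0
    add("demographics", "positive inter-visit interval", !any(bad),
        first_rows(bad))
    bad <- !demo$sex %in% c(0, 1, NA)
    add("demographics", "sex coded 0/1", !any(bad), first_rows(bad))
    same <- identical(bundle$bilateral_v1$participant_id, demo$participant_id)
    add("demographics", "participants match bilateral tables", same)
  }
  pm <- bundle$phecode_map
  add("phecode_map", "required columns",
      all(c("icd_code", "icd_version", "phecode", "disease_class") %in% names(pm)))
  add("phecode_map", "one class per phecode",
      !anyDuplicated(dplyr::distinct(pm, .data$phecode, .data$disease_class)$phecode))
  add("phecode_map", "icd version 9 or 10", all(pm$icd_version %in% c(9L, 10L)))
  meta <- bundle$phenotype_meta
  add("phenotype_meta", "known variable types",
      all(meta$var_type %in% c("continuous", "binary", "ordered", "unordered")))
  out <- dplyr::bind_rows(checks)
  attr(out, "ok") <- all(out$ok)
  out
}

#' Configure a full pipeline run
#'
#' @param bundle_dir Directory with bundle CSVs (ignored when `simulate`
#'   is TRUE).
#' @param output_dir Where result tables and the manifest are written.
#' @param simulate Generate the cohort in-process instead of reading one.
#' @param cohort A [cohort_config()] used when `simulate` is TRUE.
#' @param k Number of asymmetry patterns.
#' @param lambda Ridge penalty for the phenome stage.
#' @param n_perm_behaviour Permutations per behavioural-change model.
#' @param n_perm_pca Permutations for disease-class PCA retention.
#' @param alpha,fdr_q Multiple-testing targets for the diagnosis scan.
#' @param seed Seed for every stochastic step.
#' @param stages Character subset of
#'   `c("contrasts", "phenome", "mediwas")` to run after the mandatory
#'   asymmetry stage.
#' @return A `run_config` list.
#' @export
run_config <- function(bundle_dir = NULL, output_dir, simulate = is.null(bundle_dir),
                       cohort = cohort_config(), k = 33, lambda = 1,
                       n_perm_behaviour = 100, n_perm_pca = 5,
                       alpha = 0.05, fdr_q = 0.05, seed = 1,
                       stages = c("contrasts", "phenome", "mediwas")) {
  if (!simulate && (is.null(bundle_dir) || !dir.exists(bundle_dir))) {
    abort("`bundle_dir` does not exist")
  }
  bad <- setdiff(stages, c("contrasts", "phenome", "mediwas"))
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  structure(list(bundle_dir = bundle_dir, output_dir = output_dir,
                 simulate = simulate, cohort = cohort, k = k, lambda = lambda,
                 n_perm_behaviour = n_perm_behaviour, n_perm_pca = n_perm_pca,
                 alpha = alpha, fdr_q = fdr_q, seed = as.integer(seed),
                 stages = stages),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (asymmetry, then the enabled
#' subset of contrasts / phenome / mediwas), writes one CSV per result table
#' under `output_dir`, and records a JSON manifest with the seed, package
#' version and per-stage row/column counts. Re-running with the same config
#' and seed reproduces byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`bundle`,
#'   `asymmetry`, and any of `contrasts`, `correlations`, `phenome`,
#'   `behaviour`, `mediwas`) plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- if (config$simulate) {
    cc <- config$cohort
    cc$seed <- config$seed
    simulate_cohort(cc)
  } else read_bundle(config$bundle_dir)
  report <- validate_bundle(bundle)
  if (!attr(report, "ok")) {
    bad <- report[!report$ok, ]
    abort(paste0("bundle validation failed: ",
                 paste(paste0(bad$table, "/", bad$check), collapse = "; ")))
  }
  results <- list(bundle = bundle)
  manifest <- list(package_version = as.character(utils::packageVersion("hemishift")),
                   seed = config$seed, stages = config$stages, tables = list())
  emit <- function(name, tb) {
    p <- file.path(config$output_dir, paste0(name, ".csv"))
    readr::write_csv(tb, p, na = "")
    manifest$tables[[name]] <<- list(rows = nrow(tb), cols = ncol(tb))
  }
  asym <- asymmetry_pipeline(bundle, k = config$k)
  results$asymmetry <- asym
  emit("changes", tidy(asym$changes))
  emit("grey_reference", asym$changes$grey_reference)
  emit("homolog_correlations", asym$homolog_correlations)
  emit("pattern_basis", matrix_to_tbl(asym$basis$v, rownames(asym$basis$v), "pair"))
  if ("contrasts" %in% config$stages) {
    ct <- group_contrasts(asym$changes, bundle$demographics)
    cc <- change_correlations(asym$changes)
    results$contrasts <- ct
    results$correlations <- cc
    emit("contrasts", ct)
    emit("change_correlation_summary", cc$summary)
  }
  if ("phenome" %in% config$stages) {
    dom <- phenome_domain_scan(asym$changes, bundle, lambda = config$lambda)
    beh <- behaviour_change_scan(asym$changes, bundle, lambda = config$lambda,
                                 n_perm = config$n_perm_behaviour,
                                 seed = config$seed)
    results$phenome <- dom
    results$behaviour <- beh
    emit("phenome_domain_scan", dom)
    emit("behaviour_change_scan", beh)
  }
  if ("mediwas" %in% config$stages) {
    med <- mediwas_pipeline(asym$changes, bundle, alpha = config$alpha,
                            fdr_q = config$fdr_q, n_perm = config$n_perm_pca,
                            seed = config$seed)
    results$mediwas <- med
    emit("mediwas_scan", as_tibble(med$scan))
    emit("disease_clusters", med$clusters$meta)
  }
  mp <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Read a pipeline run configuration from a YAML file
#'
#' The file may set any scalar field of [run_config()] (`output_dir`,
#' `bundle_dir`, `simulate`, `k`, `lambda`, `n_perm_behaviour`,
#' `n_perm_pca`, `alpha`, `fdr_q`, `seed`, `stages`) plus a `cohort` block
#' whose entries are passed to [cohort_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  spec <- yaml::read_yaml(path)
  known <- c("bundle_dir", "output_dir", "simulate", "k", "lambda",
             "n_perm_behaviour", "n_perm_pca", "alpha", "fdr_q", "seed",
             "stages", "cohort")
  bad <- setdiff(names(spec), known)
  if (length(bad)) {
    abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.null(spec$cohort)) {
    spec$cohort <- do.call(cohort_config, spec$cohort)
  }
  do.call(run_config, spec)
}
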