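#' Declare a planted ground-truth effect for the synthetic cohort
#'
#' Planted effects make the generator's ground truth explicit: each effect
#' injects a known association into the participant-level drift of one
#' asymmetry pattern, so that downstream estimates can be checked against the
#' planted value.
#'
#' Drivers `"sex"`, `"age"` and `"employment"` take `effect_size` as a
#' Cohen's d on the change-score scale (male - female, oldest-quartile -
#' youngest-quartile, employed - retired). Drivers `"phenotype:<id>"`,
#' `"phenotype_change:<id>"` and `"disease:<class>"` take `effect_size` as a
#' Pearson correlation between the driver and the pattern's drift rate.
#' For `measure = "mbac"` group drivers the planted d acts on the absolute
#' drift (a group difference in drift spread).
#'
#' @param measure `"lbac"` or `"mbac"`.
#' @param pattern Target latent pattern index (1-based).
#' @param driver Driver string, see Details.
#' @param effect_size Cohen's d or correlation, see Details.
#' @return One-row tibble; rows can be combined with [dplyr::bind_rows()].
#' @export
planted_effect <- function(measure, pattern, driver, effect_size) {
  measure <- match.arg(measure, c("lbac", "mbac"))
  if (pattern < 1 || pattern != round(pattern)) {
    abort("`pattern` must be a positive integer")
  }
  tibble(measure = measure, pattern = as.integer(pattern),
         driver = driver, effect_size = as.numeric(effect_size))
}

#' Default phenotype domain specification
#'
#' Eleven baseline behavioural domains; the first nine also have a
#' between-visit change version, mirroring the 11-baseline / 9-change domain
#' layout of the target analysis. Each domain carries a small mix of
#' variable types (continuous, binary, ordered-categorical,
#' unordered-categorical).
#'
#' @param n_per_domain Phenotypes per domain (cycled over the four types).
#' @return Tibble with columns `domain`, `n_phenotypes`, `has_change`.
#' @export
default_phenotype_domains <- function(n_per_domain = 4) {
  domains <- c("lifestyle", "mental_health", "cognitive", "physical_measures",
               "sociodemographics", "early_life", "environment",
               "social_support", "medical_history", "blood_assays", "cardiac")
  tibble(domain = domains,
         n_phenotypes = as.integer(n_per_domain),
         has_change = seq_along(domains) <= 9L)
}

#' Default disease-class specification
#'
#' Seventeen disease classes with per-class phecode counts scaled down
#' (factor ~1/25) from the bundled disease-class summary table
#' (`inst/extdata/disease_class_summary.csv`), a common base prevalence and a
#' shared within-class latent loading that induces the inter-phecode
#' correlation the per-class component retention step relies on.
#'
#' @param prevalence Base ever-diagnosed probability per phecode.
#' @param loading Within-class latent loading in (0, 1).
#' @param scale_factor Divisor applied to the real per-class phecode counts.
#' @return Tibble with columns `disease_class`, `n_phecodes`, `prevalence`,
#'   `loading`.
#' @export
default_disease_classes <- function(prevalence = 0.08, loading = 0.6,
                                    scale_factor = 25) {
  ref <- disease_class_summary()
  tibble(disease_class = ref$disease_class,
         n_phecodes = pmax(2L, as.integer(ceiling(ref$n_phecodes / scale_factor))),
         prevalence = prevalence,
         loading = loading)
}

#' Disease-class summary reference table
#'
#' Per-class phecode counts, retained latent-factor counts and explained
#' variance for the 17 phecode disease classes, as tabulated for the full
#' epidemiological cohort the analysis design targets. Used to parameterize
#' [default_disease_classes()] and for arithmetic cross-checks
#' (1,662 phecodes; 58 retained factors; 174 = 3 x 58 composite clusters).
#'
#' @return Tibble with columns `disease_class`, `n_phecodes`,
#'   `n_latent_factors`, `explained_variance_pct`.
#' @export
disease_class_summary <- function() {
  path <- system.file("extdata", "disease_class_summary.csv",
                      package = "hemishift", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    disease_class = readr::col_character(),
    n_phecodes = readr::col_integer(),
    n_latent_factors = readr::col_integer(),
    explained_variance_pct = readr::col_double()
  ))
}

#' Configure the synthetic two-visit cohort
#'
#' The defaults emulate the study conditions of the target cohort: 1,425
#' participants, 49% male, first-visit age 62.5 +/- 7.2 years, 27.4 +/- 1.4
#' months between visits, employment split 870/121/308
#' (employed/retiring/retired), 85 homologous feature pairs and 33 latent
#' asymmetry patterns.
#'
#' @param n_participants Cohort size.
#' @param seed Global seed; every table draws from a named substream of it.
#' @param atlas Atlas tibble from [atlas_spec()].
#' @param n_latent_patterns Number of planted latent asymmetry patterns.
#' @param latent_loading_scale Scale of the strongest pattern's LI loading;
#'   pattern k has loading scale `latent_loading_scale / sqrt(k)`, a
#'   power-law spectrum whose leading-pattern eigengaps keep the fitted
#'   basis identifiable.
#' @param noise_sd Per-feature LI measurement noise (0 switches off all
#'   measurement-level perturbation, including visit-2 confound jitter and
#'   per-feature volume noise).
#' @param drift_sd Residual per-pattern drift spread, pattern-units/year.
#' @param drift_mean Length-`n_latent_patterns` vector of mean drift rates;
#'   default is a small decaying leftward trend on the leading patterns.
#' @param mean_interval_days,sd_interval_days Inter-visit interval (days).
#' @param age_mean,age_sd First-visit age distribution (years).
#' @param sex_fraction_male Probability of male sex.
#' @param employment_state_probs Named probabilities over
#'   employed/retiring/retired; must sum to 1.
#' @param confound_effect_scale Scale of technical-confound leakage into raw
#'   LIs.
#' @param atrophy_rate Mean fractional volume loss per year.
#' @param atrophy_sd Between-participant spread of the yearly atrophy rate;
#'   this shared component makes left and right homolog volume changes
#'   positively (but imperfectly) correlated.
#' @param planted_effects Tibble of [planted_effect()] rows.
#' @param phenotype_domain_spec See [default_phenotype_domains()].
#' @param disease_class_spec See [default_disease_classes()].
#' @param fmri_feature_count Number of connectivity features to simulate.
#' @param missing_rate Phenotype missingness rate per visit.
#' @return A validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 1425,
                          seed = 1L,
                          atlas = atlas_spec(),
                          n_latent_patterns = 33,
                          latent_loading_scale = 1,
                          noise_sd = 0.015,
                          drift_sd = 0.03,
                          drift_mean = NULL,
                          mean_interval_days = 27.4 * 30.44,
                          sd_interval_days = 1.4 * 30.44,
                          age_mean = 62.5,
                          age_sd = 7.2,
                          sex_fraction_male = 0.49,
                          employment_state_probs = c(employed = 870, retiring = 121, retired = 308) / 1299,
                          confound_effect_scale = 0.1,
                          atrophy_rate = 0.005,
                          atrophy_sd = 0.019,
                          planted_effects = NULL,
                          phenotype_domain_spec = default_phenotype_domains(),
                          disease_class_spec = default_disease_classes(),
                          fmri_feature_count = 100,
                          missing_rate = 0) {
  if (n_participants < 0 || n_participants != round(n_participants)) {
    abort("`n_participants` must be a non-negative integer")
  }
  k <- n_latent_patterns
  if (k < 1 || k > nrow(atlas)) {
    abort("`n_latent_patterns` must be between 1 and the number of feature pairs")
  }
  p <- employment_state_probs
  if (length(p) != 3 || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8) {
    abort("`employment_state_probs` must be 3 probabilities summing to 1")
  }
  names(p) <- c("employed", "retiring", "retired")
  if (sex_fraction_male < 0 || sex_fraction_male > 1) {
    abort("`sex_fraction_male` must be in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate > 1) abort("`missing_rate` must be in [0, 1]")
  if (is.null(planted_effects)) {
    planted_effects <- planted_effect("lbac", 1, "sex", 0)[0, ]
  }
  if (nrow(planted_effects) && any(planted_effects$pattern > k)) {
    abort("planted effect targets a nonexistent pattern")
  }
  if (is.null(drift_mean)) {
    drift_mean <- 0.05 * drift_sd * exp(-(seq_len(k) - 1) / 5)
  }
  stopifnot(length(drift_mean) == k)
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    atlas = atlas, n_latent_patterns = as.integer(k),
    latent_loading_scale = latent_loading_scale,
    noise_sd = noise_sd, drift_sd = drift_sd, drift_mean = drift_mean,
    mean_interval_days = mean_interval_days,
    sd_interval_days = sd_interval_days,
    age_mean = age_mean, age_sd = age_sd,
    sex_fraction_male = sex_fraction_male,
    employment_state_probs = p,
    confound_effect_scale = confound_effect_scale,
    atrophy_rate = atrophy_rate,
    atrophy_sd = atrophy_sd,
    planted_effects = planted_effects,
    phenotype_domain_spec = phenotype_domain_spec,
    disease_class_spec = disease_class_spec,
    fmri_feature_count = as.integer(fmri_feature_count),
    missing_rate = missing_rate
  ), class = "cohort_config")
}

# Per-pattern latent loading scales: 1/sqrt(k) spectrum. Leading patterns
# get large eigengaps, so the SVD-fitted basis aligns with the planted
# loadings there; planted effects should target leading patterns.
latent_scales <- function(config) {
  config$latent_loading_scale / sqrt(seq_len(config$n_latent_patterns))
}

# Standardize a driver vector; all-constant drivers become zero.
scale_driver <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# d on |N(0, s)| induced by a log-sd group shift: E|X| = s*sqrt(2/pi),
# sd|X| = s*sqrt(1 - 2/pi)  =>  d ~= delta * sqrt(2/pi) / sqrt(1 - 2/pi).
HALF_NORMAL_D_PER_SD <- sqrt(2 / pi) / sqrt(1 - 2 / pi)
# Mean separation (in sd units) between top and bottom quartile of a normal.
QUARTILE_SEPARATION <- 2 * dnorm(qnorm(0.75)) / 0.25

#' Generate a synthetic two-visit cohort bundle
#'
#' Produces every input table of the pipeline with the statistical structure
#' the analysis assumes: a low-rank latent pattern structure in visit-1
#' lateralization indices, per-pattern drift between visits that carries the
#' planted effects, technical-confound leakage, typed behavioural phenotypes
#' at both visits, correlated within-class diagnosis records with an
#' ICD-to-phecode map, and a connectivity-feature block coupled to the
#' disease-class latents. Bilateral left/right values are reconstructed from
#' the simulated LI and a lognormal pair total via R = T(2+LI)/4,
#' L = T(2-LI)/4, which inverts the LI formula exactly.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_bundle` list: `demographics`, `confounds`,
#'   `bilateral_v1`, `bilateral_v2`, `phenotypes_v1`, `phenotypes_v2`,
#'   `phenotype_meta`, `icd_records`, `phecode_map`, `fmri`, `atlas`,
#'   `config`, and `ground_truth` (planted effects, loading matrix, latent
#'   scales, drift-rate matrix).
#' @examples
#' bundle <- simulate_cohort(cohort_config(n_participants = 50, seed = 1,
#'                                         n_latent_patterns = 5))
#' names(bundle)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  atlas <- config$atlas
  f <- nrow(atlas)
  k <- config$n_latent_patterns
  ids <- sprintf("p%05d", seq_len(n))
  seed <- config$seed
  scales <- latent_scales(config)

  # -- demographics --------------------------------------------------------
  demographics <- with_seed(substream_seed(seed, "demographics"), {
    states <- names(config$employment_state_probs)
    st <- if (n) sample(states, n, replace = TRUE,
                        prob = config$employment_state_probs) else character()
    tibble(
      participant_id = ids,
      age = round(rnorm(n, config$age_mean, config$age_sd), 2),
      sex = as.numeric(runif(n) < config$sex_fraction_male),
      employment = st,
      employment_v1 = ifelse(st == "retired", "retired", "employed"),
      employment_v2 = ifelse(st == "employed", "employed", "retired"),
      delta_t_days = round(pmax(
        30, rnorm(n, config$mean_interval_days, config$sd_interval_days)))
    )
  })
  dt_years <- demographics$delta_t_days / 365

  # -- technical confounds (per participant-visit) -------------------------
  conf_names <- c("head_size", "motion_task", "motion_rest",
                  "head_position", "site_offset")
  confounds <- with_seed(substream_seed(seed, "confounds"), {
    c1 <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, conf_names))
    c2 <- c1 + matrix(rnorm(n * 5, sd = config$noise_sd), n, 5)
    dplyr::bind_rows(
      matrix_to_tbl(c1, ids) |> tibble::add_column(visit = 1, .after = 1),
      matrix_to_tbl(c2, ids) |> tibble::add_column(visit = 2, .after = 1)
    )
  })
  conf1 <- tbl_to_matrix(dplyr::filter(confounds, .data$visit == 1)[-2])
  conf2 <- tbl_to_matrix(dplyr::filter(confounds, .data$visit == 2)[-2])

  # -- latent pattern structure -------------------------------------------
  latent <- with_seed(substream_seed(seed, "latent"), {
    v <- qr.Q(qr(matrix(rnorm(f * k), f, k)))
    v <- fix_column_signs(v)
    dimnames(v) <- list(atlas$pair, pattern_labels(k))
    gamma <- matrix(rnorm(5 * f, sd = config$confound_effect_scale), 5, f)
    z1 <- matrix(rnorm(n * k), n, k) %*% diag(scales, k)
    list(v = v, gamma = gamma, z1 = z1)
  })

  # -- behavioural phenotypes ---------------------------------------------
  spec <- config$phenotype_domain_spec
  types <- c("continuous", "binary", "ordered", "unordered")
  meta <- purrr::pmap_dfr(spec, function(domain, n_phenotypes, has_change) {
    tibble(id = sprintf("%s_%02d", domain, seq_len(n_phenotypes)),
           domain = domain,
           var_type = rep_len(types, n_phenotypes),
           has_change = has_change)
  })
  ph <- with_seed(substream_seed(seed, "phenotypes"), {
    lat1 <- matrix(rnorm(n * nrow(meta)), n, nrow(meta),
                   dimnames = list(NULL, meta$id))
    dlat <- matrix(rnorm(n * nrow(meta), sd = 0.7), n, nrow(meta),
                   dimnames = list(NULL, meta$id))
    list(lat1 = lat1, dlat = dlat)
  })

  # -- disease classes, phecodes, ICD map ----------------------------------
  dspec <- config$disease_class_spec
  phecode_map <- purrr::pmap_dfr(
    dspec[c("disease_class", "n_phecodes")],
    function(disease_class, n_phecodes) {
      ci <- match(disease_class, dspec$disease_class)
      code <- sprintf("PC%02d_%02d", ci, seq_len(n_phecodes))
      dplyr::bind_rows(
        tibble(icd_code = sprintf("%s%02d.1", LETTERS[(ci - 1) %% 26 + 1],
                                  seq_len(n_phecodes)),
               icd_version = 10L, phecode = code, disease_class = disease_class),
        tibble(icd_code = sprintf("%s%02d.2", LETTERS[(ci - 1) %% 26 + 1],
                                  seq_len(n_phecodes)),
               icd_version = 10L, phecode = code, disease_class = disease_class),
        tibble(icd_code = sprintf("%03d.%d", 100 + ci, seq_len(n_phecodes)),
               icd_version = 9L, phecode = code, disease_class = disease_class)
      )
    })
  disease <- with_seed(substream_seed(seed, "disease"), {
    u <- matrix(rnorm(n * nrow(dspec)), n, nrow(dspec),
                dimnames = list(NULL, dspec$disease_class))
    phe <- purrr::pmap(dspec, function(disease_class, n_phecodes,
                                       prevalence, loading) {
      thr <- qnorm(1 - prevalence)
      lat <- loading * u[, disease_class] +
        sqrt(1 - loading^2) * matrix(rnorm(n * n_phecodes), n, n_phecodes)
      m <- (lat > thr) * 1
      colnames(m) <- sprintf("PC%02d_%02d",
                             match(disease_class, dspec$disease_class),
                             seq_len(n_phecodes))
      m
    })
    phe <- do.call(cbind, phe)
    list(u = u, phecodes = phe)
  })
  icd_records <- with_seed(substream_seed(seed, "icd"), {
    hits <- which(disease$phecodes == 1, arr.ind = TRUE)
    if (!length(hits)) {
      tibble(participant_id = character(), icd_code = character(),
             icd_version = integer())
    } else {
      code <- colnames(disease$phecodes)[hits[, 2]]
      map10 <- phecode_map[phecode_map$icd_version == 10, ]
      first10 <- map10$icd_code[match(code, map10$phecode)]
      map9 <- phecode_map[phecode_map$icd_version == 9, ]
      icd9 <- map9$icd_code[match(code, map9$phecode)]
      use9 <- runif(nrow(hits)) < 0.3
      tibble(participant_id = ids[hits[, 1]],
             icd_code = ifelse(use9, icd9, first10),
             icd_version = ifelse(use9, 9L, 10L)) |>
        dplyr::arrange(.data$participant_id, .data$icd_code)
    }
  })

  # -- per-pattern drift rates carrying the planted effects ---------------
  pe <- config$planted_effects
  drift <- with_seed(substream_seed(seed, "drift"), {
    rates <- matrix(rep(config$drift_mean, each = n), n, k)
    log_sd_mult <- matrix(0, n, k)
    resid_r2 <- rep(0, k)
    if (nrow(pe)) for (i in seq_len(nrow(pe))) {
      j <- pe$pattern[i]; es <- pe$effect_size[i]; drv <- pe$driver[i]
      driver_z <- if (drv == "sex") {
        scale_driver(demographics$sex)
      } else if (drv == "age") {
        scale_driver(demographics$age)
      } else if (drv == "employment") {
        scale_driver(dplyr::case_when(
          demographics$employment == "employed" ~ 1,
          demographics$employment == "retired" ~ -1, TRUE ~ 0))
      } else if (startsWith(drv, "phenotype_change:")) {
        scale_driver(ph$dlat[, sub("phenotype_change:", "", drv)])
      } else if (startsWith(drv, "phenotype:")) {
        scale_driver(ph$lat1[, sub("phenotype:", "", drv)])
      } else if (startsWith(drv, "disease:")) {
        scale_driver(disease$u[, sub("disease:", "", drv)])
      } else abort(paste0("unknown planted-effect driver: ", drv))
      group_driver <- drv %in% c("sex", "age", "employment")
      if (pe$measure[i] == "mbac" && group_driver) {
        # spread difference on |drift|: calibrate through half-normal moments
        delta <- es / HALF_NORMAL_D_PER_SD
        mult <- if (drv == "age") delta * driver_z / QUARTILE_SEPARATION
                else delta * driver_z / 2
        log_sd_mult[, j] <- log_sd_mult[, j] + log1p(pmax(-0.9, mult))
      } else if (group_driver) {
        # mean-shift on drift; d measured as group contrast in pooled-sd units
        shift <- if (drv == "age") es * driver_z / QUARTILE_SEPARATION
                 else es * driver_z / 2
        rates[, j] <- rates[, j] + config$drift_sd * shift
      } else {
        # correlation-type driver: variance-preserving mixture
        rates[, j] <- rates[, j] + config$drift_sd * es * driver_z
        resid_r2[j] <- resid_r2[j] + es^2
      }
    }
    eps_sd <- config$drift_sd * sqrt(pmax(0, 1 - resid_r2))
    eps <- matrix(rnorm(n * k), n, k) %*% diag(eps_sd, k)
    rates + eps * exp(log_sd_mult)
  })
  if (config$drift_sd == 0 && !nrow(pe)) drift <- drift * 0 + config$drift_mean

  z2 <- latent$z1 + drift * dt_years

  # -- phenotype values at both visits (after drift, so changes can couple)
  pheno <- with_seed(substream_seed(seed, "phenotype_values"), {
    lat1 <- ph$lat1
    dlat <- ph$dlat
    if (nrow(pe)) for (i in seq_len(nrow(pe))) {
      drv <- pe$driver[i]
      if (startsWith(drv, "phenotype_change:")) {
        id <- sub("phenotype_change:", "", drv)
        es <- pe$effect_size[i]
        # rebuild the change latent as a noisy copy of the pattern drift
        dlat[, id] <- es * scale_driver(drift[, pe$pattern[i]]) +
          sqrt(1 - es^2) * rnorm(n)
      }
    }
    lat2 <- lat1 + dlat
    encode <- function(lat, id) {
      vt <- meta$var_type[match(id, meta$id)]
      x <- lat[, id]
      if (vt == "continuous") round(x, 4)
      else if (vt == "binary") as.numeric(x > qnorm(0.7))
      else if (vt == "ordered") {
        as.numeric(cut(x, c(-Inf, -0.6, 0.3, 1.0, Inf), labels = FALSE))
      } else c("alpha", "beta", "gamma")[
        pmin(3, pmax(1, findInterval(x, c(-0.43, 0.43)) + 1))]
    }
    build <- function(lat) {
      cols <- lapply(meta$id, function(id) encode(lat, id))
      names(cols) <- meta$id
      tb <- as_tibble(cols)
      if (config$missing_rate > 0 && n > 0) {
        for (id in meta$id) {
          miss <- runif(n) < config$missing_rate
          tb[[id]][miss] <- NA
        }
      }
      tibble::add_column(tb, participant_id = ids, .before = 1)
    }
    v1 <- build(lat1)
    v2 <- build(lat2)
    list(v1 = v1, v2 = v2)
  })

  # -- LI matrices and bilateral reconstruction ---------------------------
  bilateral <- with_seed(substream_seed(seed, "bilateral"), {
    e1 <- matrix(rnorm(n * f, sd = config$noise_sd), n, f)
    e2 <- matrix(rnorm(n * f, sd = config$noise_sd), n, f)
    li1 <- latent$z1 %*% t(latent$v) + conf1 %*% latent$gamma + e1
    li2 <- z2 %*% t(latent$v) + conf2 %*% latent$gamma + e2
    li1 <- pmin(pmax(li1, -1.99), 1.99)
    li2 <- pmin(pmax(li2, -1.99), 1.99)
    meanlog <- c(cortical = log(9000), subcortical = log(2500),
                 tract = log(1), cerebellar = log(1800))[atlas$class]
    t1 <- matrix(rlnorm(n * f, meanlog = rep(meanlog, each = n), sdlog = 0.15),
                 n, f)
    rate_i <- config$atrophy_rate + config$atrophy_sd * rnorm(n)
    shrink <- pmax(0.5, 1 - rate_i * dt_years)
    vol_noise <- if (config$noise_sd > 0)
      exp(matrix(rnorm(n * f, sd = 0.5 * config$noise_sd), n, f)) else 1
    t2 <- t1 * shrink * vol_noise
    as_bilat <- function(tt, li) {
      r <- tt * (2 + li) / 4
      l <- tt * (2 - li) / 4
      colnames(r) <- paste0("R_", atlas$pair)
      colnames(l) <- paste0("L_", atlas$pair)
      idx <- as.vector(rbind(seq_len(f), f + seq_len(f)))
      matrix_to_tbl(cbind(l, r)[, idx, drop = FALSE], ids)
    }
    list(v1 = as_bilat(t1, li1), v2 = as_bilat(t2, li2),
         li1 = li1, li2 = li2)
  })

  # -- connectivity features coupled to disease-class latents --------------
  fmri <- with_seed(substream_seed(seed, "fmri"), {
    nf <- config$fmri_feature_count
    nc <- ncol(disease$u)
    w <- matrix(rnorm(nc * nf, sd = 0.5), nc, nf)
    extra <- matrix(rnorm(n * 10), n, 10) %*% matrix(rnorm(10 * nf, sd = 0.4), 10, nf)
    m <- disease$u %*% w + extra + matrix(rnorm(n * nf), n, nf)
    colnames(m) <- sprintf("conn_%03d", seq_len(nf))
    matrix_to_tbl(m, ids)
  })

  structure(list(
    demographics = demographics,
    confounds = confounds,
    bilateral_v1 = bilateral$v1,
    bilateral_v2 = bilateral$v2,
    phenotypes_v1 = pheno$v1,
    phenotypes_v2 = pheno$v2,
    phenotype_meta = meta[c("id", "domain", "var_type", "has_change")],
    icd_records = icd_records,
    phecode_map = phecode_map,
    fmri = fmri,
    atlas = atlas,
    config = config,
    ground_truth = list(
      planted_effects = pe,
      loadings = latent$v,
      latent_scales = scales,
      drift_rates = drift,
      phecode_matrix = disease$phecodes,
      class_latents = disease$u
    )
  ), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  cat("  participants:", nrow(x$demographics), "\n")
  cat("  feature pairs:", nrow(x$atlas), "\n")
  cat("  latent patterns:", x$config$n_latent_patterns, "\n")
  cat("  phenotypes:", nrow(x$phenotype_meta), "| phecodes:",
      length(unique(x$phecode_map$phecode)), "\n")
  cat("  planted effects:", nrow(x$ground_truth$planted_effects), "\n")
  invisible(x)
}
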