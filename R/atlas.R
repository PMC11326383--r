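#' Declare the homologous feature-pair atlas
#'
#' The analysis operates on left/right homologous brain feature pairs drawn
#' from several anatomical classes. The default atlas mirrors the standard
#' multi-atlas collection used for whole-brain asymmetry work: 48 cortical
#' grey-matter regions, 7 subcortical grey-matter regions, 21 white-matter
#' tracts (fractional anisotropy) and 9 cerebellar parcels, for 85 pairs in
#' total of which 55 are grey matter.
#'
#' @param cortical,subcortical,tract,cerebellar Number of feature pairs per
#'   anatomical class.
#' @return A tibble with one row per feature pair and columns `pair`
#'   (unique identifier), `class` (`cortical`, `subcortical`, `tract`,
#'   `cerebellar`) and `measure` (`volume_mm3` or `fa`).
#' @examples
#' atlas <- atlas_spec()
#' nrow(atlas)                      # 85
#' sum(atlas$class %in% c("cortical", "subcortical"))  # 55 grey-matter pairs
#' @export
atlas_spec <- function(cortical = 48, subcortical = 7, tract = 21,
                       cerebellar = 9) {
  counts <- c(cortical = cortical, subcortical = subcortical,
              tract = tract, cerebellar = cerebellar)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("atlas class counts must be non-negative integers")
  }
  if (sum(counts) < 1) abort("atlas must contain at least one feature pair")
  cls <- rep(names(counts), counts)
  idx <- unlist(lapply(counts, seq_len), use.names = FALSE)
  prefix <- c(cortical = "ctx", subcortical = "sub", tract = "wm",
              cerebellar = "cbl")
  pair <- sprintf("%s_%02d", prefix[cls], idx)
  stopifnot(!anyDuplicated(pair))
  tibble(
    pair = pair,
    class = cls,
    measure = ifelse(cls == "tract", "fa", "volume_mm3")
  )
}

#' Grey-matter pair names of an atlas
#'
#' @param atlas An atlas tibble from [atlas_spec()].
#' @return Character vector of cortical + subcortical pair names.
#' @export
grey_pairs <- function(atlas) {
  atlas$pair[atlas$class %in% c("cortical", "subcortical")]
}

cortical_pairs <- function(atlas) atlas$pair[atlas$class == "cortical"]

# Names of the left/right measurement columns of a bilateral table.
bilateral_cols <- function(atlas) {
  list(left = paste0("L_", atlas$pair), right = paste0("R_", atlas$pair))
}
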