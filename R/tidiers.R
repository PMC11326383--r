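#' Tidy asymmetry-change rates into long format
#'
#' @param x An `asym_changes` object.
#' @param ... Unused.
#' @return Long tibble `participant_id`, `pattern`, `lbac`, `mbac` (plus
#'   `dG_delta` when the grey reference is attached).
#' @exportS3Method generics::tidy
tidy.asym_changes <- function(x, ...) {
  l <- tidyr::pivot_longer(x$lbac, -"participant_id",
                           names_to = "pattern", values_to = "lbac")
  m <- tidyr::pivot_longer(x$mbac, -"participant_id",
                           names_to = "pattern", values_to = "mbac")
  out <- dplyr::left_join(l, m, by = c("participant_id", "pattern"))
  if (!is.null(x$grey_reference)) {
    out <- dplyr::left_join(
      out, x$grey_reference[c("participant_id", "dG_delta")],
      by = "participant_id")
  }
  out
}

#' One-row summary of an asymmetry-change table
#'
#' @param x An `asym_changes` object.
#' @param ... Unused.
#' @return Tibble with participant and pattern counts, mean |LBAC|, mean
#'   MBAC, mean interval and aligned-flip count.
#' @exportS3Method generics::glance
glance.asym_changes <- function(x, ...) {
  l <- tbl_to_matrix(x$lbac); m <- tbl_to_matrix(x$mbac)
  tibble(n_participants = nrow(l), n_patterns = ncol(l),
         mean_abs_lbac = mean(abs(l)), mean_mbac = mean(m),
         mean_interval_days = mean(x$delta_t_days),
         n_sign_flips = sum(x$sign_flips < 0))
}

#' Tidy a pattern basis into long loading format
#'
#' @param x A `pattern_basis`.
#' @param ... Unused.
#' @return Tibble `pair`, `pattern`, `loading`.
#' @exportS3Method generics::tidy
tidy.pattern_basis <- function(x, ...) {
  matrix_to_tbl(sweep(x$v, 2, x$sign_flips, "*"), rownames(x$v), "pair") |>
    tidyr::pivot_longer(-"pair", names_to = "pattern", values_to = "loading")
}

#' @exportS3Method generics::glance
glance.pattern_basis <- function(x, ...) {
  tibble(n_features = nrow(x$v), k = x$k, provenance = x$provenance,
         n_sign_flips = sum(x$sign_flips < 0))
}

#' Tidy a ridge fit into a coefficient table
#'
#' @param x A `ridge_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (standardized-feature scale).
#' @exportS3Method generics::tidy
tidy.ridge_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "(Intercept)", estimate = x$intercept),
    tibble(term = names(x$beta), estimate = unname(x$beta))
  )
}

#' @exportS3Method generics::glance
glance.ridge_fit <- function(x, ...) {
  tibble(r0_sq = x$r0_sq, adj_r2 = adjusted_r2(x$r0_sq, x$n, x$d),
         n = x$n, d = x$d, lambda = x$lambda)
}

#' Tidy cross-pattern change correlations into long format
#'
#' @param x A `change_correlations` object.
#' @param ... Unused.
#' @return Tibble `block`, `pattern_row`, `pattern_col`, `r`.
#' @exportS3Method generics::tidy
tidy.change_correlations <- function(x, ...) {
  one <- function(mat, block) {
    as_tibble(as.data.frame(mat), rownames = "pattern_row") |>
      tidyr::pivot_longer(-"pattern_row", names_to = "pattern_col",
                          values_to = "r") |>
      tibble::add_column(block = block, .before = 1)
  }
  dplyr::bind_rows(one(x$lbac_lbac, "lbac_lbac"),
                   one(x$mbac_mbac, "mbac_mbac"),
                   one(x$lbac_mbac, "lbac_mbac"))
}

#' Manhattan-style plot of a diagnosis-wide association scan
#'
#' @param object A `mediwas_scan` tibble.
#' @param ... Unused.
#' @return A ggplot: clusters along x (grouped and coloured by disease
#'   class, shaped by technique), -log10 p on y, with the Bonferroni
#'   threshold line; facetted by measure.
#' @exportS3Method ggplot2::autoplot
autoplot.mediwas_scan <- function(object, ...) {
  bon <- attr(object, "bonferroni_threshold")
  df <- dplyr::arrange(as_tibble(object), .data$disease_class, .data$cluster_id)
  df$x <- match(df$cluster_id, unique(df$cluster_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$neg_log10_p,
                                   colour = .data$disease_class,
                                   shape = .data$technique)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(bon), linetype = "dashed") +
    ggplot2::facet_wrap(~measure, ncol = 1) +
    ggplot2::labs(x = "composite disease cluster",
                  y = expression(-log[10](p)),
                  colour = "disease class", shape = "technique") +
    ggplot2::theme_minimal()
}

#' Plot Cohen's d contrasts across patterns
#'
#' @param contrasts Long contrast tibble from [group_contrasts()] (or any
#'   of the single-contrast functions).
#' @param measure Which change measure to show.
#' @return A ggplot of d per pattern, coloured by contrast.
#' @export
plot_contrasts <- function(contrasts, measure = c("lbac", "mbac")) {
  measure <- match.arg(measure)
  df <- dplyr::filter(contrasts, .data$measure == !!measure)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$d,
                                   colour = .data$contrast)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "asymmetry pattern", y = "Cohen's d",
                  title = toupper(measure)) +
    ggplot2::theme_minimal()
}

#' Heatmap of cross-pattern change correlations
#'
#' @param x A `change_correlations` object.
#' @param block Which block to draw.
#' @return A ggplot tile heatmap.
#' @export
plot_change_correlations <- function(x, block = c("lbac_lbac", "mbac_mbac",
                                                  "lbac_mbac")) {
  block <- match.arg(block)
  df <- dplyr::filter(tidy(x), .data$block == !!block)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern_col,
                                   y = .data$pattern_row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = block) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
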