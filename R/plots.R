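#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Box plots of normalized termination density scores
#'
#' One box per region and hemisphere with the mean marked by a diamond,
#' split by anterior/posterior end-set.
#'
#' @param cohort NTDS tibble from [compute_ntds()].
#' @return A ggplot object.
#' @export
plot_ntds <- function(cohort) {
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = .data$region, y = .data$ntds,
                               fill = .data$hemisphere)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, position = "dodge") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 23, size = 2,
                          position = ggplot2::position_dodge(width = 0.75)) +
    ggplot2::facet_grid(. ~ side, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "normalized termination density score") +
    ggplot2::theme_minimal()
}

#' Bar plot of mean termination asymmetry indexes
#'
#' @param ai_test Result of [asymmetry_test()] (uses `mean_ai` and
#'   `significant`).
#' @return A ggplot object.
#' @export
plot_asymmetry <- function(ai_test) {
  ggplot2::ggplot(ai_test,
                  ggplot2::aes(x = .data$region, y = .data$mean_ai,
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_grid(. ~ side, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "mean asymmetry index (R - L)/(R + L)") +
    ggplot2::theme_minimal()
}

#' Bundle width profile across candidate stem slices
#'
#' @param profile Profile tibble from [suggest_stem_slice()].
#' @return A ggplot object.
#' @export
plot_stem_profile <- function(profile) {
  crossed <- profile[profile$width > 0, ]
  best <- crossed$slice[which.min(crossed$width)]
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$slice, y = .data$width)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = best, linetype = 2, colour = "#c0392b") +
    ggplot2::labs(x = "slice index", y = "occupied voxels (bundle width)") +
    ggplot2::theme_minimal()
}
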