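#' Forest plot of a single-SNP association scan
#'
#' Odds ratios with 95% confidence intervals per SNP, on a log scale.
#'
#' @param object A `cg_assoc` scan result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cg_assoc <- function(object, ...) {
  df <- tidy(object)
  df$snp_id <- factor(df$snp_id, levels = rev(df$snp_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$snp_id)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_low,
                                         xmax = .data$or_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$model), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL,
                  colour = "inheritance\nmodel") +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a final risk model
#'
#' @param object A `cg_riskmodel`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cg_riskmodel <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "(Intercept)", ]
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_low,
                                         xmax = .data$or_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curves of compared risk models
#'
#' One curve per model with its optimal operating point marked, plus the
#' chance diagonal.
#'
#' @param object A `cg_roccomp` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cg_roccomp <- function(object, ...) {
  curves <- imap(object$curves, function(cv, nm) {
    tibble(model = nm, fpr = 1 - cv$specificity, tpr = cv$sensitivity)
  }) %>% bind_rows()
  pts <- object$models %>%
    filter(.data$informative) %>%
    mutate(fpr = 1 - .data$specificity, tpr = .data$sensitivity)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = pts, shape = 18, size = 3) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  colour = "model") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
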