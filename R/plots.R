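#' Plot per-gene TEI distributions by diagnostic group
#'
#' Box-and-jitter plot of the Box-Cox-transformed Target Editing Index
#' per gene, split by diagnosis.
#'
#' @param object A `tei_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tei_result <- function(object, ...) {
  samples <- unique(object$tei$sample)
  lab <- setNames(as.character(object$labels), samples)
  df <- mutate(object$tei, diagnosis = lab[.data$sample])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diagnosis, y = .data$tei,
                                   fill = .data$diagnosis)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.5, alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Target Editing Index") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot the empirical ROC curve of a virtual marker
#'
#' @param object An `mroc_signature`.
#' @param ... Unused.
#' @return A ggplot showing the ROC curve with the Youden-optimal
#'   operating point.
#' @export
autoplot.mroc_signature <- function(object, ...) {
  z <- object$scores$z
  case <- object$scores$case
  cuts <- c(-Inf, sort(unique(z)), Inf)
  df <- tibble(
    fpr = vapply(cuts, function(c) mean(z[!case] >= c), numeric(1)),
    tpr = vapply(cuts, function(c) mean(z[case] >= c), numeric(1))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::annotate("point", x = 1 - object$roc$specificity,
                      y = object$roc$sensitivity, colour = "red") +
    ggplot2::labs(
      title = object$comparison,
      subtitle = sprintf("AUC %.3f, Se %.1f%%, Sp %.1f%%", object$roc$auc,
                         100 * object$roc$sensitivity,
                         100 * object$roc$specificity),
      x = "1 - specificity", y = "Sensitivity"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot virtual-marker coordinates of a triplet view
#'
#' Pairwise 2-D projections of the three virtual markers of one triplet
#' view (Z1-Z3 over CTRL/BD/SZ+SA or Z4-Z6 over CTRL/SZ/SA), coloured by
#' diagnosis.
#'
#' @param x A `signature_set` from [run_all_comparisons()].
#' @param view `"A"` (Z1-Z3) or `"B"` (Z4-Z6).
#' @return A ggplot.
#' @export
plot_signature_space <- function(x, view = c("A", "B")) {
  view <- match.arg(view)
  coords <- x$coordinates[[view]]
  if (is.null(coords)) abort("requested triplet view was not computed")
  axes <- setdiff(names(coords), c("sample", "group"))
  long <- purrr::map_dfr(list(c(1, 2), c(1, 3), c(2, 3)), function(ij) {
    tibble(panel = paste(axes[ij[1]], "vs", axes[ij[2]]),
           x = coords[[axes[ij[1]]]], y = coords[[axes[ij[2]]]],
           group = coords$group)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$group)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot random-forest class votes
#'
#' Per-sample vote fractions for each class, grouped by the true class of
#' the held-out samples.
#'
#' @param object An `rf_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rf_report <- function(object, ...) {
  votes <- as_tibble(object$votes) |>
    mutate(truth = as.character(object$truth)) |>
    tidyr::pivot_longer(-"truth", names_to = "class", values_to = "vote")
  ggplot2::ggplot(votes, ggplot2::aes(x = .data$class, y = .data$vote,
                                      fill = .data$class)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$truth),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Voted class", y = "Vote fraction") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
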