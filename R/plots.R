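# ggplot2 displays for the main result types.

#' Plot two-group mutation frequencies with Fisher p-values
#'
#' Bar chart of per-gene mutation frequencies (percent of each group's
#' samples) for the two cohort groups, with the two-sided Fisher p-value
#' printed over each gene, in the style of a recurrence-comparison figure.
#'
#' @param object A `ss_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ss_comparison <- function(object, ...) {
  groups <- attr(object, "groups")
  if (is.null(groups)) groups <- c("group1", "group2")
  long <- as_tibble(object) %>%
    select("gene", "freq_g1_pct", "freq_g2_pct", "p_fisher") %>%
    tidyr::pivot_longer(c("freq_g1_pct", "freq_g2_pct"),
                        names_to = "group", values_to = "freq") %>%
    mutate(group = ifelse(.data$group == "freq_g1_pct",
                          groups[1], groups[2]),
           gene = factor(.data$gene, levels = object$gene))
  labels <- as_tibble(object) %>%
    mutate(gene = factor(.data$gene, levels = object$gene),
           y = pmax(.data$freq_g1_pct, .data$freq_g2_pct) + 3,
           label = paste0("p = ", sprintf("%.2f", .data$p_fisher)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$freq,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(x = .data$gene, y = .data$y,
                                    label = .data$label),
                       inherit.aes = FALSE, size = 3) +
    ggplot2::scale_fill_manual(values = setNames(c("grey60", "lightpink2"),
                                                 groups)) +
    ggplot2::labs(x = NULL, y = "mutated samples (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the six-class mutation spectrum
#'
#' @param object A `ss_spectrum` from [mutation_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ss_spectrum <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(class = factor(.data$class, levels = object$class))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of SNVs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot filter-cascade attrition
#'
#' Candidates entering and failing each cascade stage, in stage order.
#'
#' @param object A `ss_cascade` from [run_filter_cascade()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ss_cascade <- function(object, ...) {
  a <- cascade_attrition(object) %>%
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(a, ggplot2::aes(x = .data$stage)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$entering), fill = "grey80") +
    ggplot2::geom_col(ggplot2::aes(y = .data$failed), fill = "firebrick") +
    ggplot2::labs(x = NULL, y = "candidates (entering / failed)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
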