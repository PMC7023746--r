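# ggplot2 displays for catalogs, signatures, subtraction results, and the
# shared-variant relatedness matrix.

sbs_class_of <- function(labels) {
  cls <- stringr::str_match(labels, "\\[([ACGT]>[ACGT])\\]")[, 2]
  ifelse(is.na(cls), "other", cls)
}

#' @export
autoplot.mut_catalog <- function(object, samples = NULL, ...) {
  long <- tidy(object)
  if (!is.null(samples)) long <- filter(long, .data$sample_id %in% samples)
  long$channel <- factor(long$channel, levels = catalog_scheme(object)$labels)
  long$class <- sbs_class_of(as.character(long$channel))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$channel, y = .data$count,
                                     fill = .data$class)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_wrap(~sample_id, ncol = 1) +
    ggplot2::labs(x = NULL, y = "mutations", fill = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 4),
                   legend.position = "bottom")
}

#' @export
autoplot.signature_profile <- function(object, ...) {
  df <- tidy(object)
  df$channel <- factor(df$channel, levels = attr(object, "labels"))
  df$class <- sbs_class_of(as.character(df$channel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$weight,
                                   fill = .data$class)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = NULL, y = "weight", fill = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 4),
                   legend.position = "bottom")
}

#' @export
autoplot.subtraction_result <- function(object, ...) {
  df <- tidy(object)
  df$channel <- factor(df$channel, levels = df$channel)
  df$class <- sbs_class_of(as.character(df$channel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$residual, fill = .data$class),
                      width = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$ci_lower - .data$centroid + .data$residual,
      ymax = .data$ci_upper - .data$centroid + .data$residual),
      linewidth = 0.2, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "residual mutations (centroid - background)",
                  fill = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 4),
                   legend.position = "bottom")
}

#' Heatmap of the shared-variant matrix
#'
#' The visual counterpart of the lineage check: related samples form bright
#' blocks, a wrongly sequenced parent shows as a dark row/column, and a mixed
#' parental population splits the siblings into two blocks.
#'
#' @param x A [shared_variant_matrix()] result.
#' @return A ggplot object.
#' @export
plot_shared_variants <- function(x) {
  stopifnot(inherits(x, "shared_variants"))
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                   fill = .data$shared)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "shared\nvariants") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
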