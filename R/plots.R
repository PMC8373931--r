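#' @export
autoplot.contact_matrix <- function(object, log_scale = !inherits(
  object, "signed_contact_matrix"), ...) {
  df <- tidy(object)
  df <- bind_rows(df, rename(filter(df, .data$bin1_start != .data$bin2_start),
                             bin1_start = "bin2_start",
                             bin2_start = "bin1_start"))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$bin1_start, .data$bin2_start,
                                        fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0(object$chrom, " [", object$coord_system,
                                 "], ", object$bin_size, " bp bins"))
  if (inherits(object, "signed_contact_matrix")) {
    p + ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                      high = "red", midpoint = 0)
  } else if (log_scale) {
    p + ggplot2::scale_fill_viridis_c(trans = "log1p")
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
}

#' @export
autoplot.insulation_profile <- function(object, boundaries = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$start, .data$score)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "position (bp)", y = "diamond insulation score")
  if (!is.null(boundaries) && length(boundaries) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$start[boundaries],
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @export
autoplot.toy_locus <- function(object, ...) {
  feats <- bind_rows(
    tibble(name = object$genes$name, position = object$genes$tss,
           type = "gene"),
    tibble(name = object$enhancers$name,
           position = (object$enhancers$start + object$enhancers$end) / 2,
           type = paste0(object$enhancers$class, " enhancer")),
    tibble(name = object$ctcf_sites$group,
           position = object$ctcf_sites$position, type = "CTCF")
  )
  ggplot2::ggplot(feats, ggplot2::aes(.data$position, .data$type,
                                      label = .data$name)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$type),
                        show.legend = FALSE) +
    ggplot2::geom_text(angle = 90, hjust = -0.2, size = 2.5,
                       check_overlap = TRUE) +
    ggplot2::xlim(0, object$length) +
    ggplot2::labs(x = "position (bp)", y = NULL)
}

#' @export
autoplot.allele_model <- function(object, ...) {
  doms <- object$partition$domains
  ggplot2::ggplot(doms) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = 1,
                                    fill = factor(.data$domain)),
                       alpha = 0.4, show.legend = FALSE) +
    ggplot2::geom_point(data = object$locus$genes,
                        ggplot2::aes(x = .data$tss, y = 0.66)) +
    ggplot2::geom_point(data = object$locus$enhancers,
                        ggplot2::aes(x = (.data$start + .data$end) / 2,
                                     y = 0.33, colour = .data$class)) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = paste("domain partition:", object$allele)) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
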