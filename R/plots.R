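#' Plot an axial slice of a volume
#'
#' @param x an [image_volume()].
#' @param z slice index (defaults to the middle slice).
#' @return A ggplot object (raster of the slice, mm axes).
#' @export
plot_volume_slice <- function(x, z = NULL) {
  stopifnot(inherits(x, "image_volume"))
  d <- dim(x$data)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$x_mm <- (df$i - 1) * x$spacing[1] + x$origin[1]
  df$y_mm <- (df$j - 1) * x$spacing[2] + x$origin[2]
  df$value <- as.numeric(x$data[, , z][cbind(df$i, df$j)])
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "signal",
                  title = sprintf("axial slice z = %d", z)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.image_volume <- function(object, z = NULL, ...) plot_volume_slice(object, z)

#' @export
autoplot.edema_change <- function(object, z = NULL, ...) {
  lab <- array(0L, dim(object$reduction_mask$data))
  lab[object$reduction_mask$data] <- 1L
  lab[object$new_mask$data] <- 2L
  lab[object$stable_mask$data] <- 3L
  d <- dim(lab)
  if (is.null(z)) {
    nz <- apply(lab > 0, 3, sum)
    z <- if (any(nz > 0)) which.max(nz) else ceiling(d[3] / 2)
  }
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$x_mm <- (df$i - 1) * object$reduction_mask$spacing[1]
  df$y_mm <- (df$j - 1) * object$reduction_mask$spacing[2]
  df$class <- factor(lab[, , z][cbind(df$i, df$j)], levels = 0:3,
                     labels = c("none", "reduction", "new", "stable"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(none = "grey92", reduction = "#2166ac",
                                          new = "#b2182b", stable = "#fddbc7")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "edema change",
                  title = sprintf("change map, axial slice z = %d", z)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stat_table <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$stat_type == "median_iqr",
                      !.data$empty)
  long <- dplyr::bind_rows(
    dplyr::transmute(df, stratum = .data$stratum, timepoint = "t0",
                     median = .data$median_t0, q1 = .data$q1_t0, q3 = .data$q3_t0),
    dplyr::transmute(df, stratum = .data$stratum, timepoint = "t1",
                     median = .data$median_t1, q1 = .data$q1_t1, q3 = .data$q3_t1)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$stratum, .data$median,
                                     colour = .data$timepoint)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "median [IQR] (mm)",
                  title = attr(object, "title")) +
    ggplot2::theme_minimal()
}

#' @export
tidy.edema_change <- function(x, ...) x$report

#' @export
glance.edema_change <- function(x, ...) {
  dplyr::transmute(
    x$report,
    quadrant = .data$quadrant,
    baseline_mm3 = .data$reduction_mm3 + .data$stable_mm3,
    followup_mm3 = .data$new_mm3 + .data$stable_mm3,
    net_change_mm3 = .data$new_mm3 - .data$reduction_mm3
  )
}
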