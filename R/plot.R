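#' Plot radial MTF curves for selected dictionary entries
#'
#' @param dict a `psf_dictionary`
#' @param betas magnifications to plot (nearest stored levels are used)
#' @param field_rc 0-based field cell, default the on-axis-most cell
#' @param channel wavelength channel (1-based)
#' @return a ggplot object (contrast vs spatial frequency in cycles/mm)
#' @export
plot_mtf <- function(dict, betas = dict$zoom_levels,
                     field_rc = c((dict$grid[1] - 1L) %/% 2L,
                                  (dict$grid[2] - 1L) %/% 2L),
                     channel = 2L) {
  rows <- lapply(betas, function(b) {
    k <- psf_lookup(dict, b, field_rc * dict$patch_size, channel)
    m <- psf_mtf(k)
    m$magnification <- factor(sprintf("%gx", k$meta$beta))
    m
  })
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_cpmm, y = .data$mtf,
                                   colour = .data$magnification)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "spatial frequency (cycles/mm)", y = "MTF",
                  colour = "magnification") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot a PSF kernel as a raster image
#'
#' @param x a `psf_kernel`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.psf_kernel <- function(x, ...) {
  k <- x$kernel
  df <- expand.grid(row = seq_len(nrow(k)), col = seq_len(ncol(k)))
  df$value <- as.vector(k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("PSF at %gx, cell (%d, %d), %g um",
                                  x$meta$beta, x$meta$field_rc[1],
                                  x$meta$field_rc[2], x$meta$wavelength),
                  x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot the per-epoch training log of a checkpoint
#'
#' @param ckpt a `psf4d_checkpoint`
#' @return a ggplot object of the loss terms over epochs
#' @export
plot_training_log <- function(ckpt) {
  log <- ckpt$log
  long <- do.call(rbind, lapply(c("loss", "fid", "phys", "ssim_term", "tv"),
                                function(term) {
    tibble::tibble(epoch = log$epoch, term = term, value = log[[term]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss term (log scale)", colour = NULL) +
    ggplot2::theme_minimal()
}
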