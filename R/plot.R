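#' Base-composition figure for positions of interest
#'
#' Renders the native and IVT samples as one panel each: per-position read
#' depth as a gray background, with the requested positions of interest drawn
#' as percentage-stacked basecall bars using the conventional colour map
#' (A green, U red, G orange, C blue).  A position whose reads all agree with
#' the reference shows a single-colour bar; a pseudouridine site shows a
#' visible blue (C) fraction in the native panel that is absent from the IVT
#' panel.
#'
#' @param native,ivt pileup `data.frame`s over the same reference.
#' @param positions integer positions to highlight (may be empty: background
#'   depth chart only).
#' @param path output image path (`.png`); device inferred by
#'   [ggplot2::ggsave()].
#' @param width,height figure size in inches.
#' @return `path`, invisibly.
#' @export
plot_composition <- function(native, ivt, positions, path,
                             width = 9, height = 5) {
  positions <- as.integer(positions)
  if (length(positions) > 0 &&
      (any(positions < 1) || any(positions > max(native$position))))
    dc_input_error("positions of interest outside the reference")
  base_cols <- c(A = "#33a02c", U = "#e31a1c", G = "#ff7f00", C = "#1f78b4")

  one <- function(pu, label) {
    poi <- pu[pu$position %in% positions, , drop = FALSE]
    long <- do.call(rbind, lapply(RNA_BASES, function(b) {
      data.frame(sample = rep(label, nrow(poi)), position = poi$position,
                 base = rep(b, nrow(poi)), n = poi[[paste0("n", b)]],
                 depth = poi$depth, stringsAsFactors = FALSE)
    }))
    bgd <- data.frame(sample = rep(label, nrow(pu)), position = pu$position,
                      depth = pu$depth, stringsAsFactors = FALSE)
    list(long = long, bgd = bgd)
  }
  nat <- one(native, "native"); iv <- one(ivt, "IVT")
  bgd <- rbind(nat$bgd, iv$bgd)
  long <- rbind(nat$long, iv$long)
  # stacked bars scaled to the local depth so they sit inside the depth chart
  long$h <- ifelse(long$depth > 0,
                   long$n, 0)

  p <- ggplot2::ggplot() +
    ggplot2::geom_col(data = bgd,
                      ggplot2::aes(x = .data$position, y = .data$depth),
                      fill = "gray80", width = 1) +
    ggplot2::facet_wrap(~sample, ncol = 1) +
    ggplot2::labs(x = "position (nt)", y = "read depth") +
    ggplot2::theme_minimal()
  if (nrow(long) > 0) {
    p <- p + ggplot2::geom_col(
      data = long,
      ggplot2::aes(x = .data$position, y = .data$h, fill = .data$base),
      width = 1) +
      ggplot2::scale_fill_manual(values = base_cols, name = "basecall")
  }
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}
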