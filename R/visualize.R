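# Plate, well and dose-level views of summarized and per-object data.

.plate_grid <- function() {
  tidyr::expand_grid(row = factor(LETTERS[1:8], levels = rev(LETTERS[1:8])),
                     col = 1:12) |>
    dplyr::mutate(Metadata_Well = sprintf("%s%02d", as.character(.data$row),
                                          .data$col))
}

#' Plate-level heatmap of mean animal length
#'
#' One tile per well of the 8 x 12 grid, filled by mean animal length (um);
#' wells without data render as empty tiles. Accepts either the raw or the
#' processed summary of a bundle. The number of objects per well is printed
#' in each tile; [export_plate_html()] writes an interactive version with
#' hover tooltips.
#'
#' @param summary Well summary tibble (see [summarize_objects()]), with
#'   `Metadata_Plate`, `Metadata_Well`, `n`, `mean_length`.
#' @param plate Plate identifier to display.
#' @return A ggplot object.
#' @export
view_plate <- function(summary, plate) {
  dat <- summary[summary$Metadata_Plate == plate, , drop = FALSE]
  if (nrow(dat) == 0) stop("plate not present in summary: ", plate,
                           call. = FALSE)
  grid <- .plate_grid() |>
    dplyr::left_join(dat, by = "Metadata_Well")
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$mean_length)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$n), "",
                                                   .data$n)), size = 2.6) +
    ggplot2::scale_x_continuous(breaks = 1:12, position = "top",
                                expand = c(0, 0)) +
    ggplot2::scale_fill_viridis_c(name = "mean length (µm)",
                                  na.value = "grey92") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("Plate", plate), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Export an interactive plate heatmap as self-contained HTML
#'
#' Writes a standalone HTML file containing an SVG 8 x 12 plate grid whose
#' cells show well id, object count and mean length (um) on hover — no
#' external assets, viewable in any browser.
#'
#' @inheritParams view_plate
#' @param path Output `.html` path.
#' @return `path`, invisibly.
#' @export
export_plate_html <- function(summary, plate, path) {
  dat <- summary[summary$Metadata_Plate == plate, , drop = FALSE]
  if (nrow(dat) == 0) stop("plate not present in summary: ", plate,
                           call. = FALSE)
  grid <- .plate_grid() |>
    dplyr::left_join(dat, by = "Metadata_Well")
  rng <- range(grid$mean_length, na.rm = TRUE)
  ramp <- grDevices::colorRamp(c("#440154", "#21908C", "#FDE725"))
  fill <- vapply(grid$mean_length, function(v) {
    if (is.na(v)) return("#eeeeee")
    s <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else 0.5
    grDevices::rgb(ramp(s), maxColorValue = 255)
  }, character(1))
  cw <- 60; ch <- 45; pad <- 30
  cells <- sprintf(
    paste0('<rect x="%d" y="%d" width="%d" height="%d" fill="%s" ',
           'stroke="#333"><title>%s</title></rect>'),
    pad + (grid$col - 1) * cw,
    pad + (8 - as.integer(grid$row)) * ch,
    cw, ch, fill,
    ifelse(is.na(grid$n),
           sprintf("%s: no data", grid$Metadata_Well),
           sprintf("%s: n = %s, mean length = %.1f µm",
                   grid$Metadata_Well, grid$n, grid$mean_length))
  )
  labels <- c(
    sprintf('<text x="%d" y="%d" font-size="12" text-anchor="middle">%d</text>',
            pad + (1:12 - 1) * cw + cw %/% 2, pad - 8, 1:12),
    sprintf('<text x="%d" y="%d" font-size="12" text-anchor="middle">%s</text>',
            pad - 12, pad + (0:7) * ch + ch %/% 2 + 4, LETTERS[1:8])
  )
  html <- c(
    "<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    sprintf("<title>Plate %s</title></head><body>", plate),
    sprintf("<h2 style='font-family:sans-serif'>Plate %s &mdash; mean animal length</h2>",
            plate),
    sprintf('<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">',
            pad * 2 + 12 * cw, pad * 2 + 8 * ch),
    labels, cells, "</svg></body></html>"
  )
  writeLines(html, path)
  invisible(path)
}

.object_class <- function(dat) {
  cls <- dat$model_select
  if ("cluster_flag" %in% names(dat)) cls[dat$cluster_flag] <- "cluster"
  if ("well_edge_flag" %in% names(dat)) cls[dat$well_edge_flag] <- "well edge"
  if ("flag_outlier" %in% names(dat)) cls[dat$flag_outlier] <- "outlier"
  cls
}

.read_display_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- tryCatch(tiff::readTIFF(path),
                  error = function(e) stop("cannot read image: ", path, " (",
                                           conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  # 16-bit brightfield renders near-black; stretch to 1st-99th percentiles
  lims <- stats::quantile(img, c(0.01, 0.99), names = FALSE)
  if (lims[2] > lims[1]) img <- (img - lims[1]) / (lims[2] - lims[1])
  pmin(pmax(img, 0), 1)
}

#' Annotated view of one well
#'
#' Draws a marker at each object's centroid, colored by its assigned class
#' (selected model, cluster, well edge, outlier), over the well's brightfield
#' image when one is supplied (or a blank well disc otherwise). The red
#' circle marks the even-illumination radius used for edge flagging. An
#' optional side panel shows a boxplot of the object lengths.
#'
#' @param objects Flagged or processed object table.
#' @param plate,well Well to display.
#' @param image Optional TIFF path for the well background.
#' @param boxplot Add a side boxplot of object lengths (default `TRUE`).
#' @param radius Even-illumination radius in pixels (default 825).
#' @param center Image center (x, y) in pixels; defaults to
#'   `image_dim / 2`.
#' @param image_dim Image side length(s) in pixels (default 2048).
#' @return A ggplot (or patchwork, when `boxplot = TRUE`) object.
#' @export
view_well <- function(objects, plate, well, image = NULL, boxplot = TRUE,
                      radius = 825, center = NULL, image_dim = 2048) {
  well <- normalize_well(well)
  dat <- objects[objects$Metadata_Plate == plate &
                   objects$Metadata_Well == well, , drop = FALSE]
  if (nrow(dat) == 0) stop("no objects for plate ", plate, " well ", well,
                           call. = FALSE)
  if (length(image_dim) == 1) image_dim <- c(image_dim, image_dim)
  if (is.null(center)) center <- image_dim / 2
  dat$class <- if ("model_select" %in% names(dat)) .object_class(dat)
               else dat$model_name
  theta <- seq(0, 2 * pi, length.out = 256)
  circle <- tibble::tibble(x = center[1] + radius * cos(theta),
                           y = center[2] + radius * sin(theta))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$centroid_x,
                                         y = .data$centroid_y))
  if (!is.null(image)) {
    img <- .read_display_image(image)
    p <- p + ggplot2::annotation_raster(img, xmin = 0, xmax = image_dim[1],
                                        ymin = image_dim[2], ymax = 0)
  }
  p <- p +
    ggplot2::geom_path(data = circle, ggplot2::aes(x = .data$x, y = .data$y),
                       color = "red", linewidth = 0.4, inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(color = .data$class), size = 2,
                        shape = 1, stroke = 1) +
    ggplot2::scale_y_reverse(limits = c(image_dim[2], 0), expand = c(0, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, image_dim[1]),
                                expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s %s", plate, well),
                  x = "x (px)", y = "y (px)", color = "class") +
    ggplot2::theme_minimal()
  if (!boxplot) return(p)
  bp <- ggplot2::ggplot(dat, ggplot2::aes(x = "", y = .data$worm_length)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(ggplot2::aes(color = .data$class), width = 0.1,
                         size = 1.6) +
    ggplot2::labs(x = NULL, y = "length (µm)", color = "class") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p, bp, widths = c(3, 1), guides = "collect")
}

#' Dose-response panels of representative wells
#'
#' For the chosen drug and strain, picks one representative well per
#' concentration — the well whose mean animal length is closest to the
#' median of that dose's well means — and draws an annotated well view per
#' dose (ascending), plus a companion plot of the per-dose length
#' distributions.
#'
#' @param objects Flagged or processed object table carrying design columns
#'   `drug`, `strain` and `concentration_um`.
#' @param drug,strain Treatment to display.
#' @param img_dir Optional directory searched for the wells' image files
#'   (via their `Image_FileName_RawBF`); markers are drawn on a blank disc
#'   when no image is found.
#' @inheritParams view_well
#' @return A list with `wells` (patchwork of per-dose well views, ascending
#'   dose) and `lengths` (ggplot of length by dose).
#' @export
view_dose <- function(objects, drug, strain, img_dir = NULL,
                      radius = 825, center = NULL, image_dim = 2048) {
  need <- c("drug", "strain", "concentration_um")
  miss <- setdiff(need, names(objects))
  if (length(miss) > 0) stop("design column(s) missing: ",
                             paste(miss, collapse = ", "), call. = FALSE)
  dat <- objects[objects$drug == drug & objects$strain == strain, ,
                 drop = FALSE]
  if (nrow(dat) == 0) stop("no wells match drug ", drug, " and strain ",
                           strain, call. = FALSE)
  reps <- dat |>
    dplyr::group_by(.data$concentration_um, .data$Metadata_Plate,
                    .data$Metadata_Well) |>
    dplyr::summarise(well_mean = mean(.data$worm_length), .groups = "drop") |>
    dplyr::group_by(.data$concentration_um) |>
    dplyr::slice_min(abs(.data$well_mean - median(.data$well_mean)), n = 1,
                     with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$concentration_um)
  panels <- lapply(seq_len(nrow(reps)), function(i) {
    r <- reps[i, ]
    rows <- dat[dat$Metadata_Plate == r$Metadata_Plate &
                  dat$Metadata_Well == r$Metadata_Well, , drop = FALSE]
    image <- NULL
    if (!is.null(img_dir) && "Image_FileName_RawBF" %in% names(rows)) {
      cand <- file.path(img_dir, rows$Image_FileName_RawBF[1])
      if (file.exists(cand)) image <- cand
    }
    view_well(rows, r$Metadata_Plate, r$Metadata_Well, image = image,
              boxplot = FALSE, radius = radius, center = center,
              image_dim = image_dim) +
      ggplot2::labs(title = sprintf("%g µM (%s %s)",
                                    r$concentration_um, r$Metadata_Plate,
                                    r$Metadata_Well))
  })
  lengths_plot <- ggplot2::ggplot(
    dat, ggplot2::aes(x = factor(.data$concentration_um),
                      y = .data$worm_length)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 0.5, alpha = 0.4) +
    ggplot2::labs(x = sprintf("%s (µM)", drug), y = "length (µm)",
                  title = strain) +
    ggplot2::theme_minimal()
  list(wells = patchwork::wrap_plots(panels, guides = "collect"),
       lengths = lengths_plot)
}
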