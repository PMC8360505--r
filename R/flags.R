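# Well-edge and within-well outlier flagging.
#
# Uneven illumination degrades segmentation near the periphery of circular
# wells even after background correction, so objects whose centroid lies
# beyond a radius of even illumination are flagged rather than trusted.
# Remaining measurements are screened per well with Tukey's fences.

#' Flag objects near the well edge
#'
#' An object is edge-flagged when the Euclidean distance from the image
#' center to its centroid is strictly greater than `radius`. The default
#' radius of even illumination is 825 pixels; the center defaults to half the
#' image dimensions when those are known, and must be supplied explicitly
#' otherwise (there is no reliable way to guess the well geometry from the
#' object table alone).
#'
#' @param objects Selected object table (one row per primary object).
#' @param radius Radius of even illumination in pixels (default 825).
#' @param center Numeric length-2, image center in pixels (x, y).
#' @param image_dim Numeric length-1 or -2, image size in pixels; used to
#'   derive `center` as `image_dim / 2` when `center` is missing.
#' @return `objects` with a logical `well_edge_flag` column; no rows added
#'   or dropped.
#' @export
edge_flag <- function(objects, radius = 825, center = NULL, image_dim = NULL) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    stop("`radius` must be a single positive number", call. = FALSE)
  }
  if (is.null(center)) {
    if (is.null(image_dim)) {
      stop("supply `center` or `image_dim` (center = image_dim / 2); ",
           "well geometry cannot be guessed", call. = FALSE)
    }
    if (length(image_dim) == 1) image_dim <- c(image_dim, image_dim)
    center <- image_dim / 2
  }
  stopifnot(length(center) == 2, all(center >= 0))
  d <- sqrt((objects$centroid_x - center[1])^2 +
              (objects$centroid_y - center[2])^2)
  objects$well_edge_flag <- d > radius
  objects
}

#' Tukey's fences for a sample of lengths
#'
#' Quartiles are computed by linear interpolation between order statistics at
#' position `(n - 1) * p` (base R's default quantile rule); the fences are
#' `q1 - k * iqr` and `q3 + k * iqr`.
#'
#' @param values Numeric vector (at least two finite values).
#' @param k Fence multiplier (default 1.5).
#' @return A list with `q1`, `q3`, `iqr`, `lower`, `upper`.
#' @examples
#' tukey_fences(c(1, 2, 3, 4, 5, 6, 7, 8))
#' @export
tukey_fences <- function(values, k = 1.5) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 0)
  v <- values[is.finite(values)]
  if (length(v) < 2) {
    stop("need at least two finite values to compute fences", call. = FALSE)
  }
  q <- unname(stats::quantile(v, probs = c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  list(q1 = q[1], q3 = q[2], iqr = iqr,
       lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

.known_flags <- c(cluster = "cluster_flag", well_edge = "well_edge_flag",
                  outlier = "flag_outlier")

.flag_cols <- function(flags) {
  unknown <- setdiff(flags, names(.known_flags))
  if (length(unknown) > 0) {
    stop("unknown flag name(s): ", paste(unknown, collapse = ", "),
         "; known flags: ", paste(names(.known_flags), collapse = ", "),
         call. = FALSE)
  }
  unname(.known_flags[flags])
}

#' Flag within-well outlier lengths with Tukey's fences
#'
#' Fences are computed per well over `worm_length` of the rows not already
#' carrying any flag in `exclude_flags` (by default cluster- and edge-flagged
#' rows are excluded, since their measurements are known to be unreliable and
#' would distort the fences). Rows eligible for the fence computation are
#' flagged when their length falls strictly outside the fences; excluded rows
#' keep `flag_outlier = FALSE` (they already carry a flag). Wells with fewer
#' than `min_n` eligible rows are left unflagged — quartiles of so few points
#' over-flag.
#'
#' @param objects Edge-flagged selected table (needs `cluster_flag` and
#'   `well_edge_flag`).
#' @param k Tukey fence multiplier (default 1.5).
#' @param min_n Minimum eligible observations per well (default 3).
#' @param exclude_flags Subset of `c("cluster", "well_edge")` excluded from
#'   the fence computation; default both. Use `character(0)` to include all
#'   rows.
#' @return `objects` with a logical `flag_outlier` column.
#' @export
set_flags <- function(objects, k = 1.5, min_n = 3,
                      exclude_flags = c("cluster", "well_edge")) {
  stopifnot(min_n >= 2)
  need <- c("cluster_flag", "well_edge_flag", "worm_length")
  miss <- setdiff(need, names(objects))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "),
         "; run select_models() and edge_flag() first", call. = FALSE)
  }
  excl_cols <- .flag_cols(exclude_flags)
  if ("flag_outlier" %in% excl_cols) {
    stop("`exclude_flags` may only contain \"cluster\" and \"well_edge\"",
         call. = FALSE)
  }
  objects |>
    dplyr::group_by(.data$Metadata_Plate, .data$Metadata_Well) |>
    dplyr::group_modify(function(g, key) {
      eligible <- rep(TRUE, nrow(g))
      for (col in excl_cols) eligible <- eligible & !g[[col]]
      g$flag_outlier <- FALSE
      if (sum(eligible) >= min_n) {
        f <- tukey_fences(g$worm_length[eligible], k = k)
        g$flag_outlier[eligible] <-
          g$worm_length[eligible] < f$lower | g$worm_length[eligible] > f$upper
      }
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate(dplyr::all_of(names(objects)))
}
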