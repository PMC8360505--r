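# Synthetic WormToolbox-like plates with ground truth.
#
# The generator emulates the structure of per-object WormToolbox exports:
# soft matching (each animal emits its own stage's model row plus repeated
# rows for every smaller model), cluster animals (the selected model fitted
# twice), animals beyond the even-illumination radius with degraded length
# measurements, and short non-animal debris. Wells are stage-synchronized,
# as in a bleach-synchronized assay, so within-well fences are meaningful.

#' Simulation configuration
#'
#' Defaults describe a standard assay: 96-well plates titered to about 30
#' animals per well, imaged at 2X into square 16-bit frames with an
#' even-illumination radius of 825 px. Stage length distributions (um) are
#' the generator's fixtures: L1 N(250, 25), L2/L3 N(450, 50), L4 N(700, 60),
#' Adult N(1000, 80). Artifact rates default to 10% edge animals, 5% cluster
#' animals and 0.1 debris objects per animal.
#'
#' @param plates Number of plates.
#' @param wells_per_plate Wells per plate (1-96, filled row-major A01..H12).
#' @param animals_per_well Animals per well (default 30).
#' @param stage_mix Named probabilities of each stage per well; wells are
#'   synchronized, so one stage is drawn per well. Must sum to 1.
#' @param stage_length_mean,stage_length_sd Named numeric vectors (um) of the
#'   true length distribution per stage, ordered smallest to largest.
#' @param edge_fraction Fraction of animals placed beyond the
#'   even-illumination radius.
#' @param cluster_fraction Fraction of animals whose selected model is
#'   fitted twice (overlap artifact).
#' @param debris_rate Expected debris objects per animal.
#' @param debris_length_mean,debris_length_sd Debris length distribution (um).
#' @param well_radius_px Even-illumination radius in pixels (default 825).
#' @param image_size_px Square image side in pixels; the well center is at
#'   `image_size_px / 2`.
#' @param um_per_px Microns per pixel (used only when rendering images).
#' @param measurement_cv Multiplicative measurement noise (coefficient of
#'   variation) on well-measured animals.
#' @param date,experiment,magnification Metadata tokens for generated
#'   filenames.
#' @param doses_um Concentrations assigned column-wise in the design table.
#' @param strain,drug Design labels.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(plates = 1,
                       wells_per_plate = 96,
                       animals_per_well = 30,
                       stage_mix = c(L1 = 0.25, L2L3 = 0.25,
                                     L4 = 0.25, Adult = 0.25),
                       stage_length_mean = c(L1 = 250, L2L3 = 450,
                                             L4 = 700, Adult = 1000),
                       stage_length_sd = c(L1 = 25, L2L3 = 50,
                                           L4 = 60, Adult = 80),
                       edge_fraction = 0.10,
                       cluster_fraction = 0.05,
                       debris_rate = 0.10,
                       debris_length_mean = 60,
                       debris_length_sd = 20,
                       well_radius_px = 825,
                       image_size_px = 2048,
                       um_per_px = 3.3,
                       measurement_cv = 0.02,
                       date = "20230101",
                       experiment = "synthetic",
                       magnification = "m2X",
                       doses_um = c(0, 7.81, 31.25, 125, 500, 2000),
                       strain = "N2", drug = "paraquat") {
  cfg <- as.list(environment())
  stages <- names(stage_mix)
  if (is.null(stages) || !setequal(stages, names(stage_length_mean)) ||
      !setequal(stages, names(stage_length_sd))) {
    stop("stage_mix, stage_length_mean and stage_length_sd must share names",
         call. = FALSE)
  }
  if (abs(sum(stage_mix) - 1) > 1e-8) {
    stop("stage_mix must sum to 1", call. = FALSE)
  }
  for (f in c("edge_fraction", "cluster_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]",
                                           call. = FALSE)
  }
  if (debris_rate < 0) stop("debris_rate must be non-negative", call. = FALSE)
  if (wells_per_plate < 1 || wells_per_plate > 96) {
    stop("wells_per_plate must be 1-96", call. = FALSE)
  }
  if (well_radius_px * 1.02 >= image_size_px / 2) {
    stop("image_size_px too small for well_radius_px: edge objects must fit ",
         "inside the frame", call. = FALSE)
  }
  # order stages by true size so 'smaller models' is well defined
  cfg$stage_order <- stages[order(stage_length_mean[stages])]
  class(cfg) <- "sim_config"
  cfg
}

.well_ids <- function(n = 96) {
  grid <- expand.grid(col = 1:12, row = LETTERS[1:8])
  head(sprintf("%s%02d", grid$row, grid$col), n)
}

# uniform point in the annulus [r_min, r_max] around `center` (area-weighted)
.ring_points <- function(n, center, r_min, r_max) {
  r <- sqrt(runif(n, r_min^2, r_max^2))
  a <- runif(n, 0, 2 * pi)
  cbind(x = center + r * cos(a), y = center + r * sin(a))
}

.sim_plate <- function(cfg, plate_id) {
  wells <- .well_ids(cfg$wells_per_plate)
  stages <- sample(names(cfg$stage_mix), length(wells), replace = TRUE,
                   prob = cfg$stage_mix)
  center <- cfg$image_size_px / 2
  r_in <- 0.97 * cfg$well_radius_px       # interior objects stay well inside
  r_lo <- 1.02 * cfg$well_radius_px       # edge objects clearly outside
  r_hi <- center - 4

  n_a <- cfg$animals_per_well
  animals <- tibble::tibble(
    Metadata_Well = rep(wells, each = n_a),
    stage = rep(stages, each = n_a),
    primary_object_id = rep(seq_len(n_a), times = length(wells))
  )
  animals$true_length <- pmax(
    50, rnorm(nrow(animals), cfg$stage_length_mean[animals$stage],
              cfg$stage_length_sd[animals$stage]))
  animals$is_edge <- runif(nrow(animals)) < cfg$edge_fraction
  animals$is_cluster <- runif(nrow(animals)) < cfg$cluster_fraction
  pos <- matrix(NA_real_, nrow(animals), 2)
  n_edge <- sum(animals$is_edge)
  pos[animals$is_edge, ] <- .ring_points(n_edge, center, r_lo, r_hi)
  pos[!animals$is_edge, ] <- .ring_points(nrow(animals) - n_edge, center,
                                          0, r_in)
  animals$centroid_x <- pos[, 1]
  animals$centroid_y <- pos[, 2]

  # measured length of the animal's own (selected) model instance:
  # clean animals carry small multiplicative noise; edge animals are
  # partially segmented; cluster instances each cover part of the overlap
  noise <- 1 + rnorm(nrow(animals), 0, cfg$measurement_cv)
  animals$measured_length <- animals$true_length * noise
  animals$measured_length[animals$is_edge] <-
    animals$true_length[animals$is_edge] * runif(sum(animals$is_edge), 0.3, 0.8)

  own <- animals |>
    dplyr::mutate(model_name = .data$stage, worm_length = .data$measured_length)
  dup <- animals |>
    dplyr::filter(.data$is_cluster) |>
    dplyr::mutate(model_name = .data$stage,
                  worm_length = .data$true_length *
                    runif(dplyr::n(), 0.5, 0.9),
                  centroid_x = .data$centroid_x + rnorm(dplyr::n(), 0, 10),
                  centroid_y = .data$centroid_y + rnorm(dplyr::n(), 0, 10))
  # cluster animals: the first instance also only covers part of the overlap
  own$worm_length[own$is_cluster] <-
    own$true_length[own$is_cluster] * runif(sum(own$is_cluster), 0.5, 0.9)

  # soft matching: every smaller model fits 1-3 times, covering part of the
  # animal, so its length is a fraction of the true length
  stage_idx <- match(animals$stage, cfg$stage_order)
  smaller <- animals[rep(seq_len(nrow(animals)), pmax(stage_idx - 1, 0)), ]
  smaller$model_name <- cfg$stage_order[
    unlist(lapply(stage_idx, function(k) seq_len(k - 1)), use.names = FALSE)]
  reps <- sample(1:3, nrow(smaller), replace = TRUE)
  smaller <- smaller[rep(seq_len(nrow(smaller)), reps), ]
  smaller$worm_length <- smaller$true_length *
    runif(nrow(smaller), 0.25, 0.65)
  smaller$centroid_x <- pmin(pmax(
    smaller$centroid_x + rnorm(nrow(smaller), 0, 15), 0), cfg$image_size_px)
  smaller$centroid_y <- pmin(pmax(
    smaller$centroid_y + rnorm(nrow(smaller), 0, 15), 0), cfg$image_size_px)

  # debris: short non-animal objects picked up by the smallest model
  n_debris <- rpois(length(wells), cfg$debris_rate * n_a)
  debris <- tibble::tibble(
    Metadata_Well = rep(wells, n_debris),
    stage = NA_character_,
    primary_object_id = unlist(lapply(n_debris, function(k) n_a + seq_len(k)),
                               use.names = FALSE),
    true_length = pmax(10, rnorm(sum(n_debris), cfg$debris_length_mean,
                                 cfg$debris_length_sd)),
    is_edge = FALSE, is_cluster = FALSE
  )
  dpos <- .ring_points(nrow(debris), center, 0, r_in)
  debris$centroid_x <- dpos[, 1]
  debris$centroid_y <- dpos[, 2]
  debris$measured_length <- debris$true_length
  debris$model_name <- cfg$stage_order[1]
  debris$worm_length <- debris$true_length

  obj <- dplyr::bind_rows(own, dup, smaller, debris) |>
    dplyr::arrange(.data$Metadata_Well, .data$primary_object_id) |>
    dplyr::select(-dplyr::any_of(c("stage", "true_length", "is_edge",
                                   "is_cluster", "measured_length")))
  obj$Metadata_Plate <- plate_id
  obj$Metadata_Date <- cfg$date
  obj$Metadata_Experiment <- cfg$experiment
  obj$Metadata_Magnification <- cfg$magnification
  obj$Image_FileName_RawBF <- sprintf("%s-%s-%s-%s_%s.TIF", cfg$date,
                                      cfg$experiment, plate_id,
                                      cfg$magnification, obj$Metadata_Well)
  obj$Image_PathName_RawBF <- "synthetic"

  truth <- dplyr::bind_rows(
    animals |> dplyr::mutate(class = "animal"),
    debris |> dplyr::mutate(class = "debris")
  ) |>
    dplyr::transmute(
      Metadata_Plate = plate_id, .data$Metadata_Well,
      .data$primary_object_id, .data$class, stage = .data$stage,
      true_length = .data$true_length,
      is_edge = .data$is_edge, is_cluster = .data$is_cluster,
      is_outlier = .data$class == "debris"
    ) |>
    dplyr::arrange(.data$Metadata_Well, .data$primary_object_id)

  list(objects = obj, truth = truth, well_stage = setNames(stages, wells))
}

#' Generate a synthetic plate set with ground truth
#'
#' Produces an object table shaped like a WormToolbox per-object export
#' (long format, one row per model fit), a column-wise dose design table and
#' a per-primary-object truth table. One RNG stream per plate is derived
#' from the master seed so plate-level generation is reproducible.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (integer).
#' @return A list with tibbles `objects`, `design`, `truth` and the `config`.
#' @export
generate_plate_set <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  plate_seeds <- sample.int(.Machine$integer.max - 1, config$plates)
  plate_ids <- sprintf("p%02d", seq_len(config$plates))
  sims <- lapply(seq_len(config$plates), function(i) {
    set.seed(plate_seeds[i])
    .sim_plate(config, plate_ids[i])
  })
  wells <- .well_ids(config$wells_per_plate)
  cols <- as.integer(substr(wells, 2, 3))
  dose_idx <- ((cols - 1) %/% max(1, floor(12 / length(config$doses_um)))) %%
    length(config$doses_um) + 1
  design <- tidyr::expand_grid(Metadata_Plate = plate_ids,
                               Metadata_Well = wells) |>
    dplyr::mutate(strain = config$strain, drug = config$drug,
                  concentration_um = config$doses_um[
                    rep(dose_idx, times = config$plates)])
  list(
    objects = dplyr::bind_rows(lapply(sims, `[[`, "objects")),
    design = design,
    truth = dplyr::bind_rows(lapply(sims, `[[`, "truth")),
    config = config,
    seed = seed
  )
}

#' Write a simulated plate set to CSV files
#'
#' Writes `objects.csv`, `design.csv`, `truth.csv` and a `manifest.json`
#' under `dir`, in the same dialect the reader consumes.
#'
#' @param sim Output of [generate_plate_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$objects, file.path(dir, "objects.csv"), progress = FALSE)
  readr::write_csv(sim$design, file.path(dir, "design.csv"), progress = FALSE)
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), progress = FALSE)
  cfg <- unclass(sim$config)
  manifest <- list(
    command = "simulate",
    config = cfg[!vapply(cfg, is.function, logical(1))],
    outputs = file.path(dir, c("objects.csv", "design.csv", "truth.csv")),
    row_counts = list(objects = nrow(sim$objects), truth = nrow(sim$truth)),
    seed = sim$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Render a synthetic well image
#'
#' Draws dark elongated objects on a bright circular well with radial
#' vignetting, mimicking an uneven-illumination brightfield frame. This is a
#' visual aid for testing overlay plots, not an optical simulation.
#'
#' @param objects Object rows of one well (needs centroids and lengths).
#' @param config The [sim_config()] used to generate them.
#' @param px Rendered image side in pixels (downscaled from
#'   `config$image_size_px`).
#' @return Numeric matrix in `[0, 1]`, `px` x `px`.
#' @export
render_well_image <- function(objects, config, px = 256) {
  side <- config$image_size_px
  scale <- px / side
  img <- matrix(0.15, px, px)
  xi <- matrix(rep(seq_len(px), each = px), px, px)   # column index = x
  yi <- matrix(rep(seq_len(px), times = px), px, px)  # row index = y
  c0 <- px / 2
  r <- sqrt((xi - c0)^2 + (yi - c0)^2) / (config$well_radius_px * scale)
  well <- r <= 1.15
  img[well] <- 0.85 - 0.35 * pmin(r[well], 1)^2  # radial vignetting
  for (i in seq_len(nrow(objects))) {
    len_px <- objects$worm_length[i] / config$um_per_px * scale
    a <- runif(1, 0, pi)
    t <- seq(-0.5, 0.5, length.out = max(4, ceiling(len_px)))
    cx <- objects$centroid_x[i] * scale + t * len_px * cos(a)
    cy <- objects$centroid_y[i] * scale + t * len_px * sin(a)
    # wiggly body, 2 px half-thickness
    cy <- cy + sin(t * 6) * 1.5
    for (dx in -1:1) for (dy in -1:1) {
      ix <- pmin(pmax(round(cx) + dx, 1), px)
      iy <- pmin(pmax(round(cy) + dy, 1), px)
      img[cbind(iy, ix)] <- 0.08
    }
  }
  img
}

#' Write synthetic well images for a plate set
#'
#' Writes one 16-bit grayscale TIFF per well, named by the
#' `{date}-{experiment}-{plate}-{magnification}_{well}.TIF` convention.
#'
#' @param sim Output of [generate_plate_set()].
#' @param dir Output directory.
#' @param px Image side in pixels.
#' @param wells Optional subset of wells (e.g. `"A01"`) to render.
#' @return Character vector of written file paths, invisibly.
#' @export
write_well_images <- function(sim, dir, px = 256, wells = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obj <- sim$objects
  if (!is.null(wells)) obj <- obj[obj$Metadata_Well %in% wells, ]
  groups <- split(obj, paste(obj$Metadata_Plate, obj$Metadata_Well))
  paths <- vapply(groups, function(g) {
    p <- file.path(dir, g$Image_FileName_RawBF[1])
    tiff::writeTIFF(render_well_image(g, sim$config, px = px), p,
                    bits.per.sample = 16)
    p
  }, character(1))
  invisible(unname(paths))
}
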