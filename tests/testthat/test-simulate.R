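small_cfg <- function(...) {
  sim_config(plates = 1, wells_per_plate = 8, animals_per_well = 10, ...)
}

test_that("a fixed seed reproduces the simulation exactly", {
  a <- generate_plate_set(small_cfg(), seed = 42)
  b <- generate_plate_set(small_cfg(), seed = 42)
  expect_identical(a$objects, b$objects)
  expect_identical(a$truth, b$truth)
  expect_identical(a$design, b$design)
  c <- generate_plate_set(small_cfg(), seed = 43)
  expect_false(identical(a$objects, c$objects))
})

test_that("configuration defaults and validation match the assay", {
  cfg <- sim_config()
  expect_equal(cfg$animals_per_well, 30)
  expect_equal(cfg$well_radius_px, 825)
  expect_equal(cfg$stage_order, c("L1", "L2L3", "L4", "Adult"))
  expect_error(sim_config(stage_mix = c(L1 = 0.5, L2L3 = 0.4, L4 = 0.05,
                                        Adult = 0.04)), "sum to 1")
  expect_error(sim_config(stage_mix = c(L1 = 0.5, L2L3 = 0.5)),
               "share names")
  expect_error(sim_config(edge_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(wells_per_plate = 97), "1-96")
  expect_error(sim_config(image_size_px = 512), "too small")
})

test_that("soft matching and cluster structure hold by construction", {
  sim <- generate_plate_set(small_cfg(cluster_fraction = 0.3), seed = 7)
  obj <- sim$objects
  truth <- sim$truth
  keys <- c("Metadata_Plate", "Metadata_Well", "primary_object_id")
  # truth and object tables are in bijection at the primary-object level
  expect_setequal(
    do.call(paste, obj[keys]) |> unique(),
    do.call(paste, truth[keys])
  )
  # every primary object has at least one model row, and the multiplicity of
  # its largest (own-stage) model exceeds one exactly for cluster animals
  rk <- rank_models(obj)
  per_po <- obj |>
    dplyr::mutate(r = rk$rank[match(model_name, rk$model_name)]) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_rows = dplyr::n(),
                     top_mult = sum(r == max(r)), .groups = "drop") |>
    dplyr::left_join(truth, by = keys)
  expect_true(all(per_po$n_rows >= 1))
  expect_equal(per_po$top_mult > 1, per_po$is_cluster)
  # animals of stage k also carry rows for every smaller model
  adult <- obj |>
    dplyr::semi_join(truth[truth$stage %in% "Adult", keys], by = keys)
  expect_setequal(unique(adult$model_name), c("L1", "L2L3", "L4", "Adult"))
})

test_that("edge animals lie beyond the radius and debris is short", {
  sim <- generate_plate_set(small_cfg(), seed = 9)
  cfg <- sim$config
  sel <- select_models(sim$objects)
  keys <- c("Metadata_Plate", "Metadata_Well", "primary_object_id")
  j <- dplyr::inner_join(sel, sim$truth, by = keys)
  d <- sqrt((j$centroid_x - cfg$image_size_px / 2)^2 +
              (j$centroid_y - cfg$image_size_px / 2)^2)
  expect_true(all(d[j$is_edge & !j$is_cluster] > cfg$well_radius_px))
  expect_true(all(d[!j$is_edge & !j$is_cluster] < cfg$well_radius_px))
  expect_true(all(j$true_length[j$class == "debris"] <
                    min(j$true_length[j$class == "animal"])))
})

test_that("plate sets round-trip through CSV", {
  sim <- generate_plate_set(small_cfg(), seed = 3)
  dir <- withr::local_tempdir()
  write_plate_set(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("objects.csv", "design.csv", "truth.csv", "manifest.json")))))
  back <- read_object_data(file.path(dir, "objects.csv"))
  expect_equal(nrow(back), nrow(sim$objects))
  expect_equal(back$worm_length, sim$objects$worm_length)
})

test_that("precision and recall come out of the confusion counts", {
  # constructed confusion: TP = 8, FP = 2, FN = 2 -> precision = recall = 0.8
  n <- 40
  tab <- make_flagged(n, lengths = runif(n, 400, 500))
  tab$primary_object_id <- 1:n
  truth <- tibble::tibble(
    Metadata_Plate = "p01", Metadata_Well = "A01",
    primary_object_id = 1:n, class = "animal", stage = "L4",
    true_length = tab$worm_length,
    is_edge = c(rep(TRUE, 10), rep(FALSE, 30)),
    is_cluster = FALSE, is_outlier = FALSE
  )
  tab$well_edge_flag <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2),
                          rep(FALSE, 28))
  b <- process_bundle(tab)
  ev <- evaluate_against_truth(b, truth)
  edge_row <- ev$flag_metrics[ev$flag_metrics$flag == "well_edge", ]
  expect_equal(edge_row$precision, 0.8)
  expect_equal(edge_row$recall, 0.8)
  # the other families are perfectly (vacuously) clean
  expect_equal(ev$flag_metrics$fp[ev$flag_metrics$flag == "cluster"], 0)
  expect_equal(ev$model_accuracy, 1)

  # artifact-free table: raw and processed well means agree exactly
  clean <- make_flagged(10, lengths = runif(10, 400, 500))
  clean$primary_object_id <- 1:10
  truth2 <- truth[1:10, ]
  truth2$is_edge <- FALSE
  truth2$true_length <- clean$worm_length
  ev2 <- evaluate_against_truth(process_bundle(clean), truth2)
  expect_equal(ev2$well_errors$raw_abs_error,
               ev2$well_errors$processed_abs_error)

  # key mismatch is an error
  expect_error(evaluate_against_truth(b, truth[-1, ]), "bijection")
})
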