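test_that("pruning drops exactly the rows carrying a dropped flag", {
  tab <- make_flagged(100, lengths = runif(100, 400, 500),
                      plate = "p01", well = "A01")
  tab$primary_object_id <- 1:100
  tab$cluster_flag[1:7] <- TRUE
  tab$well_edge_flag[8:12] <- TRUE
  tab$flag_outlier[13:15] <- TRUE

  expect_equal(nrow(prune(tab)), 85)
  # keeping edge cases retains those five rows
  expect_equal(nrow(prune(tab, drop_flags = c("cluster", "outlier"))), 90)
  # empty drop set is the identity
  expect_identical(prune(tab, drop_flags = character(0)), tab)
  # unflagged input passes through unchanged
  clean <- make_flagged(5)
  expect_identical(prune(clean), clean)
  expect_error(prune(tab, drop_flags = "bogus"), "unknown flag")
})

test_that("well summaries match closed-form statistics", {
  tab <- make_flagged(2, lengths = c(100, 200))
  s <- summarize_objects(tab)
  expect_equal(s$n, 2)
  expect_equal(s$mean_length, 150)
  expect_equal(s$var_length, 5000)  # ((100-150)^2 + (200-150)^2) / 1
  expect_equal(s$min_length, 100)
  expect_equal(s$max_length, 200)
  expect_equal(s$q50_length, 150)

  # degenerate single-object group: variance is missing, not zero
  one <- summarize_objects(make_flagged(1, lengths = 250))
  expect_equal(one$n, 1)
  expect_equal(one$mean_length, 250)
  expect_true(is.na(one$var_length))

  expect_error(summarize_objects(tab, group_by = character(0)),
               "at least one")
  expect_error(summarize_objects(tab, group_by = "no_such_column"),
               "no_such_column")
})

test_that("summary quantiles are ordered and groups partition the table", {
  withr::local_seed(41)
  tab <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_flagged(sample(1:20, 1), lengths = runif(20, 100, 1000),
                 well = sprintf("C%02d", i))
  }))
  tab$strain <- rep_len(c("N2", "CB4856"), nrow(tab))
  s <- summarize_objects(tab, group_by = c("Metadata_Plate", "Metadata_Well",
                                           "strain"))
  expect_equal(sum(s$n), nrow(tab))
  ord <- with(s, min_length <= q10_length & q10_length <= q25_length &
                q25_length <= q50_length & q50_length <= q75_length &
                q75_length <= q90_length & q90_length <= max_length)
  expect_true(all(ord))
  # brute-force recomputation of one group
  g <- tab[tab$Metadata_Well == "C03" & tab$strain == "N2", ]
  row <- s[s$Metadata_Well == "C03" & s$strain == "N2", ]
  expect_equal(row$mean_length, mean(g$worm_length))
  expect_equal(row$q75_length, interp_quantile(g$worm_length, 0.75))
})

test_that("extra measurement columns are summarized alongside length", {
  tab <- make_flagged(4, lengths = c(100, 200, 300, 400))
  tab$Worm_Area <- c(10, 20, 30, 40)
  s <- summarize_objects(tab, extra_cols = "Worm_Area")
  expect_equal(s$Worm_Area_mean, 25)
  expect_equal(s$Worm_Area_q50, 25)
})

test_that("the bundle carries raw, processed and both summaries", {
  tab <- make_flagged(20, lengths = runif(20, 400, 500))
  tab$primary_object_id <- 1:20
  tab$well_edge_flag[1:4] <- TRUE
  b <- process_bundle(tab)
  expect_s3_class(b, "xpress_bundle")
  expect_named(b, c("raw_data", "processed_data", "summarized_raw",
                    "summarized_processed"))
  expect_equal(nrow(b$processed_data), 16)
  expect_identical(b$raw_data, tab)
  # every processed row exists identically in the raw data
  expect_true(all(vapply(seq_len(nrow(b$processed_data)), function(i) {
    any(vapply(seq_len(nrow(tab)), function(j)
      identical(b$processed_data[i, ], tab[j, ]), logical(1)))
  }, logical(1))))
  # per-well counts can only shrink after pruning
  cmp <- dplyr::left_join(b$summarized_raw, b$summarized_processed,
                          by = c("Metadata_Plate", "Metadata_Well"),
                          suffix = c("_raw", "_proc"))
  expect_true(all(is.na(cmp$n_proc) | cmp$n_proc <= cmp$n_raw))

  # no flags: raw and processed elements identical
  clean <- make_flagged(5)
  b2 <- process_bundle(clean)
  expect_identical(b2$raw_data, b2$processed_data)
  expect_identical(b2$summarized_raw, b2$summarized_processed)
  expect_output(print(b2), "xpress_bundle")
})

test_that("the one-call wrapper equals the hand-chained pipeline", {
  withr::local_seed(51)
  sim <- generate_plate_set(sim_config(plates = 1, wells_per_plate = 12,
                                       animals_per_well = 12), seed = 5)
  obj_csv <- withr::local_tempfile(fileext = ".csv")
  des_csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sim$objects, obj_csv)
  readr::write_csv(sim$design, des_csv)

  b1 <- xpress(obj_csv, design_path = des_csv,
               image_dim = sim$config$image_size_px)
  chained <- read_object_data(obj_csv) |>
    join_design(read_design(des_csv)) |>
    select_models() |>
    edge_flag(image_dim = sim$config$image_size_px) |>
    set_flags() |>
    process_bundle()
  expect_equal(b1$raw_data, chained$raw_data)
  expect_equal(b1$summarized_processed, chained$summarized_processed)

  # a radius override propagates to the edge flags
  b_tight <- xpress(obj_csv, image_dim = sim$config$image_size_px,
                    radius = 400)
  expect_gt(sum(b_tight$raw_data$well_edge_flag),
            sum(b1$raw_data$well_edge_flag))
  # without a design file the bundle simply lacks design columns
  b_nodesign <- xpress(obj_csv, image_dim = sim$config$image_size_px)
  expect_false("strain" %in% names(b_nodesign$raw_data))
  expect_equal(nrow(b_nodesign$raw_data), nrow(b1$raw_data))
})

test_that("bundles write four CSVs plus a manifest", {
  tab <- make_flagged(6, lengths = runif(6, 100, 200))
  b <- process_bundle(tab)
  dir <- withr::local_tempdir()
  write_bundle(b, dir, config = list(radius = 825), seed = 3)
  expect_true(all(file.exists(file.path(
    dir, c("raw.csv", "processed.csv", "summary_raw.csv",
           "summary_processed.csv", "manifest.json")))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$row_counts$raw, 6)
  expect_equal(man$seed, 3)
})
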