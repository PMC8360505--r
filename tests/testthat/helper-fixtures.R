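# Builders for small in-code fixtures shaped like the canonical object table.

# one row per (well, primary object, model instance); defaults fill metadata
make_objects <- function(model_name, worm_length = NULL,
                         primary_object_id = 1L,
                         plate = "p01", well = "A01",
                         centroid_x = 1000, centroid_y = 1000) {
  n <- length(model_name)
  if (is.null(worm_length)) worm_length <- seq(100, by = 10, length.out = n)
  tibble::tibble(
    Metadata_Plate = rep_len(plate, n),
    Metadata_Well = rep_len(well, n),
    Metadata_Date = "20230101",
    Metadata_Experiment = "test",
    Metadata_Magnification = "m2X",
    Image_FileName_RawBF = "20230101-test-p01-m2X_A01.TIF",
    Image_PathName_RawBF = "fixtures",
    primary_object_id = as.integer(rep_len(primary_object_id, n)),
    model_name = model_name,
    worm_length = rep_len(worm_length, n),
    centroid_x = rep_len(centroid_x, n),
    centroid_y = rep_len(centroid_y, n)
  )
}

# a flagged single-well table ready for prune()/summarize()
make_flagged <- function(n = 10, lengths = NULL, cluster = FALSE,
                         edge = FALSE, outlier = FALSE,
                         plate = "p01", well = "A01") {
  tab <- make_objects(rep("L4", n), worm_length = lengths %||% rep(100, n),
                      primary_object_id = seq_len(n), plate = plate,
                      well = well)
  tab$model_select <- tab$model_name
  tab$cluster_flag <- rep_len(cluster, n)
  tab$well_edge_flag <- rep_len(edge, n)
  tab$flag_outlier <- rep_len(outlier, n)
  tab
}

# random many-well, many-model object table for oracle comparisons
random_objects <- function(n_rows, n_models = 4, n_wells = 3, n_po = 5) {
  models <- paste0("M", seq_len(n_models))
  tibble::tibble(
    Metadata_Plate = "p01",
    Metadata_Well = sprintf("A%02d", sample.int(n_wells, n_rows,
                                                replace = TRUE)),
    primary_object_id = sample.int(n_po, n_rows, replace = TRUE),
    model_name = sample(models, n_rows, replace = TRUE),
    worm_length = round(runif(n_rows, 50, 1200), 3),
    centroid_x = runif(n_rows, 0, 2048),
    centroid_y = runif(n_rows, 0, 2048)
  )
}

# independent quantile oracle: sort + interpolate at position (n-1)*p
interp_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h)
  hi <- min(lo + 1, n - 1)
  s[lo + 1] + (h - lo) * (s[hi + 1] - s[lo + 1])
}

# independent Tukey fence oracle built on interp_quantile
oracle_fences <- function(x, k = 1.5) {
  q1 <- interp_quantile(x, 0.25)
  q3 <- interp_quantile(x, 0.75)
  list(q1 = q1, q3 = q3, iqr = q3 - q1,
       lower = q1 - k * (q3 - q1), upper = q3 + k * (q3 - q1))
}

# brute-force model selection: enumerate groups, sort by ranking, pick max
oracle_select <- function(objects, ranking) {
  rk <- stats::setNames(ranking$rank, ranking$model_name)
  key <- paste(objects$Metadata_Plate, objects$Metadata_Well,
               objects$primary_object_id)
  out <- lapply(split(objects, key), function(g) {
    best_rank <- max(rk[g$model_name])
    best_model <- names(rk)[match(best_rank, rk)]
    hits <- g[g$model_name == best_model, , drop = FALSE]
    rep_row <- hits[which.max(hits$worm_length), , drop = FALSE]
    rep_row$model_select <- best_model
    rep_row$cluster_flag <- nrow(hits) > 1
    rep_row
  })
  dplyr::bind_rows(out)
}

# canonical ordering for table comparisons
sort_by_keys <- function(tab) {
  tab[order(tab$Metadata_Plate, tab$Metadata_Well, tab$primary_object_id), ,
      drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
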