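# Pruning flagged objects, summarizing lengths per experimental unit, and the
# four-element raw/processed bundle.

.summary_quantiles <- c(0.10, 0.25, 0.50, 0.75, 0.90)

#' Drop flagged objects
#'
#' Removes rows carrying any flag in `drop_flags`. By default all three flag
#' families (cluster, well edge, outlier) are dropped; objects the user chose
#' to keep unflagged upstream are naturally retained.
#'
#' @param objects Flagged table (output of [set_flags()]).
#' @param drop_flags Subset of `c("cluster", "well_edge", "outlier")`.
#' @return Pruned tibble.
#' @export
prune <- function(objects, drop_flags = c("cluster", "well_edge", "outlier")) {
  cols <- .flag_cols(drop_flags)
  miss <- setdiff(cols, names(objects))
  if (length(miss) > 0) {
    stop("flag column(s) not present: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(objects))
  for (col in cols) keep <- keep & !objects[[col]]
  objects[keep, , drop = FALSE]
}

#' Summarize animal length by experimental unit
#'
#' One row per group with the count, mean, sample variance (missing for
#' groups of one), minimum, maximum, and the 10/25/50/75/90% quantiles of
#' `worm_length` (linear interpolation between order statistics, the same
#' rule used for the outlier fences). Additional measurement columns can be
#' summarized identically via `extra_cols`.
#'
#' @param objects Object table.
#' @param group_by Character vector of grouping column names (default
#'   plate and well).
#' @param extra_cols Optional further numeric measurement columns to
#'   summarize with the same statistics (prefixed by the column name).
#' @return Summary tibble, one row per non-empty group.
#' @export
summarize_objects <- function(objects,
                              group_by = c("Metadata_Plate", "Metadata_Well"),
                              extra_cols = character(0)) {
  if (length(group_by) == 0) stop("`group_by` must name at least one column",
                                  call. = FALSE)
  miss <- setdiff(c(group_by, extra_cols), names(objects))
  if (length(miss) > 0) {
    stop("grouping/measurement column(s) not present: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  stat_block <- function(x, prefix = "") {
    qs <- stats::quantile(x, probs = .summary_quantiles, type = 7, names = FALSE)
    out <- tibble::tibble(
      mean = mean(x),
      var = if (length(x) > 1) stats::var(x) else NA_real_,
      min = min(x), max = max(x),
      q10 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4], q90 = qs[5]
    )
    names(out) <- paste0(prefix, names(out), "_length")
    out
  }
  objects |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::group_modify(function(g, key) {
      out <- dplyr::bind_cols(tibble::tibble(n = nrow(g)),
                              stat_block(g$worm_length))
      for (col in extra_cols) {
        blk <- stat_block(g[[col]], prefix = paste0(col, "_"))
        names(blk) <- sub("_length$", "", names(blk))
        out <- dplyr::bind_cols(out, blk)
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Assemble the four-element raw/processed bundle
#'
#' Returns the flagged table unchanged (`raw_data`), the pruned table
#' (`processed_data`), and per-group summaries of both (`summarized_raw`,
#' `summarized_processed`). Wells whose objects are all pruned are absent
#' from the processed summary; plate views render them as empty.
#'
#' @inheritParams prune
#' @inheritParams summarize_objects
#' @return An object of class `xpress_bundle`: a list with elements
#'   `raw_data`, `processed_data`, `summarized_raw`, `summarized_processed`.
#' @export
process_bundle <- function(objects,
                           group_by = c("Metadata_Plate", "Metadata_Well"),
                           drop_flags = c("cluster", "well_edge", "outlier"),
                           extra_cols = character(0)) {
  processed <- prune(objects, drop_flags = drop_flags)
  structure(
    list(
      raw_data = objects,
      processed_data = processed,
      summarized_raw = summarize_objects(objects, group_by, extra_cols),
      summarized_processed = summarize_objects(processed, group_by, extra_cols)
    ),
    class = "xpress_bundle"
  )
}

#' @export
print.xpress_bundle <- function(x, ...) {
  cat("<xpress_bundle>\n")
  cat("  raw_data:             ", nrow(x$raw_data), "objects\n")
  cat("  processed_data:       ", nrow(x$processed_data), "objects\n")
  cat("  summarized_raw:       ", nrow(x$summarized_raw), "groups\n")
  cat("  summarized_processed: ", nrow(x$summarized_processed), "groups\n")
  invisible(x)
}

#' Run the whole pipeline in one call
#'
#' Reads the object CSVs (and optional design file), resolves worm models,
#' flags edge objects and within-well outliers, and assembles the
#' four-element bundle — equivalent to chaining [read_object_data()],
#' [join_design()], [rank_models()], [select_models()], [edge_flag()],
#' [set_flags()] and [process_bundle()] with the same arguments.
#'
#' @param data_paths Character vector of per-object CSV paths.
#' @param design_path Optional design CSV path.
#' @inheritParams read_object_data
#' @inheritParams edge_flag
#' @inheritParams set_flags
#' @inheritParams process_bundle
#' @return An `xpress_bundle`.
#' @export
xpress <- function(data_paths, design_path = NULL,
                   col_map = default_col_map(),
                   radius = 825, center = NULL, image_dim = NULL,
                   k = 1.5, min_n = 3,
                   exclude_flags = c("cluster", "well_edge"),
                   drop_flags = c("cluster", "well_edge", "outlier"),
                   group_by = c("Metadata_Plate", "Metadata_Well"),
                   extra_cols = character(0)) {
  dat <- read_object_data(data_paths, col_map = col_map)
  if (!is.null(design_path)) dat <- join_design(dat, read_design(design_path))
  dat |>
    select_models() |>
    edge_flag(radius = radius, center = center, image_dim = image_dim) |>
    set_flags(k = k, min_n = min_n, exclude_flags = exclude_flags) |>
    process_bundle(group_by = group_by, drop_flags = drop_flags,
                   extra_cols = extra_cols)
}

#' Write a bundle to a directory of CSVs plus a run manifest
#'
#' Writes `raw.csv`, `processed.csv`, `summary_raw.csv`,
#' `summary_processed.csv` and `manifest.json` (config echo, input files, row
#' counts, optional seed).
#'
#' @param bundle An `xpress_bundle`.
#' @param dir Output directory (created if needed).
#' @param config Optional named list echoed into the manifest.
#' @param inputs Optional character vector of input paths for the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, config = list(), inputs = character(0),
                         seed = NULL) {
  stopifnot(inherits(bundle, "xpress_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$raw_data, file.path(dir, "raw.csv"), progress = FALSE)
  readr::write_csv(bundle$processed_data, file.path(dir, "processed.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$summarized_raw, file.path(dir, "summary_raw.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$summarized_processed,
                   file.path(dir, "summary_processed.csv"), progress = FALSE)
  manifest <- list(
    command = "process",
    config = config,
    inputs = as.character(inputs),
    outputs = file.path(dir, c("raw.csv", "processed.csv", "summary_raw.csv",
                               "summary_processed.csv")),
    row_counts = list(
      raw = nrow(bundle$raw_data),
      processed = nrow(bundle$processed_data),
      summarized_raw = nrow(bundle$summarized_raw),
      summarized_processed = nrow(bundle$summarized_processed)
    ),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}
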