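# Reading CellProfiler per-object exports and experiment design files.
#
# The canonical object table keeps the CellProfiler metadata columns verbatim
# (Metadata_Plate, Metadata_Well, ...) and adds canonical measurement columns:
# primary_object_id, model_name, worm_length, centroid_x, centroid_y.

#' Default mapping from canonical measurement columns to CellProfiler names
#'
#' The reader first looks for the canonical name itself (so its own output
#' round-trips), then for the mapped CellProfiler export name. WormToolbox
#' column vocabularies vary between pipelines, so the map is user-adjustable.
#'
#' @return Named character vector: canonical name -> CellProfiler column name.
#' @export
default_col_map <- function() {
  c(
    primary_object_id = "Parent_Object",
    model_name        = "Model",
    worm_length       = "Worm_Length",
    centroid_x        = "AreaShape_Center_X",
    centroid_y        = "AreaShape_Center_Y"
  )
}

.required_metadata <- c("Metadata_Plate", "Metadata_Well")
.canonical_cols <- c("primary_object_id", "model_name", "worm_length",
                     "centroid_x", "centroid_y")

#' Normalize a well identifier to letter + zero-padded column
#'
#' `"c3"` becomes `"C03"`. Idempotent; anything not of the form row letter
#' A-H followed by column 1-12 is an error.
#'
#' @param well Character vector of well tokens.
#' @return Character vector of normalized wells matching `^[A-H](0[1-9]|1[0-2])$`.
#' @examples
#' normalize_well(c("C3", "c03", "H12"))
#' @export
normalize_well <- function(well) {
  w <- toupper(trimws(as.character(well)))
  m <- stringr::str_match(w, "^([A-H])0?([1-9]|1[0-2])$")
  bad <- is.na(m[, 1]) & !is.na(w)
  if (any(bad)) {
    stop("invalid well identifier(s): ",
         paste(unique(w[bad]), collapse = ", "), call. = FALSE)
  }
  out <- sprintf("%s%02d", m[, 2], as.integer(m[, 3]))
  out[is.na(w)] <- NA_character_
  out
}

#' Parse image-file metadata from its name
#'
#' File names follow the `{date}-{experiment}-{plate}-{magnification}_{well}.{ext}`
#' convention used by the CellProfiler metadata module, e.g.
#' `20191119-growth-p05-m2X_C03.TIF`.
#'
#' @param filename Image file name (path components are ignored).
#' @return A tibble with columns `date`, `experiment`, `plate`,
#'   `magnification`, `well` (well normalized to zero-padded form).
#' @examples
#' parse_filename_metadata("20191119-growth-p05-m2X_C03.TIF")
#' @export
parse_filename_metadata <- function(filename) {
  stopifnot(is.character(filename), length(filename) >= 1)
  base <- basename(filename)
  m <- stringr::str_match(
    base, "^([^-_]+)-([^-_]+)-([^-_]+)-([^-_]+)_([A-Ha-h]0?[0-9]{1,2})\\.[A-Za-z]+$"
  )
  if (any(is.na(m[, 1]))) {
    stop("cannot parse image filename(s): ",
         paste(base[is.na(m[, 1])], collapse = ", "),
         "\nexpected {date}-{experiment}-{plate}-{magnification}_{well}.{ext}",
         call. = FALSE)
  }
  tibble::tibble(
    date = m[, 2], experiment = m[, 3], plate = m[, 4],
    magnification = m[, 5], well = normalize_well(m[, 6])
  )
}

#' Read CellProfiler per-object CSV exports into the canonical object table
#'
#' Concatenates one or more per-object CSV files, validates the required
#' metadata columns, normalizes well identifiers, and renames the mapped
#' measurement columns to their canonical names. All other columns are carried
#' through untouched, so any extra WormToolbox features stay available for
#' later summaries.
#'
#' @param paths Character vector of CSV file paths.
#' @param col_map Named character vector mapping canonical measurement columns
#'   to their export names; see [default_col_map()].
#' @return A tibble with one row per worm-model object.
#' @export
read_object_data <- function(paths, col_map = default_col_map()) {
  if (length(paths) == 0) stop("no input files given", call. = FALSE)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0) {
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  }
  tabs <- lapply(paths, function(p) {
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  })
  dat <- dplyr::bind_rows(tabs)
  as_object_table(dat, col_map = col_map)
}

#' Validate and canonicalize an in-memory object table
#'
#' @param dat A data frame with CellProfiler-style columns.
#' @inheritParams read_object_data
#' @return Canonical object tibble.
#' @export
as_object_table <- function(dat, col_map = default_col_map()) {
  dat <- tibble::as_tibble(dat)
  miss <- setdiff(.required_metadata, names(dat))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  # canonical name wins; otherwise take the mapped export name
  for (canon in .canonical_cols) {
    if (canon %in% names(dat)) next
    mapped <- unname(col_map[canon])
    if (!is.na(mapped) && mapped %in% names(dat)) {
      names(dat)[names(dat) == mapped] <- canon
    }
  }
  miss <- setdiff(.canonical_cols, names(dat))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         " (adjust `col_map` if your export uses different names)",
         call. = FALSE)
  }
  dat$Metadata_Well <- normalize_well(dat$Metadata_Well)
  dat$primary_object_id <- as.integer(dat$primary_object_id)
  if (any(!is.finite(dat$worm_length) | dat$worm_length <= 0)) {
    stop("worm_length must be finite and strictly positive", call. = FALSE)
  }
  if (any(dat$centroid_x < 0 | dat$centroid_y < 0, na.rm = TRUE)) {
    stop("centroid coordinates must be non-negative", call. = FALSE)
  }
  dat
}

#' Read an experiment design file
#'
#' A design file maps (plate, well) to experimental conditions such as strain,
#' drug and concentration. The (plate, well) pair must be unique.
#'
#' @param path CSV file path.
#' @return A tibble of design records with normalized wells.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  des <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(.required_metadata, names(des))
  if (length(miss) > 0) {
    stop("design file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  des$Metadata_Well <- normalize_well(des$Metadata_Well)
  des
}

#' Join a design table onto an object table
#'
#' Left join on (Metadata_Plate, Metadata_Well): every object row is retained,
#' rows without a design match get missing values in the design columns.
#'
#' @param objects Canonical object table.
#' @param design Design tibble (see [read_design()]).
#' @return Object table with design columns attached; row count unchanged.
#' @export
join_design <- function(objects, design) {
  keys <- .required_metadata
  for (nm in keys) {
    if (!nm %in% names(objects)) stop("objects lack column ", nm, call. = FALSE)
    if (!nm %in% names(design)) stop("design lacks column ", nm, call. = FALSE)
  }
  dup <- design[duplicated(design[keys]), keys, drop = FALSE]
  if (nrow(dup) > 0) {
    stop("duplicated (plate, well) in design file: ",
         paste(unique(paste(dup$Metadata_Plate, dup$Metadata_Well)),
               collapse = ", "), call. = FALSE)
  }
  dplyr::left_join(objects, design, by = keys)
}

#' Write the canonical object table to CSV
#'
#' @param objects Object tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_object_data <- function(objects, path) {
  readr::write_csv(objects, path, progress = FALSE)
  invisible(path)
}
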