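# Scoring pipeline output against simulation ground truth.

.prf <- function(pred, truth) {
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
}

#' Score a processed bundle against simulation ground truth
#'
#' Joins the bundle's raw (flag-annotated, one row per primary object) table
#' to the truth table by (plate, well, primary object) and reports:
#' precision/recall of each flag family against its constructed truth label;
#' per-well absolute and relative error of the processed and raw mean lengths
#' against the true animal mean; and model-selection accuracy on animals that
#' carry no flag.
#'
#' @param bundle An `xpress_bundle` (see [process_bundle()]).
#' @param truth Truth tibble from [generate_plate_set()].
#' @return A list with `flag_metrics` (one row per flag family),
#'   `well_errors` (per-well raw/processed mean errors), and
#'   `model_accuracy` (scalar).
#' @export
evaluate_against_truth <- function(bundle, truth) {
  stopifnot(inherits(bundle, "xpress_bundle"))
  keys <- c("Metadata_Plate", "Metadata_Well", "primary_object_id")
  raw <- bundle$raw_data
  miss <- setdiff(keys, names(truth))
  if (length(miss) > 0) stop("truth lacks key column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  joined <- dplyr::inner_join(raw, truth, by = keys,
                              suffix = c("", ".truth"))
  if (nrow(joined) != nrow(raw) || nrow(joined) != nrow(truth)) {
    stop("key mismatch: raw table and truth table are not in bijection (",
         nrow(raw), " raw rows, ", nrow(truth), " truth rows, ",
         nrow(joined), " matched)", call. = FALSE)
  }

  flag_metrics <- dplyr::bind_rows(
    cluster  = .prf(joined$cluster_flag, joined$is_cluster),
    well_edge = .prf(joined$well_edge_flag, joined$is_edge),
    outlier  = .prf(joined$flag_outlier, joined$is_outlier),
    .id = "flag"
  )

  wkeys <- keys[1:2]
  true_means <- truth |>
    dplyr::filter(.data$class == "animal") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(wkeys))) |>
    dplyr::summarise(true_mean = mean(.data$true_length), .groups = "drop")
  raw_means <- raw |>
    dplyr::group_by(dplyr::across(dplyr::all_of(wkeys))) |>
    dplyr::summarise(raw_mean = mean(.data$worm_length), .groups = "drop")
  proc_means <- bundle$processed_data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(wkeys))) |>
    dplyr::summarise(processed_mean = mean(.data$worm_length),
                     .groups = "drop")
  well_errors <- true_means |>
    dplyr::left_join(raw_means, by = wkeys) |>
    dplyr::left_join(proc_means, by = wkeys) |>
    dplyr::mutate(
      raw_abs_error = abs(.data$raw_mean - .data$true_mean),
      processed_abs_error = abs(.data$processed_mean - .data$true_mean),
      raw_rel_error = .data$raw_abs_error / .data$true_mean,
      processed_rel_error = .data$processed_abs_error / .data$true_mean
    )

  eligible <- joined |>
    dplyr::filter(.data$class == "animal", !.data$cluster_flag,
                  !.data$well_edge_flag, !.data$flag_outlier)
  model_accuracy <- mean(eligible$model_select == eligible$stage)

  list(flag_metrics = flag_metrics, well_errors = well_errors,
       model_accuracy = model_accuracy)
}
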