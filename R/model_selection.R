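# Resolving the one-to-many match between animals (primary objects) and
# worm-model objects. WormToolbox "soft matching" deliberately fits several
# size-class models so that animals of slightly different sizes are still
# detected; each animal therefore carries one row per model fit.

.group_keys <- c("Metadata_Plate", "Metadata_Well", "primary_object_id")

#' Rank worm models by dataset-wide frequency
#'
#' Small models are fitted repeatedly to parts of large animals, so the most
#' frequent model in a dataset is the smallest and the least frequent is the
#' largest. Rank 1 is the smallest (most frequent) model, rank K the largest
#' (least frequent). Exact frequency ties are broken by ascending mean
#' `worm_length` per model, length being the direct size measure.
#'
#' @param objects Canonical object table (see [read_object_data()]).
#' @return A tibble with columns `model_name`, `n`, `mean_length`, `rank`.
#' @export
rank_models <- function(objects) {
  if (nrow(objects) == 0) stop("cannot rank models of an empty table",
                               call. = FALSE)
  objects |>
    dplyr::group_by(.data$model_name) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_length = mean(.data$worm_length),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$mean_length) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Select the best-fitting model per primary object
#'
#' Within each (plate, well, primary object) group the largest-ranked model
#' present is selected as the best fit. If that model was fitted more than
#' once to the same primary object the object is flagged as a cluster
#' (typically overlapping animals), since its measurements are unreliable.
#' The representative row kept for the object is the selected model's
#' instance with maximal `worm_length` (for a cluster, the instance closest
#' to covering the whole animal).
#'
#' @param objects Canonical object table.
#' @param ranking Optional [rank_models()] output; computed from `objects`
#'   when omitted. Must cover every model present.
#' @return One row per primary object: all columns of the representative row
#'   plus `model_select` and `cluster_flag`.
#' @export
select_models <- function(objects, ranking = NULL) {
  if (is.null(ranking)) ranking <- rank_models(objects)
  unknown <- setdiff(unique(objects$model_name), ranking$model_name)
  if (length(unknown) > 0) {
    stop("model(s) absent from ranking: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rk <- setNames(ranking$rank, ranking$model_name)
  objects |>
    dplyr::mutate(.model_rank = unname(rk[.data$model_name])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(.group_keys))) |>
    dplyr::filter(.data$.model_rank == max(.data$.model_rank)) |>
    dplyr::mutate(cluster_flag = dplyr::n() > 1) |>
    dplyr::slice_max(.data$worm_length, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(model_select = .data$model_name) |>
    dplyr::select(-".model_rank")
}
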