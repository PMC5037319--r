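#' Normalize raw well intensities to percent-of-cells-dead
#'
#' Converts raw luminescence/fluorescence readouts to the percent-response
#' scale using plate controls:
#' `r = 100 - 100 * (I - neg) / (pos - neg)`,
#' where `pos` is the untreated (maximal-viability) control and `neg` the
#' cell-free (fully-killed) control. At `I = pos` the response is 0 (no
#' killing); at `I = neg` it is 100 (complete kill). Values outside
#' \[0, 100\] are preserved, not clipped: isotonic pooling averages noise
#' correctly on the raw scale, and AUC/summary steps clip later.
#'
#' @param intensity Numeric vector of raw well intensities.
#' @param pos_ctrl,neg_ctrl Scalar control intensities (same units).
#' @return Numeric vector of responses (percent dead).
#' @examples
#' normalize_response(550, pos_ctrl = 1000, neg_ctrl = 100)  # 50
#' @export
normalize_response <- function(intensity, pos_ctrl, neg_ctrl) {
  if (!is.finite(pos_ctrl) || !is.finite(neg_ctrl) || pos_ctrl < 0 || neg_ctrl < 0) {
    abort("controls must be finite and >= 0.")
  }
  if (pos_ctrl == neg_ctrl) {
    abort("degenerate controls: positive and negative control intensities are equal.")
  }
  bad <- which(!is.finite(intensity))
  if (length(bad)) {
    abort(paste0("non-finite intensity at well index ",
                 paste(bad, collapse = ", "), "."))
  }
  100 - 100 * (intensity - neg_ctrl) / (pos_ctrl - neg_ctrl)
}

#' Normalize a long-format plate table
#'
#' Data-frame front end to [normalize_response()]. Sample wells are
#' normalized against the mean positive/negative control intensity of their
#' plate (columns `plate_id`/`date` define the plate; absent columns mean a
#' single plate). Out-of-range responses are flagged, and optionally clipped.
#'
#' @param data Long table with columns `intensity`, `well_role`
#'   (`"sample"`, `"pos_ctrl"`, `"neg_ctrl"`) and any identifier columns
#'   (`model_id`, `passage_id`, `drug_id`, `dose_uM`, `replicate`,
#'   `plate_id`, `date`, `assay`).
#' @param clip Clip responses to \[0, 100\]? Default `FALSE`.
#' @param signal_increases_with_death Set `TRUE` for assays (e.g. SYTOX)
#'   where the readout rises as cells die; control orientation is then
#'   validated in the opposite direction.
#' @return Tibble of the sample rows with `response_pct` and `qc_flag`
#'   (`"ok"`, `"above_100"`, `"below_0"`) appended.
#' @export
normalize_plate <- function(data, clip = FALSE, signal_increases_with_death = FALSE) {
  data <- as_tibble(data)
  if (!all(c("intensity", "well_role") %in% names(data))) {
    abort("`data` needs `intensity` and `well_role` columns.")
  }
  batch_cols <- intersect(c("date", "plate_id"), names(data))
  grouped <- if (length(batch_cols)) group_by(data, across(all_of(batch_cols))) else group_by(data)
  out <- grouped %>%
    mutate(
      .pos = mean(.data$intensity[.data$well_role == "pos_ctrl"]),
      .neg = mean(.data$intensity[.data$well_role == "neg_ctrl"])
    ) %>%
    ungroup()
  if (any(!is.finite(out$.pos)) || any(!is.finite(out$.neg))) {
    abort("every plate must contain both pos_ctrl and neg_ctrl wells.")
  }
  if (any(out$.pos == out$.neg)) {
    abort("degenerate controls: a plate has equal mean pos_ctrl and neg_ctrl intensity.")
  }
  bad_orient <- if (signal_increases_with_death) out$.pos > out$.neg else out$.pos < out$.neg
  if (any(bad_orient)) {
    warn("some plates have inverted control orientation; check `signal_increases_with_death`.")
  }
  out <- out %>%
    filter(.data$well_role == "sample") %>%
    mutate(
      response_pct = 100 - 100 * (.data$intensity - .data$.neg) / (.data$.pos - .data$.neg),
      qc_flag = case_when(
        .data$response_pct > 100 ~ "above_100",
        .data$response_pct < 0 ~ "below_0",
        TRUE ~ "ok"
      )
    )
  if (clip) out <- mutate(out, response_pct = pmin(pmax(.data$response_pct, 0), 100))
  select(out, -".pos", -".neg")
}

#' Plate control-separation QC report
#'
#' Descriptive per-plate quality report: control means, SDs and a
#' signal-window statistic `(pos - neg) / pooled SD`. Plates whose window
#' falls below `min_window` are flagged, and plates with inverted controls
#' (`pos < neg`) are flagged as such. Purely descriptive; the data are never
#' modified.
#'
#' @param data Long plate table as in [normalize_plate()].
#' @param min_window Minimum acceptable signal window (default 2).
#' @return Tibble with one row per (date, plate): control summaries,
#'   `signal_window`, `flag` (`"ok"`, `"low_window"`, `"inverted"`).
#' @export
control_qc <- function(data, min_window = 2) {
  data <- as_tibble(data)
  if (!nrow(data)) {
    return(tibble(pos_mean = double(), pos_sd = double(), neg_mean = double(),
                  neg_sd = double(), n_pos = integer(), n_neg = integer(),
                  signal_window = double(), flag = character()))
  }
  batch_cols <- intersect(c("date", "plate_id"), names(data))
  grouped <- if (length(batch_cols)) group_by(data, across(all_of(batch_cols))) else group_by(data)
  grouped %>%
    summarise(
      pos_mean = mean(.data$intensity[.data$well_role == "pos_ctrl"]),
      pos_sd = sd(.data$intensity[.data$well_role == "pos_ctrl"]),
      neg_mean = mean(.data$intensity[.data$well_role == "neg_ctrl"]),
      neg_sd = sd(.data$intensity[.data$well_role == "neg_ctrl"]),
      n_pos = sum(.data$well_role == "pos_ctrl"),
      n_neg = sum(.data$well_role == "neg_ctrl"),
      .groups = "drop"
    ) %>%
    mutate(
      pooled_sd = sqrt((ifelse(is.na(.data$pos_sd), 0, .data$pos_sd)^2 +
                          ifelse(is.na(.data$neg_sd), 0, .data$neg_sd)^2) / 2),
      signal_window = ifelse(.data$pooled_sd == 0,
                             ifelse(.data$pos_mean == .data$neg_mean, 0, Inf),
                             (.data$pos_mean - .data$neg_mean) / .data$pooled_sd),
      flag = case_when(
        .data$pos_mean < .data$neg_mean ~ "inverted",
        .data$signal_window < min_window ~ "low_window",
        TRUE ~ "ok"
      )
    ) %>%
    select(-"pooled_sd")
}
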