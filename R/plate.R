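CHANNEL_ALIASES <- c(OD = "OD", OD600 = "OD", RFP = "RFP", YFP = "YFP",
                     CFP = "CFP")

#' Plate dataset
#'
#' The unit of I/O and of the characterization pipeline: long-format
#' kinetic measurements (`well`, `sample`, `channel`, `time`, `value`)
#' plus a per-sample metadata table (`sample`, `strain`, `media`,
#' `vector`, `replicate`, `is_media_blank`, `is_no_reporter_control`).
#' Each `(well, channel)` series must sit on a strictly increasing time
#' grid. Times are shifted so the first measurement defines `t = 0`.
#'
#' @param measurements Long-format measurement tibble.
#' @param metadata Per-sample metadata tibble.
#' @return An object of class `plate_dataset`.
#' @export
plate_dataset <- function(measurements, metadata) {
  req <- c("well", "sample", "channel", "time", "value")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) {
    abort(paste0("Measurements missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"sample" %in% names(metadata)) abort("Metadata must contain `sample`.")
  measurements <- dplyr::as_tibble(measurements)
  measurements$channel <- canonical_channel(measurements$channel)
  measurements <- dplyr::arrange(measurements, .data$well, .data$channel, .data$time)
  dup <- duplicated(measurements[, c("well", "channel", "time")])
  if (any(dup)) {
    abort(paste0("Duplicate (well, channel, time) rows, e.g. row ",
                 which(dup)[1], "."))
  }
  bad <- measurements |>
    dplyr::group_by(.data$well, .data$channel) |>
    dplyr::summarise(ok = all(diff(.data$time) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    abort(paste0("Non-monotone times in well ", bad$well[1], " channel ",
                 bad$channel[1], "."))
  }
  measurements$time <- measurements$time - min(measurements$time)
  structure(list(measurements = measurements,
                 metadata = dplyr::as_tibble(metadata)),
            class = "plate_dataset")
}

canonical_channel <- function(x) {
  up <- toupper(as.character(x))
  out <- unname(CHANNEL_ALIASES[up])
  out[is.na(out)] <- up[is.na(out)]
  out
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat("<plate_dataset>", dplyr::n_distinct(x$measurements$well), "wells,",
      dplyr::n_distinct(x$measurements$channel), "channels,",
      nrow(x$measurements), "measurements",
      if (isTRUE(attr(x, "corrected"))) "(background-corrected)" else "", "\n")
  invisible(x)
}

#' Read a plate dataset from long-format CSV
#'
#' Expects the long schema `well, sample, channel, time, value` and a
#' metadata side table. Ingestion validates the schema, canonicalizes
#' channel names (e.g. `OD600 -> OD`), is insensitive to row order, and
#' shifts times so the first measurement is `t = 0`.
#'
#' @param path CSV of measurements.
#' @param metadata_path CSV of per-sample metadata; defaults to
#'   `<path-sans-ext>_metadata.csv`.
#' @return A [plate_dataset()].
#' @export
read_plate_csv <- function(path,
                           metadata_path = sub("\\.csv$", "_metadata.csv", path)) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (!file.exists(metadata_path)) {
    abort(paste0("No metadata file: ", metadata_path))
  }
  meas <- readr::read_csv(path, show_col_types = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE)
  plate_dataset(meas, meta)
}

#' Write a plate dataset to long-format CSV
#'
#' @param ds A [plate_dataset()].
#' @param path Output CSV for measurements.
#' @param metadata_path Output CSV for metadata.
#' @return `ds`, invisibly.
#' @export
write_plate_csv <- function(ds, path,
                            metadata_path = sub("\\.csv$", "_metadata.csv", path)) {
  stopifnot(inherits(ds, "plate_dataset"))
  readr::write_csv(ds$measurements, path)
  readr::write_csv(ds$metadata, metadata_path)
  invisible(ds)
}

control_samples <- function(ds, flag) {
  ds$metadata$sample[which(ds$metadata[[flag]])]
}

#' Subtract background estimated from control wells
#'
#' OD channels have the time-wise mean of the media-blank wells
#' subtracted; fluorescence channels the time-wise mean of the
#' no-reporter control wells (per channel). Negative corrected values
#' are retained, not clipped: downstream estimators must face them.
#' A `corrected` flag prevents double application.
#'
#' @param ds A [plate_dataset()] containing at least one media blank
#'   and one no-reporter control.
#' @return The corrected [plate_dataset()].
#' @export
subtract_background <- function(ds) {
  stopifnot(inherits(ds, "plate_dataset"))
  if (isTRUE(attr(ds, "corrected"))) {
    abort("Dataset already background-corrected.")
  }
  need <- c("is_media_blank", "is_no_reporter_control")
  miss <- setdiff(need, names(ds$metadata))
  if (length(miss)) abort(paste0("Metadata missing flag(s): ",
                                 paste(miss, collapse = ", ")))
  blanks <- control_samples(ds, "is_media_blank")
  norep <- control_samples(ds, "is_no_reporter_control")
  if (!length(blanks) || !length(norep)) {
    abort("Background correction needs >= 1 media blank and >= 1 no-reporter control well on the plate.")
  }
  meas <- ds$measurements
  od_bg <- meas |>
    dplyr::filter(.data$sample %in% blanks, .data$channel == "OD") |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(bg = mean(.data$value), .groups = "drop")
  fl_bg <- meas |>
    dplyr::filter(.data$sample %in% norep, .data$channel != "OD") |>
    dplyr::group_by(.data$channel, .data$time) |>
    dplyr::summarise(bg = mean(.data$value), .groups = "drop")
  od <- meas |>
    dplyr::filter(.data$channel == "OD") |>
    dplyr::left_join(od_bg, by = "time") |>
    dplyr::mutate(value = .data$value - .data$bg) |>
    dplyr::select(-"bg")
  fl <- meas |>
    dplyr::filter(.data$channel != "OD") |>
    dplyr::left_join(fl_bg, by = c("channel", "time")) |>
    dplyr::mutate(value = .data$value - dplyr::coalesce(.data$bg, 0)) |>
    dplyr::select(-"bg")
  out <- plate_dataset(dplyr::bind_rows(od, fl), ds$metadata)
  attr(out, "truth") <- attr(ds, "truth")
  attr(out, "corrected") <- TRUE
  out
}

# Extract one (well, channel) series as a tibble(time, value).
well_series <- function(ds, well, channel) {
  x <- ds$measurements |>
    dplyr::filter(.data$well == !!well, .data$channel == !!channel) |>
    dplyr::select("time", "value")
  if (!nrow(x)) abort(paste0("No data for well ", well, " channel ", channel, "."))
  x
}
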