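# External formats: track tables as CSV, cell image stacks as multi-page
# TIFF with a JSON sidecar carrying pixel size and metadata.

#' Write / read single-molecule track tables as CSV
#'
#' Columns follow the convention `track_id, frame, t_s, x_nm, y_nm[, z_nm],
#' sx_nm, sy_nm[, sz_nm][, true_state]`; extra columns are preserved.
#'
#' @param tracks data.frame (e.g. from [simulate_tracks()] or
#'   [link_localizations()]).
#' @param path CSV path.
#' @return `write_tracks_csv`: `path` invisibly; `read_tracks_csv`: the
#'   data.frame.
#' @export
write_tracks_csv <- function(tracks, path) {
  write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path)
  need <- c("track_id", "frame", "x_nm", "y_nm")
  if (!all(need %in% names(df))) {
    stop("track CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write a cell record as multi-page TIFF + JSON sidecar
#'
#' Pages are stored in the order transmitted, channel_a, channel_b as 32-bit
#' float TIFF scaled to \[0, 1\]; the per-page photon scale, pixel size and
#' stalk side live in `<path>.json`.
#'
#' @param record A [cell_record()].
#' @param path Path of the TIFF to write (sidecar is `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_cell_tiff <- function(record, path) {
  stopifnot(inherits(record, "cell_record"))
  pages <- list(record$transmitted, record$channel_a)
  if (!is.null(record$channel_b)) pages <- c(pages, list(record$channel_b))
  scales <- vapply(pages, function(p) max(p, 1), numeric(1))
  norm <- mapply(function(p, s) p / s, pages, scales, SIMPLIFY = FALSE)
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  meta <- list(
    pixel_size_nm = record$pixel_size_nm,
    stalk_side = record$stalk_side,
    page_order = c("transmitted", "channel_a",
                   if (!is.null(record$channel_b)) "channel_b"),
    photon_scale = scales
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cell record from multi-page TIFF + JSON sidecar
#'
#' @param path TIFF path written by [write_cell_tiff()] (or any TIFF whose
#'   sidecar `<path>.json` provides `pixel_size_nm` and optionally
#'   `stalk_side` and `photon_scale`).
#' @return A [cell_record()].
#' @export
read_cell_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  scales <- unlist(meta$photon_scale)
  if (is.null(scales)) scales <- rep(1, length(pages))
  pages <- mapply(function(p, s) p * s, pages, scales, SIMPLIFY = FALSE)
  px <- if (!is.null(meta$pixel_size_nm)) as.numeric(meta$pixel_size_nm) else 20
  side <- if (!is.null(meta$stalk_side)) meta$stalk_side else "unknown"
  cell_record(
    transmitted = pages[[1]],
    channel_a = pages[[2]],
    channel_b = if (length(pages) >= 3) pages[[3]],
    pixel_size_nm = px,
    stalk_side = side
  )
}

#' Write a per-cell binary profile as CSV
#'
#' @param profiles Named list of [project_profile()] results (names become
#'   column suffixes, e.g. `upper_a`).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profiles, path) {
  if (inherits(profiles, "binary_profile")) profiles <- list(a = profiles)
  nb <- profiles[[1]]$n_bins
  out <- data.frame(bin = seq_len(nb))
  for (nm in names(profiles)) {
    out[[paste0("upper_", nm)]] <- profiles[[nm]]$upper
    out[[paste0("lower_", nm)]] <- profiles[[nm]]$lower
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a population profile as CSV
#'
#' @param pop A [population_fraction()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path) {
  write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(path)
}
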