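# Shared readers/writers: grayscale float TIFF for ring images, flat CSV for
# tracks/landmarks/traces, JSON sidecars for ground truth and reports. All
# pipeline CSV artifacts start with a provenance comment line
# ("# config_hash=... seed=...") which the readers skip.

#' Write / read a ring image as 32-bit float grayscale TIFF
#'
#' @param image A `ring_image` (see [sim_ring_image()]).
#' @param path Output `.tif` path.
#' @param truth_sidecar If `TRUE` (default) and the image carries ground
#'   truth, write it to a `.json` sidecar next to the TIFF.
#' @return `path`, invisibly.
#' @export
write_ring_tiff <- function(image, path, truth_sidecar = TRUE) {
  stopifnot(is.list(image), !is.null(image$pixels))
  # TIFF float samples are stored on [0, 1]; rescale and record the affine
  # map in the sidecar so reading restores the original intensities
  lo <- min(image$pixels)
  hi <- max(image$pixels)
  span <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((image$pixels - lo) / span, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(pixel_size = image$pixel_size,
               intensity_offset = lo, intensity_scale = span)
  if (truth_sidecar && !is.null(image$truth)) {
    meta$truth <- unclass(image$truth)
  }
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ring_tiff
#' @param pixel_size Pixel size (nm/pixel); if `NULL`, read from the JSON
#'   sidecar.
#' @return For `read_ring_tiff()`: a `ring_image`.
#' @export
read_ring_tiff <- function(path, pixel_size = NULL) {
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3) px <- px[, , 1]
  sidecar <- sub("\\.tiff?$", ".json", path)
  truth <- NULL
  if (is.null(pixel_size) || file.exists(sidecar)) {
    if (!file.exists(sidecar)) {
      abort("supply `pixel_size` (no JSON sidecar found).")
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pixel_size <- pixel_size %||% meta$pixel_size
    truth <- meta$truth
    if (!is.null(meta$intensity_scale)) {
      px <- px * meta$intensity_scale + meta$intensity_offset
    }
  }
  structure(list(pixels = px, pixel_size = pixel_size, truth = truth),
            class = "ring_image")
}

write_artifact_csv <- function(df, path, hash = NULL, seed = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(hash)) {
    writeLines(sprintf("# config_hash=%s seed=%s", hash, format(seed)), con)
  }
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(path)
}

read_artifact_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' Write / read track and landmark tables
#'
#' CSV schemas: tracks `(embryo_id, centriole_id, time_s, intensity)`,
#' landmarks `(embryo_id, cs_s, neb_s)`.
#'
#' @param tracks,landmarks Tibbles with the schema columns.
#' @param path File path.
#' @return The tibble (readers) or `path` invisibly (writers).
#' @export
write_tracks_csv <- function(tracks, path) {
  check_columns(tracks, c("embryo_id", "centriole_id", "time_s", "intensity"),
                "tracks")
  write_artifact_csv(tracks, path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  check_columns(read_artifact_csv(path),
                c("embryo_id", "centriole_id", "time_s", "intensity"),
                "tracks file")
}

#' @rdname write_tracks_csv
#' @export
write_landmarks_csv <- function(landmarks, path) {
  check_columns(landmarks, c("embryo_id", "cs_s", "neb_s"), "landmarks")
  write_artifact_csv(landmarks, path)
}

#' @rdname write_tracks_csv
#' @export
read_landmarks_csv <- function(path) {
  check_columns(read_artifact_csv(path), c("embryo_id", "cs_s", "neb_s"),
                "landmarks file")
}

#' Write / read photon traces as CSV
#'
#' Long format: one row per bin, columns `trace_id`, `bin_index`, `counts`.
#'
#' @param traces A `pecos_traces` object.
#' @param path File path.
#' @return For the reader: a `pecos_traces` object (`bin_width`/`duration`
#'   must be supplied if no sidecar metadata is present).
#' @param bin_width,duration Trace metadata for the reader.
#' @export
write_traces_csv <- function(traces, path) {
  lst <- as_trace_list(traces)
  df <- tibble::tibble(
    trace_id = rep(seq_along(lst), lengths(lst)),
    bin_index = unlist(lapply(lst, seq_along), use.names = FALSE),
    counts = unlist(lst, use.names = FALSE))
  write_artifact_csv(df, path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path, bin_width = 1, duration = NULL) {
  df <- check_columns(read_artifact_csv(path),
                      c("trace_id", "bin_index", "counts"), "traces file")
  lst <- lapply(split(df, df$trace_id), function(d) {
    d$counts[order(d$bin_index)]
  })
  names(lst) <- NULL
  structure(
    list(counts = lst, bin_width = bin_width,
         duration = duration %||% (length(lst[[1]]) * bin_width),
         truth = NULL),
    class = "pecos_traces"
  )
}
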