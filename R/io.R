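#' Channel time-series CSV round trip
#'
#' Long-format CSV (`channel, wavelength_nm, time_s, value`) with
#' `#`-comment header lines recording the series type, sample rate and
#' reference intensity, so a written file reads back into an identical
#' object.
#'
#' @param x An `intensity_series` or `attenuation_series`.
#' @param path Output path.
#' @return `path` invisibly (`write_series_csv`); the series
#'   (`read_series_csv`).
#' @export
write_series_csv <- function(x, path) {
  type <- class(x)[1]
  con <- file(path, "w")
  writeLines(c(paste0("# type: ", type),
               paste0("# sample_rate_hz: ", x$sample_rate),
               paste0("# reference_intensity: ",
                      if (is.null(x$reference_intensity) ||
                          is.na(x$reference_intensity)) "NA"
                      else format(x$reference_intensity, digits = 17))), con)
  utils::write.csv(as_tibble_series(x), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  type <- sub("^# type: ", "", hdr[1])
  fs <- as.numeric(sub("^# sample_rate_hz: ", "", hdr[2]))
  ref <- suppressWarnings(as.numeric(sub("^# reference_intensity: ",
                                         "", hdr[3])))
  tab <- utils::read.csv(path, comment.char = "#")
  channels <- unique(tab$channel)
  wl <- sort(unique(tab$wavelength_nm))
  times <- sort(unique(tab$time_s))
  a <- array(NA_real_, c(length(channels), length(wl), length(times)))
  ci <- match(tab$channel, channels)
  wi <- match(tab$wavelength_nm, wl)
  ti <- match(tab$time_s, times)
  a[cbind(ci, wi, ti)] <- tab$value
  if (anyNA(a)) stop("incomplete channel x wavelength x time grid in ", path)
  if (type == "intensity_series")
    intensity_series(a, wl, fs, channels)
  else
    attenuation_series(a, wl, fs, channels, reference_intensity = ref)
}

#' Optode array CSV round trip
#'
#' Writes two CSV files: `<stem>_optodes.csv` (`id, type, x, y, z` in mm)
#' and `<stem>_channels.csv` (`source_id, detector_id`).
#'
#' @param array An `optode_array`.
#' @param stem Path stem (no extension).
#' @return The stem invisibly (`write_array_csv`); the array
#'   (`read_array_csv`).
#' @export
write_array_csv <- function(array, stem) {
  opt <- rbind(
    data.frame(id = paste0("S", seq_len(nrow(array$sources))),
               type = "source", array$sources),
    data.frame(id = paste0("D", seq_len(nrow(array$detectors))),
               type = "detector", array$detectors)
  )
  names(opt)[3:5] <- c("x", "y", "z")
  utils::write.csv(opt, paste0(stem, "_optodes.csv"), row.names = FALSE)
  ch <- data.frame(source_id = paste0("S", array$channels$source),
                   detector_id = paste0("D", array$channels$detector))
  utils::write.csv(ch, paste0(stem, "_channels.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_array_csv
#' @export
read_array_csv <- function(stem) {
  opt <- utils::read.csv(paste0(stem, "_optodes.csv"))
  ch <- utils::read.csv(paste0(stem, "_channels.csv"))
  src <- as.matrix(opt[opt$type == "source", c("x", "y", "z")])
  det <- as.matrix(opt[opt$type == "detector", c("x", "y", "z")])
  sid <- opt$id[opt$type == "source"]; did <- opt$id[opt$type == "detector"]
  optode_array(src, det,
               data.frame(source = match(ch$source_id, sid),
                          detector = match(ch$detector_id, did)))
}

#' Write a concentration image as NIfTI volumes
#'
#' One NIfTI file per chromophore (`<prefix>_<chromophore>.nii.gz`) with the
#' grid spacing in the header, plus a JSON sidecar (`<prefix>.json`)
#' recording units, time label, chromophores and any reconstruction
#' diagnostics attached to the image.
#'
#' @param image A `concentration_image`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_image_nifti <- function(image, dir, prefix = "conc") {
  stopifnot(inherits(image, "concentration_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- image$grid$spacing
  files <- character(0)
  for (ch in image$chromophores) {
    vol <- image_volume(image, ch)
    f <- file.path(dir, paste0(prefix, "_", ch, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(h, h, h)), f)
    files <- c(files, f)
  }
  sidecar <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(
    units = "uM", chromophores = image$chromophores,
    time_s = image$time_s, grid_dims = image$grid$dims,
    spacing_mm = image$grid$spacing,
    lambda_reg = attr(image, "lambda_reg"),
    iterations = attr(image, "iterations"),
    rnorm_data = attr(image, "rnorm_data"),
    penalty_norm = attr(image, "penalty_norm")
  ), sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, sidecar))
}

#' Write a labelled geometry as a NIfTI tissue-label volume
#'
#' @param geometry A `slab_geometry`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path` invisibly; tissue names map to integer labels in file
#'   order of `geometry$tissues`.
#' @export
write_labels_nifti <- function(geometry, path) {
  stopifnot(!is.null(geometry$labels))
  lab <- array(match(geometry$labels, geometry$tissues), geometry$dims)
  h <- geometry$spacing
  RNifti::writeNifti(RNifti::asNifti(lab, pixdim = c(h, h, h)), path)
  invisible(path)
}
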