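## File formats.
## Raw scans: flat binary float32 (little-endian, [fast, slow, sample] in
## column-major order) + JSON sidecar holding the typed acquisition
## attributes. Volumes: multi-page float TIFF (one page per depth slice,
## values scaled to [0,1]) + JSON sidecar with voxel size, band and scale.
## Cohort tables: plain CSV, UTF-8, "." decimal, mandatory header.
## All on-disk indices are 0-based; R objects are 1-based.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

read_sidecar <- function(path, required, what) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop(sprintf("%s: missing sidecar '%s'", what, sp))
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop(sprintf("%s format error: missing attribute(s): %s",
                 what, paste(miss, collapse = ", ")))
  meta
}

#' Write / read a raw scan
#'
#' The signal block is stored as little-endian float32 in `[fast, slow,
#' sample]` column-major order; all acquisition attributes
#' (`sample_rate_hz`, `step_fast_um`, `step_slow_um`, `speed_of_sound_m_s`,
#' `wavelengths_nm`, `rep_rate_hz`, `acquisition_order`, `wavelength_index`,
#' `shape`) travel in a JSON sidecar next to the binary file. Indices in the
#' file are 0-based.
#'
#' @param scan a [raw_scan()].
#' @param path destination of the binary signal block; the sidecar is written
#'   to the same path with extension `.json`.
#' @return `write_raw_scan` returns `path` invisibly; `read_raw_scan`
#'   returns a [raw_scan()].
#' @export
write_raw_scan <- function(scan, path) {
  stopifnot(inherits(scan, "raw_scan"))
  cfg <- scan$config
  meta <- list(
    shape = c(cfg$n_fast, cfg$n_slow, cfg$n_samples),
    sample_rate_hz = cfg$sample_rate,
    step_fast_um = cfg$step_fast, step_slow_um = cfg$step_slow,
    speed_of_sound_m_s = cfg$speed_of_sound,
    wavelengths_nm = cfg$wavelengths, rep_rate_hz = cfg$rep_rate,
    acquisition_order = scan$acquisition_order - 1L,
    wavelength_index = scan$wavelength_index - 1L)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.numeric(scan$signals), con, size = 4L, endian = "little")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_raw_scan
#' @export
read_raw_scan <- function(path) {
  if (!file.exists(path)) stop(sprintf("raw scan file '%s' not found", path))
  req <- c("shape", "sample_rate_hz", "step_fast_um", "step_slow_um",
           "speed_of_sound_m_s", "wavelengths_nm", "rep_rate_hz",
           "acquisition_order")
  meta <- read_sidecar(path, req, "raw scan")
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  con <- file(path, "rb"); on.exit(close(con))
  x <- readBin(con, numeric(), n = n + 1L, size = 4L, endian = "little")
  if (length(x) != n)
    stop(sprintf(
      "raw scan validation error: %d float32 values on disk, shape [%s] needs %d",
      length(x), paste(shape, collapse = ", "), n))
  cfg <- scan_config(n_fast = shape[1], n_slow = shape[2],
                     n_samples = shape[3],
                     step_fast = meta$step_fast_um,
                     step_slow = meta$step_slow_um,
                     sample_rate = meta$sample_rate_hz,
                     speed_of_sound = meta$speed_of_sound_m_s,
                     wavelengths = meta$wavelengths_nm,
                     rep_rate = meta$rep_rate_hz)
  wl <- if (is.null(meta$wavelength_index)) 1L
        else as.integer(meta$wavelength_index) + 1L
  raw_scan(cfg, array(x, dim = shape),
           acquisition_order = matrix(as.integer(meta$acquisition_order),
                                      ncol = 2L) + 1L,
           wavelength_index = wl)
}

#' Write / read a reconstructed volume
#'
#' Volumes are stored as multi-page grayscale float TIFF (one page per depth
#' slice, values divided by the recorded `scale`) plus a JSON sidecar with
#' `voxel_size_um`, `band_mhz`, `origin_um`, `scale` and provenance.
#'
#' @param volume a [recon_volume()].
#' @param path destination TIFF path; sidecar written with extension `.json`.
#' @return `write_volume` returns `path` invisibly; `read_volume` a
#'   [recon_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "recon_volume"))
  v <- volume$intensity
  if (!all(is.finite(v))) stop("volume must be finite")
  scale <- max(v, 0)
  if (scale == 0) scale <- 1
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(voxel_size_um = volume$voxel_size, band_mhz = volume$band,
               origin_um = volume$origin, scale = scale,
               shape = dim(v),
               provenance = list(writer = "rsomvasc",
                                 version = as.character(utils::packageVersion("rsomvasc"))))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("volume file '%s' not found", path))
  meta <- read_sidecar(path, c("voxel_size_um", "band_mhz", "origin_um",
                               "scale", "shape"), "volume")
  pages <- tiff::readTIFF(path, all = TRUE)
  shape <- as.integer(meta$shape)
  v <- array(0, dim = shape)
  for (k in seq_len(shape[3])) v[, , k] <- pages[[k]] * meta$scale
  recon_volume(v, voxel_size = as.numeric(meta$voxel_size_um),
               band = as.numeric(meta$band_mhz),
               origin = as.numeric(meta$origin_um))
}

cohort_columns <- c("lesion_id", "group", "region", "tbv", "vessel_density",
                    "avg_vessel_length_um", "tortuosity", "fractal_number",
                    "lacunarity")
cohort_groups <- c("nevus", "melanoma")
cohort_regions <- c("edge", "center")

#' Validate a cohort biomarker table
#'
#' A cohort table holds one row per scanned lesion region: an identifier,
#' the diagnostic group (`nevus` or `melanoma`), the region (`edge` or
#' `center`) and the six vascular biomarkers. TBV is stored as a fraction in
#' `[0, 1]`.
#'
#' @param df a data.frame with columns `lesion_id, group, region, tbv,
#'   vessel_density, avg_vessel_length_um, tortuosity, fractal_number,
#'   lacunarity`.
#' @return the validated data.frame (class `cohort_table`, group/region as
#'   factors with the full level sets).
#' @export
cohort_table <- function(df) {
  miss <- setdiff(cohort_columns, names(df))
  if (length(miss))
    stop(sprintf("cohort table format error: missing column(s): %s",
                 paste(miss, collapse = ", ")))
  df <- df[cohort_columns]
  bad <- which(!(df$group %in% cohort_groups))
  if (length(bad))
    stop(sprintf("cohort table validation error: row %d has unknown group '%s'",
                 bad[1], df$group[bad[1]]))
  bad <- which(!(df$region %in% cohort_regions))
  if (length(bad))
    stop(sprintf("cohort table validation error: row %d has unknown region '%s'",
                 bad[1], df$region[bad[1]]))
  num <- cohort_columns[-(1:3)]
  for (cl in num) {
    df[[cl]] <- as.numeric(df[[cl]])
    if (nrow(df) && any(!is.finite(df[[cl]])))
      stop(sprintf("cohort table validation error: non-finite '%s' in row %d",
                   cl, which(!is.finite(df[[cl]]))[1]))
  }
  if (nrow(df) && any(df$tbv < 0 | df$tbv > 1))
    stop("cohort table validation error: tbv must lie in [0, 1]")
  df$group <- factor(df$group, levels = cohort_groups)
  df$region <- factor(df$region, levels = cohort_regions)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read / write a cohort biomarker table (CSV)
#'
#' @param path CSV path; header row mandatory, "." decimal, UTF-8.
#' @param table a [cohort_table()] (or coercible data.frame).
#' @return `read_cohort_table` returns a [cohort_table()];
#'   `write_cohort_table` returns `path` invisibly.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort table '%s' not found", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  cohort_table(df)
}

#' @rdname read_cohort_table
#' @export
write_cohort_table <- function(table, path) {
  table <- cohort_table(as.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}
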