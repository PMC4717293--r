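#' Acquisition metadata
#'
#' Bundles the pulse-sequence parameters the analysis needs: echo time,
#' repetition time, sequence family, and (for dynamic series) the number of
#' pre-bolus baseline frames.
#'
#' @param te_s Echo time in seconds (must be > 0). Defaults used in this
#'   study type: 0.0055 (gradient echo), 0.030 (spin echo), 0.010 (dynamic EPI).
#' @param tr_s Repetition time in seconds (must be > 0). For a dynamic series
#'   this is the frame spacing (temporal resolution).
#' @param sequence One of `"gradient_echo"`, `"spin_echo"`, `"dynamic_epi"`.
#' @param baseline_frames Number of pre-contrast frames recorded before bolus
#'   injection. Required (>= 1) for `"dynamic_epi"`, ignored otherwise.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(te_s, tr_s,
                             sequence = c("gradient_echo", "spin_echo", "dynamic_epi"),
                             baseline_frames = NULL) {
  sequence <- match.arg(sequence)
  if (!is.numeric(te_s) || length(te_s) != 1L || !is.finite(te_s) || te_s <= 0)
    stop("te_s must be a single positive number (seconds)")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("tr_s must be a single positive number (seconds)")
  if (sequence == "dynamic_epi") {
    if (is.null(baseline_frames) || !is.numeric(baseline_frames) ||
        baseline_frames < 1 || baseline_frames != round(baseline_frames))
      stop("baseline_frames must be an integer >= 1 for a dynamic series")
    baseline_frames <- as.integer(baseline_frames)
  }
  structure(list(te_s = te_s, tr_s = tr_s, sequence = sequence,
                 baseline_frames = baseline_frames),
            class = "acquisition_meta")
}

#' 3D image volume
#'
#' A scalar 3D grid with voxel spacing and acquisition metadata. Values may
#' contain `NA`/`NaN` (masked voxels in derived maps) but never `Inf`.
#'
#' @param values 3D numeric array.
#' @param spacing_mm Voxel size per axis in millimetres, length 3, all > 0.
#' @param meta An [acquisition_meta()] object, or `NULL` for derived maps.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, spacing_mm, meta = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array; got ",
         if (is.array(values)) paste0(length(dim(values)), "D") else "non-array",
         " input (dimensionality error)")
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive numbers")
  if (any(is.infinite(values))) stop("values must not contain Inf")
  if (!is.null(meta) && !inherits(meta, "acquisition_meta"))
    stop("meta must be an acquisition_meta object")
  structure(list(values = values, spacing_mm = spacing_mm, meta = meta),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' 4D dynamic series
#'
#' A time-resolved image (x, y, z, t) with a uniform time axis constructed
#' from the repetition time: frame k (0-based) is acquired at `k * tr_s`.
#'
#' @param values 4D numeric array (x, y, z, t).
#' @param meta An [acquisition_meta()] with `sequence = "dynamic_epi"`.
#' @param spacing_mm Voxel size per spatial axis in mm.
#' @return An object of class `dynamic_series` with elements `values`,
#'   `time_s`, `spacing_mm`, `meta`.
#' @export
dynamic_series <- function(values, meta, spacing_mm = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("values must be a 4D array (x, y, z, t); got ",
         if (is.array(values)) paste0(length(dim(values)), "D") else "non-array",
         " input (dimensionality error)")
  if (!inherits(meta, "acquisition_meta") || meta$sequence != "dynamic_epi")
    stop("meta must be an acquisition_meta with sequence = 'dynamic_epi'")
  n_t <- dim(values)[4L]
  if (n_t < meta$baseline_frames + 2L)
    stop("frame count (", n_t, ") must be >= baseline_frames + 2")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive numbers")
  structure(list(values = values,
                 time_s = (seq_len(n_t) - 1) * meta$tr_s,
                 spacing_mm = spacing_mm, meta = meta),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$values)
  cat("<dynamic_series> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " frames @ ", x$meta$tr_s, " s (", signif(max(x$time_s), 5),
      " s total)\n", sep = "")
  invisible(x)
}

#' Region-of-interest label set
#'
#' An integer label volume plus a label -> name mapping. Label 0 is
#' background; every named label must occur in the volume.
#'
#' @param labels 3D integer array of region labels.
#' @param names Named integer vector mapping region name -> label, e.g.
#'   `c(cortex = 2L, striatum = 3L)`.
#' @param spacing_mm Voxel size in mm.
#' @return An object of class `region_set`.
#' @export
region_set <- function(labels, names, spacing_mm = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (any(labels != round(labels), na.rm = TRUE))
    stop("labels must be integer-valued")
  if (is.null(base::names(names)) || any(base::names(names) == ""))
    stop("names must be a fully named label vector")
  present <- unique(as.integer(labels))
  missing <- setdiff(as.integer(names), present)
  if (length(missing) > 0)
    stop("named labels absent from the label volume: ",
         paste(missing, collapse = ", "))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  structure(list(labels = labels, names = names, spacing_mm = spacing_mm),
            class = "region_set")
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path Path to a NIfTI-1 file holding a 3D volume.
#' @param meta Optional [acquisition_meta()] to attach.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop("expected a 3D volume, file holds a ", length(dim(a)),
         "D payload (dimensionality error)")
  volume_image(array(as.numeric(a), dim(a)),
               spacing_mm = RNifti::pixdim(img)[1:3], meta = meta)
}

#' Read a 4D dynamic series from a NIfTI file
#'
#' The time axis is rebuilt from `meta$tr_s` as `k * tr_s`, k = 0..T-1.
#'
#' @param path Path to a NIfTI-1 file holding a 4D series.
#' @param meta An [acquisition_meta()] with `sequence = "dynamic_epi"`.
#' @return A [dynamic_series()].
#' @export
read_series <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4L)
    stop("expected a 4D series, file holds a ", length(dim(a)),
         "D payload (dimensionality error)")
  dynamic_series(array(as.numeric(a), dim(a)), meta = meta,
                 spacing_mm = RNifti::pixdim(img)[1:3])
}

#' Write a map or volume to a NIfTI file
#'
#' Values are stored at double precision so that a write/read round trip is
#' exact. Maps containing `NA`/`NaN` are rejected: mask or zero-fill first.
#'
#' @param vol A [volume_image()] (or bare 3D array).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_map <- function(vol, path) {
  if (is.array(vol) && length(dim(vol)) == 3L)
    vol <- volume_image(vol, c(1, 1, 1))
  if (!inherits(vol, "volume_image")) stop("vol must be a volume_image")
  if (any(!is.finite(vol$values)))
    stop("map contains non-finite values; mask or zero-fill before writing")
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a 4D dynamic series to a NIfTI file
#'
#' @param series A [dynamic_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_series <- function(series, path) {
  if (!inherits(series, "dynamic_series")) stop("series must be a dynamic_series")
  if (any(!is.finite(series$values))) stop("series contains non-finite values")
  img <- RNifti::asNifti(series$values)
  RNifti::pixdim(img) <- c(series$spacing_mm, series$meta$tr_s)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read acquisition metadata from a YAML or JSON config
#'
#' Expects keys `te_s`, `tr_s` and, for dynamic series, `baseline_frames`;
#' an optional `sequence` key selects the sequence family.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [acquisition_meta()].
#' @export
read_acquisition_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (key in c("te_s", "tr_s"))
    if (is.null(cfg[[key]])) stop("config is missing required key '", key, "'")
  acquisition_meta(te_s = cfg$te_s, tr_s = cfg$tr_s,
                   sequence = cfg$sequence %||% "dynamic_epi",
                   baseline_frames = cfg$baseline_frames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Physical voxel-centre coordinates along one axis (corner-aligned grids).
axis_coords <- function(n, spacing) (seq_len(n) - 0.5) * spacing
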