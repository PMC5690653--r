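#' Voxel volume with physical spacing
#'
#' Container for a 3D scalar intensity grid with isotropic voxel spacing in
#' micrometres. The array layout is `dim = c(nz, ny, nx)` and axis order is
#' fixed to `"zyx"` (page, row, column of the TIFF stack). Voxel `(i, j, k)`
#' (1-based) has its center at physical coordinate
#' `(i-1, j-1, k-1) * spacing_um + origin_um`.
#'
#' @param data numeric 3D array, `dim = c(nz, ny, nx)`.
#' @param spacing_um isotropic voxel size in micrometres (default 5, the
#'   scan resolution the pipeline is designed around).
#' @param origin_um physical coordinate (z, y, x) of the center of voxel
#'   `(1, 1, 1)`, in micrometres.
#' @return an object of class `VoxelVolume`.
#' @export
voxel_volume <- function(data, spacing_um = 5, origin_um = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1)) stop("grid needs >= 1 voxel per axis", call. = FALSE)
  if (!is.numeric(spacing_um) || length(spacing_um) != 1 || spacing_um <= 0)
    stop("`spacing_um` must be a single positive number", call. = FALSE)
  structure(list(data = data, spacing_um = spacing_um,
                 origin_um = as.numeric(origin_um), axis_order = "zyx"),
            class = "VoxelVolume")
}

#' @export
print.VoxelVolume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("VoxelVolume %d x %d x %d (z,y,x), %.3g um/voxel, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing_um,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Integer-labeled tubule instances
#'
#' A `LabelVolume` shares the geometry of its source [voxel_volume()] but
#' holds non-negative integer instance labels (0 = background).
#'
#' @param labels integer 3D array; 0 is background.
#' @param spacing_um isotropic voxel size in micrometres.
#' @param origin_um physical coordinate of voxel `(1, 1, 1)`.
#' @param meta list of provenance fields (e.g. dropped-component summary).
#' @return an object of class `LabelVolume`.
#' @export
label_volume <- function(labels, spacing_um = 5, origin_um = c(0, 0, 0),
                         meta = list()) {
  if (!is.array(labels) || length(dim(labels)) != 3)
    stop("`labels` must be a 3D array", call. = FALSE)
  if (any(labels < 0)) stop("labels must be non-negative", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing_um = spacing_um,
                 origin_um = as.numeric(origin_um), axis_order = "zyx",
                 meta = meta),
            class = "LabelVolume")
}

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("LabelVolume %d x %d x %d (z,y,x), %.3g um/voxel, %d labels\n",
              d[1], d[2], d[3], x$spacing_um,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

.default_sidecar <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a volume from a multi-page TIFF with a JSON sidecar
#'
#' Pages become z-slices; the sidecar supplies the voxel spacing. A missing
#' sidecar falls back to 5 um/voxel with a warning. Intensities are restored
#' to their integer 16-bit scale (0..65535); label stacks written by
#' [write_volume()] read back exactly.
#'
#' @param path multi-page TIFF file.
#' @param sidecar_path JSON sidecar with at least `spacing_um`; defaults to
#'   `path` with the extension replaced by `.json`.
#' @param type `"intensity"` returns a [voxel_volume()], `"labels"` a
#'   [label_volume()].
#' @return a `VoxelVolume` or `LabelVolume`.
#' @export
read_volume <- function(path, sidecar_path = .default_sidecar(path),
                        type = c("intensity", "labels")) {
  type <- match.arg(type)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("cannot read TIFF '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  for (p in seq_along(pages))
    if (!identical(dim(pages[[p]]), d1))
      stop(sprintf("inconsistent page shape at page %d of '%s'", p, path),
           call. = FALSE)
  vol <- array(0, dim = c(length(pages), d1[1], d1[2]))
  for (p in seq_along(pages)) vol[p, , ] <- pages[[p]]
  vol <- round(vol * 65535)
  spacing <- 5
  origin <- c(0, 0, 0)
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(side$spacing_um)) spacing <- as.numeric(side$spacing_um)
    if (!is.null(side$origin_um)) origin <- as.numeric(side$origin_um)
  } else {
    warning("sidecar '", sidecar_path, "' not found; assuming 5 um/voxel",
            call. = FALSE)
  }
  if (type == "labels") label_volume(vol, spacing, origin)
  else voxel_volume(vol, spacing, origin)
}

#' Write a volume as a multi-page TIFF with a JSON sidecar
#'
#' Intensities (and labels) are stored as 16-bit unsigned pages; values are
#' clamped to \[0, 65535\] and rounded, so integer-valued volumes round-trip
#' exactly. The sidecar records `spacing_um`, `axis_order` and `grid_shape`.
#'
#' @param vol a [voxel_volume()] or [label_volume()].
#' @param path output TIFF path.
#' @param sidecar_path output JSON path (default: `path` with `.json`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, sidecar_path = .default_sidecar(path)) {
  arr <- if (inherits(vol, "LabelVolume")) vol$labels else vol$data
  if (inherits(vol, "LabelVolume") && max(arr) > 65535)
    stop("label values exceed the 16-bit storage range", call. = FALSE)
  arr <- pmin(pmax(arr, 0), 65535)
  pages <- lapply(seq_len(dim(arr)[1]), function(i) arr[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(spacing_um = vol$spacing_um,
                            axis_order = "zyx",
                            grid_shape = dim(arr),
                            origin_um = vol$origin_um),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-tubule measurements to CSV
#'
#' One row per tubule; numeric fields are serialized in micrometres with six
#' decimals; the per-slice diameter list is stored as a `;`-separated field.
#'
#' @param records measurement data.frame as returned by [measure_tubules()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  df <- as.data.frame(records)
  if ("slice_diameters_um" %in% names(df) && is.list(df$slice_diameters_um))
    df$slice_diameters_um <- vapply(df$slice_diameters_um, function(v)
      paste(sprintf("%.6f", v), collapse = ";"), character(1))
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- sprintf("%.6f", df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a measurement CSV written by [write_measurements()]
#'
#' @param path CSV path.
#' @return data.frame with numeric columns restored; the per-slice diameter
#'   field (if present) is parsed back into a list column.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("slice_diameters_um" %in% names(df))
    df$slice_diameters_um <- I(lapply(strsplit(as.character(df$slice_diameters_um), ";"),
                                      function(v) as.numeric(v[nzchar(v)])))
  df
}
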