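# Dataset container: a directory holding 32-bit-float multi-page TIFF arrays,
# a CSV of scan positions and a JSON manifest. The manifest mirrors a
# CXI-style tree (entry/data, entry/geometry, entry/ground_truth) as JSON
# groups and carries a layout-version attribute guarding dialect drift.
# Arrays are stored normalized to [0, 1] with a recorded affine (offset,
# scale), so storage precision is 32-bit float as documented.

LAYOUT_VERSION <- "ptychor-1"

write_f32_array <- function(arr, path) {
  arr <- as.array(arr)
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  norm <- (arr - lo) / scale
  pages <- if (length(dim(arr)) == 3L)
    lapply(seq_len(dim(arr)[3]), function(k) norm[, , k]) else list(norm)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  list(file = basename(path), offset = lo, scale = scale,
       dim = dim(arr))
}

read_f32_array <- function(dir, meta) {
  path <- file.path(dir, meta$file)
  if (!file.exists(path))
    stop_ptychor("dataset array missing: ", path, class = "ptychor_load_error")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dm <- as.integer(unlist(meta$dim))
  if (length(dm) == 3L && length(pages) != dm[3])
    stop_ptychor("truncated array in ", meta$file, ": expected ", dm[3],
                 " frames, found ", length(pages), class = "ptychor_load_error")
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  arr <- arr * meta$scale + meta$offset
  if (length(dm) == 2L) dim(arr) <- dm
  arr
}

write_complex_array <- function(values, dir, stem) {
  list(real = write_f32_array(Re(values), file.path(dir, paste0(stem, "_real.tif"))),
       imag = write_f32_array(Im(values), file.path(dir, paste0(stem, "_imag.tif"))))
}

read_complex_array <- function(dir, meta) {
  complex(real = read_f32_array(dir, meta$real),
          imaginary = read_f32_array(dir, meta$imag)) |>
    array(dim = as.integer(unlist(meta$real$dim)))
}

#' Save a diffraction dataset to a directory container
#'
#' Writes intensities and masks as multi-page 32-bit-float TIFF stacks, scan
#' positions as a CSV (`index, x_m, y_m`) and all geometry plus array scaling
#' metadata to a JSON manifest with a layout-version attribute. Initial or
#' ground-truth object/probe guesses may be embedded under their own groups.
#'
#' @param stack A [diffraction_stack()].
#' @param path Directory to create/overwrite.
#' @param object,probe Optional [ptycho_object()] / [ptycho_probe()] initial
#'   guesses embedded with the data.
#' @param ground_truth Optional list with elements `object` and/or `probe`
#'   stored under a `ground_truth` group.
#' @param config Optional reconstruction configuration echoed verbatim.
#' @return `path`, invisibly.
#' @seealso [load_dataset()]
#' @export
save_dataset <- function(stack, path, object = NULL, probe = NULL,
                         ground_truth = NULL, config = NULL) {
  stopifnot(inherits(stack, "diffraction_stack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path))
    stop_ptychor("cannot create dataset directory ", path,
                 class = "ptychor_io_error")
  g <- stack$geometry
  manifest <- list(
    layout_version = LAYOUT_VERSION,
    geometry = list(energy_keV = g$energy_keV, distance_m = g$distance_m,
                    pixel_m = g$pixel_m, frame_shape = g$frame_shape,
                    regime = g$regime),
    n_frames = n_frames(stack),
    data = list(
      intensities = write_f32_array(stack$intensities,
                                    file.path(path, "intensities.tif")),
      masks = write_f32_array(stack$masks, file.path(path, "masks.tif"))
    )
  )
  utils::write.csv(
    data.frame(index = seq_len(n_frames(stack)) - 1L,
               x_m = stack$scan$positions_m[, 1],
               y_m = stack$scan$positions_m[, 2]),
    file.path(path, "positions.csv"), row.names = FALSE)

  store_field <- function(obj, stem) {
    meta <- write_complex_array(obj$values, path, stem)
    meta$pixel_m <- obj$pixel_m
    meta
  }
  store_probe <- function(pr, stem) {
    meta <- write_complex_array(pr$modes, path, stem)
    meta$occupancies <- pr$occupancies
    meta
  }
  if (!is.null(object)) manifest$object <- store_field(object, "object")
  if (!is.null(probe)) manifest$probe <- store_probe(probe, "probe")
  if (!is.null(ground_truth)) {
    manifest$ground_truth <- list()
    if (!is.null(ground_truth$object))
      manifest$ground_truth$object <- store_field(ground_truth$object, "gt_object")
    if (!is.null(ground_truth$probe))
      manifest$ground_truth$probe <- store_probe(ground_truth$probe, "gt_probe")
  }
  if (!is.null(config)) manifest$config <- config
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a diffraction dataset from a directory container
#'
#' Inverse of [save_dataset()]. A dataset lacking masks gets all-ones masks;
#' embedded object/probe guesses and ground truth are returned when present.
#'
#' @param path Dataset directory.
#' @return List with elements `stack` ([diffraction_stack()]), and where
#'   present `object`, `probe`, `ground_truth` and `config`.
#' @export
load_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop_ptychor("no manifest.json under ", path, class = "ptychor_load_error")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$layout_version, LAYOUT_VERSION))
    stop_ptychor("unknown dataset layout version: ",
                 manifest$layout_version %||% "<missing>",
                 class = "ptychor_load_error")
  gm <- manifest$geometry
  geometry <- detector_geometry(gm$energy_keV, gm$distance_m, gm$pixel_m,
                                unlist(gm$frame_shape), gm$regime)
  pos <- utils::read.csv(file.path(path, "positions.csv"))
  scan <- scan_pattern(cbind(pos$x_m, pos$y_m))

  intensities <- read_f32_array(path, manifest$data$intensities)
  if (dim(intensities)[3] != manifest$n_frames)
    stop_ptychor("intensities.tif: expected ", manifest$n_frames,
                 " frames, found ", dim(intensities)[3],
                 class = "ptychor_load_error")
  masks <- if (!is.null(manifest$data$masks))
    round(read_f32_array(path, manifest$data$masks)) else NULL
  out <- list(stack = diffraction_stack(intensities, scan, geometry, masks))

  load_field <- function(meta)
    ptycho_object(read_complex_array(path, meta), meta$pixel_m)
  load_probe <- function(meta)
    ptycho_probe(read_complex_array(path, meta), unlist(meta$occupancies))
  if (!is.null(manifest$object)) out$object <- load_field(manifest$object)
  if (!is.null(manifest$probe)) out$probe <- load_probe(manifest$probe)
  if (!is.null(manifest$ground_truth)) {
    gt <- list()
    if (!is.null(manifest$ground_truth$object))
      gt$object <- load_field(manifest$ground_truth$object)
    if (!is.null(manifest$ground_truth$probe))
      gt$probe <- load_probe(manifest$ground_truth$probe)
    out$ground_truth <- gt
  }
  if (!is.null(manifest$config)) out$config <- manifest$config
  out
}
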