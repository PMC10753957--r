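#' Label volume: a 3D grid of instance ids
#'
#' The universal container for ground-truth and predicted segmentations.
#' The grid is a 3D integer array with axes ordered (z, y, x) — the thick,
#' anisotropic sectioning axis first — and id 0 reserved for background.
#' `spacing` holds the physical voxel edge lengths in nm, in the same (z, y,
#' x) order; the serial-section EM convention of 30 x 8 x 8 nm is the
#' default.
#'
#' @param grid 3D array of non-negative integers; dim = c(nz, ny, nx).
#' @param spacing numeric length-3, physical voxel size in nm (z, y, x);
#'   all components strictly positive.
#' @return An object of class `label_volume` with elements `grid` and
#'   `spacing`.
#' @examples
#' g <- array(0L, c(4, 4, 4)); g[2:3, 2:3, 2:3] <- 1L
#' v <- label_volume(g)
#' instance_ids(v)
#' @export
label_volume <- function(grid, spacing = c(30, 8, 8)) {
  if (length(dim(grid)) != 3L) {
    stop("`grid` must be a 3D array", call. = FALSE)
  }
  if (length(grid) == 0L) {
    stop("`grid` must contain at least one voxel", call. = FALSE)
  }
  if (anyNA(grid)) stop("`grid` contains NA values", call. = FALSE)
  if (is.double(grid)) {
    if (any(grid != round(grid))) {
      stop("label grid contains non-integer values", call. = FALSE)
    }
    storage.mode(grid) <- "integer"
  }
  if (min(grid) < 0L) stop("label ids must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (z, y, x) in nm",
         call. = FALSE)
  }
  structure(list(grid = grid, spacing = spacing), class = "label_volume")
}

#' Probability volume: a 3D grid of values in \[0, 1\]
#'
#' Holds a foreground or instance-contour probability map, voxel-aligned
#' with a [label_volume()] of the same shape.
#'
#' @param grid 3D numeric array with all values in \[0, 1\].
#' @inheritParams label_volume
#' @return An object of class `prob_volume`.
#' @export
prob_volume <- function(grid, spacing = c(30, 8, 8)) {
  if (length(dim(grid)) != 3L) {
    stop("`grid` must be a 3D array", call. = FALSE)
  }
  if (length(grid) == 0L) {
    stop("`grid` must contain at least one voxel", call. = FALSE)
  }
  if (anyNA(grid)) stop("`grid` contains NA values", call. = FALSE)
  storage.mode(grid) <- "double"
  rng <- range(grid)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("probability values must lie in [0, 1]; observed range [",
         format(rng[1]), ", ", format(rng[2]), "]", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (z, y, x) in nm",
         call. = FALSE)
  }
  structure(list(grid = grid, spacing = spacing), class = "prob_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$grid)
  ids <- instance_ids(x)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), spacing %s nm, %d instance%s\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = "x"),
              length(ids), if (length(ids) == 1) "" else "s"))
  invisible(x)
}

#' @export
print.prob_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<prob_volume> %d x %d x %d (z,y,x), spacing %s nm, range [%.3f, %.3f]\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = "x"),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$grid)

#' @export
dim.prob_volume <- function(x) dim(x$grid)

#' Instance ids present in a label volume
#'
#' @param vol a [label_volume()].
#' @return Sorted integer vector of the positive ids (background excluded).
#' @export
instance_ids <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  ids <- sort(unique(as.vector(vol$grid)))
  ids[ids > 0L]
}

is_hdf5_path <- function(path) {
  grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)
}

is_tiff_path <- function(path) {
  grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a label or probability volume from HDF5 or multi-page TIFF
#'
#' Integer data yields a [label_volume()], floating-point data a
#' [prob_volume()]. For HDF5, the dataset (default `"main"`) is read along
#' with a `spacing_nm` attribute when present. For TIFF, each page is one z
#' slice and spacing is read from a JSON sidecar `<path>.json` with key
#' `spacing_nm`. When no spacing metadata is found, the 30 x 8 x 8 nm
#' convention is used with a warning.
#'
#' @param path file path (`.h5`/`.hdf5` or `.tif`/`.tiff`).
#' @param dataset HDF5 dataset name (ignored for TIFF).
#' @param spacing optional numeric length-3 (z, y, x) in nm, overriding any
#'   file metadata.
#' @return A [label_volume()] or [prob_volume()].
#' @export
read_volume <- function(path, dataset = "main", spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is_hdf5_path(path)) {
    contents <- rhdf5::h5ls(path, recursive = FALSE)
    dsets <- contents$name[contents$otype == "H5I_DATASET"]
    if (!(dataset %in% dsets)) {
      if (length(dsets) == 1L) {
        dataset <- dsets
      } else {
        stop("dataset '", dataset, "' not found in ", path,
             "; available: ", paste(dsets, collapse = ", "), call. = FALSE)
      }
    }
    grid <- rhdf5::h5read(path, dataset)
    if (is.null(spacing)) {
      at <- rhdf5::h5readAttributes(path, dataset)
      if (!is.null(at$spacing_nm)) spacing <- as.numeric(at$spacing_nm)
    }
  } else if (is_tiff_path(path)) {
    info <- tiff::readTIFF(path, payload = FALSE)
    # convention: labels are 16-bit unsigned, probabilities 32-bit float
    is_float <- any(info$bits.per.sample >= 32)
    # integer TIFFs carry label ids: read raw values, not [0,1] rescaled
    pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float)
    if (!is.list(pages)) pages <- list(pages)
    if (any(!vapply(pages, is.matrix, logical(1)))) {
      stop("multi-channel TIFF pages are not supported", call. = FALSE)
    }
    d <- dim(pages[[1]])
    grid <- array(0, c(length(pages), d[1], d[2]))
    for (z in seq_along(pages)) grid[z, , ] <- pages[[z]]
    if (is.null(spacing) && file.exists(sidecar_path(path))) {
      meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
      if (!is.null(meta$spacing_nm)) spacing <- as.numeric(meta$spacing_nm)
    }
  } else {
    stop("unsupported volume format: ", path,
         " (expected .h5/.hdf5 or .tif/.tiff)", call. = FALSE)
  }
  if (length(dim(grid)) != 3L) {
    stop("dataset in ", path, " is not 3D", call. = FALSE)
  }
  if (is.null(spacing)) {
    warning("no spacing metadata for ", path,
            "; assuming 30 x 8 x 8 nm (z, y, x)")
    spacing <- c(30, 8, 8)
  }
  integral <- is.integer(grid) || all(grid == round(grid))
  if (integral) {
    if (min(grid) < 0) stop("negative label ids in ", path, call. = FALSE)
    label_volume(grid, spacing)
  } else {
    prob_volume(grid, spacing)
  }
}

#' Write a volume to HDF5 or multi-page TIFF
#'
#' Integer grids round-trip bit-exactly through both formats (TIFF stores
#' 16-bit samples, so ids must not exceed 65535). Probability grids are
#' stored as 64-bit floats in HDF5 and 32-bit floats in TIFF. Spacing goes
#' into an HDF5 attribute or a JSON sidecar `<path>.json` for TIFF.
#'
#' @param vol a [label_volume()] or [prob_volume()].
#' @param path destination path; format chosen by extension.
#' @param dataset HDF5 dataset name.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, dataset = "main") {
  stopifnot(inherits(vol, "label_volume") || inherits(vol, "prob_volume"))
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  is_label <- inherits(vol, "label_volume")
  if (is_hdf5_path(path)) {
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(vol$grid, path, dataset)
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, dataset)
    rhdf5::h5writeAttribute(vol$spacing, did, "spacing_nm")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  } else if (is_tiff_path(path)) {
    d <- dim(vol$grid)
    if (is_label) {
      if (max(vol$grid) > 65535L) {
        stop("TIFF label storage is 16-bit; ids above 65535 need HDF5",
             call. = FALSE)
      }
      pages <- lapply(seq_len(d[1]), function(z) {
        matrix(vol$grid[z, , ] / 65535, d[2], d[3])
      })
      tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    } else {
      pages <- lapply(seq_len(d[1]), function(z) {
        matrix(vol$grid[z, , ], d[2], d[3])
      })
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    }
    jsonlite::write_json(list(spacing_nm = vol$spacing), sidecar_path(path),
                         auto_unbox = FALSE, digits = NA)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Relabel instances to consecutive ids 1..K
#'
#' Ids are renumbered in first-occurrence order under the internal linear
#' scan (z fastest, then y, then x); background is preserved and the voxel
#' support of every instance is unchanged, so every downstream metric is
#' invariant.
#'
#' @param vol a [label_volume()].
#' @return A list with `volume` (the relabeled [label_volume()]) and `map`,
#'   a named integer vector old id -> new id.
#' @export
relabel_consecutive <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  v <- as.vector(vol$grid)
  old <- unique(v[v > 0L])  # unique() preserves first-occurrence order
  map <- seq_along(old)
  names(map) <- old
  out <- vol$grid
  if (length(old)) {
    out[] <- c(0L, map)[match(v, c(0L, old))]
  }
  list(volume = label_volume(out, vol$spacing), map = map)
}

#' Per-instance sizes and bounding boxes
#'
#' @param vol a [label_volume()].
#' @return An object of class `instance_index`: list with `ids` (sorted),
#'   `sizes` (named integer, voxel counts) and `bbox` (named list of 2 x 3
#'   matrices, rows `lo`/`hi`, 0-based half-open voxel intervals per axis
#'   z, y, x).
#' @export
build_index <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  v <- as.vector(vol$grid)
  pos <- which(v > 0L)
  ids <- sort(unique(v[pos]))
  sizes <- integer(length(ids))
  names(sizes) <- ids
  bbox <- vector("list", length(ids))
  names(bbox) <- ids
  if (length(pos)) {
    tab <- table(v[pos])
    sizes[names(tab)] <- as.integer(tab)
    d <- dim(vol$grid)
    z <- (pos - 1L) %% d[1]
    y <- ((pos - 1L) %/% d[1]) %% d[2]
    x <- (pos - 1L) %/% (d[1] * d[2])
    lab <- v[pos]
    lo_z <- tapply(z, lab, min); hi_z <- tapply(z, lab, max)
    lo_y <- tapply(y, lab, min); hi_y <- tapply(y, lab, max)
    lo_x <- tapply(x, lab, min); hi_x <- tapply(x, lab, max)
    for (id in as.character(ids)) {
      bbox[[id]] <- matrix(c(lo_z[[id]], lo_y[[id]], lo_x[[id]],
                             hi_z[[id]] + 1L, hi_y[[id]] + 1L, hi_x[[id]] + 1L),
                           nrow = 2, byrow = TRUE,
                           dimnames = list(c("lo", "hi"), c("z", "y", "x")))
    }
  }
  structure(list(ids = ids, sizes = sizes, bbox = bbox),
            class = "instance_index")
}

#' @export
print.instance_index <- function(x, ...) {
  cat(sprintf("<instance_index> %d instances, %d voxels total\n",
              length(x$ids), sum(x$sizes)))
  invisible(x)
}

# extract the binary mask of one instance, cropped to its bounding box
# (with an optional pad); returns list(mask, offset) with 0-based offset
crop_instance <- function(vol, index, id, pad = 1L) {
  bb <- index$bbox[[as.character(id)]]
  d <- dim(vol$grid)
  lo <- pmax(bb["lo", ] - pad, 0L)
  hi <- pmin(bb["hi", ] + pad, d)
  sub <- vol$grid[(lo[1] + 1L):hi[1], (lo[2] + 1L):hi[2], (lo[3] + 1L):hi[3],
                  drop = FALSE]
  list(mask = array(sub == id, dim(sub)), offset = lo)
}
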