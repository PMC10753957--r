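#' Decoder parameters
#'
#' Thresholds and options for the baseline foreground + contour watershed
#' decoder. `theta_seed` must be at least `theta_fg`, so seeds always lie
#' inside the foreground mask. The named presets carry the challenge
#' post-processing settings: `"mitoem-h"` uses thresholds 0.7 / 0.6 / 0.6
#' (seeds / contour / foreground) and `"mitoem-r"` 0.85 / 0.6 / 0.8, both
#' with a 1024-voxel minimum instance size.
#'
#' @param theta_seed foreground threshold for seed extraction.
#' @param theta_contour contour threshold; voxels with contour probability
#'   at or above it are excluded from seeds.
#' @param theta_fg foreground threshold of the watershed mask.
#' @param min_voxels minimum surviving instance size (voxels).
#' @param connectivity 6 or 26 (3D), for seeds, flooding and components.
#' @param median_filter apply [median_filter_yz()] to both probability maps
#'   before decoding.
#' @param median_radius radius of that filter.
#' @return A `decoder_params` list.
#' @export
decoder_params <- function(theta_seed = 0.7, theta_contour = 0.6,
                           theta_fg = 0.6, min_voxels = 1024L,
                           connectivity = 26L, median_filter = FALSE,
                           median_radius = 1L) {
  if (theta_seed < theta_fg) {
    stop("theta_seed must be >= theta_fg (seeds must lie inside the mask)",
         call. = FALSE)
  }
  for (th in c(theta_seed, theta_contour, theta_fg)) {
    if (th < 0 || th > 1) stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (min_voxels < 0) stop("min_voxels must be >= 0", call. = FALSE)
  if (!connectivity %in% c(6L, 26L)) {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
  structure(list(theta_seed = theta_seed, theta_contour = theta_contour,
                 theta_fg = theta_fg, min_voxels = as.integer(min_voxels),
                 connectivity = as.integer(connectivity),
                 median_filter = isTRUE(median_filter),
                 median_radius = as.integer(median_radius)),
            class = "decoder_params")
}

#' @rdname decoder_params
#' @param preset `"mitoem-h"` or `"mitoem-r"`.
#' @param ... overrides passed to [decoder_params()].
#' @export
decoder_preset <- function(preset = c("mitoem-h", "mitoem-r"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "mitoem-h" = list(theta_seed = 0.7, theta_contour = 0.6, theta_fg = 0.6),
    "mitoem-r" = list(theta_seed = 0.85, theta_contour = 0.6, theta_fg = 0.8))
  do.call(decoder_params, modifyList(base, list(...)))
}

check_aligned <- function(a, b) {
  if (!identical(dim(a$grid), dim(b$grid))) {
    stop("probability volumes have different shapes", call. = FALSE)
  }
}

#' Extract instance seeds from foreground and contour maps
#'
#' Seed mask = (foreground >= theta_seed) AND (contour < theta_contour):
#' the only combination of the two thresholded maps that yields distinct,
#' non-touching seeds, since the contour map is high exactly where
#' instances meet. Connected components of the seed mask become seed
#' labels.
#'
#' @param fg,contour aligned [prob_volume()]s.
#' @param params a [decoder_params()].
#' @return A [label_volume()] of seed labels.
#' @export
extract_seeds <- function(fg, contour, params = decoder_params()) {
  stopifnot(inherits(fg, "prob_volume"), inherits(contour, "prob_volume"))
  check_aligned(fg, contour)
  seed_mask <- fg$grid >= params$theta_seed &
    contour$grid < params$theta_contour
  lab <- cc_label_3d(as.logical(seed_mask), dim(fg$grid),
                     params$connectivity)
  label_volume(array(lab, dim(fg$grid)), fg$spacing)
}

#' Marker-controlled watershed from seeds
#'
#' Floods the inverted foreground probabilities (the topography) from the
#' seed markers, confined to the binarized foreground mask (fg >=
#' theta_fg). Every output instance contains its seed, and the output
#' support never leaves the mask. Plateau ties are resolved by
#' deterministic insertion order, so identical inputs give identical
#' labels.
#'
#' @param fg a [prob_volume()].
#' @param seeds a [label_volume()] of markers; nonzero only where fg >=
#'   theta_fg.
#' @param params a [decoder_params()].
#' @return A [label_volume()] of instances.
#' @export
watershed_decode <- function(fg, seeds, params = decoder_params()) {
  stopifnot(inherits(fg, "prob_volume"), inherits(seeds, "label_volume"))
  if (!identical(dim(fg$grid), dim(seeds$grid))) {
    stop("fg and seeds have different shapes", call. = FALSE)
  }
  mask <- fg$grid >= params$theta_fg
  if (any(seeds$grid > 0L & !mask)) {
    stop("seed voxels found outside the foreground mask", call. = FALSE)
  }
  lab <- watershed_3d(as.double(1 - fg$grid), as.integer(seeds$grid),
                      as.logical(mask), dim(fg$grid), params$connectivity)
  label_volume(array(lab, dim(fg$grid)), fg$spacing)
}

#' Remove instances below a voxel-count threshold
#'
#' Instances with fewer than `min_voxels` voxels become background; an
#' instance of exactly `min_voxels` voxels is kept.
#'
#' @param vol a [label_volume()].
#' @param min_voxels minimum size in voxels.
#' @return The filtered [label_volume()].
#' @export
filter_small_instances <- function(vol, min_voxels = 1024L) {
  stopifnot(inherits(vol, "label_volume"))
  if (min_voxels <= 0L) return(vol)
  sizes <- size_table(as.vector(vol$grid))
  drop <- as.integer(names(sizes)[sizes < min_voxels])
  if (length(drop)) {
    g <- vol$grid
    g[g %in% drop] <- 0L
    vol <- label_volume(g, vol$spacing)
  }
  vol
}

#' Median filter in the (y, z) plane
#'
#' Applies a 2D median filter of the given radius independently to every
#' x slice, a denoising step for anisotropic serial-section predictions
#' whose artifacts run across sections. Windows are truncated at volume
#' borders; values stay in \[0, 1\].
#'
#' @param prob a [prob_volume()].
#' @param radius window radius (window side 2*radius + 1); >= 1.
#' @return The filtered [prob_volume()].
#' @export
median_filter_yz <- function(prob, radius = 1L) {
  stopifnot(inherits(prob, "prob_volume"))
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  out <- median_filter_yz_cpp(as.double(prob$grid), dim(prob$grid),
                              as.integer(radius))
  prob_volume(array(out, dim(prob$grid)), prob$spacing)
}

#' Decode instances from foreground + contour probability maps
#'
#' The baseline BC decoding pipeline: optional median pre-filtering, seed
#' extraction ([extract_seeds()]), marker-controlled watershed
#' ([watershed_decode()]), and small-instance removal
#' ([filter_small_instances()]). Deterministic for fixed inputs.
#'
#' @param fg,contour aligned [prob_volume()]s.
#' @param params a [decoder_params()] or [decoder_preset()].
#' @return A [label_volume()] of decoded instances.
#' @export
decode <- function(fg, contour, params = decoder_params()) {
  stopifnot(inherits(fg, "prob_volume"), inherits(contour, "prob_volume"))
  check_aligned(fg, contour)
  if (params$median_filter) {
    fg <- median_filter_yz(fg, params$median_radius)
    contour <- median_filter_yz(contour, params$median_radius)
  }
  seeds <- extract_seeds(fg, contour, params)
  inst <- watershed_decode(fg, seeds, params)
  filter_small_instances(inst, params$min_voxels)
}
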