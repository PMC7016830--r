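#' Voxelised RBE-weighted dose grid
#'
#' A `dose_grid` holds a 3-D array of RBE-weighted dose values in Gy(RBE) on a
#' regular grid, together with the voxel size, grid origin and the RBE model
#' the dose was computed with (LEM or mMKM).  It is the physical substrate all
#' DVH metrics are derived from.
#'
#' @param values 3-D numeric array of dose values, Gy(RBE).  All values must
#'   be finite and non-negative.
#' @param voxel_size numeric length-3 vector `(dx, dy, dz)` in mm, all > 0.
#' @param origin numeric length-3 vector, grid origin in mm.
#' @param rbe_model `"LEM"` or `"MKM"`.
#' @return An object of class `dose_grid`.
#' @seealso [structure_mask()], [compute_dvh()]
#' @export
dose_grid <- function(values, voxel_size, origin = c(0, 0, 0),
                      rbe_model = c("LEM", "MKM")) {
  rbe_model <- match.arg(rbe_model)
  if (!is.array(values) || length(dim(values)) != 3L || length(values) == 0L)
    stop("`values` must be a non-empty 3-D array")
  if (anyNA(values) || any(!is.finite(values)))
    stop("dose values must be finite")
  if (any(values < 0))
    stop("dose values must be >= 0")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  structure(
    list(values = values, voxel_size = voxel_size, origin = origin,
         rbe_model = rbe_model),
    class = "dose_grid"
  )
}

#' Binary structure mask on a dose grid
#'
#' @param mask logical 3-D array, `TRUE` inside the structure.  Must be
#'   congruent (same dimensions) with the [dose_grid()] it is used with.
#' @param name structure name, e.g. `"rectum"`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(mask, name = "structure") {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3-D array")
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stop("`mask` must be logical or 0/1")
    mask <- array(as.logical(mask), dim = dim(mask))
  }
  if (anyNA(mask)) stop("`mask` must not contain NA")
  structure(list(mask = mask, name = name), class = "structure_mask")
}

#' Structure volume in cc
#'
#' Volume of the masked voxels: `count(TRUE) * dx * dy * dz / 1000`.
#'
#' @param mask a [structure_mask()].
#' @param voxel_size voxel size in mm (length-3), or a [dose_grid()] whose
#'   voxel size is used.
#' @return volume in cc.
#' @export
mask_volume_cc <- function(mask, voxel_size) {
  if (inherits(voxel_size, "dose_grid")) voxel_size <- voxel_size$voxel_size
  sum(mask$mask) * prod(voxel_size) / 1000
}

#' Isotropic margin expansion of a structure mask
#'
#' Morphological 3-D dilation of a binary mask with a spherical structuring
#' element of the given radius, used e.g. to build a 5 mm planning risk
#' volume (PRV) around the rectum for sacral chordoma constraint sets.
#'
#' @param mask a [structure_mask()].
#' @param voxel_size voxel size in mm (length-3) or a [dose_grid()].
#' @param margin_mm expansion margin in mm (default 5).
#' @return a new [structure_mask()] with name suffixed `"_prv"`.
#' @export
expand_mask <- function(mask, voxel_size, margin_mm = 5) {
  if (inherits(voxel_size, "dose_grid")) voxel_size <- voxel_size$voxel_size
  if (margin_mm < 0) stop("`margin_mm` must be >= 0")
  m <- mask$mask
  if (margin_mm == 0)
    return(structure_mask(m, paste0(mask$name, "_prv")))
  d <- dim(m)
  nmax <- ceiling(margin_mm / voxel_size)
  out <- m
  for (ix in -nmax[1]:nmax[1]) {
    for (iy in -nmax[2]:nmax[2]) {
      for (iz in -nmax[3]:nmax[3]) {
        if (ix == 0 && iy == 0 && iz == 0) next
        r2 <- (ix * voxel_size[1])^2 + (iy * voxel_size[2])^2 +
          (iz * voxel_size[3])^2
        if (r2 > margin_mm^2) next
        # shift m by (ix, iy, iz) and OR into out
        sx <- shift_range(d[1], ix); sy <- shift_range(d[2], iy)
        sz <- shift_range(d[3], iz)
        out[sx$to, sy$to, sz$to] <-
          out[sx$to, sy$to, sz$to] | m[sx$from, sy$from, sz$from]
      }
    }
  }
  structure_mask(out, paste0(mask$name, "_prv"))
}

# index ranges implementing an integer shift along one dimension
shift_range <- function(n, k) {
  if (k >= 0) list(to = seq_len(n - k) + k, from = seq_len(n - k))
  else list(to = seq_len(n + k), from = seq_len(n + k) - k)
}
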