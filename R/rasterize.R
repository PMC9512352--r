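# Even-odd point-in-polygon rasterization of planar contours onto a dose
# grid.  Voxels are included wholly or not at all (center-in-polygon test);
# there is no inter-slice interpolation: each contour polygon claims exactly
# the grid slice whose z matches its plane.

# Ray-crossing test, vectorized over query points.  Points exactly on a
# horizontal edge follow the half-open convention (yv[i] > y) xor
# (yv[j] > y), which keeps adjacent polygons non-overlapping.
point_in_polygon <- function(px, py, xv, yv) {
  n <- length(xv)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((yv[i] > py) != (yv[j] > py))
    if (any(crosses)) {
      xint <- xv[i] + (py[crosses] - yv[i]) / (yv[j] - yv[i]) * (xv[j] - xv[i])
      hit <- which(crosses)[px[crosses] < xint]
      inside[hit] <- !inside[hit]
    }
    j <- i
  }
  inside
}

#' Rasterize a contour set onto a dose grid
#'
#' Tests each voxel center of the matching grid slice against the contour
#' polygon with the even-odd rule, so holes (e.g. the inner wall of a shell)
#' and multiple polygons per slice combine correctly.  A contour plane that
#' does not coincide with any grid slice within half a slice spacing raises
#' a geometry error.
#'
#' @param contours A [contour_set()].
#' @param grid The [dose_grid()] defining the voxel lattice.
#' @return A [structure_mask()] congruent with `grid`.
#' @export
rasterize <- function(contours, grid) {
  stopifnot(inherits(contours, "contour_set"), inherits(grid, "dose_grid"))
  dm <- dim(grid$values)
  mask <- array(FALSE, dm)
  xs <- grid$origin[1] + (seq_len(dm[2]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(dm[1]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(dm[3]) - 1) * grid$spacing[3]
  pts <- expand.grid(row = seq_len(dm[1]), col = seq_len(dm[2]))
  px <- xs[pts$col]; py <- ys[pts$row]
  for (p in contours$contours) {
    z <- p[1, 3]
    k <- which.min(abs(zs - z))
    if (abs(zs[k] - z) > grid$spacing[3] / 2 + 1e-6)
      abort_isodvh(sprintf("contour plane z = %g matches no grid slice", z),
                   "geometry")
    inside <- point_in_polygon(px, py, p[, 1], p[, 2])
    slice <- mask[, , k]
    slice[cbind(pts$row, pts$col)] <- xor(slice[cbind(pts$row, pts$col)],
                                          inside)
    mask[, , k] <- slice
  }
  structure_mask(contours$roi_name, mask, voxel_volume_cc(grid$spacing))
}
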