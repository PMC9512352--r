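#' Dose-volume histogram
#'
#' A binned dose-versus-volume table for one structure.  Bins are
#' left-closed/right-open intervals `[bin_lower, bin_upper)` on an ascending,
#' non-overlapping dose axis; zero-width bins (point masses) are permitted,
#' which is convenient for toy DVHs quoted at exact doses.  The dose axis is
#' tagged with its scale (`physical`, `BED` or `EQD2`) and, for converted
#' histograms, the \eqn{\alpha/\beta} identifying the unit subscript.
#'
#' @param volume Volume per bin (cm3, or percent after
#'   [rescale_to_relative()]); non-negative.
#' @param bin_lower,bin_upper Bin edges in Gy.  If `bin_upper` is omitted,
#'   contiguous bins of width `bin_width` starting at each `bin_lower` are
#'   assumed.
#' @param bin_width Bin width used when `bin_upper` is missing.
#' @param structure Structure name.
#' @param scale One of `"physical"`, `"BED"`, `"EQD2"`.
#' @param alpha_beta_tag \eqn{\alpha/\beta} tag (Gy) for converted scales.
#' @return An object of class `dvh`.
#' @export
dvh <- function(volume, bin_lower, bin_upper = NULL, bin_width = NULL,
                structure = "", scale = c("physical", "BED", "EQD2"),
                alpha_beta_tag = NA_real_) {
  scale <- match.arg(scale)
  if (is.null(bin_upper)) {
    if (is.null(bin_width))
      abort_isodvh("either bin_upper or bin_width is required",
                   "invalid_parameter")
    bin_upper <- bin_lower + bin_width
  }
  dvh_new(volume, bin_lower, bin_upper, structure, scale, alpha_beta_tag)
}

# Internal constructor; validates bin geometry.
dvh_new <- function(volume, bin_lower, bin_upper, structure = "",
                    scale = "physical", alpha_beta_tag = NA_real_,
                    volume_unit = "cm3", total_volume = NULL) {
  if (length(volume) != length(bin_lower) ||
      length(volume) != length(bin_upper))
    abort_isodvh("volume and bin edges must have equal length", "invalid_parameter")
  if (any(volume < 0))
    abort_isodvh("bin volumes must be non-negative", "invalid_parameter")
  if (length(volume) > 0) {
    if (any(bin_upper < bin_lower))
      abort_isodvh("bin_upper must be >= bin_lower", "invalid_parameter")
    if (is.unsorted(bin_lower, strictly = FALSE) ||
        any(utils::head(bin_upper, -1) > utils::tail(bin_lower, -1) + 1e-12 *
              max(1, max(abs(bin_upper)))))
      abort_isodvh("bins must be ascending and non-overlapping", "invalid_parameter")
  }
  structure(list(structure = as.character(structure),
                 bin_lower = as.numeric(bin_lower),
                 bin_upper = as.numeric(bin_upper),
                 volume = as.numeric(volume),
                 scale = scale,
                 alpha_beta_tag = alpha_beta_tag,
                 volume_unit = volume_unit,
                 total_volume = total_volume %||% sum(volume)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  occ <- x$volume > 0
  cat(sprintf("<dvh> %s: %d bins (%d occupied), scale %s%s, total volume %.4g %s\n",
              if (nzchar(x$structure)) x$structure else "(unnamed)",
              length(x$volume), sum(occ), x$scale,
              if (!is.na(x$alpha_beta_tag))
                sprintf(" Gy[%g]", x$alpha_beta_tag) else "",
              sum(x$volume), x$volume_unit))
  if (any(occ))
    cat(sprintf("  dose range of occupied bins: [%.4g, %.4g] Gy\n",
                min(x$bin_lower[occ]), max(x$bin_upper[occ])))
  invisible(x)
}

dvh_bin_centers <- function(x) (x$bin_lower + x$bin_upper) / 2

#' Dose grid
#'
#' A 3-D array of dose values on a regular grid.  Arrays are indexed
#' `[row, col, slice]`; the voxel center at index `(i, j, k)` lies at
#' patient coordinates `origin + ((j-1) dx, (i-1) dy, (k-1) dz)` mm.
#'
#' @param values 3-D numeric array of dose in Gy (non-negative).
#' @param spacing `(dx, dy, dz)` voxel spacing in mm (> 0).
#' @param origin Patient-space coordinates of the first voxel center (mm).
#' @param dose_scaling Multiplicative quantization step applied on DICOM
#'   read/write (recorded for round-trip fidelity; `NA` if not quantized).
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0),
                      dose_scaling = NA_real_) {
  if (length(dim(values)) != 3L)
    abort_isodvh("values must be a 3-D array", "invalid_parameter")
  if (any(values < 0))
    abort_isodvh("doses must be non-negative", "invalid_parameter")
  if (length(spacing) != 3L || any(spacing <= 0))
    abort_isodvh("spacing must be three positive numbers", "invalid_parameter")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 dose_scaling = dose_scaling),
            class = "dose_grid")
}

#' Structure mask
#'
#' Boolean voxel mask congruent with an associated [dose_grid()].
#'
#' @param name Structure name.
#' @param array Logical 3-D array, same dimensions as the dose grid.
#' @param voxel_volume Volume of one voxel in cm3.
#' @return An object of class `structure_mask`; its `volume` field is
#'   `sum(array) * voxel_volume`.
#' @export
structure_mask <- function(name, array, voxel_volume) {
  if (!is.logical(array) || length(dim(array)) != 3L)
    abort_isodvh("mask array must be a logical 3-D array", "invalid_parameter")
  if (voxel_volume <= 0)
    abort_isodvh("voxel_volume must be > 0", "invalid_parameter")
  structure(list(name = as.character(name), array = array,
                 voxel_volume = voxel_volume,
                 volume = sum(array) * voxel_volume),
            class = "structure_mask")
}

voxel_volume_cc <- function(spacing) prod(spacing) / 1000  # mm3 -> cm3

#' Compute a differential DVH from a dose grid and structure mask
#'
#' Each masked voxel contributes its full voxel volume to the bin containing
#' its center dose (left-closed/right-open bins of uniform width starting at
#' 0 Gy).  No spatial interpolation of the dose grid or the contours is
#' performed: the dose at the voxel center stands for the whole voxel.  This
#' deliberately reproduces the staggered histograms seen for structures that
#' are small relative to the dose grid.
#'
#' @param grid [dose_grid()].
#' @param mask [structure_mask()] congruent with `grid`.
#' @param bin_width Bin width in Gy (default 0.01 Gy = 1 cGy).
#' @return A [dvh()] on the physical scale; total volume equals the mask
#'   volume exactly.
#' @export
dvh_from_grid <- function(grid, mask, bin_width = 0.01) {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "structure_mask"))
  if (!identical(dim(grid$values), dim(mask$array)))
    abort_isodvh("dose grid and mask are not congruent", "congruence")
  if (bin_width <= 0)
    abort_isodvh("bin_width must be > 0", "invalid_parameter")
  doses <- grid$values[mask$array]
  if (length(doses) == 0L)
    abort_isodvh(sprintf("structure '%s' is empty", mask$name), "empty_structure")
  idx <- floor(doses / bin_width) + 1L   # bin [k*bw, (k+1)*bw)
  counts <- tabulate(idx, nbins = max(idx))
  lower <- (seq_along(counts) - 1) * bin_width
  dvh_new(counts * mask$voxel_volume, lower, lower + bin_width,
          structure = mask$name, scale = "physical")
}

# Exact cumulative volume (volume receiving >= dose), assuming uniform
# density within each bin; point-mass bins count fully when lower >= dose.
dvh_cum_at_dose <- function(x, dose) {
  lo <- x$bin_lower; hi <- x$bin_upper; vol <- x$volume
  vapply(dose, function(d) {
    w <- hi - lo
    frac <- ifelse(w == 0, as.numeric(lo >= d),
                   pmin(1, pmax(0, (hi - d) / ifelse(w == 0, 1, w))))
    sum(vol * frac)
  }, numeric(1))
}

#' Cumulative DVH curve
#'
#' Evaluates the cumulative curve (volume receiving at least a given dose)
#' at the edges of the occupied bins.  The curve is non-increasing and
#' equals the total volume at dose 0.
#'
#' @param x A [dvh()].
#' @param at Optional dose values at which to evaluate; defaults to the
#'   sorted unique edges of the occupied bins, prepended with 0.
#' @return A data.frame with columns `dose` and `volume`.
#' @export
cumulative_dvh <- function(x, at = NULL) {
  stopifnot(inherits(x, "dvh"))
  if (is.null(at)) {
    occ <- x$volume > 0
    at <- sort(unique(c(0, x$bin_lower[occ], x$bin_upper[occ])))
  }
  data.frame(dose = at, volume = dvh_cum_at_dose(x, at))
}

# Dose at which the cumulative curve reaches `target` volume: walk the
# occupied bins from hottest to coldest, interpolating linearly *within*
# the bin where the crossing occurs (mass is uniform within a bin; the
# curve is flat across empty gaps).  At a plateau boundary this returns the
# highest dose still covering the target volume.
dvh_dose_at_cum <- function(x, target) {
  occ <- x$volume > 0
  if (!any(occ)) abort_isodvh("DVH has no occupied bins", "empty_structure")
  total <- sum(x$volume)
  if (target > total + 1e-9 * max(1, total))
    abort_isodvh("requested volume exceeds total structure volume", "parameter")
  lo <- x$bin_lower[occ]; hi <- x$bin_upper[occ]; vol <- x$volume[occ]
  ord <- order(lo, decreasing = TRUE)     # hottest first
  lo <- lo[ord]; hi <- hi[ord]; vol <- vol[ord]
  if (target <= 0) return(hi[1])
  above <- 0
  for (k in seq_along(vol)) {
    if (target <= above + vol[k] + 1e-12 * max(1, total))
      return(hi[k] - (min(target, above + vol[k]) - above) / vol[k] *
               (hi[k] - lo[k]))
    above <- above + vol[k]
  }
  lo[length(lo)]
}

#' DVH summary statistics
#'
#' Computes a statistic from a DVH using the field's standard mini-language:
#' `"Dmin"`, `"Dmax"`, `"Dmean"`, `"D<x>%"` (minimum dose to the hottest
#' x percent of the volume), `"D<x>cc"` (hottest x cm3), and `"V<x>Gy"`
#' (volume receiving at least x Gy).
#'
#' Percentile statistics are read from the cumulative curve with linear
#' interpolation between bin edges; at a plateau the highest dose still
#' covering the requested volume is returned.  `Dmax`/`Dmin` are reported as
#' the center of the highest/lowest occupied bin (upper edge minus half a
#' bin width), reflecting the voxel-center binning of [dvh_from_grid()].
#'
#' @param x A [dvh()].
#' @param metric Statistic name, e.g. `"D98%"`, `"D2cc"`, `"V50Gy"`.
#' @return The statistic's value: a dose in Gy for `D*` metrics, a volume
#'   (in the DVH's volume unit) for `V*` metrics.
#' @examples
#' d <- dvh(c(50, 50), bin_lower = c(10, 20), bin_width = 1)
#' dvh_statistic(d, "Dmean")
#' dvh_statistic(d, "D50%")
#' @export
dvh_statistic <- function(x, metric) {
  stopifnot(inherits(x, "dvh"))
  total <- sum(x$volume)
  if (total <= 0 || length(x$volume) == 0L)
    abort_isodvh("DVH is empty", "empty_structure")
  occ <- which(x$volume > 0)
  if (metric == "Dmean")
    return(sum(x$volume * dvh_bin_centers(x)) / total)
  if (metric == "Dmax") {
    i <- max(occ)
    return(x$bin_upper[i] - (x$bin_upper[i] - x$bin_lower[i]) / 2)
  }
  if (metric == "Dmin") {
    i <- min(occ)
    return(x$bin_lower[i] + (x$bin_upper[i] - x$bin_lower[i]) / 2)
  }
  m <- regmatches(metric, regexec("^D([0-9.]+)%$", metric))[[1]]
  if (length(m)) {
    pct <- as.numeric(m[2])
    if (pct < 0 || pct > 100)
      abort_isodvh("percent metric requires x in [0, 100]", "parameter")
    return(dvh_dose_at_cum(x, pct / 100 * total))
  }
  m <- regmatches(metric, regexec("^D([0-9.]+)cc$", metric))[[1]]
  if (length(m)) {
    cc <- as.numeric(m[2])
    if (x$volume_unit != "cm3")
      abort_isodvh("D<x>cc requires absolute volumes", "parameter")
    if (cc > total)
      abort_isodvh("requested volume exceeds structure volume", "parameter")
    return(dvh_dose_at_cum(x, cc))
  }
  m <- regmatches(metric, regexec("^V([0-9.]+)Gy$", metric))[[1]]
  if (length(m))
    return(dvh_cum_at_dose(x, as.numeric(m[2])))
  abort_isodvh(paste("unknown DVH metric:", metric), "parameter")
}

#' Rescale DVH volumes to percent of total
#'
#' @param x A [dvh()] with absolute volumes and total volume > 0.
#' @return The DVH with volumes in percent (summing to 100); the absolute
#'   total is retained so [rescale_to_absolute()] recovers the input.
#' @export
rescale_to_relative <- function(x) {
  stopifnot(inherits(x, "dvh"))
  total <- sum(x$volume)
  if (x$volume_unit == "percent") return(x)
  if (total <= 0)
    abort_isodvh("cannot rescale a zero-volume structure", "empty_structure")
  dvh_new(x$volume * 100 / total, x$bin_lower, x$bin_upper, x$structure,
          x$scale, x$alpha_beta_tag, volume_unit = "percent",
          total_volume = total)
}

#' Restore absolute volumes on a relative DVH
#'
#' @param x A [dvh()] previously rescaled by [rescale_to_relative()].
#' @return The DVH with volumes in cm3.
#' @export
rescale_to_absolute <- function(x) {
  stopifnot(inherits(x, "dvh"))
  if (x$volume_unit == "cm3") return(x)
  dvh_new(x$volume * x$total_volume / 100, x$bin_lower, x$bin_upper,
          x$structure, x$scale, x$alpha_beta_tag, volume_unit = "cm3",
          total_volume = x$total_volume)
}

#' Scale the dose axis of a DVH
#'
#' Used when a revised plan reuses the original plan's dose distribution
#' shape with a different total physical dose: the dose axis is multiplied
#' by `factor`, volumes are unchanged.
#'
#' @param x A [dvh()].
#' @param factor Positive scale factor.
#' @return The scaled [dvh()].
#' @export
scale_dvh <- function(x, factor) {
  stopifnot(inherits(x, "dvh"))
  if (factor <= 0)
    abort_isodvh("factor must be > 0", "invalid_parameter")
  dvh_new(x$volume, x$bin_lower * factor, x$bin_upper * factor, x$structure,
          x$scale, x$alpha_beta_tag, x$volume_unit, x$total_volume)
}

# Bin-wise sum of dose axes across DVHs sharing the same volume vector
# (same structure geometry and normalized dose shape).  Used to accumulate
# per-segment EQD2 histograms into a whole-course histogram.
sum_dvh_dose <- function(dvhs) {
  stopifnot(length(dvhs) >= 1)
  v <- dvhs[[1]]$volume
  for (d in dvhs[-1])
    if (length(d$volume) != length(v) || any(abs(d$volume - v) > 1e-9))
      abort_isodvh("DVHs must share identical bin volumes to be dose-summed",
                   "consistency")
  lo <- Reduce(`+`, lapply(dvhs, `[[`, "bin_lower"))
  hi <- Reduce(`+`, lapply(dvhs, `[[`, "bin_upper"))
  d1 <- dvhs[[1]]
  dvh_new(v, lo, hi, d1$structure, d1$scale, d1$alpha_beta_tag,
          d1$volume_unit, d1$total_volume)
}
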