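#' Specify a synthetic phantom
#'
#' Describes a regular dose grid, a set of geometric structures and an
#' analytic dose field, from which [build_phantom()] produces a
#' [dose_grid()], polygonal contours and closed-form expected DVHs.  It is
#' the test bed standing in for clinical plan exports: every downstream
#' module can be exercised against analytically known answers.
#'
#' @param shape Grid dimensions `(rows, cols, slices)`.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm.
#' @param origin Patient coordinates of the first voxel center (mm).
#' @param structures List of structure primitives, each a list with
#'   `type` (`"sphere"`, `"box"` or `"shell"`), `name`, `center` (mm) and
#'   size parameters: `radius` for spheres, `size` (full widths, mm) for
#'   boxes, `r_inner`/`r_outer` for shells.
#' @param field Dose field: `list(type = "uniform", dose = ...)`,
#'   `list(type = "linear", axis = 1|2|3, d0 = ..., gradient = Gy/mm)`
#'   (dose = d0 + gradient * coordinate along the axis), or
#'   `list(type = "gaussian", center = ..., amplitude = ..., sigma = mm)`.
#' @param noise_sd Standard deviation of optional Gaussian dose noise (Gy).
#' @param seed Seed used when `noise_sd > 0`, making outputs byte-identical
#'   across runs.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing, origin = c(0, 0, 0),
                         structures = list(), field = list(type = "uniform",
                                                           dose = 10),
                         noise_sd = 0, seed = 1L) {
  if (length(shape) != 3L || any(shape < 1))
    abort_isodvh("shape must be three positive integers", "spec")
  if (length(spacing) != 3L || any(spacing <= 0))
    abort_isodvh("spacing must be three positive numbers", "spec")
  nm <- vapply(structures, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    abort_isodvh("structure names must be unique", "spec")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 origin = as.numeric(origin), structures = structures,
                 field = field, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_coords <- function(spec) {
  list(x = spec$origin[1] + (seq_len(spec$shape[2]) - 1) * spec$spacing[1],
       y = spec$origin[2] + (seq_len(spec$shape[1]) - 1) * spec$spacing[2],
       z = spec$origin[3] + (seq_len(spec$shape[3]) - 1) * spec$spacing[3])
}

phantom_dose_values <- function(spec) {
  co <- phantom_coords(spec)
  f <- spec$field
  dm <- spec$shape
  vals <- switch(f$type,
    uniform = array(f$dose, dm),
    linear = {
      coord <- switch(f$axis, `1` = co$x, `2` = co$y, `3` = co$z)
      per <- f$d0 + f$gradient * coord
      switch(f$axis,
             `1` = aperm(array(rep(per, each = dm[1]), c(dm[1], dm[2], dm[3])),
                         c(1, 2, 3)),
             `2` = array(rep(per, times = dm[2] * dm[3]), dm),
             `3` = aperm(array(rep(per, each = dm[1] * dm[2]), dm), c(1, 2, 3)))
    },
    gaussian = {
      g <- expand.grid(y = co$y, x = co$x, z = co$z)
      r2 <- (g$x - f$center[1])^2 + (g$y - f$center[2])^2 +
            (g$z - f$center[3])^2
      array(f$amplitude * exp(-r2 / (2 * f$sigma^2)), dm)
    },
    abort_isodvh(paste("unknown field type:", f$type), "spec"))
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vals[] <- pmax(0, vals + stats::rnorm(prod(dm), 0, spec$noise_sd))
  }
  vals
}

structure_inside <- function(st, x, y, z) {
  # x, y, z: equal-length vectors of voxel-center coordinates
  switch(st$type,
    sphere = (x - st$center[1])^2 + (y - st$center[2])^2 +
             (z - st$center[3])^2 <= st$radius^2,
    box = abs(x - st$center[1]) <= st$size[1] / 2 &
          abs(y - st$center[2]) <= st$size[2] / 2 &
          abs(z - st$center[3]) <= st$size[3] / 2,
    shell = {
      r2 <- (x - st$center[1])^2 + (y - st$center[2])^2 +
            (z - st$center[3])^2
      r2 <= st$r_outer^2 & r2 > st$r_inner^2
    },
    abort_isodvh(paste("unknown structure type:", st$type), "spec"))
}

structure_mask_for <- function(spec, st) {
  co <- phantom_coords(spec)
  g <- expand.grid(y = co$y, x = co$x, z = co$z)
  arr <- array(structure_inside(st, g$x, g$y, g$z), spec$shape)
  structure_mask(st$name, arr, voxel_volume_cc(spec$spacing))
}

# Polygonal contours approximating a primitive, one closed polygon per grid
# slice intersecting it (two concentric polygons per slice for shells,
# combined downstream by the even-odd rule).
structure_contours_for <- function(spec, st, n_vertices = 96L) {
  co <- phantom_coords(spec)
  polys <- list()
  circle <- function(cx, cy, r, z) {
    th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    cbind(cx + r * cos(th), cy + r * sin(th), z)
  }
  for (z in co$z) {
    if (st$type == "sphere" || st$type == "shell") {
      router <- if (st$type == "sphere") st$radius else st$r_outer
      dz2 <- router^2 - (z - st$center[3])^2
      if (dz2 <= 0) next
      polys[[length(polys) + 1L]] <-
        circle(st$center[1], st$center[2], sqrt(dz2), z)
      if (st$type == "shell") {
        din2 <- st$r_inner^2 - (z - st$center[3])^2
        if (din2 > 0)
          polys[[length(polys) + 1L]] <-
            circle(st$center[1], st$center[2], sqrt(din2), z)
      }
    } else if (st$type == "box") {
      if (abs(z - st$center[3]) > st$size[3] / 2) next
      hx <- st$size[1] / 2; hy <- st$size[2] / 2
      polys[[length(polys) + 1L]] <-
        cbind(st$center[1] + c(-hx, hx, hx, -hx),
              st$center[2] + c(-hy, -hy, hy, hy), z)
    }
  }
  contour_set(0L, st$name, polys)
}

analytic_volume <- function(st) {
  switch(st$type,
    sphere = 4 / 3 * pi * st$radius^3 / 1000,
    box = prod(st$size) / 1000,
    shell = 4 / 3 * pi * (st$r_outer^3 - st$r_inner^3) / 1000)
}

# Closed-form cumulative DVH (volume in cm3 with dose >= D) for the
# supported structure/field combinations.
analytic_cumulative <- function(spec, st) {
  f <- spec$field
  vol <- analytic_volume(st)
  if (f$type == "uniform") {
    function(D) ifelse(D <= f$dose, vol, 0)
  } else if (f$type == "linear" && st$type == "box") {
    ax <- f$axis
    lo_c <- st$center[ax] - st$size[ax] / 2
    hi_c <- st$center[ax] + st$size[ax] / 2
    d_lo <- f$d0 + f$gradient * (if (f$gradient >= 0) lo_c else hi_c)
    d_hi <- f$d0 + f$gradient * (if (f$gradient >= 0) hi_c else lo_c)
    function(D) vol * pmin(1, pmax(0, (d_hi - D) / (d_hi - d_lo)))
  } else if (f$type == "gaussian" && st$type == "sphere" &&
             sqrt(sum((f$center - st$center)^2)) < 1e-9) {
    A <- f$amplitude; s <- f$sigma; R <- st$radius
    function(D) {
      r <- rep(0, length(D))
      pos <- D > 0 & D < A
      r[pos] <- s * sqrt(2 * log(A / D[pos]))
      r[D <= 0] <- Inf
      4 / 3 * pi * pmin(r, R)^3 / 1000
    }
  } else {
    abort_isodvh(sprintf("no closed-form DVH for %s structure in %s field",
                         st$type, f$type), "spec")
  }
}

# Analytic cumulative curve discretized onto the engine's bin grid: bin
# [k bw, (k+1) bw) holds V(k bw) - V((k+1) bw).  Volume normalization uses
# the exact primitive volume.
analytic_dvh <- function(spec, st, bin_width) {
  cumf <- analytic_cumulative(spec, st)
  co <- phantom_coords(spec)
  dmax <- switch(spec$field$type,
                 uniform = spec$field$dose,
                 linear = max(spec$field$d0 + spec$field$gradient *
                                range(switch(spec$field$axis, `1` = co$x,
                                             `2` = co$y, `3` = co$z))),
                 gaussian = spec$field$amplitude)
  edges <- seq(0, (floor(dmax / bin_width) + 1) * bin_width, by = bin_width)
  cums <- cumf(edges)
  dvh_new(pmax(0, utils::head(cums, -1) - utils::tail(cums, -1)),
          utils::head(edges, -1), utils::tail(edges, -1),
          structure = st$name, scale = "physical")
}

#' Build a synthetic phantom
#'
#' Generates the dose grid (quantized to the 32-bit DICOM scaling step it
#' will be written with, so DICOM round trips are bit-exact), the voxel
#' masks and polygonal contours of every structure, and -- where a closed
#' form exists (uniform field over any primitive, linear gradient over a
#' box, centered Gaussian over a sphere) -- the analytic expected DVH
#' discretized at `bin_width`.
#'
#' @param spec A [phantom_spec()].
#' @param bin_width Bin width (Gy) at which expected DVHs are evaluated.
#' @return A list with elements `grid` ([dose_grid()]), `masks`,
#'   `contours`, and `expected_dvh` (named lists per structure;
#'   `expected_dvh` entries are `NULL` where no closed form applies).
#' @export
build_phantom <- function(spec, bin_width = 0.01) {
  stopifnot(inherits(spec, "phantom_spec"))
  vals <- phantom_dose_values(spec)
  # Quantization step: DS-representable decimal (10 significant digits, as
  # written into DoseGridScaling) with headroom so integers stay < 2^31 - 2.
  scaling <- as.numeric(sprintf("%.10g",
                                max(max(vals), .Machine$double.eps) /
                                  (2^31 - 1000)))
  vals <- round(vals / scaling) * scaling   # pre-quantize: DICOM-exact
  grid <- dose_grid(vals, spec$spacing, spec$origin, dose_scaling = scaling)
  masks <- list(); contours <- list(); expected <- list()
  for (i in seq_along(spec$structures)) {
    st <- spec$structures[[i]]
    masks[[st$name]] <- structure_mask_for(spec, st)
    cs <- structure_contours_for(spec, st)
    cs$roi_number <- i
    contours[[st$name]] <- cs
    expected[[st$name]] <- tryCatch(analytic_dvh(spec, st, bin_width),
                                    isodvh_error_spec = function(e) NULL)
  }
  list(grid = grid, masks = masks, contours = contours,
       expected_dvh = expected)
}

#' Scalar schedule fixtures for the five interrupted case studies
#'
#' Returns the published prescription summary for one of five anonymized
#' Category-1 case studies (left tonsil, larynx, vocal cord, right lung,
#' parotid) whose courses were interrupted for 12--13 days: the intended
#' schedule, the pre-gap block actually delivered, and the remaining block
#' delivered without compensation, all as [schedule_summary()] objects with
#' cumulative overall times, plus the C1 tumor parameter set
#' (\eqn{\alpha/\beta} = 10 Gy, K = 0.9 Gy/day, \eqn{T_{delay}} = 28 d).
#'
#' @param label One of `"A"` ... `"E"`.
#' @return A list with `label`, `site`, `params`, `gap_days`, and
#'   schedules `intended`, `pre_gap`, `post_gap` (the uncompensated
#'   remainder; its `T` is the final overall time of the interrupted
#'   course).
#' @export
build_case_study <- function(label = c("A", "B", "C", "D", "E")) {
  label <- match.arg(label)
  tab <- list(
    A = list(site = "left tonsil", d = 2.2, N = 30, T = 42, gap = 12,
             pre = c(18, 26), post = c(12, 52)),
    B = list(site = "larynx", d = 2.0, N = 35, T = 50, gap = 12,
             pre = c(31, 46), post = c(4, 59)),
    C = list(site = "vocal cord", d = 2.0, N = 35, T = 50, gap = 13,
             pre = c(6, 9), post = c(29, 63)),
    D = list(site = "right lung", d = 2.0, N = 30, T = 44, gap = 12,
             pre = c(12, 18), post = c(18, 51)),
    E = list(site = "parotid", d = 2.0, N = 30, T = 43, gap = 12,
             pre = c(7, 10), post = c(23, 49))
  )[[label]]
  list(label = label, site = tab$site,
       params = tissue_params(paste("PTV", tab$site), 10, "tumor",
                              K = 0.9, T_delay = 28),
       gap_days = tab$gap,
       intended = schedule_summary(tab$N, tab$d, tab$T),
       pre_gap = schedule_summary(tab$pre[1], tab$d, tab$pre[2]),
       post_gap = schedule_summary(tab$post[1], tab$d, tab$post[2]))
}
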