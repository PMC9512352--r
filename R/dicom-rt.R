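UID_RT_DOSE   <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RT_STRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"

#' Contour set for one region of interest
#'
#' Per-slice closed polygons in patient coordinates describing one ROI of an
#' RT-Structure-Set.
#'
#' @param roi_number Integer ROI identifier.
#' @param roi_name ROI name.
#' @param contours List of numeric matrices with columns x, y, z (mm); each
#'   polygon must be planar in z and have at least 3 vertices.
#' @param frame_of_reference Frame-of-reference UID (free text here).
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(roi_number, roi_name, contours,
                        frame_of_reference = "") {
  for (p in contours) {
    if (!is.matrix(p) || ncol(p) != 3 || nrow(p) < 3)
      abort_isodvh("each contour must be an n x 3 matrix with n >= 3",
                   "invalid_parameter")
    if (diff(range(p[, 3])) > 1e-6)
      abort_isodvh("contour polygons must be planar in z", "invalid_parameter")
  }
  structure(list(roi_number = as.integer(roi_number),
                 roi_name = as.character(roi_name),
                 contours = contours,
                 frame_of_reference = as.character(frame_of_reference)),
            class = "contour_set")
}

#' Write a dose grid as a DICOM RT-Dose file
#'
#' Doses are quantized to 32-bit unsigned integers with a dose-grid scaling
#' factor.  If the grid already records its quantization step
#' (`dose_scaling`), that step is reused so a grid built by the phantom
#' factory round-trips bit-exactly.
#'
#' @param grid [dose_grid()].
#' @param path Output file path.
#' @param frame_of_reference Frame-of-reference UID shared with the matching
#'   structure set.
#' @return `path`, invisibly.
#' @export
write_rt_dose <- function(grid, path, frame_of_reference = dicom_new_uid()) {
  stopifnot(inherits(grid, "dose_grid"))
  dm <- dim(grid$values)
  scaling <- grid$dose_scaling
  if (is.na(scaling))   # DS-representable decimal so the reader recovers it
    scaling <- as.numeric(sprintf("%.10g",
                                  max(max(grid$values),
                                      .Machine$double.eps) / (2^31 - 1000)))
  ints <- as.integer(round(grid$values / scaling))
  if (any(ints < 0) || any(ints > 2^31 - 2))
    abort_isodvh("dose values out of range for 32-bit quantization", "format")
  pix <- writeBin(as.integer(aperm(array(ints, dm), c(2, 1, 3))),
                  raw(), size = 4, endian = "little")
  offsets <- (seq_len(dm[3]) - 1) * grid$spacing[3]
  sop_uid <- dicom_new_uid()
  ds <- list(
    el(0x0008, 0x0016, "UI", UID_RT_DOSE),
    el(0x0008, 0x0018, "UI", sop_uid),
    el(0x0008, 0x0060, "CS", "RTDOSE"),
    el(0x0020, 0x0032, "DS", grid$origin),
    el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    el(0x0020, 0x0052, "UI", frame_of_reference),
    el(0x0028, 0x0002, "US", 1L),
    el(0x0028, 0x0004, "CS", "MONOCHROME2"),
    el(0x0028, 0x0008, "IS", dm[3]),
    el(0x0028, 0x0010, "US", dm[1]),
    el(0x0028, 0x0011, "US", dm[2]),
    el(0x0028, 0x0030, "DS", c(grid$spacing[2], grid$spacing[1])),
    el(0x0028, 0x0100, "US", 32L),
    el(0x0028, 0x0101, "US", 32L),
    el(0x0028, 0x0102, "US", 31L),
    el(0x0028, 0x0103, "US", 0L),
    el(0x3004, 0x0002, "CS", "GY"),
    el(0x3004, 0x0004, "CS", "PHYSICAL"),
    el(0x3004, 0x000A, "CS", "PLAN"),
    el(0x3004, 0x000C, "DS", offsets),
    el(0x3004, 0x000E, "DS", scaling),
    el(0x7FE0, 0x0010, "OW", pix)
  )
  dicom_write_file(path, UID_RT_DOSE, sop_uid, ds)
}

#' Read a DICOM RT-Dose file into a dose grid
#'
#' Supports the explicit-VR little-endian, uncompressed, uniform-frame-offset
#' dialect written by [write_rt_dose()] (and by mainstream planning systems
#' exporting plan doses with 32-bit pixels).
#'
#' @param path Path to an RT-Dose file.
#' @return A [dose_grid()]; values are `stored integer * DoseGridScaling`,
#'   the grid's `dose_scaling` records the scaling factor, and the dose
#'   summation type is attached as attribute `summation_type`.
#' @export
read_rt_dose <- function(path) {
  d <- dicom_read_file(path)
  modality <- d[["0008,0060"]]
  if (!identical(modality, "RTDOSE"))
    abort_isodvh(paste("not an RT-Dose object; modality:",
                       modality %||% "(missing)"), "type")
  scaling <- d[["3004,000E"]]
  offsets <- d[["3004,000C"]]
  if (is.null(scaling) || is.null(offsets))
    abort_isodvh("RT-Dose missing dose grid scaling or frame offsets",
                 "format")
  nrow_ <- d[["0028,0010"]]; ncol_ <- d[["0028,0011"]]
  nfrm <- as.integer(d[["0028,0008"]])
  if (nfrm > 1) {
    dz <- diff(offsets)
    if (any(abs(dz - dz[1]) > 1e-6))
      abort_isodvh("non-uniform frame offsets are not supported", "format")
    dz <- dz[1]
  } else dz <- 1
  bits <- d[["0028,0100"]]
  if (!identical(as.integer(bits), 32L))
    abort_isodvh("only 32-bit dose grids are supported", "format")
  ints <- readBin(d[["7FE0,0010"]], "integer", n = nrow_ * ncol_ * nfrm,
                  size = 4, endian = "little")
  vals <- aperm(array(ints, dim = c(ncol_, nrow_, nfrm)), c(2, 1, 3)) * scaling
  ps <- d[["0028,0030"]]  # (row spacing, col spacing) = (dy, dx)
  g <- dose_grid(vals, spacing = c(ps[2], ps[1], dz),
                 origin = d[["0020,0032"]], dose_scaling = scaling)
  attr(g, "summation_type") <- d[["3004,000A"]]
  attr(g, "frame_of_reference") <- d[["0020,0052"]]
  g
}

#' Write contour sets as a DICOM RT-Structure-Set file
#'
#' @param contour_sets List of [contour_set()] objects.
#' @param path Output file path.
#' @param frame_of_reference Frame-of-reference UID.
#' @return `path`, invisibly.
#' @export
write_rt_struct <- function(contour_sets, path,
                            frame_of_reference = dicom_new_uid()) {
  roi_items <- lapply(contour_sets, function(cs)
    dicom_enc_dataset(list(
      el(0x3006, 0x0022, "IS", cs$roi_number),
      el(0x3006, 0x0024, "UI", frame_of_reference),
      el(0x3006, 0x0026, "LO", cs$roi_name))))
  contour_items <- lapply(contour_sets, function(cs) {
    c_items <- lapply(cs$contours, function(p)
      dicom_enc_dataset(list(
        el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        el(0x3006, 0x0046, "IS", nrow(p)),
        el(0x3006, 0x0050, "DS", as.vector(t(p))))))
    # ContourSequence (3006,0040) precedes ReferencedROINumber (3006,0084)
    c(if (length(c_items)) dicom_enc_sequence(0x3006, 0x0040, c_items)
      else raw(0),
      dicom_enc_element(0x3006, 0x0084, "IS", cs$roi_number))
  })
  sop_uid <- dicom_new_uid()
  ds <- list(
    el(0x0008, 0x0016, "UI", UID_RT_STRUCT),
    el(0x0008, 0x0018, "UI", sop_uid),
    el(0x0008, 0x0060, "CS", "RTSTRUCT"),
    el(0x3006, 0x0002, "SH", "isodvh"),
    sq(0x3006, 0x0020, roi_items),
    sq(0x3006, 0x0039, contour_items)
  )
  dicom_write_file(path, UID_RT_STRUCT, sop_uid, ds)
}

#' Read a DICOM RT-Structure-Set file
#'
#' @param path Path to an RT-Structure-Set file.
#' @return A named list of [contour_set()] objects (names = ROI names,
#'   preserved verbatim; order follows the structure-set ROI sequence).
#'   ROIs without contour data yield an empty contour set with a warning.
#' @export
read_rt_struct <- function(path) {
  d <- dicom_read_file(path)
  if (!identical(d[["0008,0060"]], "RTSTRUCT"))
    abort_isodvh("not an RT-Structure-Set object", "type")
  rois <- d[["3006,0020"]] %||% list()
  roic <- d[["3006,0039"]] %||% list()
  by_number <- list()
  for (item in roic) {
    num <- as.character(item[["3006,0084"]])
    polys <- lapply(item[["3006,0040"]] %||% list(), function(ci) {
      xyz <- ci[["3006,0050"]]
      matrix(xyz, ncol = 3, byrow = TRUE,
             dimnames = list(NULL, c("x", "y", "z")))
    })
    by_number[[num]] <- polys
  }
  out <- list()
  for (item in rois) {
    num <- item[["3006,0022"]]
    name <- item[["3006,0026"]]
    polys <- by_number[[as.character(num)]]
    if (is.null(polys) || length(polys) == 0L) {
      warning(sprintf("ROI '%s' (#%d) has no contour data; returning empty set",
                      name, num), call. = FALSE)
      polys <- list()
    }
    out[[name]] <- contour_set(num, name, polys,
                               item[["3006,0024"]] %||% "")
  }
  out
}
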