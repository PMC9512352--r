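simple_phantom <- function() {
  phantom_spec(shape = c(20, 20, 12), spacing = c(3, 3, 3),
               origin = c(-28.5, -28.5, -16.5),
               structures = list(
                 list(type = "sphere", name = "ball", center = c(0, 0, 0),
                      radius = 15),
                 list(type = "box", name = "slab", center = c(0, 0, 0),
                      size = c(30, 24, 18))),
               field = list(type = "linear", axis = 1, d0 = 20,
                            gradient = 0.3))
}

test_that("RT-Dose write/read round-trips the grid bit-exactly", {
  ph <- build_phantom(simple_phantom())
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rt_dose(ph$grid, path)
  g2 <- read_rt_dose(path)
  expect_identical(g2$values, ph$grid$values)
  expect_equal(g2$spacing, ph$grid$spacing)
  expect_equal(g2$origin, ph$grid$origin)
  expect_equal(g2$dose_scaling, ph$grid$dose_scaling)
  expect_identical(attr(g2, "summation_type"), "PLAN")
})

test_that("stored integers scale by the dose grid scaling on read", {
  vals <- array(c(0, 1, 2, 3), c(2, 2, 1)) * 0.5
  g <- dose_grid(vals, c(1, 1, 1), dose_scaling = 0.5)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rt_dose(g, path)
  g2 <- read_rt_dose(path)
  expect_equal(g2$dose_scaling, 0.5)
  expect_identical(g2$values, vals)   # integers 0..3 times 0.5
})

test_that("RT-Dose reader rejects wrong modality and malformed offsets", {
  ph <- build_phantom(simple_phantom())
  rd <- withr::local_tempfile(fileext = ".dcm")
  rs <- withr::local_tempfile(fileext = ".dcm")
  write_rt_dose(ph$grid, rd)
  write_rt_struct(ph$contours, rs)
  expect_error(read_rt_dose(rs), class = "isodvh_error_type")
  expect_error(read_rt_struct(rd), class = "isodvh_error_type")
  # corrupt the frame offsets to a non-uniform vector
  bytes <- readBin(rd, "raw", file.size(rd))
  tag <- as.raw(c(0x04, 0x30, 0x0c, 0x00))
  hit <- which(vapply(seq_len(length(bytes) - 3), function(i)
    all(bytes[i:(i + 3)] == tag), logical(1)))[1]
  len <- readBin(bytes[(hit + 6):(hit + 7)], "integer", size = 2,
                 signed = FALSE, endian = "little")
  offsets <- paste(c(0, 3, 7, seq(9, by = 3,
                                  length.out = 9)), collapse = "\\")
  payload <- charToRaw(formatC(offsets, width = len, flag = "-"))
  bytes[(hit + 8):(hit + 7 + len)] <- payload[seq_len(len)]
  bad <- withr::local_tempfile(fileext = ".dcm")
  writeBin(bytes, bad)
  expect_error(read_rt_dose(bad), class = "isodvh_error_format")
  expect_error(read_rt_dose(withr::local_tempfile(fileext = ".txt",
                                                  lines = "not dicom")),
               class = "isodvh_error_format")
})

test_that("RT-Struct preserves ROI names/numbers verbatim and order-independently", {
  ph <- build_phantom(simple_phantom())
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rt_struct(rev(ph$contours), path)
  back <- read_rt_struct(path)
  expect_setequal(names(back), c("ball", "slab"))
  expect_equal(back$ball$roi_number, ph$contours$ball$roi_number)
  expect_equal(length(back$ball$contours), length(ph$contours$ball$contours))
  expect_equal(back$slab$contours[[1]], ph$contours$slab$contours[[1]],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ROI without contour data yields a warning and an empty set", {
  empty <- contour_set(7L, "ghost", list())
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rt_struct(list(empty), path)
  expect_warning(out <- read_rt_struct(path), "no contour data")
  expect_equal(length(out$ghost$contours), 0)
})

test_that("rasterization matches brute-force point-in-primitive tests", {
  spec <- simple_phantom()
  ph <- build_phantom(spec)
  for (nm in names(ph$contours)) {
    m <- rasterize(ph$contours[[nm]], ph$grid)
    direct <- ph$masks[[nm]]
    # sphere contours are 96-gon approximations: allow a thin rim of
    # disagreement; the box is exact
    mismatch <- sum(xor(m$array, direct$array))
    if (nm == "slab") expect_equal(mismatch, 0)
    else expect_lt(mismatch / sum(direct$array), 0.02)
  }
})

test_that("even-odd rule carves shell holes and circle volume converges", {
  spec <- phantom_spec(shape = c(60, 60, 5), spacing = c(1, 1, 2),
                       origin = c(-29.5, -29.5, -4),
                       structures = list(
                         list(type = "shell", name = "ring", center = c(0, 0, 0),
                              r_inner = 10, r_outer = 20)),
                       field = list(type = "uniform", dose = 10))
  ph <- build_phantom(spec)
  m <- rasterize(ph$contours$ring, ph$grid)
  # central voxel of the central slice is inside the hole
  expect_false(m$array[30, 30, 3])
  expect_lt(abs(m$volume - ph$masks$ring$volume) / ph$masks$ring$volume, 0.02)
  # circle area pi*r^2*dz within 2% on a 1 mm grid
  slice_area_cc <- sum(m$array[, , 3]) * 1 * 1 * 2 / 1000
  expect_lt(abs(slice_area_cc - pi * (20^2 - 10^2) * 2 / 1000) /
              (pi * (20^2 - 10^2) * 2 / 1000), 0.02)
})

test_that("contour planes off the slice grid raise a geometry error", {
  ph <- build_phantom(simple_phantom())
  cs <- ph$contours$slab
  cs$contours[[1]][, 3] <- cs$contours[[1]][, 3] + 30  # beyond the grid
  expect_error(rasterize(cs, ph$grid), class = "isodvh_error_geometry")
})

test_that("DVH tables round-trip exactly in CSV and JSON", {
  d <- dvh(c(0.25, 1 / 3, 2.5), bin_lower = c(0.1, 7.3, 31.00625),
           bin_width = 0.01, structure = "PTV test", scale = "physical")
  conv <- convert_dvh(d, schedule_summary(30, 2, 44), c1_params())
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_dvh_table(conv, path)
    back <- read_dvh_table(path)
    expect_identical(back$bin_lower, conv$bin_lower)
    expect_identical(back$bin_upper, conv$bin_upper)
    expect_identical(back$volume, conv$volume)
    expect_identical(back$scale, "EQD2")
    expect_equal(back$alpha_beta_tag, 10)
    expect_identical(back$structure, "PTV test")
  }
})
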