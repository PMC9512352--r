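# Minimal DICOM codec: explicit-VR little-endian only, uncompressed,
# defined- or undefined-length sequences on read, defined lengths on write.
# Scope is deliberately narrow -- enough to write and re-read the RT-Dose /
# RT-Structure-Set dialect produced by the phantom factory; it is not a
# general DICOM implementation.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_UID_ROOT <- "1.2.826.0.1.3680043.10.9410."  # package UID namespace

dicom_new_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste0(DICOM_UID_ROOT,
           format(as.integer(Sys.time()) %% 100000000L),
           ".", sample.int(99999L, 1), ".", counter)
  }
})

dicom_tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

# ---- encoding -------------------------------------------------------------

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.pad_even <- function(bytes, pad = as.raw(0)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

dicom_enc_value <- function(vr, value) {
  switch(vr,
    US = do.call(c, lapply(as.integer(value), .u16)),
    UL = do.call(c, lapply(as.integer(value), .u32)),
    UI = .pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0)),
    DS = .pad_even(charToRaw(paste(
           vapply(value, function(v) sprintf("%.10g", v), character(1)),
           collapse = "\\")), charToRaw(" ")),
    IS = .pad_even(charToRaw(paste(as.integer(value), collapse = "\\")),
                   charToRaw(" ")),
    OW = value,  # already raw
    OB = value,
    # string VRs: CS, LO, SH, PN, DA, TM, ST, LT
    .pad_even(charToRaw(paste(value, collapse = "\\")), charToRaw(" "))
  )
}

dicom_enc_element <- function(group, element, vr, value) {
  body <- if (vr == "SQ") value else dicom_enc_value(vr, value)
  head <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .u32(length(body)), body)
  } else {
    if (length(body) > 65534L)
      abort_isodvh("value too long for short-form VR", "format")
    c(head, .u16(length(body)), body)
  }
}

# items: list of raw vectors (encoded item datasets)
dicom_enc_sequence <- function(group, element, items) {
  body <- do.call(c, c(lapply(items, function(it)
    c(.u16(0xFFFE), .u16(0xE000), .u32(length(it)), it)), list(raw(0))))
  dicom_enc_element(group, element, "SQ", body)
}

# elements: list of lists(group, element, vr, value) -- must be pre-sorted.
dicom_enc_dataset <- function(elements) {
  do.call(c, c(lapply(elements, function(e)
    if (e$vr == "SQ") dicom_enc_sequence(e$group, e$element, e$items)
    else dicom_enc_element(e$group, e$element, e$vr, e$value)), list(raw(0))))
}

el <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}
sq <- function(group, element, items) {
  list(group = group, element = element, vr = "SQ", items = items)
}

dicom_write_file <- function(path, sop_class_uid, sop_instance_uid, dataset) {
  meta <- c(
    dicom_enc_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dicom_enc_element(0x0002, 0x0002, "UI", sop_class_uid),
    dicom_enc_element(0x0002, 0x0003, "UI", sop_instance_uid),
    dicom_enc_element(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT_LE),
    dicom_enc_element(0x0002, 0x0012, "UI", paste0(DICOM_UID_ROOT, "1"))
  )
  out <- c(raw(128), charToRaw("DICM"),
           dicom_enc_element(0x0002, 0x0000, "UL", length(meta)),
           meta, dicom_enc_dataset(dataset))
  writeBin(out, path)
  invisible(path)
}

# ---- decoding -------------------------------------------------------------

# Cursor-based parser over a raw vector.
dicom_parse <- function(bytes, pos, end) {
  out <- list()
  while (pos < end) {
    group <- readBin(bytes[(pos + 1):(pos + 2)], "integer", size = 2,
                     signed = FALSE, endian = "little")
    element <- readBin(bytes[(pos + 3):(pos + 4)], "integer", size = 2,
                       signed = FALSE, endian = "little")
    pos <- pos + 4L
    if (group == 0xFFFE) {  # delimiter items inside undefined-length content
      pos <- pos + 4L       # skip length
      if (element == 0xE0DD || element == 0xE00D) break
      next
    }
    vr <- rawToChar(bytes[(pos + 1):(pos + 2)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- readBin(bytes[(pos + 5):(pos + 8)], "integer", size = 4,
                     endian = "little")
      pos <- pos + 8L
    } else {
      len <- readBin(bytes[(pos + 3):(pos + 4)], "integer", size = 2,
                     signed = FALSE, endian = "little")
      pos <- pos + 4L
    }
    undefined <- (len == -1L)
    key <- dicom_tag_key(group, element)
    if (vr == "SQ") {
      item_end <- if (undefined) length(bytes) else pos + len
      items <- list()
      while (pos < item_end) {
        ig <- readBin(bytes[(pos + 1):(pos + 2)], "integer", size = 2,
                      signed = FALSE, endian = "little")
        ie <- readBin(bytes[(pos + 3):(pos + 4)], "integer", size = 2,
                      signed = FALSE, endian = "little")
        il <- readBin(bytes[(pos + 5):(pos + 8)], "integer", size = 4,
                      endian = "little")
        pos <- pos + 8L
        if (ig == 0xFFFE && ie == 0xE0DD) break
        if (!(ig == 0xFFFE && ie == 0xE000))
          abort_isodvh("malformed sequence item", "format")
        if (il == -1L) {
          parsed <- dicom_parse(bytes, pos, length(bytes))
          items[[length(items) + 1L]] <- parsed$data
          pos <- parsed$pos
        } else {
          parsed <- dicom_parse(bytes, pos, pos + il)
          items[[length(items) + 1L]] <- parsed$data
          pos <- pos + il
        }
      }
      out[[key]] <- items
    } else {
      if (undefined)
        abort_isodvh("undefined length on non-SQ element unsupported", "format")
      val_raw <- if (len > 0) bytes[(pos + 1):(pos + len)] else raw(0)
      pos <- pos + len
      out[[key]] <- dicom_dec_value(vr, val_raw)
    }
  }
  list(data = out, pos = pos)
}

dicom_dec_value <- function(vr, bytes) {
  trim <- function(b) {   # drop trailing padding (NUL or space) before decode
    n <- length(b)
    while (n > 0 && (b[n] == as.raw(0) || b[n] == as.raw(32))) n <- n - 1L
    rawToChar(b[seq_len(n)])
  }
  switch(vr,
    US = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    UL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    DS = as.numeric(strsplit(trim(bytes), "\\", fixed = TRUE)[[1]]),
    IS = as.integer(strsplit(trim(bytes), "\\", fixed = TRUE)[[1]]),
    OW = bytes,
    OB = bytes,
    trim(bytes)
  )
}

dicom_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    abort_isodvh(paste("not a DICOM file:", path), "format")
  # the meta group length element delimits the file meta information
  glen_el <- dicom_parse(bytes, 132L, 132L + 12L)
  glen <- glen_el$data[["0002,0000"]]
  meta_end <- 132L + 12L + glen
  meta <- dicom_parse(bytes, 132L + 12L, meta_end)$data
  ts <- meta[["0002,0010"]]
  if (!identical(ts, DICOM_TS_EXPLICIT_LE))
    abort_isodvh(paste("unsupported transfer syntax:", ts), "format")
  dicom_parse(bytes, meta_end, length(bytes))$data
}
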