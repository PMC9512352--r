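#' Write a DVH to a plain-text table
#'
#' CSV files carry the DVH metadata (structure, scale, alpha/beta tag,
#' volume unit, stored absolute total) in `#`-prefixed header lines followed
#' by columns `bin_lower, bin_upper, volume, cumulative_volume`; JSON files
#' carry the same fields as one object.  Doses and volumes are written at
#' full double precision so a round-trip recovers the DVH exactly.
#'
#' @param x A [dvh()].
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default: inferred from the extension).
#' @return `path`, invisibly.
#' @export
write_dvh_table <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "dvh"))
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  cum <- rev(cumsum(rev(x$volume)))
  if (format == "json") {
    jsonlite::write_json(list(structure = x$structure, scale = x$scale,
                              alpha_beta_tag = x$alpha_beta_tag,
                              volume_unit = x$volume_unit,
                              total_volume = x$total_volume,
                              bin_lower = x$bin_lower,
                              bin_upper = x$bin_upper,
                              volume = x$volume),
                         path, auto_unbox = TRUE, digits = I(17),
                         na = "null")
  } else if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# structure: %s", x$structure),
                 sprintf("# scale: %s", x$scale),
                 sprintf("# alpha_beta_tag: %.17g", x$alpha_beta_tag),
                 sprintf("# volume_unit: %s", x$volume_unit),
                 sprintf("# total_volume: %.17g", x$total_volume),
                 "bin_lower,bin_upper,volume,cumulative_volume"), con)
    writeLines(sprintf("%.17g,%.17g,%.17g,%.17g",
                       x$bin_lower, x$bin_upper, x$volume, cum), con)
  } else abort_isodvh(paste("unknown DVH format:", format), "format")
  invisible(path)
}

#' Read a DVH written by [write_dvh_table()]
#'
#' @param path Path to a CSV or JSON DVH table.
#' @return A [dvh()].
#' @export
read_dvh_table <- function(path) {
  if (!file.exists(path))
    abort_isodvh(paste("DVH table not found:", path), "io")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(dvh_new(j$volume, j$bin_lower, j$bin_upper, j$structure,
                   j$scale, j$alpha_beta_tag %||% NA_real_,
                   j$volume_unit, j$total_volume))
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE)[1])
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  dvh_new(tab$volume, tab$bin_lower, tab$bin_upper, get("structure"),
          get("scale"), suppressWarnings(as.numeric(get("alpha_beta_tag"))),
          get("volume_unit"), as.numeric(get("total_volume")))
}
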