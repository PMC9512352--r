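#' Radiobiological tissue parameters
#'
#' Bundles the linear-quadratic and repopulation constants for one structure:
#' the fractionation-sensitivity ratio \eqn{\alpha/\beta} (Gy), the
#' repopulation rate \eqn{K} (Gy/day, dose lost per day once rapid
#' repopulation has started), the repopulation onset lag \eqn{T_{delay}}
#' (calendar days), and the mono-exponential sublethal-damage repair half-time
#' (hours) used for twice-daily fractionation.
#'
#' Organs at risk do not accrue a repopulation correction within the time
#' frame of a radiotherapy course, so `tissue_class = "oar"` requires
#' `K = 0`.
#'
#' @param name Structure name.
#' @param alpha_beta Fractionation sensitivity \eqn{\alpha/\beta} in Gy
#'   (> 0; typically ~10 for tumors, 2--3 for late-responding normal tissue).
#' @param tissue_class `"tumor"` or `"oar"`.
#' @param K Repopulation rate in Gy/day (>= 0; must be 0 for OARs).
#' @param T_delay Days from the start of treatment to repopulation onset.
#' @param repair_half_time Sublethal-damage repair half-time in hours (> 0).
#' @return An object of class `tissue_params`.
#' @examples
#' ptv <- tissue_params("PTV", alpha_beta = 10, tissue_class = "tumor",
#'                      K = 0.9, T_delay = 28)
#' cord <- tissue_params("SpinalCord", alpha_beta = 2, tissue_class = "oar")
#' @export
tissue_params <- function(name, alpha_beta, tissue_class = c("tumor", "oar"),
                          K = 0, T_delay = 0, repair_half_time = 2) {
  tissue_class <- match.arg(tissue_class)
  if (!is.numeric(alpha_beta) || length(alpha_beta) != 1L || alpha_beta <= 0)
    abort_isodvh("alpha_beta must be a single positive number", "invalid_parameter")
  if (!is.numeric(K) || length(K) != 1L || K < 0)
    abort_isodvh("K must be a single non-negative number", "invalid_parameter")
  if (!is.numeric(T_delay) || length(T_delay) != 1L || T_delay < 0)
    abort_isodvh("T_delay must be a single non-negative number", "invalid_parameter")
  if (!is.numeric(repair_half_time) || length(repair_half_time) != 1L ||
      repair_half_time <= 0)
    abort_isodvh("repair_half_time must be a single positive number",
                 "invalid_parameter")
  if (tissue_class == "oar" && K != 0)
    abort_isodvh("OAR tissue has no repopulation term: K must be 0",
                 "invalid_parameter")
  structure(list(name = as.character(name), alpha_beta = alpha_beta,
                 K = K, T_delay = T_delay,
                 repair_half_time = repair_half_time,
                 tissue_class = tissue_class),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("<tissue_params> %s (%s): alpha/beta = %g Gy, K = %g Gy/day, T_delay = %g d, T1/2 = %g h\n",
              x$name, x$tissue_class, x$alpha_beta, x$K, x$T_delay,
              x$repair_half_time))
  invisible(x)
}

#' Read a tissue-parameter configuration table
#'
#' The configuration is a plain CSV with one record per structure and columns
#' `name, alpha_beta, K, T_delay, repair_half_time, class`.  Shipped presets
#' (see [tissue_presets()]) use the same format.
#'
#' @param path Path to a CSV file.
#' @return A named list of [tissue_params()] objects.
#' @export
read_tissue_config <- function(path) {
  if (!file.exists(path))
    abort_isodvh(paste("tissue config not found:", path), "io")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "alpha_beta", "K", "T_delay", "repair_half_time", "class")
  if (!all(need %in% names(tab)))
    abort_isodvh(paste("tissue config must have columns:",
                       paste(need, collapse = ", ")), "format")
  out <- lapply(seq_len(nrow(tab)), function(i)
    tissue_params(tab$name[i], tab$alpha_beta[i], tab$class[i],
                  K = tab$K[i], T_delay = tab$T_delay[i],
                  repair_half_time = tab$repair_half_time[i]))
  names(out) <- tab$name
  out
}

#' Shipped tissue-parameter presets
#'
#' Returns the parameter presets bundled with the package: the RCR
#' Category-1 head-and-neck/lung tumor preset (\eqn{\alpha/\beta} = 10 Gy,
#' K = 0.9 Gy/day, \eqn{T_{delay}} = 28 days) and generic late-responding
#' OAR presets (\eqn{\alpha/\beta} = 3 Gy, and 2 Gy for spinal cord).
#'
#' @return Named list of [tissue_params()] objects.
#' @export
tissue_presets <- function() {
  read_tissue_config(system.file("extdata", "tissue_presets.csv",
                                 package = "isodvh", mustWork = TRUE))
}
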