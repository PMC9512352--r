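# Independent oracles used by the unit and acceptance tests.  These
# deliberately avoid the package's vectorized code paths: plain loops,
# fraction-by-fraction accumulation, dense search.

# Fraction-by-fraction LQ accumulation: for a structure dose D delivered in
# N fractions (variable dose per fraction D/N), iterate over every single
# fraction of every session group, summing its BED contribution, then apply
# the repopulation loss and the EQD2 factor.
oracle_eqd2 <- function(D, N, alpha_beta, groups, loss = 0) {
  d <- D / N
  bed <- 0
  for (k in seq_len(nrow(groups))) {
    for (f in seq_len(groups$n[k])) {
      bed <- bed + d * (1 + d * (1 + groups$h[k]) / alpha_beta)
    }
  }
  (bed - loss) / (1 + 2 / alpha_beta)
}

# Dense-search gamma oracle: evaluated polyline oversampled very finely,
# direct double loop over reference points.
oracle_gamma <- function(ref_dose, ref_vol, ev_dose, ev_vol, dD, dV,
                         oversample = 1000L) {
  dd <- numeric(0); vv <- numeric(0)
  for (i in seq_len(length(ev_dose) - 1L)) {
    t <- seq(0, 1, length.out = oversample + 1L)[-(oversample + 1L)]
    dd <- c(dd, ev_dose[i] + t * (ev_dose[i + 1] - ev_dose[i]))
    vv <- c(vv, ev_vol[i] + t * (ev_vol[i + 1] - ev_vol[i]))
  }
  dd <- c(dd, ev_dose[length(ev_dose)])
  vv <- c(vv, ev_vol[length(ev_vol)])
  g <- numeric(length(ref_dose))
  for (i in seq_along(ref_dose)) {
    best <- Inf
    for (j in seq_along(dd)) {
      val <- ((dd[j] - ref_dose[i]) / dD)^2 + ((vv[j] - ref_vol[i]) / dV)^2
      if (val < best) best <- val
    }
    g[i] <- sqrt(best)
  }
  g
}

# Toy DVH with point-mass bins at exact doses (zero-width bins).
point_dvh <- function(doses, volumes, structure = "toy",
                      scale = "physical") {
  dvh(volumes, bin_lower = doses, bin_upper = doses, structure = structure,
      scale = scale)
}

c1_params <- function() tissue_params("PTV", 10, "tumor", K = 0.9,
                                      T_delay = 28)
oar_params <- function(ab = 3) tissue_params("OAR", ab, "oar")
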