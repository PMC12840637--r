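# Independent oracles and small fixture builders used across test files.

# naive double-loop Ra/Rq on a matrix ROI (0-based half-open), mean-centered,
# no detrending: the brute-force reference for roughness()
brute_ra_rq <- function(z, roi = c(0L, 0L, nrow(z), ncol(z))) {
  w <- z[(roi[1] + 1L):(roi[1] + roi[3]), (roi[2] + 1L):(roi[2] + roi[4]),
         drop = FALSE]
  zbar <- mean(w)
  sa <- 0; sq <- 0; n <- 0L
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(ncol(w))) {
      d <- w[i, j] - zbar
      sa <- sa + abs(d)
      sq <- sq + d^2
      n <- n + 1L
    }
  }
  c(Ra = sa / n, Rq = sqrt(sq / n))
}

# closed-form spherical Hertz force in SI units, independent of the package
# constant: R [m], E_r [Pa], delta [m] -> F [N]
hertz_si <- function(delta_m, R_m, E_r_Pa) {
  4 / 3 * sqrt(R_m) * E_r_Pa * delta_m^1.5
}

# pooled two-sample t statistic, closed form
pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# a small lens-cell-like spectrum with pinned order parameters, on the fine
# acceptance grid
control_spectrum <- function(S_l = 0.7287, S_t = 0.41002, noise = TRUE,
                             seed = 42, step = 0.5,
                             baseline = c(0.2, 1e-4)) {
  pk <- raman_cell_peaks(S_l, S_t)
  gen_raman(raman_spec(600, 3100, step, pk, baseline_coeffs = baseline,
                       noise_sd = if (noise) 0.001 * max(pk$amplitude) else 0,
                       seed = seed))
}
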