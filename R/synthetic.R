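# Synthetic-data generators. Each generator is a pure function of its spec
# (including the seed), so identical specs give bitwise-identical records.
# The cohort generator links raw records to per-cell latent metric values by
# inverting the analysis equations, which makes pipeline recovery exact in
# the noiseless limit.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## ---- topography ----------------------------------------------------------

#' Specification of a synthetic AFM topography scan
#'
#' Describes a cell sitting on a flat substrate as a spherical cap (the
#' simplest shape with a well-defined apex height) plus a stationary
#' correlated Gaussian roughness texture. A Gaussian texture of SD `sigma`
#' has expected Rq = `sigma` and expected Ra = `sigma * sqrt(2/pi)` (the
#' half-normal mean), so roughness targets can be set analytically.
#'
#' @param grid_px pixels per side (>= 16).
#' @param pixel_nm nm per pixel.
#' @param substrate_level_nm baseline substrate height (nm).
#' @param cap_height_um apex height of the cell dome above the substrate
#'   (um).
#' @param cap_radius_um footprint radius of the dome (um); must fit on the
#'   grid.
#' @param texture_sd_nm SD of the additive roughness texture (nm, >= 0).
#' @param texture_corr_px correlation length of the texture in pixels
#'   (0 = white noise).
#' @param seed integer RNG seed.
#' @return A list of class `topo_spec`.
#' @export
topo_spec <- function(grid_px = 128L, pixel_nm = 30000 / 128,
                      substrate_level_nm = 0, cap_height_um = 3.5,
                      cap_radius_um = 12, texture_sd_nm = 20,
                      texture_corr_px = 2, seed = 1L) {
  grid_px <- as.integer(grid_px)
  if (grid_px < 16L) stop("topo_spec: grid_px must be >= 16", call. = FALSE)
  if (pixel_nm <= 0 || cap_height_um <= 0 || cap_radius_um <= 0) {
    stop("topo_spec: physical scales must be > 0", call. = FALSE)
  }
  if (texture_sd_nm < 0) stop("topo_spec: texture_sd_nm must be >= 0",
                              call. = FALSE)
  structure(list(grid_px = grid_px, pixel_nm = pixel_nm,
                 substrate_level_nm = substrate_level_nm,
                 cap_height_um = cap_height_um, cap_radius_um = cap_radius_um,
                 texture_sd_nm = texture_sd_nm,
                 texture_corr_px = texture_corr_px, seed = as.integer(seed)),
            class = "topo_spec")
}

# zero-mean, unit-variance correlated Gaussian field (separable Gaussian
# kernel smoothing of white noise, renormalised to the sample SD so the
# realised field SD equals the requested texture SD exactly)
gaussian_field <- function(n, corr_px) {
  z <- matrix(stats::rnorm(n * n), n, n)
  if (corr_px > 0) {
    half <- max(1L, ceiling(3 * corr_px))
    k <- stats::dnorm(seq(-half, half), sd = corr_px)
    k <- k / sum(k)
    sm <- function(m) {
      t(apply(m, 1, function(row) {
        stats::filter(c(rev(row[seq_len(half)]), row,
                        rev(row[n - seq_len(half) + 1L])),
                      k, sides = 2)[(half + 1L):(half + n)]
      }))
    }
    z <- sm(t(sm(z)))
  }
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic AFM height map
#'
#' Substrate plane + spherical-cap dome + correlated zero-mean Gaussian
#' texture, per the [topo_spec()]. With zero texture, apex minus substrate
#' equals `cap_height_um` exactly.
#'
#' @param spec a [topo_spec()].
#' @return A [heightmap()].
#' @export
gen_topography <- function(spec) {
  stopifnot(inherits(spec, "topo_spec"))
  n <- spec$grid_px
  half_nm <- n * spec$pixel_nm / 2
  if (spec$cap_radius_um * 1e3 > half_nm) {
    stop("gen_topography: cap footprint exceeds grid", call. = FALSE)
  }
  ctr <- floor(n / 2) + 1   # apex sits on a grid node exactly
  x <- (seq_len(n) - ctr) * spec$pixel_nm
  r2 <- outer(x^2, x^2, `+`)
  h <- spec$cap_height_um * 1e3
  a <- spec$cap_radius_um * 1e3
  Rc <- (a^2 + h^2) / (2 * h)   # radius of curvature of the cap sphere
  dome <- sqrt(pmax(Rc^2 - r2, 0)) - (Rc - h)
  dome[r2 > a^2 | dome < 0] <- 0
  z <- spec$substrate_level_nm + dome
  if (spec$texture_sd_nm > 0) {
    z <- z + spec$texture_sd_nm *
      with_seed(spec$seed, gaussian_field(n, spec$texture_corr_px))
  }
  heightmap(z, spec$pixel_nm)
}

## ---- force curves --------------------------------------------------------

#' Specification of a synthetic force-indentation curve
#'
#' Forward model of the spherical Hertz contact: the piezo ramps from 0 to
#' `contact_offset_nm + delta_max_nm`; before the (hidden) contact offset
#' the force is noise only, beyond it
#' `F = (4/3) sqrt(R) E_r (z - offset)^(3/2)` with the reduced modulus
#' derived from `E_s_kPa` and `nu_s` under a rigid tip. Noise is additive
#' Gaussian on force only.
#'
#' @param E_s_kPa sample Young's modulus (kPa, > 0).
#' @param nu_s sample Poisson ratio (0 to 0.5; default 0.5,
#'   incompressible).
#' @param R_nm tip radius (nm, > 0; default 20).
#' @param delta_max_nm maximum true indentation (nm).
#' @param n_points samples per curve (>= 20).
#' @param noise_nN SD of the additive force noise (nN).
#' @param contact_offset_nm piezo offset of the true contact point (nm).
#' @param k_N_per_m spring-constant metadata carried on the record.
#' @param seed integer RNG seed.
#' @return A list of class `curve_spec`.
#' @export
curve_spec <- function(E_s_kPa, nu_s = 0.5, R_nm = 20, delta_max_nm = 500,
                       n_points = 200L, noise_nN = 0,
                       contact_offset_nm = 100, k_N_per_m = 0.4017,
                       seed = 1L) {
  if (E_s_kPa <= 0) stop("curve_spec: E_s_kPa must be > 0", call. = FALSE)
  if (nu_s < 0 || nu_s > 0.5) stop("curve_spec: nu_s must be in [0, 0.5]",
                                   call. = FALSE)
  if (R_nm <= 0) stop("curve_spec: R_nm must be > 0", call. = FALSE)
  n_points <- as.integer(n_points)
  if (n_points < 20L) stop("curve_spec: n_points must be >= 20",
                           call. = FALSE)
  structure(list(E_s_kPa = E_s_kPa, nu_s = nu_s, R_nm = R_nm,
                 delta_max_nm = delta_max_nm, n_points = n_points,
                 noise_nN = noise_nN, contact_offset_nm = contact_offset_nm,
                 k_N_per_m = k_N_per_m, seed = as.integer(seed)),
            class = "curve_spec")
}

#' Generate a synthetic force curve
#'
#' @param spec a [curve_spec()].
#' @return A [forcecurve()].
#' @export
gen_force_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  E_r <- spec$E_s_kPa / (1 - spec$nu_s^2)
  z <- seq(0, spec$contact_offset_nm + spec$delta_max_nm,
           length.out = spec$n_points)
  de <- pmax(z - spec$contact_offset_nm, 0)
  f <- hertz_force(de, spec$R_nm, E_r)
  if (spec$noise_nN > 0) {
    f <- f + with_seed(spec$seed,
                       stats::rnorm(spec$n_points, sd = spec$noise_nN))
  }
  forcecurve(z, f, R_nm = spec$R_nm, k_N_per_m = spec$k_N_per_m)
}

## ---- Raman spectra -------------------------------------------------------

#' Specification of a synthetic Raman spectrum
#'
#' Sum of Lorentzian bands plus an additive polynomial baseline plus
#' Gaussian noise. Lorentzian line shape with a default FWHM of 12 cm^-1 is
#' the conventional choice for Raman bands. The baseline polynomial is
#' evaluated in `x = wn - wn_start_cm1` (ascending powers), which keeps the
#' coefficients well scaled.
#'
#' @param wn_start_cm1,wn_stop_cm1,wn_step_cm1 wavenumber grid bounds and
#'   step (cm^-1); step > 0.
#' @param peaks data.frame with columns `center_cm1`, `amplitude`,
#'   `fwhm_cm1` (amplitudes >= 0, FWHM > 0, centers inside the grid).
#' @param baseline_coeffs numeric vector, ascending-power polynomial
#'   coefficients of the additive baseline (default 0).
#' @param noise_sd SD of the additive Gaussian noise.
#' @param seed integer RNG seed.
#' @return A list of class `raman_spec`.
#' @export
raman_spec <- function(wn_start_cm1 = 600, wn_stop_cm1 = 3100,
                       wn_step_cm1 = 0.5, peaks,
                       baseline_coeffs = 0, noise_sd = 0, seed = 1L) {
  if (wn_step_cm1 <= 0) stop("raman_spec: wn_step_cm1 must be > 0",
                             call. = FALSE)
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center_cm1", "amplitude", "fwhm_cm1") %in% names(peaks)))
  if (any(peaks$fwhm_cm1 <= 0)) stop("raman_spec: all FWHM must be > 0",
                                     call. = FALSE)
  if (any(peaks$amplitude < 0)) stop("raman_spec: amplitudes must be >= 0",
                                     call. = FALSE)
  if (any(peaks$center_cm1 < wn_start_cm1 | peaks$center_cm1 > wn_stop_cm1)) {
    stop("raman_spec: peak center outside the wavenumber grid", call. = FALSE)
  }
  structure(list(wn_start_cm1 = wn_start_cm1, wn_stop_cm1 = wn_stop_cm1,
                 wn_step_cm1 = wn_step_cm1, peaks = peaks,
                 baseline_coeffs = baseline_coeffs, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "raman_spec")
}

lorentzian <- function(x, center, amplitude, fwhm) {
  amplitude / (1 + ((x - center) / (fwhm / 2))^2)
}

#' Generate a synthetic Raman spectrum
#'
#' @param spec a [raman_spec()].
#' @return A [ramanspectrum()].
#' @export
gen_raman <- function(spec) {
  stopifnot(inherits(spec, "raman_spec"))
  wn <- seq(spec$wn_start_cm1, spec$wn_stop_cm1, by = spec$wn_step_cm1)
  y <- rep(0, length(wn))
  for (i in seq_len(nrow(spec$peaks))) {
    y <- y + lorentzian(wn, spec$peaks$center_cm1[i],
                        spec$peaks$amplitude[i], spec$peaks$fwhm_cm1[i])
  }
  x <- wn - spec$wn_start_cm1
  for (j in seq_along(spec$baseline_coeffs)) {
    y <- y + spec$baseline_coeffs[j] * x^(j - 1)
  }
  if (spec$noise_sd > 0) {
    y <- y + with_seed(spec$seed,
                       stats::rnorm(length(wn), sd = spec$noise_sd))
  }
  ramanspectrum(wn, y)
}

#' Solve Lorentzian amplitudes that realise target composite band heights
#'
#' Neighbouring Lorentzian bands overlap, so the composite spectrum's height
#' at a band center exceeds that band's own amplitude. Given target heights
#' at each center, this solves the linear cross-talk system
#' `M %*% A = h`, `M[i, j] = L(center_i; center_j, 1, fwhm_j)`, so that the
#' generated spectrum's height at every center equals its target exactly
#' (noiseless, baseline-free limit). This is the inversion the cohort
#' generator uses to pin latent band ratios.
#'
#' @param centers_cm1 band centers.
#' @param heights target composite heights at those centers (> 0).
#' @param fwhm_cm1 FWHM per band (recycled).
#' @return data.frame `center_cm1`, `amplitude`, `fwhm_cm1`.
#' @export
solve_band_amplitudes <- function(centers_cm1, heights, fwhm_cm1 = 12) {
  stopifnot(length(centers_cm1) == length(heights), all(heights > 0))
  fwhm_cm1 <- rep_len(fwhm_cm1, length(centers_cm1))
  M <- outer(seq_along(centers_cm1), seq_along(centers_cm1),
             function(i, j) lorentzian(centers_cm1[i], centers_cm1[j], 1,
                                       fwhm_cm1[j]))
  A <- solve(M, heights)
  if (any(A < 0)) {
    warning("solve_band_amplitudes: negative amplitude; targets too close")
    A <- pmax(A, 0)
  }
  data.frame(center_cm1 = centers_cm1, amplitude = A, fwhm_cm1 = fwhm_cm1)
}

#' Band table of a cell-like Raman spectrum with pinned order parameters
#'
#' Builds the peak table of a synthetic cell spectrum: the characteristic
#' protein and lipid bands at their literature positions, with the
#' fluidity-relevant band heights chosen so the spectrum realises the
#' requested order parameters exactly through the analysis equations:
#' `h2890 = (1.5 S_l + 0.7) h2850` and `h1130 = 1.77 S_t * h1090`.
#' Amplitudes are then solved with [solve_band_amplitudes()] so the
#' composite heights (not just the isolated amplitudes) hit the targets.
#'
#' @param S_l,S_t target order parameters.
#' @param fwhm_cm1 FWHM applied to all bands (default 12).
#' @param h2850,h1090 reference band heights (defaults 1).
#' @return data.frame of peaks suitable for [raman_spec()].
#' @export
raman_cell_peaks <- function(S_l, S_t, fwhm_cm1 = 12, h2850 = 1, h1090 = 1) {
  h2890 <- (1.5 * S_l + 0.7) * h2850
  h1130 <- 1.77 * S_t * h1090
  if (h2890 <= 0 || h1130 <= 0) {
    stop("raman_cell_peaks: order-parameter targets give non-positive heights",
         call. = FALSE)
  }
  centers <- c(1006, 1055, 1090, 1130, 1205, 1308, 1448, 1660,
               2850, 2890, 2937)
  # plausible relative heights for the non-fluidity bands of a cell spectrum
  heights <- c(0.50, 0.30, h1090, h1130, 0.25, 0.35, 0.90, 0.80,
               h2850, h2890, 1.60)
  solve_band_amplitudes(centers, heights, fwhm_cm1)
}

## ---- cohorts -------------------------------------------------------------

#' Specification of a synthetic three-group cohort
#'
#' `groups` maps each group label to per-metric `(mean, sd)` pairs for the
#' six pipeline metrics (`height_um`, `Ra_nm`, `Rq_nm`, `E_s_kPa`, `S_l`,
#' `S_t`). Per-cell latent values are drawn Normal(mean, sd), truncated to
#' positivity, and each cell's raw records are generated so the analysis
#' pipeline recovers its latent values.
#'
#' @param groups named list; each element a named list of `c(mean, sd)`
#'   pairs for the six metrics.
#' @param n_cells cells per group (>= 2).
#' @param seed integer RNG seed.
#' @param curves_per_cell force curves per cell (default 3).
#' @param raman_step_cm1 wavenumber step of generated spectra (default 1).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, n_cells = 20L, seed = 1L,
                        curves_per_cell = 3L, raman_step_cm1 = 1) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (anyDuplicated(names(groups))) {
    stop("cohort_spec: group labels must be unique", call. = FALSE)
  }
  metrics <- c("height_um", "Ra_nm", "Rq_nm", "E_s_kPa", "S_l", "S_t")
  for (g in names(groups)) {
    if (!all(metrics %in% names(groups[[g]]))) {
      stop(sprintf("cohort_spec: group '%s' missing metrics", g),
           call. = FALSE)
    }
    if (any(vapply(groups[[g]], function(ms) ms[2] < 0, TRUE))) {
      stop("cohort_spec: SDs must be >= 0", call. = FALSE)
    }
  }
  n_cells <- as.integer(n_cells)
  if (n_cells < 2L) stop("cohort_spec: n_cells must be >= 2", call. = FALSE)
  structure(list(groups = groups, n_cells = n_cells,
                 seed = as.integer(seed),
                 curves_per_cell = as.integer(curves_per_cell),
                 raman_step_cm1 = raman_step_cm1),
            class = "cohort_spec")
}

#' Three-group cohort preset: control / high-glucose model / gigantol
#'
#' Group means and SDs are the reported single-cell biophysical values for
#' human lens epithelial cells under control, high-glucose (50 mM) and
#' gigantol-rescue conditions: cell height (um), Ra/Rq roughness (nm),
#' Young's modulus (kPa) and the membrane order parameters S_l/S_t. Cohort
#' recovery of these numbers is a self-consistency check of the pipeline
#' (the values are generator presets), not an independent reproduction.
#'
#' @param n_cells cells per group (default 20, the per-group cell count used
#'   for the AFM means).
#' @param seed integer RNG seed.
#' @param ... passed on to [cohort_spec()].
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_cells = 20L, seed = 1L, ...) {
  g <- function(height, Ra, Rq, E, Sl, St) {
    list(height_um = height, Ra_nm = Ra, Rq_nm = Rq, E_s_kPa = E,
         S_l = Sl, S_t = St)
  }
  groups <- list(
    control  = g(c(3.5, 0.35), c(112.25, 2.01), c(155.0, 3.07),
                 c(5.7, 0.56), c(0.7287, 0.11), c(0.41002, 0.09)),
    model    = g(c(1.8, 0.25), c(144.2, 4.13), c(176.6, 3.54),
                 c(11.6, 0.91), c(0.90807, 0.056), c(0.51303, 0.089)),
    gigantol = g(c(3.1, 0.15), c(114.0, 3.45), c(135.0, 5.12),
                 c(7.5, 0.45), c(0.75949, 0.078), c(0.42909, 0.058))
  )
  cohort_spec(groups, n_cells = n_cells, seed = seed, ...)
}

# normal draw truncated to (lo, inf) by redraw
rtnorm_pos <- function(n, mean, sd, lo = 0) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- x <= lo
  tries <- 0L
  while (any(bad) && tries < 100L) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x <= lo
    tries <- tries + 1L
  }
  x[bad] <- max(lo + 1e-9, mean)
  x
}

#' Generate a full synthetic cohort
#'
#' For each cell, draws latent metric values from its group's distributions
#' and generates the raw records the pipeline consumes:
#' * an overview topography scan (30 um field, spherical-cap dome of the
#'   latent height plus a small instrument-level texture) for the height
#'   cross-section;
#' * a local 5 um x 5 um membrane patch whose Gaussian texture SD equals the
#'   latent Rq (a Gaussian texture fixes Ra/Rq = sqrt(2/pi), so Ra and Rq
#'   cannot be targeted independently; the generator pins Rq);
#' * `curves_per_cell` force curves forward-modelled from the latent E_s;
#' * one Raman spectrum with band heights pinned to the latent S_l/S_t.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `cohort`: `cells` (list with `group`, `cell_id`,
#'   `latent`, `topo`, `local`, `curves`, `raman`) and `spec`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  metrics <- c("height_um", "Ra_nm", "Rq_nm", "E_s_kPa", "S_l", "S_t")
  cells <- with_seed(spec$seed, {
    out <- list()
    for (grp in names(spec$groups)) {
      ms <- spec$groups[[grp]]
      lat <- sapply(metrics, function(m) {
        rtnorm_pos(spec$n_cells, ms[[m]][1], ms[[m]][2])
      })
      lat <- matrix(lat, nrow = spec$n_cells,
                    dimnames = list(NULL, metrics))
      for (i in seq_len(spec$n_cells)) {
        seeds <- sample.int(.Machine$integer.max, 4L)
        li <- as.list(lat[i, ])
        topo <- gen_topography(topo_spec(
          grid_px = 128L, pixel_nm = 30000 / 128,
          cap_height_um = li$height_um, cap_radius_um = 12,
          texture_sd_nm = 20, texture_corr_px = 2, seed = seeds[1]))
        local <- gen_topography(topo_spec(
          grid_px = 64L, pixel_nm = 5000 / 64,
          cap_height_um = 1e-6, cap_radius_um = 1e-6,
          texture_sd_nm = li$Rq_nm, texture_corr_px = 2, seed = seeds[2]))
        curves <- lapply(seq_len(spec$curves_per_cell), function(k) {
          gen_force_curve(curve_spec(
            E_s_kPa = li$E_s_kPa, noise_nN = 0.05,
            seed = (seeds[3] + k) %% .Machine$integer.max))
        })
        peaks <- raman_cell_peaks(li$S_l, li$S_t)
        raman <- gen_raman(raman_spec(
          wn_start_cm1 = 600, wn_stop_cm1 = 3100,
          wn_step_cm1 = spec$raman_step_cm1, peaks = peaks,
          baseline_coeffs = c(0.2, 1e-4), noise_sd = 0.002,
          seed = seeds[4]))
        out[[length(out) + 1L]] <- list(
          group = grp, cell_id = sprintf("%s_%03d", grp, i),
          latent = li, topo = topo, local = local, curves = curves,
          raman = raman)
      }
    }
    out
  })
  structure(list(cells = cells, spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d cells in %d group(s): %s\n", length(x$cells),
              length(x$spec$groups),
              paste(names(x$spec$groups), collapse = ", ")))
  invisible(x)
}
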