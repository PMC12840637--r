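# synthetic-data generators: determinism, stated-world geometry, latent
# recovery

test_that("gen_topography builds the stated dome and is seed-deterministic", {
  sp <- topo_spec(grid_px = 64, pixel_nm = 500, cap_height_um = 3.5,
                  cap_radius_um = 12, texture_sd_nm = 0, seed = 1)
  hm <- gen_topography(sp)
  # noiseless dome: apex minus substrate is the cap height exactly
  expect_equal(max(hm$heights) - min(hm$heights), 3500, tolerance = 1e-12)

  sp2 <- topo_spec(grid_px = 64, pixel_nm = 500, texture_sd_nm = 80,
                   seed = 7)
  expect_identical(gen_topography(sp2)$heights, gen_topography(sp2)$heights)

  # cap footprint exceeding the grid is rejected
  expect_error(gen_topography(topo_spec(grid_px = 16, pixel_nm = 100,
                                        cap_radius_um = 5)),
               "footprint")
})

test_that("topography texture realises the requested SD on a flat field", {
  # sample-SD oracle on the generated Gaussian field (flat substrate only)
  sp <- topo_spec(grid_px = 256, pixel_nm = 100, cap_height_um = 1e-6,
                  cap_radius_um = 1e-6, texture_sd_nm = 50,
                  texture_corr_px = 2, seed = 3)
  hm <- gen_topography(sp)
  roi_sd <- sd(hm$heights[1:128, 1:128])
  expect_lt(abs(roi_sd - 50) / 50, 0.10)
})

test_that("gen_force_curve is the Hertz forward model in consistent units", {
  # direct SI-unit hand evaluation: R=20 nm, E_r=10 kPa, delta=500 nm
  f_si <- hertz_si(500e-9, 20e-9, 10e3)    # N
  expect_equal(hertz_force(500, 20, 10), f_si * 1e9, tolerance = 1e-12)
  expect_equal(f_si * 1e9, 2 / 3, tolerance = 1e-9)

  sp <- curve_spec(E_s_kPa = 5, noise_nN = 0, contact_offset_nm = 0,
                   n_points = 50, seed = 1)
  cv <- gen_force_curve(sp)
  expect_equal(cv$force_nN[1], 0)           # zero indentation, zero force
  # linearity in E_s at zero noise
  sp2 <- curve_spec(E_s_kPa = 10, noise_nN = 0, contact_offset_nm = 0,
                    n_points = 50, seed = 1)
  expect_equal(gen_force_curve(sp2)$force_nN, 2 * cv$force_nN,
               tolerance = 1e-12)
  # pre-contact samples carry no force
  sp3 <- curve_spec(E_s_kPa = 5, noise_nN = 0, contact_offset_nm = 200,
                    n_points = 100, seed = 1)
  cv3 <- gen_force_curve(sp3)
  expect_true(all(cv3$force_nN[cv3$indentation_nm <= 200] == 0))
})

test_that("gen_raman realises single-band amplitudes and is deterministic", {
  pk <- data.frame(center_cm1 = 1500, amplitude = 1.0, fwhm_cm1 = 12)
  sp <- gen_raman(raman_spec(1000, 2000, 0.5, pk))
  expect_equal(max(sp$intensity_au), 1.0, tolerance = 1e-12)
  expect_equal(sp$wavenumber_cm1[which.max(sp$intensity_au)], 1500)

  spec <- raman_spec(600, 3100, 1, raman_cell_peaks(0.7, 0.4),
                     noise_sd = 0.01, seed = 9)
  expect_identical(gen_raman(spec)$intensity_au,
                   gen_raman(spec)$intensity_au)

  expect_error(raman_spec(1000, 2000, 0.5,
                          data.frame(center_cm1 = 2500, amplitude = 1,
                                     fwhm_cm1 = 12)),
               "outside")
})

test_that("solve_band_amplitudes pins composite heights despite overlap", {
  tgt <- c(1.0, 1.79305)
  pk <- solve_band_amplitudes(c(2850, 2890), tgt, fwhm_cm1 = 12)
  sp <- gen_raman(raman_spec(2700, 3000, 0.1, pk))
  at <- function(cc) sp$intensity_au[which.min(abs(sp$wavenumber_cm1 - cc))]
  expect_equal(at(2850), 1.0, tolerance = 1e-6)
  expect_equal(at(2890), 1.79305, tolerance = 1e-6)
  # raw amplitudes are below the composite targets (tails add up)
  expect_true(all(pk$amplitude < tgt))
})

test_that("cohort latents are recovered by the pipeline at group level", {
  co <- gen_cohort(default_cohort_spec(n_cells = 20, seed = 101))
  res <- analyze_cohort(co)
  ctrl <- res[res$group == "control", ]
  # group mean height within 2 SE of the 3.5 um preset
  expect_lt(abs(mean(ctrl$height_um) - 3.5), 2 * 0.35 / sqrt(20) + 0.05)
  # modulus within 2 SE + fit-noise allowance of the 5.7 kPa preset
  expect_lt(abs(mean(ctrl$E_s_kPa) - 5.7), 2 * 0.56 / sqrt(20) + 0.1)
  # order parameters within 2 SE of their presets
  expect_lt(abs(mean(ctrl$S_l) - 0.7287), 2 * 0.11 / sqrt(20) + 0.01)
  expect_lt(abs(mean(ctrl$S_t) - 0.41002), 2 * 0.09 / sqrt(20) + 0.01)
})

test_that("zero-SD cohorts give identical latent values per cell", {
  g <- list(height_um = c(2, 0), Ra_nm = c(100, 0), Rq_nm = c(120, 0),
            E_s_kPa = c(6, 0), S_l = c(0.7, 0), S_t = c(0.4, 0))
  co <- gen_cohort(cohort_spec(list(only = g), n_cells = 3, seed = 2))
  lat <- do.call(rbind, lapply(co$cells, function(cell)
    as.data.frame(cell$latent)))
  expect_true(all(apply(lat, 2, function(v) length(unique(v)) == 1L)))
})
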