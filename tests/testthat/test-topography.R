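# flattening, profiles, cell height, Ra/Rq roughness

test_that("flatten removes planes exactly and is idempotent", {
  n <- 32
  r <- row(matrix(0, n, n)); c_ <- col(matrix(0, n, n))
  plane <- heightmap(3 * r - 2 * c_ + 7, pixel_nm = 100)
  fl <- flatten(plane, order = 1)
  expect_lt(max(abs(fl$heights)), 1e-9)

  dome <- gen_topography(topo_spec(grid_px = 64, pixel_nm = 500,
                                   texture_sd_nm = 0))
  tilted <- heightmap(dome$heights + 0.5 * row(dome$heights), 500)
  # dome preserved up to the removed plane: flatten(tilted) == flatten(dome)
  expect_equal(flatten(tilted, 1)$heights, flatten(dome, 1)$heights,
               tolerance = 1e-9)
  # idempotence, both orders
  for (ord in 0:1) {
    once <- flatten(dome, ord)
    expect_equal(flatten(once, ord)$heights, once$heights,
                 tolerance = 1e-10)
  }
})

test_that("extract_profile interpolates sections correctly", {
  z <- matrix(seq_len(12), 3, 4)   # columns vary along a row
  hm <- heightmap(z, pixel_nm = 10)
  # horizontal line returns the row
  pr <- extract_profile(hm, c(2, 1), c(2, 4))
  expect_equal(pr$heights_nm, z[2, ], tolerance = 1e-12)
  expect_equal(pr$positions_nm, seq(0, 30, by = 10))

  # diagonal on the plane z = col: closed-form linear profile
  n <- 21
  plane <- heightmap(matrix(rep(seq_len(n), each = n), n, n, byrow = TRUE),
                     pixel_nm = 1)
  dg <- extract_profile(plane, c(1, 1), c(n, n))
  expect_equal(dg$heights_nm,
               seq(1, n, length.out = length(dg$heights_nm)),
               tolerance = 1e-10)

  # reversed endpoints mirror the profile
  fw <- extract_profile(hm, c(1, 1), c(3, 4))
  bw <- extract_profile(hm, c(3, 4), c(1, 1))
  expect_equal(bw$heights_nm, rev(fw$heights_nm), tolerance = 1e-12)

  expect_error(extract_profile(hm, c(2, 2), c(2, 2)), "zero-length")
})

test_that("cell_height inverts the dome generator and handles flats", {
  hm <- gen_topography(topo_spec(grid_px = 128, pixel_nm = 30000 / 128,
                                 cap_height_um = 3.5, cap_radius_um = 12,
                                 texture_sd_nm = 0))
  mid <- (nrow(hm$heights) + 1) / 2
  pr <- extract_profile(hm, c(mid, 1), c(mid, ncol(hm$heights)))
  expect_equal(cell_height(pr), 3.5, tolerance = 1e-3)

  flat <- extract_profile(heightmap(matrix(5, 16, 16), 100),
                          c(8, 1), c(8, 16))
  expect_equal(cell_height(flat), 0)

  short <- structure(list(positions_nm = 1:5, heights_nm = rep(0, 5)),
                     class = "lineprofile")
  expect_error(cell_height(short), "shorter")
})

test_that("roughness matches direct-summation oracles", {
  # constant ROI
  rr <- roughness(heightmap(matrix(3, 8, 8), 100), detrend = 0)
  expect_equal(rr$Ra_nm, 0)
  expect_equal(rr$Rq_nm, 0)

  # alternating +/- h about zero: Ra = Rq = h
  h <- 2.5
  chk <- heightmap(h * (-1)^(row(matrix(0, 8, 8)) + col(matrix(0, 8, 8))),
                   100)
  rr <- roughness(chk, detrend = 0)
  expect_equal(rr$Ra_nm, h, tolerance = 1e-12)
  expect_equal(rr$Rq_nm, h, tolerance = 1e-12)

  # brute-force double-loop oracle on random maps, incl. sub-ROIs
  set.seed(42)
  for (i in 1:50) {
    z <- matrix(rnorm(64, sd = runif(1, 1, 100)), 8, 8)
    ref <- brute_ra_rq(z)
    got <- roughness(heightmap(z, 50), detrend = 0)
    expect_equal(got$Ra_nm, ref[["Ra"]], tolerance = 1e-12)
    expect_equal(got$Rq_nm, ref[["Rq"]], tolerance = 1e-12)
    roi <- c(2L, 1L, 4L, 5L)
    ref2 <- brute_ra_rq(z, roi)
    got2 <- roughness(heightmap(z, 50), roi = roi, detrend = 0)
    expect_equal(got2$Ra_nm, ref2[["Ra"]], tolerance = 1e-12)
    expect_equal(got2$Rq_nm, ref2[["Rq"]], tolerance = 1e-12)
    expect_identical(got2$N, 20L)
  }
})

test_that("Gaussian texture obeys the half-normal identity", {
  # Ra -> sigma * sqrt(2/pi), Rq -> sigma on a large white-noise field
  sigma <- 80
  hm <- gen_topography(topo_spec(grid_px = 128, pixel_nm = 100,
                                 cap_height_um = 1e-6, cap_radius_um = 1e-6,
                                 texture_sd_nm = sigma, texture_corr_px = 0,
                                 seed = 8))
  rr <- roughness(hm, detrend = 0)
  expect_lt(abs(rr$Ra_nm - sigma * sqrt(2 / pi)) / (sigma * sqrt(2 / pi)),
            0.05)
  expect_lt(abs(rr$Rq_nm - sigma) / sigma, 0.05)
})

test_that("roughness invariances hold on random fixtures", {
  set.seed(7)
  for (i in 1:20) {
    z <- matrix(rnorm(15 * 11), 15, 11)
    base <- roughness(heightmap(z, 10), detrend = 0)
    # Rq >= Ra (power-mean inequality)
    expect_gte(base$Rq_nm, base$Ra_nm)
    # scale equivariance
    c0 <- runif(1, 0.1, 10)
    sc <- roughness(heightmap(c0 * z, 10), detrend = 0)
    expect_equal(sc$Ra_nm, c0 * base$Ra_nm, tolerance = 1e-12)
    expect_equal(sc$Rq_nm, c0 * base$Rq_nm, tolerance = 1e-12)
    # translation invariance
    tr <- roughness(heightmap(z + rnorm(1, sd = 100), 10), detrend = 0)
    expect_equal(tr$Ra_nm, base$Ra_nm, tolerance = 1e-9)
    expect_equal(tr$Rq_nm, base$Rq_nm, tolerance = 1e-9)
  }
  expect_error(roughness(heightmap(matrix(0, 4, 4), 10),
                         roi = c(0, 0, 1, 4)),
               "degenerate")
})
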