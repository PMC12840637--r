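# AFM topography analysis: flattening, cross-section profiles, cell height,
# and Ra/Rq roughness over a selected region.

#' Flatten a height map
#'
#' Removes the scan-wide background from raw topography before any profile or
#' roughness measurement: order 0 subtracts the mean height, order 1 subtracts
#' the least-squares best-fit plane. Both are idempotent.
#'
#' @param map a [heightmap()].
#' @param order 0 (mean removal) or 1 (plane removal).
#' @return A flattened [heightmap()].
#' @export
flatten <- function(map, order = 1) {
  stopifnot(inherits(map, "heightmap"))
  if (!order %in% c(0, 1)) stop("flatten: order must be 0 or 1",
                                call. = FALSE)
  z <- map$heights
  if (order == 0) {
    z <- z - mean(z)
  } else {
    nr <- nrow(z); nc <- ncol(z)
    r <- rep(seq_len(nr), times = nc)
    c_ <- rep(seq_len(nc), each = nr)
    fit <- stats::lm.fit(cbind(1, r, c_), as.vector(z))
    z <- matrix(fit$residuals, nr, nc)
  }
  heightmap(z, map$pixel_nm)
}

#' Extract a cross-section line profile
#'
#' Samples heights along the segment from `p0` to `p1` by bilinear
#' interpolation, at a spacing of about one pixel. Positions are distances in
#' nm along the section from `p0`.
#'
#' @param map a [heightmap()].
#' @param p0,p1 numeric `(row, col)` endpoints, 1-based, inside the grid
#'   (fractional coordinates allowed).
#' @return A list of class `lineprofile` with `positions_nm` (strictly
#'   increasing) and `heights_nm`.
#' @export
extract_profile <- function(map, p0, p1) {
  stopifnot(inherits(map, "heightmap"))
  z <- map$heights
  chk <- function(p, nm) {
    if (length(p) != 2L || !all(is.finite(p)) ||
        p[1] < 1 || p[1] > nrow(z) || p[2] < 1 || p[2] > ncol(z)) {
      stop(sprintf("extract_profile: %s outside grid", nm), call. = FALSE)
    }
  }
  chk(p0, "p0"); chk(p1, "p1")
  len_px <- sqrt(sum((p1 - p0)^2))
  if (len_px == 0) stop("extract_profile: zero-length segment", call. = FALSE)
  n <- max(2L, ceiling(len_px) + 1L)
  t <- seq(0, 1, length.out = n)
  rr <- p0[1] + t * (p1[1] - p0[1])
  cc <- p0[2] + t * (p1[2] - p0[2])
  # bilinear interpolation on the grid
  r0 <- pmin(floor(rr), nrow(z) - 1L); r0[nrow(z) == 1] <- 1
  c0 <- pmin(floor(cc), ncol(z) - 1L); c0[ncol(z) == 1] <- 1
  fr <- rr - r0; fc <- cc - c0
  r1 <- pmin(r0 + 1L, nrow(z)); c1 <- pmin(c0 + 1L, ncol(z))
  h <- (1 - fr) * (1 - fc) * z[cbind(r0, c0)] +
       fr * (1 - fc) * z[cbind(r1, c0)] +
       (1 - fr) * fc * z[cbind(r0, c1)] +
       fr * fc * z[cbind(r1, c1)]
  structure(list(positions_nm = t * len_px * map$pixel_nm, heights_nm = h),
            class = "lineprofile")
}

#' Cell height from a cross-section profile
#'
#' The profile must span substrate on both sides of the cell. The substrate
#' level is the median of the lowest `substrate_frac` fraction of samples;
#' cell height is the profile maximum minus that level, reported in um
#' (figure-axis convention; raw heights stay in nm).
#'
#' @param profile a `lineprofile` from [extract_profile()].
#' @param substrate_frac fraction of lowest samples taken as substrate
#'   (default 0.2).
#' @return Cell height in um.
#' @export
cell_height <- function(profile, substrate_frac = 0.2) {
  stopifnot(inherits(profile, "lineprofile"))
  h <- profile$heights_nm
  if (length(h) < 10L) {
    stop("cell_height: profile shorter than 10 samples", call. = FALSE)
  }
  if (substrate_frac <= 0 || substrate_frac > 1) {
    stop("cell_height: substrate_frac must be in (0, 1]", call. = FALSE)
  }
  k <- max(1L, floor(substrate_frac * length(h)))
  substrate <- stats::median(sort(h)[seq_len(k)])
  (max(h) - substrate) / 1e3
}

#' Surface roughness Ra and Rq over a region of interest
#'
#' Computes the arithmetic-mean roughness Ra and root-mean-square roughness
#' Rq of a rectangular region, after local detrending:
#' \deqn{R_a = \frac{1}{N} \sum_{j=1}^{N} |Z_j - \bar Z|, \qquad
#'       R_q = \sqrt{\frac{1}{N} \sum_{i=1}^{N} (Z_i - \bar Z)^2}}
#' where N is the number of sampling points in the region and Z the local
#' height. Deviations are taken about the detrended-region mean, so Rq is a
#' (population) standard deviation of the region and Rq >= Ra always holds.
#'
#' @param map a [heightmap()].
#' @param roi integer `(row0, col0, rows, cols)`: 0-based half-open rectangle,
#'   default the whole map.
#' @param detrend 0 (mean removal only) or 1 (remove best-fit plane within
#'   the ROI, the default; strips residual cell curvature/tilt).
#' @return A list of class `roughnessresult` with `Ra_nm`, `Rq_nm`, `roi`,
#'   `N`.
#' @examples
#' hm <- heightmap(matrix(c(1, -1), 8, 8), pixel_nm = 100)
#' roughness(hm, detrend = 0)
#' @export
roughness <- function(map, roi = NULL, detrend = 1) {
  stopifnot(inherits(map, "heightmap"))
  if (!detrend %in% c(0, 1)) stop("roughness: detrend must be 0 or 1",
                                  call. = FALSE)
  z <- map$heights
  if (is.null(roi)) roi <- c(0L, 0L, nrow(z), ncol(z))
  roi <- as.integer(roi)
  if (length(roi) != 4L) stop("roughness: roi must be (row0, col0, rows, cols)",
                              call. = FALSE)
  r0 <- roi[1]; c0 <- roi[2]; nr <- roi[3]; nc <- roi[4]
  if (nr < 2L || nc < 2L || r0 < 0L || c0 < 0L ||
      r0 + nr > nrow(z) || c0 + nc > ncol(z)) {
    stop("roughness: roi degenerate or outside grid", call. = FALSE)
  }
  w <- z[(r0 + 1L):(r0 + nr), (c0 + 1L):(c0 + nc), drop = FALSE]
  if (detrend == 1) {
    r <- rep(seq_len(nr), times = nc)
    c_ <- rep(seq_len(nc), each = nr)
    fit <- stats::lm.fit(cbind(1, r, c_), as.vector(w))
    dev <- fit$residuals
  } else {
    dev <- as.vector(w) - mean(w)
  }
  n <- length(dev)
  structure(list(Ra_nm = mean(abs(dev)), Rq_nm = sqrt(sum(dev^2) / n),
                 roi = roi, N = n),
            class = "roughnessresult")
}

#' @export
print.roughnessresult <- function(x, ...) {
  cat(sprintf("<roughness> Ra = %.5g nm, Rq = %.5g nm (N = %d)\n",
              x$Ra_nm, x$Rq_nm, x$N))
  invisible(x)
}

#' Convert a physical ROI side length to pixels
#'
#' Convenience for selecting e.g. a 5 um x 5 um local region on a map:
#' returns `round(side_nm / pixel_nm)` pixels.
#'
#' @param side_nm side length in nm.
#' @param pixel_nm pixel size in nm.
#' @export
roi_side_px <- function(side_nm, pixel_nm) {
  as.integer(round(side_nm / pixel_nm))
}
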