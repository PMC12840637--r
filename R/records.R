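#' @keywords internal
"_PACKAGE"

# Internal unit conventions, used everywhere:
#   heights / indentation / pixel size  nm
#   force                               nN
#   moduli                              kPa
#   reported cell height                um
# hertz_force() documents the nN = f(nm, kPa) conversion constant.

#' Construct an AFM height map
#'
#' A height map is the topography record of one AFM scan: a rectangular grid
#' of surface heights (nm) with a physical pixel size. Row 1 is the first
#' scan line; indices are 1-based in R but stored metadata uses physical
#' units only.
#'
#' @param heights numeric matrix of heights in nm; all values finite.
#' @param pixel_nm physical size of one pixel in nm (> 0).
#' @return An object of class `heightmap`.
#' @examples
#' hm <- heightmap(matrix(0, 16, 16), pixel_nm = 100)
#' dim(hm$heights)
#' @export
heightmap <- function(heights, pixel_nm) {
  heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  stopifnot(is.numeric(pixel_nm), length(pixel_nm) == 1L)
  if (!all(is.finite(heights))) {
    stop("heightmap: all heights must be finite", call. = FALSE)
  }
  if (!is.finite(pixel_nm) || pixel_nm <= 0) {
    stop("heightmap: pixel_nm must be > 0", call. = FALSE)
  }
  structure(list(heights = heights, pixel_nm = pixel_nm),
            class = "heightmap")
}

#' @export
print.heightmap <- function(x, ...) {
  cat(sprintf("<heightmap> %d x %d px, pixel %.4g nm (%.3g x %.3g um)\n",
              nrow(x$heights), ncol(x$heights), x$pixel_nm,
              nrow(x$heights) * x$pixel_nm / 1e3,
              ncol(x$heights) * x$pixel_nm / 1e3))
  cat(sprintf("  height range [%.4g, %.4g] nm\n",
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Construct a force-indentation curve
#'
#' The force-spectroscopy record: paired piezo indentation (nm) and cantilever
#' force (nN) samples, plus the probe metadata (tip radius, spring constant)
#' that a Hertz fit needs. Indentation is stored ascending; the true
#' tip-sample contact point is somewhere inside the ramp and must be
#' estimated (see [detect_contact()]).
#'
#' @param indentation_nm numeric vector, ascending piezo positions in nm.
#' @param force_nN numeric vector, same length, forces in nN.
#' @param R_nm tip radius in nm (> 0).
#' @param k_N_per_m cantilever spring constant in N/m (metadata only).
#' @param sort if `TRUE`, sort samples by indentation instead of failing.
#' @return An object of class `forcecurve`.
#' @export
forcecurve <- function(indentation_nm, force_nN, R_nm, k_N_per_m = NA_real_,
                       sort = FALSE) {
  indentation_nm <- as.double(indentation_nm)
  force_nN <- as.double(force_nN)
  if (length(indentation_nm) != length(force_nN)) {
    stop("forcecurve: indentation and force must have equal length",
         call. = FALSE)
  }
  if (length(indentation_nm) < 20L) {
    stop("forcecurve: need at least 20 samples", call. = FALSE)
  }
  if (!all(is.finite(indentation_nm)) || !all(is.finite(force_nN))) {
    stop("forcecurve: non-finite samples", call. = FALSE)
  }
  if (is.unsorted(indentation_nm)) {
    if (!sort) stop("forcecurve: indentation must be non-decreasing",
                    call. = FALSE)
    o <- order(indentation_nm)
    indentation_nm <- indentation_nm[o]
    force_nN <- force_nN[o]
  }
  if (!is.finite(R_nm) || R_nm <= 0) {
    stop("forcecurve: R_nm must be > 0", call. = FALSE)
  }
  structure(list(indentation_nm = indentation_nm, force_nN = force_nN,
                 R_nm = as.double(R_nm), k_N_per_m = as.double(k_N_per_m)),
            class = "forcecurve")
}

#' @export
print.forcecurve <- function(x, ...) {
  cat(sprintf(
    "<forcecurve> %d samples, indentation [%.4g, %.4g] nm, R = %.4g nm\n",
    length(x$indentation_nm), min(x$indentation_nm), max(x$indentation_nm),
    x$R_nm))
  invisible(x)
}

#' Construct a Raman spectrum
#'
#' Wavenumber/intensity series from a spectrometer export. Wavenumbers are
#' stored strictly ascending; descending inputs are flipped.
#'
#' @param wavenumber_cm1 numeric vector of wavenumbers (cm^-1).
#' @param intensity_au numeric vector of intensities (arbitrary units).
#' @return An object of class `ramanspectrum`.
#' @export
ramanspectrum <- function(wavenumber_cm1, intensity_au) {
  wavenumber_cm1 <- as.double(wavenumber_cm1)
  intensity_au <- as.double(intensity_au)
  if (length(wavenumber_cm1) != length(intensity_au)) {
    stop("ramanspectrum: wavenumber and intensity lengths differ",
         call. = FALSE)
  }
  if (!all(is.finite(wavenumber_cm1)) || !all(is.finite(intensity_au))) {
    stop("ramanspectrum: non-finite values", call. = FALSE)
  }
  if (anyDuplicated(wavenumber_cm1)) {
    stop("ramanspectrum: duplicate wavenumbers", call. = FALSE)
  }
  d <- diff(wavenumber_cm1)
  if (all(d < 0)) {
    wavenumber_cm1 <- rev(wavenumber_cm1)
    intensity_au <- rev(intensity_au)
  } else if (any(d < 0)) {
    o <- order(wavenumber_cm1)
    wavenumber_cm1 <- wavenumber_cm1[o]
    intensity_au <- intensity_au[o]
  }
  structure(list(wavenumber_cm1 = wavenumber_cm1,
                 intensity_au = intensity_au),
            class = "ramanspectrum")
}

#' @export
print.ramanspectrum <- function(x, ...) {
  cat(sprintf("<ramanspectrum> %d points, %.5g-%.5g cm-1\n",
              length(x$wavenumber_cm1), min(x$wavenumber_cm1),
              max(x$wavenumber_cm1)))
  invisible(x)
}

#' Summarize per-cell metric values for one treatment group
#'
#' The group record every between-group comparison runs on: the raw per-cell
#' values, their mean, sample SD (n - 1 denominator) and n.
#'
#' @param values numeric vector of per-cell metric values, length >= 2.
#' @param label group label, e.g. `"control"`.
#' @return An object of class `groupsummary` with fields `group_label`,
#'   `values`, `mean`, `sd`, `n`.
#' @examples
#' summarize_group(c(1, 2, 3), "control")
#' @export
summarize_group <- function(values, label) {
  values <- as.double(values)
  if (length(values) < 2L) {
    stop("summarize_group: need n >= 2 values", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("summarize_group: non-finite values", call. = FALSE)
  }
  structure(list(group_label = as.character(label), values = values,
                 mean = mean(values), sd = stats::sd(values),
                 n = length(values)),
            class = "groupsummary")
}

#' @export
print.groupsummary <- function(x, ...) {
  cat(sprintf("<groupsummary> %s: %.5g +/- %.3g (n = %d)\n",
              x$group_label, x$mean, x$sd, x$n))
  invisible(x)
}

# quiet, switchable progress/audit logging
lm_log <- function(fmt, ...) {
  if (isTRUE(getOption("lensmech.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}
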