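# Raman membrane-fluidity analysis: asymmetric-least-squares baseline
# correction, windowed peak heights, and the lipid-chain order parameters
#   S_l = (I_CH2 - 0.7) / 1.5,  I_CH2 = I_2890 / I_2850
#   S_t = I_C=C / 1.77,         I_C=C = I_1130 / I_1090
# The 0.7 / 1.5 / 1.77 constants are literature calibration constants and
# are treated as fixed.

#' Default Raman band set for the fluidity analysis
#'
#' Band centers and the half-window used when reading peak heights. The CH
#' stretching pair (2890/2850 cm^-1) feeds the lateral order parameter S_l;
#' the C-C skeletal pair (1130/1090 cm^-1, trans vs gauche conformers) feeds
#' the trans order parameter S_t.
#'
#' @param half_window_cm1 half-width of the peak-search window (default 8).
#' @return A data.frame with columns `band`, `center_cm1`,
#'   `half_window_cm1`.
#' @export
default_bands <- function(half_window_cm1 = 8) {
  data.frame(
    band = c("I2890", "I2850", "I1130", "I1090"),
    center_cm1 = c(2890, 2850, 1130, 1090),
    half_window_cm1 = half_window_cm1,
    stringsAsFactors = FALSE
  )
}

# Whittaker-smoother-based asymmetric least squares (Eilers & Boelens):
# minimise sum w_i (y_i - z_i)^2 + lambda * sum (diff^2 z)^2 with
# w_i = p where y > z (peaks), 1 - p elsewhere.
als_baseline <- function(y, lam = 1e11, p = 0.001, n_iter = 10L) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  DtD <- lam * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (i in seq_len(n_iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.vector(Matrix::solve(W + DtD, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Baseline-correct a Raman spectrum
#'
#' Subtracts an asymmetric-least-squares (Whittaker smoother) baseline
#' estimate. The asymmetry weight `p` keeps the smooth curve under the peaks
#' so peak heights survive correction; `lam` sets the stiffness of the
#' baseline (larger = smoother).
#'
#' @details The default stiffness is deliberately high. The smoother's
#' effective length scale grows as `lam^(1/4)` in grid points; on the dense
#' grids produced by modern spectrometers (0.5-1 cm^-1 per point) it must
#' exceed the width of overlapping band *clusters* (the CH stretching region
#' spans ~100 cm^-1), otherwise the baseline climbs into the cluster's
#' shared Lorentzian tails and the corrected peak heights - and every height
#' ratio built from them - are biased. `lam = 1e11`, `p = 0.001` keeps band
#' heights within 1% on peaks-plus-linear-baseline data; the cost is that
#' strongly curved (high-order) backgrounds are tracked only approximately.
#'
#' @param spectrum a [ramanspectrum()].
#' @param lam smoothness penalty (default 1e11; see Details).
#' @param p asymmetry weight for points above the baseline (default 0.001).
#' @param n_iter reweighting iterations (default 10).
#' @return A baseline-corrected [ramanspectrum()].
#' @export
baseline_correct <- function(spectrum, lam = 1e11, p = 0.001, n_iter = 10L) {
  stopifnot(inherits(spectrum, "ramanspectrum"))
  if (length(spectrum$intensity_au) < 50L) {
    stop("baseline_correct: spectrum too short for analysis (< 50 points)",
         call. = FALSE)
  }
  z <- als_baseline(spectrum$intensity_au, lam = lam, p = p,
                    n_iter = as.integer(n_iter))
  out <- spectrum$intensity_au - z
  if (!all(is.finite(out))) {
    stop("baseline_correct: non-finite corrected intensities", call. = FALSE)
  }
  lm_log("baseline_correct: lam = %g, p = %g, n_iter = %d", lam, p, n_iter)
  ramanspectrum(spectrum$wavenumber_cm1, out)
}

#' Peak height within a wavenumber window
#'
#' Height of a band measured as the maximum (baseline-corrected) intensity
#' inside `[center - w, center + w]`. A warning is logged when the window
#' maximum sits at a window edge, the usual sign that the window missed the
#' peak.
#'
#' @param spectrum a (baseline-corrected) [ramanspectrum()].
#' @param center_cm1 band center in cm^-1.
#' @param half_window_cm1 half-window in cm^-1 (default 8).
#' @return Peak height in the spectrum's intensity units.
#' @export
peak_height <- function(spectrum, center_cm1, half_window_cm1 = 8) {
  stopifnot(inherits(spectrum, "ramanspectrum"))
  wn <- spectrum$wavenumber_cm1
  sel <- wn >= center_cm1 - half_window_cm1 & wn <= center_cm1 + half_window_cm1
  if (!any(sel)) stop("peak_height: empty window", call. = FALSE)
  ii <- which(sel)
  k <- which.max(spectrum$intensity_au[ii])
  if (k == 1L || k == length(ii)) {
    lm_log("peak_height: window max at edge for center %.1f cm-1", center_cm1)
  }
  spectrum$intensity_au[ii][k]
}

#' Lipid-chain order parameters from band-height ratios
#'
#' \deqn{S_l = (I_{CH_2} - 0.7)/1.5, \qquad S_t = I_{C=C}/1.77}
#' where \eqn{I_{CH_2} = I_{2890}/I_{2850}} measures lateral inter-chain
#' packing and \eqn{I_{C=C} = I_{1130}/I_{1090}} the trans/gauche conformer
#' balance along the chain. Both are strictly increasing in their input;
#' higher values mean a more ordered, less fluid membrane.
#'
#' @param I_CH2 height ratio I_2890 / I_2850 (> 0).
#' @param I_CdoubleC height ratio I_1130 / I_1090 (> 0).
#' @return A list with `S_l` and `S_t`.
#' @examples
#' order_parameters(1.79305, 0.72574) # S_l = 0.7287, S_t = 0.41002
#' @export
order_parameters <- function(I_CH2, I_CdoubleC) {
  if (any(I_CH2 <= 0) || any(I_CdoubleC <= 0)) {
    stop("order_parameters: ratios must be > 0", call. = FALSE)
  }
  list(S_l = (I_CH2 - 0.7) / 1.5, S_t = I_CdoubleC / 1.77)
}

#' Full membrane-fluidity pipeline for one spectrum
#'
#' Composition of [baseline_correct()], [peak_height()] for the four bands
#' of `bands`, and [order_parameters()]. All intermediate heights are
#' reported so ratios are auditable. Because both order parameters are
#' ratios of heights, the result is invariant to rescaling the whole
#' spectrum.
#'
#' @param spectrum a raw [ramanspectrum()] covering at least 1000-3050
#'   cm^-1.
#' @param bands band table as from [default_bands()].
#' @param lam,p,n_iter baseline parameters, see [baseline_correct()].
#' @return An object of class `fluidityresult`: per-band heights `I_2890`,
#'   `I_2850`, `I_1130`, `I_1090`, ratios `I_CH2`, `I_CdoubleC`, and `S_l`,
#'   `S_t`.
#' @export
fluidity_pipeline <- function(spectrum, bands = default_bands(),
                              lam = 1e11, p = 0.001, n_iter = 10L) {
  stopifnot(inherits(spectrum, "ramanspectrum"))
  wn <- spectrum$wavenumber_cm1
  if (min(wn) > 1000 || max(wn) < 3050) {
    stop("fluidity_pipeline: spectrum must cover 1000-3050 cm-1",
         call. = FALSE)
  }
  corrected <- baseline_correct(spectrum, lam = lam, p = p, n_iter = n_iter)
  hs <- vapply(seq_len(nrow(bands)), function(i) {
    peak_height(corrected, bands$center_cm1[i], bands$half_window_cm1[i])
  }, numeric(1))
  names(hs) <- bands$band
  if (any(hs <= 0)) {
    stop("fluidity_pipeline: non-positive band height", call. = FALSE)
  }
  I_CH2 <- hs[["I2890"]] / hs[["I2850"]]
  I_CdoubleC <- hs[["I1130"]] / hs[["I1090"]]
  op <- order_parameters(I_CH2, I_CdoubleC)
  structure(list(I_2890 = hs[["I2890"]], I_2850 = hs[["I2850"]],
                 I_1130 = hs[["I1130"]], I_1090 = hs[["I1090"]],
                 I_CH2 = I_CH2, I_CdoubleC = I_CdoubleC,
                 S_l = op$S_l, S_t = op$S_t),
            class = "fluidityresult")
}

#' @export
print.fluidityresult <- function(x, ...) {
  cat(sprintf("<fluidity> S_l = %.5g, S_t = %.5g (I_CH2 = %.5g, I_C=C = %.5g)\n",
              x$S_l, x$S_t, x$I_CH2, x$I_CdoubleC))
  invisible(x)
}

#' Between-group variation rate of a metric
#'
#' Percent change of the comparison group's mean relative to the reference
#' group's mean: `100 * (mean_cmp - mean_ref) / mean_ref`.
#'
#' @param ref,cmp `groupsummary` records ([summarize_group()]).
#' @param metric metric name carried into the result (default `""`).
#' @return A list of class `varrate` with `metric`, `reference`,
#'   `comparison`, `percent_change`.
#' @export
var_rate <- function(ref, cmp, metric = "") {
  stopifnot(inherits(ref, "groupsummary"), inherits(cmp, "groupsummary"))
  if (ref$mean == 0) stop("var_rate: zero reference mean", call. = FALSE)
  structure(list(metric = metric, reference = ref$group_label,
                 comparison = cmp$group_label,
                 percent_change = 100 * (cmp$mean - ref$mean) / ref$mean),
            class = "varrate")
}

#' @export
print.varrate <- function(x, ...) {
  cat(sprintf("<varrate> %s %s vs %s: %+.2f%%\n", x$metric, x$comparison,
              x$reference, x$percent_change))
  invisible(x)
}
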