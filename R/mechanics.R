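# Spherical Hertz contact analysis of AFM force-indentation curves.
#
# All arithmetic is done in nm / nN / kPa. For a spherical indenter,
#   F = (4/3) sqrt(R) E_r delta^(3/2)
# in SI units; with R, delta in nm and E_r in kPa the same expression times
# 1e-6 gives F in nN (1 kPa * nm^2 = 1e-6 nN).
HERTZ_NN <- 4 / 3 * 1e-6

#' Hertz force for a spherical indenter
#'
#' Evaluates the spherical Hertz contact model
#' \deqn{F(\delta) = \tfrac{4}{3} \sqrt{R}\, E_r\, \delta^{3/2}}
#' with tip radius `R_nm` (nm), reduced modulus `E_r_kPa` (kPa) and
#' indentation `delta_nm` (nm), returning force in nN. Monotone increasing
#' and convex in delta, linear in E_r.
#'
#' @param delta_nm indentation(s) in nm, >= 0.
#' @param R_nm tip radius in nm.
#' @param E_r_kPa reduced Young's modulus in kPa.
#' @return Force(s) in nN.
#' @examples
#' hertz_force(500, R_nm = 20, E_r_kPa = 10) # 0.6667 nN
#' @export
hertz_force <- function(delta_nm, R_nm, E_r_kPa) {
  if (any(delta_nm < 0)) stop("hertz_force: negative indentation",
                              call. = FALSE)
  stopifnot(R_nm > 0, E_r_kPa > 0)
  HERTZ_NN * sqrt(R_nm) * E_r_kPa * delta_nm^1.5
}

#' Sample Young's modulus from the reduced modulus
#'
#' Under the rigid-tip assumption the reduced modulus of the contact obeys
#' \eqn{1/E_r = (1 - \nu_s^2)/E_s}, i.e. \eqn{E_s = E_r (1 - \nu_s^2)}.
#' Cells are conventionally treated as incompressible (`nu_s = 0.5`), giving
#' \eqn{E_s = 0.75 E_r}.
#'
#' @param E_r_kPa reduced modulus in kPa.
#' @param nu_s sample Poisson ratio in \[0, 0.5\].
#' @return Sample Young's modulus in kPa.
#' @export
sample_modulus <- function(E_r_kPa, nu_s = 0.5) {
  if (any(nu_s < 0) || any(nu_s > 0.5)) {
    stop("sample_modulus: nu_s must be in [0, 0.5]", call. = FALSE)
  }
  E_r_kPa * (1 - nu_s^2)
}

#' Detect the tip-sample contact point of a force curve
#'
#' The pre-contact baseline is taken as the first 20% of samples. The contact
#' point is the first sample whose force exceeds the baseline level by
#' `threshold_sd` baseline-noise units and stays above that threshold for at
#' least 5 consecutive samples. Baseline level and noise are the median and
#' MAD of the baseline segment: the baseline window is fixed at 20%, so when
#' true contact falls inside it the robust statistics ignore the
#' contaminating post-contact tail where mean/SD would inflate the
#' threshold. Curves with no crossing are rejected as unanalyzable.
#'
#' @param curve a [forcecurve()].
#' @param threshold_sd threshold in baseline-SD units (default 3).
#' @return Contact position in nm (same axis as `indentation_nm`).
#' @export
detect_contact <- function(curve, threshold_sd = 3) {
  stopifnot(inherits(curve, "forcecurve"))
  f <- curve$force_nN
  n <- length(f)
  nb <- max(2L, floor(0.2 * n))
  b <- f[seq_len(nb)]
  thr <- stats::median(b) + threshold_sd * stats::mad(b)
  above <- f > thr
  run <- 5L
  # first index from which `run` consecutive samples sit above threshold
  idx <- which(above)
  for (i in idx) {
    if (i + run - 1L <= n && all(above[i:(i + run - 1L)])) {
      return(curve$indentation_nm[i])
    }
  }
  stop("detect_contact: no contact crossing found; curve unanalyzable",
       call. = FALSE)
}

#' Fit the spherical Hertz model to a force curve
#'
#' Least-squares fit of \eqn{F = \tfrac{4}{3}\sqrt{R} E_r (\delta - c)^{3/2}}
#' over the post-contact segment, with the reduced modulus \eqn{E_r} free and
#' the contact point \eqn{c} refined continuously in the least-squares
#' objective. The refinement window is asymmetric around the threshold
#' detection ([detect_contact()]): a threshold crossing always fires *after*
#' true contact (the force has to climb out of the noise), never before, so
#' \eqn{c} is searched from the start of the ramp up to 10 sample spacings
#' past the detection. Because the model is linear in \eqn{E_r}, the modulus
#' is profiled out exactly for each candidate contact point and only \eqn{c}
#' is searched numerically, which removes the need for multi-start
#' initialisation.
#'
#' The fitted segment runs from the contact point up to `fit_fraction` of the
#' maximum post-contact indentation. Fits are flagged (and should be excluded
#' from group summaries) when the modulus lands on its bounds
#' (\[0.01, 1e4\] kPa) or when the mean squared residual exceeds 25x the
#' curve's noise variance (robustly estimated from second differences, which
#' cancel any smooth force trend), indicating non-Hertzian data.
#'
#' @param curve a [forcecurve()].
#' @param nu_s sample Poisson ratio (default 0.5).
#' @param fit_fraction fraction of the maximum post-contact indentation to
#'   fit (default 1.0).
#' @param threshold_sd passed to [detect_contact()].
#' @return An object of class `hertzfit`: `E_r_kPa`, `E_s_kPa`, `nu_s`,
#'   `contact_nm`, `rss`, `n_used`, `flag` (`"ok"`, `"bounds"` or
#'   `"misfit"`).
#' @export
fit_hertz <- function(curve, nu_s = 0.5, fit_fraction = 1.0,
                      threshold_sd = 3) {
  stopifnot(inherits(curve, "forcecurve"))
  if (fit_fraction <= 0 || fit_fraction > 1) {
    stop("fit_hertz: fit_fraction must be in (0, 1]", call. = FALSE)
  }
  d <- curve$indentation_nm
  f <- curve$force_nN
  c0 <- detect_contact(curve, threshold_sd)
  h <- stats::median(diff(d))
  lo <- min(d)
  hi <- min(max(d) - 10 * h, c0 + 10 * h)
  if (hi < lo) hi <- lo
  bounds <- c(0.01, 1e4)
  sqR <- sqrt(curve$R_nm)

  profile <- function(cc) {
    post <- d > cc
    if (sum(post) < 10L) return(list(obj = Inf))
    de <- d[post] - cc
    keep <- de <= fit_fraction * max(de)
    de <- de[keep]; fe <- f[post][keep]
    if (length(de) < 10L) return(list(obj = Inf))
    g <- HERTZ_NN * sqR * de^1.5
    Er <- sum(fe * g) / sum(g^2)
    Er <- min(max(Er, bounds[1]), bounds[2])
    res <- fe - Er * g
    list(obj = mean(res^2), Er = Er, rss = sum(res^2), n = length(de),
         c = cc)
  }

  # coarse grid over candidate contact points, then continuous refinement
  cand <- unique(pmin(pmax(seq(lo, hi, length.out = 41L), lo), hi))
  objs <- vapply(cand, function(cc) profile(cc)$obj, numeric(1))
  if (all(!is.finite(objs))) {
    stop("fit_hertz: fewer than 10 post-contact samples", call. = FALSE)
  }
  cbest <- cand[which.min(objs)]
  span <- max(h, (hi - lo) / 40)
  opt <- stats::optimize(function(cc) profile(cc)$obj,
                         lower = max(lo, cbest - span),
                         upper = min(hi, cbest + span),
                         tol = max(h * 1e-8, .Machine$double.eps^0.5))
  best <- profile(opt$minimum)
  if (!is.finite(best$obj) || best$obj > min(objs, na.rm = TRUE)) {
    best <- profile(cbest)
  }

  # noise floor from second differences: smooth signal cancels, white noise
  # of SD sigma leaves second differences of SD sigma * sqrt(6)
  noise_var <- (1.4826 * stats::median(abs(diff(f, differences = 2))) /
                  sqrt(6))^2
  flag <- "ok"
  if (best$Er <= bounds[1] * (1 + 1e-9) || best$Er >= bounds[2] * (1 - 1e-9)) {
    flag <- "bounds"
  } else if (best$obj > max(25 * noise_var, 1e-12)) {
    flag <- "misfit"
  }
  if (flag != "ok") {
    lm_log("fit_hertz: flagged curve (%s), E_r = %.4g kPa, msr = %.3g",
           flag, best$Er, best$obj)
  }
  structure(list(E_r_kPa = best$Er,
                 E_s_kPa = sample_modulus(best$Er, nu_s),
                 nu_s = nu_s, contact_nm = best$c, rss = best$rss,
                 n_used = best$n, flag = flag),
            class = "hertzfit")
}

#' @export
print.hertzfit <- function(x, ...) {
  cat(sprintf(
    "<hertzfit> E_s = %.4g kPa (E_r = %.4g), contact %.4g nm, n = %d [%s]\n",
    x$E_s_kPa, x$E_r_kPa, x$contact_nm, x$n_used, x$flag))
  invisible(x)
}

#' Aggregate per-curve Hertz fits into a group summary
#'
#' Collects the sample moduli of unflagged fits into a [summarize_group()]
#' record; flagged fits (bounds, misfit) are dropped with a log line.
#'
#' @param fits list of `hertzfit` objects.
#' @param label group label.
#' @return A `groupsummary` of `E_s_kPa`.
#' @export
aggregate_moduli <- function(fits, label) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, TRUE, "hertzfit")))
  ok <- vapply(fits, function(f) f$flag == "ok", TRUE)
  if (sum(!ok) > 0) {
    lm_log("aggregate_moduli: dropping %d flagged fit(s)", sum(!ok))
  }
  if (sum(ok) < 2L) {
    stop("aggregate_moduli: fewer than 2 unflagged fits", call. = FALSE)
  }
  summarize_group(vapply(fits[ok], `[[`, numeric(1), "E_s_kPa"), label)
}
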