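# Group statistics and report tables: mean +/- SD summaries, unpaired
# two-tailed Student's t-tests (pooled variance by default, Welch optional),
# one-way ANOVA, and the per-metric report the pipeline ends in.

#' Unpaired two-tailed t-test between two group summaries
#'
#' Pooled-variance Student's t by default; Welch's correction optionally.
#' When both groups have zero variance and equal means the comparison is
#' vacuous and `p = 1` is returned by convention.
#'
#' @param a,b `groupsummary` records ([summarize_group()]).
#' @param welch use Welch's unequal-variance t (default `FALSE`).
#' @param alpha significance level recorded on the result (default 0.05).
#' @return A list of class `comparisonresult`: `metric`, `test`, `groups`,
#'   `statistic`, `p_value`, `significant_at`.
#' @export
group_ttest <- function(a, b, welch = FALSE, alpha = 0.05) {
  stopifnot(inherits(a, "groupsummary"), inherits(b, "groupsummary"))
  if (a$sd == 0 && b$sd == 0) {
    if (a$mean == b$mean) {
      return(structure(list(metric = "", test = "t-test (degenerate)",
                            groups = c(a$group_label, b$group_label),
                            statistic = 0, p_value = 1,
                            significant_at = alpha),
                       class = "comparisonresult"))
    }
    # zero variance, different means: perfectly separated
    return(structure(list(metric = "", test = "t-test (degenerate)",
                          groups = c(a$group_label, b$group_label),
                          statistic = Inf, p_value = 0,
                          significant_at = alpha),
                     class = "comparisonresult"))
  }
  tt <- stats::t.test(a$values, b$values, var.equal = !welch,
                      alternative = "two.sided")
  structure(list(metric = "",
                 test = if (welch) "Welch t-test" else "Student t-test",
                 groups = c(a$group_label, b$group_label),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value, significant_at = alpha),
            class = "comparisonresult")
}

#' One-way ANOVA across group summaries
#'
#' @param groups list of `groupsummary` records (>= 2).
#' @param alpha significance level recorded on the result.
#' @return A `comparisonresult` with the F statistic and p value.
#' @export
group_anova <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups),
            all(vapply(groups, inherits, TRUE, "groupsummary")))
  if (length(groups) < 2L) stop("group_anova: need >= 2 groups",
                                call. = FALSE)
  values <- unlist(lapply(groups, `[[`, "values"))
  labels <- factor(rep(vapply(groups, `[[`, character(1), "group_label"),
                       vapply(groups, `[[`, integer(1), "n")))
  if (stats::var(values) == 0) {
    return(structure(list(metric = "", test = "one-way ANOVA (degenerate)",
                          groups = levels(labels), statistic = 0,
                          p_value = 1, significant_at = alpha),
                     class = "comparisonresult"))
  }
  av <- stats::anova(stats::lm(values ~ labels))
  structure(list(metric = "", test = "one-way ANOVA",
                 groups = levels(labels),
                 statistic = av$`F value`[1], p_value = av$`Pr(>F)`[1],
                 significant_at = alpha),
            class = "comparisonresult")
}

#' @export
print.comparisonresult <- function(x, ...) {
  cat(sprintf("<comparison> %s %s: stat = %.4g, p = %.3g\n", x$test,
              paste(x$groups, collapse = " vs "), x$statistic, x$p_value))
  invisible(x)
}

## ---- pipeline over cohorts / datasets ------------------------------------

analyze_one_cell <- function(topo, local, curves, raman, nu_s = 0.5,
                             fit_fraction = 1.0, substrate_frac = 0.2,
                             bands = default_bands(), lam = 1e11, p = 0.001) {
  out <- list(height_um = NA_real_, Ra_nm = NA_real_, Rq_nm = NA_real_,
              E_s_kPa = NA_real_, S_l = NA_real_, S_t = NA_real_)
  if (!is.null(topo)) {
    fl <- flatten(topo, order = 1)
    mid <- (nrow(fl$heights) + 1) / 2
    prof <- extract_profile(fl, c(mid, 1), c(mid, ncol(fl$heights)))
    out$height_um <- cell_height(prof, substrate_frac)
  }
  if (!is.null(local)) {
    rr <- roughness(local, detrend = 1)
    out$Ra_nm <- rr$Ra_nm
    out$Rq_nm <- rr$Rq_nm
  }
  if (!is.null(curves) && length(curves) > 0) {
    fits <- lapply(curves, fit_hertz, nu_s = nu_s,
                   fit_fraction = fit_fraction)
    es <- vapply(fits, function(f) {
      if (f$flag == "ok") f$E_s_kPa else NA_real_
    }, numeric(1))
    out$E_s_kPa <- mean(es, na.rm = TRUE)
  }
  if (!is.null(raman)) {
    fr <- fluidity_pipeline(raman, bands = bands, lam = lam, p = p)
    out$S_l <- fr$S_l
    out$S_t <- fr$S_t
  }
  out
}

#' Run the full analysis pipeline on an in-memory cohort
#'
#' Per cell: order-1 flattening and a central cross-section for cell height;
#' plane-detrended Ra/Rq on the local membrane patch; Hertz fits of all
#' force curves averaged into one modulus; the Raman fluidity pipeline for
#' S_l/S_t.
#'
#' @param cohort a `cohort` from [gen_cohort()].
#' @param ... analysis parameters passed to the per-cell steps (`nu_s`,
#'   `fit_fraction`, `substrate_frac`, `bands`, `lam`, `p`).
#' @return data.frame with one row per cell: `group`, `cell_id`, and the
#'   six metrics.
#' @export
analyze_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$cells, function(cell) {
    m <- analyze_one_cell(cell$topo, cell$local, cell$curves, cell$raman,
                          ...)
    cbind(data.frame(group = cell$group, cell_id = cell$cell_id,
                     stringsAsFactors = FALSE),
          as.data.frame(m))
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on an on-disk dataset
#'
#' Reads each cell's records named in the manifest and applies the same
#' per-cell analysis as [analyze_cohort()], so the CLI `analyze` path is a
#' thin shell over the module operations.
#'
#' @param dataset a `dataset` from [read_dataset()] (or a manifest path).
#' @param ... analysis parameters, as in [analyze_cohort()].
#' @return data.frame with one row per cell.
#' @export
analyze_dataset <- function(dataset, ...) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  stopifnot(inherits(dataset, "dataset"))
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    r <- dataset[i, ]
    topo <- if (nzchar(r$height_map %||% "")) read_heightmap(r$height_map)
    local <- if (nzchar(r$local_map %||% "")) read_heightmap(r$local_map)
    curves <- if (nzchar(r$force_curves %||% "")) {
      lapply(strsplit(r$force_curves, ";")[[1]], read_curve)
    }
    raman <- if (nzchar(r$raman %||% "")) read_spectrum(r$raman)
    if (is.null(topo) && is.null(local) && is.null(curves) &&
        is.null(raman)) {
      stop(sprintf("analyze_dataset: cell %s has no modality", r$cell_id),
           call. = FALSE)
    }
    m <- analyze_one_cell(topo, local, curves, raman, ...)
    cbind(data.frame(group = r$group, cell_id = r$cell_id,
                     stringsAsFactors = FALSE),
          as.data.frame(m))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

## ---- report --------------------------------------------------------------

p_stars <- function(p) {
  if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Build the final report tables from per-cell results
#'
#' Produces the three tables the analysis ends in:
#' * `summary`: per metric and group, mean +/- sample SD and n;
#' * `tests`: the figure-style pairwise comparisons (each non-reference
#'   group vs control, and the rescue group vs model when three groups are
#'   present) plus a per-metric one-way ANOVA, with significance tiers at
#'   `alpha` and `alpha / 5` (0.05 / 0.01 by default). No multiple-testing
#'   correction is applied by default; `correction = "bonferroni"`
#'   multiplies pairwise p-values by the number of pairwise tests per
#'   metric.
#' * `varrates`: percent change of the order parameters S_l/S_t for
#'   model-vs-control and (when present) gigantol-vs-model.
#'
#' @param results per-cell data.frame from [analyze_cohort()] /
#'   [analyze_dataset()].
#' @param control,model,rescue group labels used for the pairwise scheme
#'   (defaults `"control"`, `"model"`, `"gigantol"`); missing labels are
#'   skipped.
#' @param alpha significance level (default 0.05).
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @param welch use Welch's t-test (default `FALSE`, pooled).
#' @return A list of class `report` with data.frames `summary`, `tests`,
#'   `varrates`.
#' @export
build_report <- function(results, control = "control", model = "model",
                         rescue = "gigantol", alpha = 0.05,
                         correction = c("none", "bonferroni"),
                         welch = FALSE) {
  correction <- match.arg(correction)
  metrics <- intersect(c("height_um", "Ra_nm", "Rq_nm", "E_s_kPa",
                         "S_l", "S_t"), names(results))
  groups <- unique(results$group)
  if (length(groups) < 2L) stop("build_report: need >= 2 groups",
                                call. = FALSE)

  summaries <- list()
  sum_rows <- list(); test_rows <- list(); var_rows <- list()
  for (m in metrics) {
    gs <- list()
    for (g in groups) {
      v <- results[[m]][results$group == g]
      v <- v[is.finite(v)]
      if (length(v) < 2L) next
      gs[[g]] <- summarize_group(v, g)
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        metric = m, group = g, mean = gs[[g]]$mean, sd = gs[[g]]$sd,
        n = gs[[g]]$n, stringsAsFactors = FALSE)
    }
    if (length(gs) < 2L) {
      warning(sprintf("build_report: metric %s has < 2 usable groups; omitted",
                      m))
      next
    }
    summaries[[m]] <- gs

    pairs <- list()
    for (g in setdiff(names(gs), control)) {
      if (control %in% names(gs)) pairs <- c(pairs, list(c(control, g)))
    }
    if (all(c(model, rescue) %in% names(gs))) {
      pairs <- c(pairs, list(c(model, rescue)))
    }
    k <- length(pairs)
    for (pr in pairs) {
      tt <- group_ttest(gs[[pr[1]]], gs[[pr[2]]], welch = welch,
                        alpha = alpha)
      p <- tt$p_value
      if (correction == "bonferroni") p <- min(1, p * k)
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        metric = m, test = tt$test, reference = pr[1], comparison = pr[2],
        statistic = tt$statistic, p_value = p, stars = p_stars(p),
        stringsAsFactors = FALSE)
    }
    av <- group_anova(gs, alpha = alpha)
    test_rows[[length(test_rows) + 1L]] <- data.frame(
      metric = m, test = av$test, reference = "all", comparison = "all",
      statistic = av$statistic, p_value = av$p_value,
      stars = p_stars(av$p_value), stringsAsFactors = FALSE)

    if (m %in% c("S_l", "S_t")) {
      if (all(c(control, model) %in% names(gs))) {
        vr <- var_rate(gs[[control]], gs[[model]], metric = m)
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          metric = m, reference = control, comparison = model,
          percent_change = vr$percent_change, stringsAsFactors = FALSE)
      }
      if (all(c(model, rescue) %in% names(gs))) {
        vr <- var_rate(gs[[model]], gs[[rescue]], metric = m)
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          metric = m, reference = model, comparison = rescue,
          percent_change = vr$percent_change, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(summary = do.call(rbind, sum_rows),
                 tests = do.call(rbind, test_rows),
                 varrates = if (length(var_rows)) do.call(rbind, var_rows)
                            else NULL,
                 groups = summaries),
            class = "report")
}

#' @export
print.report <- function(x, ...) {
  cat("<report>\nSummary:\n")
  print(x$summary, row.names = FALSE)
  cat("Tests:\n")
  print(x$tests, row.names = FALSE)
  if (!is.null(x$varrates)) {
    cat("Variation rates:\n")
    print(x$varrates, row.names = FALSE)
  }
  invisible(x)
}

#' Write report tables to TSV files
#'
#' Writes `report_summary.tsv`, `report_tests.tsv` and (if present)
#' `report_varrates.tsv` under `dir`.
#'
#' @param report a `report` from [build_report()].
#' @param dir output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wt <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.table(d, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(paths, wt(report$summary, "report_summary.tsv"),
             wt(report$tests, "report_tests.tsv"))
  if (!is.null(report$varrates)) {
    paths <- c(paths, wt(report$varrates, "report_varrates.tsv"))
  }
  invisible(paths)
}
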