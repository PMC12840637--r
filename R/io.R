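# Plain-text on-disk formats.
#
# height map  : ASCII matrix with a `# pixel_nm=<v>` header (rows = scan
#               lines, whitespace-separated heights in nm), or three-column
#               XYZ triples (x nm, y nm, z nm) on a regular grid.
# force curve : TSV `indentation_nm  force_nN` with `# R_nm=` and
#               `# k_N_per_m=` header comments.
# spectrum    : two-column CSV/TSV (cm^-1, intensity) or JCAMP-DX XYDATA.
# manifest    : flat TSV (group, cell_id, paths), diff-able.

read_text_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  readLines(path, warn = FALSE)
}

parse_header_kv <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, gregexpr("([A-Za-z_][A-Za-z0-9_]*)=([-+0-9.eE]+)",
                                h))[[1]]
    for (p in m) {
      parts <- strsplit(p, "=", fixed = TRUE)[[1]]
      kv[[parts[1]]] <- as.numeric(parts[2])
    }
  }
  kv
}

#' Read a height map from disk
#'
#' Accepts either the ASCII matrix format (header line `# pixel_nm=<v>`,
#' then whitespace-separated rows of heights in nm) or three-column XYZ
#' triples on a regular grid (pixel size inferred from the grid spacing).
#' Ragged matrix rows, irregular XYZ grids and a missing pixel size are
#' rejected with a message naming the offending line.
#'
#' @param path file path.
#' @return A [heightmap()].
#' @export
read_heightmap <- function(path) {
  lines <- read_text_lines(path)
  kv <- parse_header_kv(lines)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) == 0L) stop(sprintf("%s: no data lines", path),
                               call. = FALSE)
  toks <- strsplit(trimws(body), "\\s+")
  ncols <- lengths(toks)
  if (!is.null(kv$pixel_nm)) {
    # matrix format
    if (length(unique(ncols)) != 1L) {
      bad <- which(ncols != ncols[1])[1]
      stop(sprintf("%s: ragged row at data line %d (%d values, expected %d)",
                   path, bad, ncols[bad], ncols[1]), call. = FALSE)
    }
    vals <- suppressWarnings(lapply(toks, as.numeric))
    nas <- vapply(vals, anyNA, TRUE)
    if (any(nas)) {
      stop(sprintf("%s: non-numeric value at data line %d", path,
                   which(nas)[1]), call. = FALSE)
    }
    z <- do.call(rbind, vals)
    return(heightmap(z, kv$pixel_nm))
  }
  if (all(ncols == 3L)) return(read_heightmap_xyz(path, toks))
  stop(sprintf("%s: missing '# pixel_nm=' header (matrix format) and not 3-column XYZ",
               path), call. = FALSE)
}

read_heightmap_xyz <- function(path, toks) {
  m <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), ncol = 3, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop(sprintf("%s: non-numeric value at data line %d", path, bad),
         call. = FALSE)
  }
  xs <- sort(unique(m[, 1])); ys <- sort(unique(m[, 2]))
  reg <- function(v) length(v) < 2L ||
    max(abs(diff(v) - mean(diff(v)))) <= 1e-6 * max(mean(abs(diff(v))), 1)
  if (!reg(xs) || !reg(ys)) {
    stop(sprintf("%s: irregular XYZ grid spacing", path), call. = FALSE)
  }
  if (nrow(m) != length(xs) * length(ys) ||
      anyDuplicated(m[, 1:2, drop = FALSE])) {
    stop(sprintf("%s: XYZ grid incomplete or duplicated (%d triples for %d x %d grid)",
                 path, nrow(m), length(ys), length(xs)), call. = FALSE)
  }
  z <- matrix(NA_real_, length(ys), length(xs))
  z[cbind(match(m[, 2], ys), match(m[, 1], xs))] <- m[, 3]
  px <- mean(c(if (length(xs) > 1) diff(xs), if (length(ys) > 1) diff(ys)))
  heightmap(z, px)
}

#' Write a height map to disk (ASCII matrix format)
#'
#' @param map a [heightmap()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_heightmap <- function(map, path) {
  stopifnot(inherits(map, "heightmap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_nm=%.10g", map$pixel_nm), con)
  utils::write.table(format(map$heights, digits = 10, trim = TRUE,
                            scientific = NA),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a force curve from disk
#'
#' TSV with columns `indentation_nm` and `force_nN`; header comments must
#' carry the probe metadata `R_nm` and `k_N_per_m`. Non-monotone
#' indentation is sorted on read (logged).
#'
#' @param path file path.
#' @return A [forcecurve()].
#' @export
read_curve <- function(path) {
  lines <- read_text_lines(path)
  kv <- parse_header_kv(lines)
  if (is.null(kv$R_nm) || is.null(kv$k_N_per_m)) {
    stop(sprintf("%s: missing probe metadata header (R_nm, k_N_per_m)", path),
         call. = FALSE)
  }
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (grepl("indentation", body[1])) body <- body[-1]
  toks <- strsplit(trimws(body), "\\s+")
  if (any(lengths(toks) != 2L)) {
    bad <- which(lengths(toks) != 2L)[1]
    stop(sprintf("%s: expected 2 columns at data row %d", path, bad),
         call. = FALSE)
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), ncol = 2, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop(sprintf("%s: non-numeric value at data row %d", path, bad),
         call. = FALSE)
  }
  if (is.unsorted(m[, 1])) {
    lm_log("read_curve: %s indentation not monotone, sorting", path)
  }
  forcecurve(m[, 1], m[, 2], R_nm = kv$R_nm, k_N_per_m = kv$k_N_per_m,
             sort = TRUE)
}

#' Write a force curve to disk
#'
#' @param curve a [forcecurve()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "forcecurve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# R_nm=%.10g", curve$R_nm),
               sprintf("# k_N_per_m=%.10g", curve$k_N_per_m),
               "indentation_nm\tforce_nN"), con)
  utils::write.table(
    data.frame(format(curve$indentation_nm, digits = 10, trim = TRUE),
               format(curve$force_nN, digits = 10, trim = TRUE)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Raman spectrum from disk
#'
#' Accepts two-column CSV/TSV (wavenumber cm^-1, intensity) or JCAMP-DX
#' with an `##XYDATA=(X++(Y..Y))` block. Descending wavenumber order is
#' flipped on read (logged); duplicate wavenumbers are rejected.
#'
#' @param path file path.
#' @return A [ramanspectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- read_text_lines(path)
  if (any(grepl("^##", lines))) return(read_spectrum_jcamp(path, lines))
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  sep <- if (grepl(",", body[length(body)])) "," else "\\s+"
  if (grepl("[A-Za-z]", body[1])) body <- body[-1]  # column header
  toks <- strsplit(trimws(body), sep)
  if (any(lengths(toks) != 2L)) {
    bad <- which(lengths(toks) != 2L)[1]
    stop(sprintf("%s: expected 2 columns at data row %d", path, bad),
         call. = FALSE)
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), ncol = 2, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop(sprintf("%s: non-numeric value at data row %d", path, bad),
         call. = FALSE)
  }
  if (all(diff(m[, 1]) < 0)) {
    lm_log("read_spectrum: %s descending wavenumbers, flipping", path)
  }
  ramanspectrum(m[, 1], m[, 2])
}

# minimal JCAMP-DX: fixed-form numeric ##XYDATA=(X++(Y..Y)) tables with
# optional XFACTOR / YFACTOR / DELTAX; enough for spectrometer exports.
read_spectrum_jcamp <- function(path, lines) {
  get_num <- function(key, default = NA_real_) {
    i <- grep(sprintf("^##%s\\s*=", key), lines, ignore.case = TRUE)
    if (length(i) == 0L) return(default)
    as.numeric(sub(sprintf("^##%s\\s*=\\s*", key), "", lines[i[1]],
                   ignore.case = TRUE))
  }
  xf <- get_num("XFACTOR", 1); yf <- get_num("YFACTOR", 1)
  dx <- get_num("DELTAX")
  i0 <- grep("^##XYDATA", lines, ignore.case = TRUE)
  if (length(i0) == 0L) stop(sprintf("%s: no ##XYDATA block", path),
                             call. = FALSE)
  i1 <- grep("^##", lines)
  i_end <- i1[i1 > i0[1]]
  i_end <- if (length(i_end)) i_end[1] - 1L else length(lines)
  data_lines <- lines[(i0[1] + 1L):i_end]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  wn <- c(); y <- c()
  for (dl in data_lines) {
    v <- as.numeric(strsplit(trimws(dl), "\\s+")[[1]])
    if (anyNA(v) || length(v) < 2L) {
      stop(sprintf("%s: malformed XYDATA line '%s'", path, dl),
           call. = FALSE)
    }
    ys <- v[-1]
    step <- if (!is.na(dx)) dx else {
      # infer from consecutive line starts later; default spacing 1
      NA_real_
    }
    wn <- c(wn, v[1] + (seq_along(ys) - 1L) *
              ifelse(is.na(step), 1, step))
    y <- c(y, ys)
  }
  if (is.na(dx) && length(data_lines) > 1L) {
    # recompute spacing from the first two line-start x values
    x1 <- as.numeric(strsplit(trimws(data_lines[1]), "\\s+")[[1]])[1]
    x2 <- as.numeric(strsplit(trimws(data_lines[2]), "\\s+")[[1]])[1]
    ny <- length(strsplit(trimws(data_lines[1]), "\\s+")[[1]]) - 1L
    step <- (x2 - x1) / ny
    wn <- c()
    for (dl in data_lines) {
      v <- as.numeric(strsplit(trimws(dl), "\\s+")[[1]])
      wn <- c(wn, v[1] + (seq_len(length(v) - 1L) - 1L) * step)
    }
  }
  ramanspectrum(wn * xf, y * yf)
}

#' Write a Raman spectrum to disk (two-column CSV)
#'
#' @param spectrum a [ramanspectrum()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ramanspectrum"))
  utils::write.table(
    data.frame(wavenumber_cm1 = format(spectrum$wavenumber_cm1,
                                       digits = 10, trim = TRUE),
               intensity_au = format(spectrum$intensity_au, digits = 10,
                                     trim = TRUE)),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- dataset manifest ----------------------------------------------------

#' Write a generated cohort to disk with a manifest
#'
#' Writes every record of a [gen_cohort()] result under `dir` and a flat
#' TSV manifest (`group`, `cell_id`, `height_map`, `local_map`,
#' `force_curves` (semicolon-separated), `raman`) that [read_dataset()] and
#' the `analyze` CLI consume.
#'
#' @param cohort a `cohort` from [gen_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$cells, function(cell) {
    base <- file.path(dir, cell$cell_id)
    tp <- paste0(base, "_topo.txt")
    lp <- paste0(base, "_local.txt")
    sp <- paste0(base, "_raman.csv")
    write_heightmap(cell$topo, tp)
    write_heightmap(cell$local, lp)
    write_spectrum(cell$raman, sp)
    cps <- vapply(seq_along(cell$curves), function(k) {
      p <- sprintf("%s_curve%02d.tsv", base, k)
      write_curve(cell$curves[[k]], p)
      p
    }, character(1))
    data.frame(group = cell$group, cell_id = cell$cell_id,
               height_map = basename(tp), local_map = basename(lp),
               force_curves = paste(basename(cps), collapse = ";"),
               raman = basename(sp), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(mp)
}

#' Read a dataset manifest
#'
#' @param manifest_path path to a manifest TSV written by [write_cohort()]
#'   (paths are resolved relative to the manifest's directory).
#' @return A data.frame of class `dataset` with resolved paths.
#' @export
read_dataset <- function(manifest_path) {
  d <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("group", "cell_id")
  if (!all(need %in% names(d))) {
    stop("read_dataset: manifest must have group and cell_id columns",
         call. = FALSE)
  }
  if (anyDuplicated(d[c("group", "cell_id")])) {
    stop("read_dataset: duplicate cell_id within a group", call. = FALSE)
  }
  root <- dirname(manifest_path)
  for (col in intersect(c("height_map", "local_map", "raman"), names(d))) {
    d[[col]] <- ifelse(nzchar(d[[col]]), file.path(root, d[[col]]), "")
  }
  if ("force_curves" %in% names(d)) {
    d$force_curves <- vapply(d$force_curves, function(s) {
      if (!nzchar(s)) return("")
      paste(file.path(root, strsplit(s, ";")[[1]]), collapse = ";")
    }, character(1), USE.NAMES = FALSE)
  }
  class(d) <- c("dataset", class(d))
  d
}
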