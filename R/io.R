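#' Spectrum file input/output
#'
#' Spectra are exchanged as two-column CSV with the exact header
#' `wavenumber_cm-1,value` preceded by `#` comment lines carrying the kind
#' and any provenance, or read from a minimal JCAMP-DX subset
#' (`##XYDATA=(X++(Y..Y))` with optional `##XFACTOR`, `##YFACTOR`,
#' `##DELTAX`). A descending JCAMP abscissa is reordered ascending with the
#' values permuted consistently. Write-then-read round-trips preserve grid
#' and values to better than 1e-9.
#'
#' @param spectrum A [seira_spectrum()].
#' @param path File path.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns a [seira_spectrum()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' s <- seira_spectrum(seq(1000, 1100, 4), runif(26), kind = "difference")
#' write_spectrum(s, f)
#' all.equal(read_spectrum(f)$value, s$value)
#' @export
write_spectrum <- function(spectrum, path) {
  spectrum <- as_spectrum_like(spectrum)
  meta <- spectrum_meta(spectrum)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", spectrum_kind(spectrum)), con)
  if (length(meta) > 0) {
    writeLines(sprintf("# meta: %s", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                      digits = NA)), con)
  }
  writeLines("wavenumber_cm-1,value", con)
  writeLines(sprintf("%.12g,%.12g", spectrum$wavenumber, spectrum$value), con)
  invisible(path)
}

#' @rdname write_spectrum
#' @param dialect `"auto"` (sniff), `"csv"` or `"jcamp"`.
#' @export
read_spectrum <- function(path, dialect = c("auto", "csv", "jcamp")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    dialect <- if (any(grepl("^##", head(lines, 20)))) "jcamp" else "csv"
  }
  if (dialect == "jcamp") return(read_jcamp(lines))
  kind <- "absorbance"
  meta <- list()
  km <- grep("^# kind:", lines, value = TRUE)
  if (length(km) > 0) kind <- trimws(sub("^# kind:", "", km[1]))
  mm <- grep("^# meta:", lines, value = TRUE)
  if (length(mm) > 0) {
    meta <- tryCatch(
      jsonlite::fromJSON(trimws(sub("^# meta:", "", mm[1])),
                         simplifyVector = TRUE),
      error = function(e) list())
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) abort("Malformed spectrum file: no data rows.")
  header <- strsplit(body[1], ",")[[1]]
  if (length(header) < 2 || trimws(header[1]) != "wavenumber_cm-1") {
    abort("Malformed spectrum header: expected `wavenumber_cm-1,value`.")
  }
  df <- utils::read.csv(text = body, check.names = FALSE)
  if (ncol(df) < 2) abort("Spectrum file must have two columns.")
  wn <- as.numeric(df[[1]]); va <- as.numeric(df[[2]])
  if (anyNA(wn) || anyNA(va)) abort("Non-numeric entries in spectrum file.")
  if (any(diff(wn) <= 0)) abort("Spectrum grid must be strictly increasing.")
  seira_spectrum(wn, va, kind = kind, meta = as.list(meta))
}

read_jcamp <- function(lines) {
  getnum <- function(key, default = NA_real_) {
    ln <- grep(paste0("^##", key, "="), lines, value = TRUE, ignore.case = TRUE)
    if (length(ln) == 0) return(default)
    as.numeric(sub(paste0("^##", key, "="), "", ln[1], ignore.case = TRUE))
  }
  xf <- getnum("XFACTOR", 1); yf <- getnum("YFACTOR", 1)
  dx <- getnum("DELTAX")
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines,
                ignore.case = TRUE)
  if (length(start) == 0) {
    abort("Unsupported JCAMP file: need ##XYDATA=(X++(Y..Y)).")
  }
  end <- grep("^##END", lines, ignore.case = TRUE)
  end <- end[end > start[1]]
  end <- if (length(end) == 0) length(lines) + 1L else end[1]
  block <- lines[(start[1] + 1L):(end - 1L)]
  block <- block[nzchar(trimws(block)) & !grepl("^##", block)]
  rows <- lapply(block, function(b) as.numeric(strsplit(trimws(b), "[ ,\t]+")[[1]]))
  if (any(vapply(rows, function(r) anyNA(r) || length(r) < 2, logical(1)))) {
    abort("Malformed JCAMP XYDATA block.")
  }
  xs <- vapply(rows, `[`, numeric(1), 1)
  if (is.na(dx)) {
    ny <- vapply(rows, length, integer(1)) - 1L
    if (length(rows) > 1) {
      dx <- (xs[2] - xs[1]) / ny[1]
    } else {
      lastx <- getnum("LASTX"); npts <- getnum("NPOINTS")
      if (is.na(lastx) || is.na(npts)) {
        abort("Cannot infer JCAMP abscissa spacing (need DELTAX or LASTX/NPOINTS).")
      }
      dx <- (lastx - xs[1]) / (npts - 1)
    }
  }
  wn <- numeric(0); va <- numeric(0)
  for (k in seq_along(rows)) {
    ys <- rows[[k]][-1]
    wn <- c(wn, xs[k] + dx * (seq_along(ys) - 1))
    va <- c(va, ys)
  }
  wn <- wn * xf; va <- va * yf
  ord <- order(wn)
  seira_spectrum(wn[ord], va[ord], kind = "absorbance",
                 meta = list(source = "jcamp"))
}

#' Complex trajectory input/output
#'
#' Trajectories are written as three-column CSV
#' (`wavenumber_cm-1,re_r,im_r`).
#'
#' @param trajectory A `complex_trajectory` from [reflection()].
#' @param path File path.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- data.frame(`wavenumber_cm-1` = trajectory$wavenumber,
                   re_r = Re(trajectory$r), im_r = Im(trajectory$r),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("wavenumber_cm-1", "re_r", "im_r") %in% names(df))) {
    abort("Trajectory file must have columns wavenumber_cm-1, re_r, im_r.")
  }
  out <- tibble(wavenumber = df[["wavenumber_cm-1"]],
                r = complex(real = df$re_r, imaginary = df$im_r))
  class(out) <- c("complex_trajectory", class(out))
  out
}
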