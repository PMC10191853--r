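#' Write a flash series to disk
#'
#' Two on-disk layouts are supported. `"delimited"` mirrors the deposited
#' per-flash time-course layout: a directory holding one tab-separated file
#' per flash (first column `time_us`, one column per wavenumber, full
#' round-trip precision) plus a `manifest.json` with the axes and metadata.
#' `"rds"` is a single binary container with named axes.
#'
#' @param fs a [flash_series()].
#' @param path target directory (`delimited`) or file (`rds`).
#' @param format `"delimited"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_flash_series <- function(fs, path, format = c("delimited", "rds")) {
  if (!inherits(fs, "flash_series"))
    abort("`fs` must be a flash_series (0-flash or invalid data are rejected at construction).")
  format <- match.arg(format)
  tg <- attr(fs, "time"); wg <- attr(fs, "wavenumbers")
  cube <- flash_cube(fs)
  if (format == "rds") {
    saveRDS(list(data = cube, dt_us = tg$dt_us, n_samples = tg$n_samples,
                 pre_flash_samples = tg$pre_flash_samples,
                 wavenumbers = as.numeric(wg),
                 flash_spacing_ms = attr(fs, "flash_spacing_ms"),
                 metadata = attr(fs, "metadata")), path)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  nf <- attr(fs, "n_flashes")
  manifest <- list(
    format = "flash-series-delimited-v1",
    n_flashes = nf,
    dt_us = tg$dt_us, n_samples = tg$n_samples,
    pre_flash_samples = tg$pre_flash_samples,
    flash_spacing_ms = attr(fs, "flash_spacing_ms"),
    units = list(time = "us", wavenumber = "cm-1", absorbance = "OD"),
    files = sprintf("flash_%02d.tsv", seq_len(nf)))
  md <- attr(fs, "metadata")
  if (length(md)) manifest$metadata <- md
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tt <- times(tg)
  for (n in seq_len(nf)) {
    # doubles are serialised with 17 significant digits so the text file
    # round-trips to bit-identical values
    tb <- tibble::as_tibble(cube[n, , ], .name_repair = "minimal")
    tb[] <- lapply(tb, function(x) sprintf("%.17g", x))
    names(tb) <- format(as.numeric(wg), digits = 17, trim = TRUE,
                        scientific = FALSE)
    tb <- dplyr::bind_cols(tibble::tibble(time_us = sprintf("%.17g", tt)), tb)
    readr::write_tsv(tb, file.path(path, manifest$files[n]))
  }
  invisible(path)
}

#' Read a flash series from disk
#'
#' Reads either layout written by [write_flash_series()]. Descending
#' wavenumber columns are normalised to the ascending internal convention
#' (data reordered accordingly); any non-finite cell aborts the read with its
#' location.
#'
#' @param path directory (`delimited`) or `.rds` file.
#' @param format `"delimited"` or `"rds"`; inferred from `path` when missing.
#' @return A [flash_series()].
#' @export
read_flash_series <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (dir.exists(path)) "delimited" else "rds"
  format <- match.arg(format, c("delimited", "rds"))
  if (format == "rds") {
    if (!file.exists(path)) abort(sprintf("file not found: %s", path))
    x <- readRDS(path)
    need <- c("data", "dt_us", "n_samples", "pre_flash_samples",
              "wavenumbers")
    if (!all(need %in% names(x)))
      abort(sprintf("malformed rds container: missing %s.",
                    paste(setdiff(need, names(x)), collapse = ", ")))
    tg <- time_grid(x$dt_us, x$n_samples, x$pre_flash_samples)
    return(flash_series(x$data, tg, wavenumber_grid(x$wavenumbers),
                        x$flash_spacing_ms %||% 700,
                        x$metadata %||% list()))
  }
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path))
    abort(sprintf("no manifest.json in %s.", path))
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  need <- c("n_flashes", "dt_us", "n_samples", "pre_flash_samples", "files")
  if (!all(need %in% names(mf)))
    abort(sprintf("malformed manifest (%s): missing %s.", mf_path,
                  paste(setdiff(need, names(mf)), collapse = ", ")))
  tg <- time_grid(mf$dt_us, mf$n_samples, mf$pre_flash_samples)
  tt <- times(tg)
  cube <- NULL
  wg <- NULL
  for (n in seq_len(mf$n_flashes)) {
    f <- file.path(path, mf$files[n])
    # columns are parsed as text and converted with R's strtod so the
    # 17-digit serialisation round-trips bit-exactly
    tb <- readr::read_tsv(f, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"),
                          name_repair = "minimal")
    tb[] <- lapply(tb, function(x) suppressWarnings(as.numeric(x)))
    if (names(tb)[1] != "time_us")
      abort(sprintf("malformed header in %s line 1: first column must be 'time_us', got '%s'.",
                    f, names(tb)[1]))
    wn_raw <- suppressWarnings(as.numeric(names(tb)[-1]))
    if (anyNA(wn_raw))
      abort(sprintf("malformed header in %s line 1: non-numeric wavenumber column name(s): %s.",
                    f, paste(names(tb)[-1][is.na(wn_raw)], collapse = ", ")))
    if (nrow(tb) != tg$n_samples)
      abort(sprintf("%s: %d rows but manifest declares %d samples.",
                    f, nrow(tb), tg$n_samples))
    if (max(abs(tb$time_us - tt)) > 1e-6 * tg$dt_us)
      abort(sprintf("%s: time column disagrees with the manifest grid.", f))
    g <- wavenumber_grid(wn_raw)
    m <- as.matrix(tb[, -1])
    if (attr(g, "descending_input")) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad))
      abort(sprintf("%s: %d non-finite cell(s), first at data row %d, wavenumber %g.",
                    f, nrow(bad), bad[1, 1], as.numeric(g)[bad[1, 2]]))
    if (is.null(cube)) {
      wg <- g
      cube <- array(NA_real_, dim = c(mf$n_flashes, tg$n_samples, length(g)))
    } else if (length(g) != length(wg) || any(abs(as.numeric(g) - as.numeric(wg)) > 1e-9)) {
      abort(sprintf("%s: wavenumber grid differs from flash 1.", f))
    }
    cube[n, , ] <- m
  }
  md <- mf$metadata %||% list()
  flash_series(cube, tg, wg, mf$flash_spacing_ms %||% 700,
               if (is.list(md)) md else as.list(md))
}
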