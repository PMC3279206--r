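#' Construct a hyperspectral cube
#'
#' The central image object: an `H x W x B` array of radiance counts
#' (`kind = "raw"`) or dimensionless relative reflectance
#' (`kind = "reflectance"`), together with its wavelength grid.
#'
#' @param data numeric `H x W x B` array. Raw cubes must be non-negative;
#'   reflectance cubes must be finite (glare may exceed 1).
#' @param wavelengths_nm strictly increasing numeric vector of length `B`.
#'   Defaults to the 81-band grid 600, 605, ..., 1000 nm when `B == 81`.
#' @param kind `"raw"` or `"reflectance"`.
#' @return A `spectral_cube` object.
#' @examples
#' cube <- spectral_cube(array(0.5, c(4, 4, 81)), kind = "reflectance")
#' dim(cube$data)
#' @export
spectral_cube <- function(data, wavelengths_nm = NULL, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_srhsi("`data` must be a 3-d H x W x B array", "srhsi_consistency_error")
  B <- dim(data)[3]
  if (is.null(wavelengths_nm)) {
    if (B == 81L) wavelengths_nm <- seq(600, 1000, by = 5)
    else stop_srhsi("`wavelengths_nm` must be given when B != 81", "srhsi_consistency_error")
  }
  if (length(wavelengths_nm) != B)
    stop_srhsi(sprintf("wavelength count (%d) != band count (%d)",
                       length(wavelengths_nm), B), "srhsi_consistency_error")
  if (any(diff(wavelengths_nm) <= 0))
    stop_srhsi("wavelengths must be strictly increasing", "srhsi_consistency_error")
  if (any(!is.finite(data)))
    stop_srhsi("cube values must be finite", "srhsi_consistency_error")
  if (kind == "raw" && any(data < 0))
    stop_srhsi("raw cubes must be non-negative", "srhsi_consistency_error")
  structure(
    list(data = data, wavelengths_nm = as.numeric(wavelengths_nm), kind = kind),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.0f-%.0f nm), kind = %s\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm), x$kind))
  invisible(x)
}

#' Construct a white/dark reference pair
#'
#' Holds the white-board radiance `I_white(lambda)` and the closed-shutter
#' dark current `I_dark(lambda)` used for reflectance calibration. Elementwise
#' `white >= dark` is *not* assumed (sensor noise); near-zero denominators are
#' guarded in [normalize_reflectance()].
#'
#' @param white,dark numeric `H x W x B` arrays with identical dimensions.
#' @return A `reference_pair` object.
#' @export
reference_pair <- function(white, dark) {
  if (!is.array(white) || !is.array(dark) || !identical(dim(white), dim(dark)) ||
      length(dim(white)) != 3L)
    stop_srhsi("white and dark must be 3-d arrays of identical shape",
               "srhsi_consistency_error")
  structure(list(white = white, dark = dark), class = "reference_pair")
}

#' Construct a pixel label mask
#'
#' Ground-truth annotation per pixel: 0 = noncancerous, 1 = cancerous,
#' 255 = unlabeled. Clinical scenes are only partially annotated, so 255
#' pixels are excluded from training and evaluation but still classified.
#'
#' @param labels integer `H x W` matrix over \{0, 1, 255\}.
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels) {
  if (!is.matrix(labels))
    stop_srhsi("labels must be an H x W matrix", "srhsi_consistency_error")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(0L, 1L, 255L)))
    stop_srhsi("mask values must be 0 (noncancerous), 1 (cancerous) or 255 (unlabeled)",
               "srhsi_format_error")
  structure(list(labels = labels), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(0L, 1L, 255L)))
  cat(sprintf("<label_mask> %d x %d: %d noncancerous, %d cancerous, %d unlabeled\n",
              nrow(x$labels), ncol(x$labels), tab[1], tab[2], tab[3]))
  invisible(x)
}

# ENVI cube I/O -------------------------------------------------------------

# ENVI integer codes for the sample types supported here.
.envi_dtypes <- list(
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `4`  = list(what = "numeric", size = 4L, signed = TRUE),
  `5`  = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.envi_data_path <- function(header_path, must_exist = FALSE) {
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  if (!must_exist) return(paste0(base, ".raw"))
  for (cand in c(paste0(base, ".raw"), base, paste0(base, ".dat"), paste0(base, ".img")))
    if (file.exists(cand) && !dir.exists(cand)) return(cand)
  stop_srhsi(sprintf("no data file found for header '%s'", header_path),
             "srhsi_format_error")
}

#' Write a hyperspectral cube as ENVI header + raw binary
#'
#' Emits the de-facto standard ENVI dialect: a text `.hdr` with samples /
#' lines / bands / data type / interleave / wavelength keys, and a companion
#' flat binary file (`<stem>.raw`, little-endian) in the requested interleave.
#'
#' @param cube a [spectral_cube()].
#' @param header_path path for the `.hdr` file; the binary goes next to it.
#' @param interleave `"bsq"` (band-sequential), `"bil"` (line-interleaved) or
#'   `"bip"` (pixel-interleaved).
#' @param data_type ENVI type code: 4 = 32-bit float (default for
#'   reflectance), 12 = unsigned 16-bit (default for raw counts, which are
#'   rounded), 5 = 64-bit float, 2 = signed 16-bit.
#' @return `header_path`, invisibly.
#' @export
write_envi_cube <- function(cube, header_path,
                            interleave = c("bsq", "bil", "bip"),
                            data_type = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  if (is.null(data_type)) data_type <- if (cube$kind == "reflectance") 4L else 12L
  dt <- .envi_dtypes[[as.character(data_type)]]
  if (is.null(dt))
    stop_srhsi(sprintf("unsupported ENVI data type %s", data_type), "srhsi_format_error")
  d <- dim(cube$data)
  # storage orders: bsq = sample,line,band; bil = sample,band,line; bip = band,sample,line
  perm <- switch(interleave, bsq = c(2, 1, 3), bil = c(2, 3, 1), bip = c(3, 2, 1))
  v <- as.vector(aperm(cube$data, perm))
  if (dt$what == "integer") v <- as.integer(round(v))
  hdr <- c(
    "ENVI",
    sprintf("description = {srhsi %s cube}", cube$kind),
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("cube kind = %s", cube$kind),
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths_nm, digits = 15, trim = TRUE,
                         scientific = FALSE), collapse = ", "))
  )
  ok <- tryCatch({
    writeLines(hdr, header_path)
    con <- file(.envi_data_path(header_path), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(v, con, size = dt$size, endian = "little")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_srhsi(sprintf("cannot write ENVI files at '%s': %s",
                       header_path, conditionMessage(ok)), "srhsi_io_error")
  invisible(header_path)
}

.parse_envi_header <- function(header_path) {
  if (!file.exists(header_path))
    stop_srhsi(sprintf("header '%s' not found", header_path), "srhsi_format_error")
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*ENVI", txt))
    stop_srhsi(sprintf("'%s' is not an ENVI header (missing ENVI magic)", header_path),
               "srhsi_format_error")
  get1 <- function(key, required = TRUE) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key, "\\s*=\\s*([^\\{\\n]+)$"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) {
      if (required)
        stop_srhsi(sprintf("header key '%s' missing in '%s'", key, header_path),
                   "srhsi_format_error")
      return(NA_character_)
    }
    trimws(m[2])
  }
  getblock <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key, "\\s*=\\s*\\{([^\\}]*)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    trimws(strsplit(m[2], ",")[[1]])
  }
  wl <- getblock("wavelength")
  if (is.null(wl))
    stop_srhsi(sprintf("wavelength block missing in '%s'", header_path),
               "srhsi_format_error")
  list(
    samples = as.integer(get1("samples")),
    lines = as.integer(get1("lines")),
    bands = as.integer(get1("bands")),
    data_type = as.integer(get1("data type")),
    interleave = tolower(get1("interleave")),
    byte_order = as.integer(get1("byte order")),
    kind = { k <- get1("cube kind", required = FALSE); if (is.na(k)) "reflectance" else k },
    wavelengths = as.numeric(wl)
  )
}

#' Read a hyperspectral cube from ENVI header + raw binary
#'
#' Supports bsq/bil/bip interleaves and data types 2, 4, 5, 12 (little
#' endian). The companion binary is searched for as `<stem>.raw`, `<stem>`,
#' `<stem>.dat`, `<stem>.img`. Band order follows the header's wavelength
#' list.
#'
#' @param header_path path to the `.hdr` file.
#' @return A [spectral_cube()].
#' @export
read_envi_cube <- function(header_path) {
  h <- .parse_envi_header(header_path)
  if (any(is.na(c(h$samples, h$lines, h$bands, h$data_type))))
    stop_srhsi(sprintf("garbled numeric fields in header '%s'", header_path),
               "srhsi_format_error")
  if (!h$interleave %in% c("bsq", "bil", "bip"))
    stop_srhsi(sprintf("unsupported interleave '%s'", h$interleave), "srhsi_format_error")
  if (length(h$wavelengths) != h$bands)
    stop_srhsi(sprintf("header declares %d wavelengths for %d bands",
                       length(h$wavelengths), h$bands), "srhsi_consistency_error")
  dt <- .envi_dtypes[[as.character(h$data_type)]]
  if (is.null(dt))
    stop_srhsi(sprintf("unsupported ENVI data type %d", h$data_type), "srhsi_format_error")
  dp <- .envi_data_path(header_path, must_exist = TRUE)
  n <- h$samples * h$lines * h$bands
  con <- file(dp, "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = "little")
  if (length(v) != n)
    stop_srhsi(sprintf("data file '%s' holds %d samples, header implies %d",
                       dp, length(v), n), "srhsi_consistency_error")
  dims <- switch(h$interleave,
    bsq = c(h$samples, h$lines, h$bands),
    bil = c(h$samples, h$bands, h$lines),
    bip = c(h$bands, h$samples, h$lines))
  perm <- switch(h$interleave, bsq = c(2, 1, 3), bil = c(3, 1, 2), bip = c(3, 2, 1))
  arr <- aperm(array(v, dims), perm)
  spectral_cube(arr, h$wavelengths, kind = match.arg(h$kind, c("raw", "reflectance")))
}

# Mask I/O -------------------------------------------------------------------

#' Read or write a pixel label mask (PNG or PGM)
#'
#' Masks are single-channel 8-bit images. On read, stored pixel values are
#' mapped to the canonical \{0, 1, 255\} coding: 0 stays 0 (noncancerous),
#' any value in `cancer_values` becomes 1 (cancerous; some annotation tools
#' store foreground as 128), 255 stays 255 (unlabeled). Both PNG and the
#' plain-text PGM dialects (P2/P5) are supported, chosen by file extension.
#'
#' @param path image path ending in `.png` or `.pgm`.
#' @param cancer_values stored values mapped to class 1 (default `c(1, 128)`).
#' @return [read_mask()]: a [label_mask()]; [write_mask()]: `path`, invisibly.
#' @export
read_mask <- function(path, cancer_values = c(1L, 128L)) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L)
      stop_srhsi("multi-channel image: masks must be single-channel 8-bit",
                 "srhsi_format_error")
    vals <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  } else if (ext == "pgm") {
    vals <- .read_pgm(path)
  } else {
    stop_srhsi(sprintf("unsupported mask format '.%s' (use .png or .pgm)", ext),
               "srhsi_format_error")
  }
  out <- vals
  out[vals %in% as.integer(cancer_values)] <- 1L
  bad <- !(out %in% c(0L, 1L, 255L))
  if (any(bad))
    stop_srhsi(sprintf("mask holds %d pixels outside {0, cancer values, 255}",
                       sum(bad)), "srhsi_format_error")
  label_mask(out)
}

#' @param mask a [label_mask()] (for [write_mask()]).
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(mask$labels / 255, path)
  } else if (ext == "pgm") {
    .write_pgm(mask$labels, path)
  } else {
    stop_srhsi(sprintf("unsupported mask format '.%s' (use .png or .pgm)", ext),
               "srhsi_format_error")
  }
  invisible(path)
}

# Plain-text PGM (P2) and binary PGM (P5), maxval <= 255, single channel.
.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5"))
    stop_srhsi(sprintf("'%s' is not a PGM file", path), "srhsi_format_error")
  # header tokens: width height maxval (comments starting with # allowed)
  toks <- integer(0)
  buf <- ""
  while (length(toks) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0 || ch == "")
      stop_srhsi("truncated PGM header", "srhsi_format_error")
    if (ch == "#") { repeat { c2 <- rawToChar(readBin(con, "raw", 1L)); if (c2 == "\n") break } ; next }
    if (grepl("[0-9]", ch)) buf <- paste0(buf, ch)
    else if (nzchar(buf)) { toks <- c(toks, as.integer(buf)); buf <- "" }
  }
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  if (maxval > 255L)
    stop_srhsi("only 8-bit PGM masks are supported", "srhsi_format_error")
  if (magic == "P5") {
    v <- as.integer(readBin(con, "raw", w * h))
  } else {
    txt <- readChar(con, nchars = 8L * w * h + 64L, useBytes = TRUE)
    v <- as.integer(strsplit(trimws(txt), "\\s+")[[1]])[seq_len(w * h)]
  }
  if (length(v) != w * h || anyNA(v))
    stop_srhsi("truncated PGM pixel data", "srhsi_format_error")
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

.write_pgm <- function(labels, path) {
  h <- nrow(labels); w <- ncol(labels)
  lines <- c("P2", sprintf("%d %d", w, h), "255",
             apply(labels, 1, paste, collapse = " "))
  writeLines(lines, path)
}

# Dictionary I/O -------------------------------------------------------------

#' Save or load a spectral dictionary as a delimited text table
#'
#' One row per atom: a `class` column (`noncancerous` / `cancerous`) followed
#' by the B per-band values, with a header row naming the wavelengths.
#' Round trips preserve atom values to at least 12 significant digits and the
#' class partition sizes.
#'
#' @param dict a [build_dictionary()] result (for [save_dictionary()]).
#' @param path CSV path.
#' @return [load_dictionary()]: a `spectral_dictionary`;
#'   [save_dictionary()]: `path`, invisibly.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "spectral_dictionary"))
  wl <- dict$wavelengths_nm
  if (is.null(wl)) wl <- seq_len(nrow(dict$atoms))
  df <- data.frame(class = dict$labels,
                   t(dict$atoms), check.names = FALSE)
  names(df) <- c("class", format(wl, digits = 15, trim = TRUE, scientific = FALSE))
  utils::write.table(
    cbind(class = df$class,
          apply(df[-1], 2, function(x) format(x, digits = 17, trim = TRUE))),
    path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (length(raw) < 2L)
    stop_srhsi("dictionary table needs a header row and at least one atom",
               "srhsi_format_error")
  hdr <- strsplit(raw[1], ",")[[1]]
  B <- length(hdr) - 1L
  rows <- strsplit(raw[-1], ",")
  nf <- lengths(rows)
  if (any(nf != B + 1L))
    stop_srhsi(sprintf("dictionary row(s) %s have wrong field count (expected %d)",
                       paste(which(nf != B + 1L), collapse = ", "), B + 1L),
               "srhsi_format_error")
  labels <- vapply(rows, `[`, "", 1L)
  atoms <- vapply(rows, function(r) as.numeric(r[-1]), numeric(B))
  atoms <- matrix(atoms, nrow = B)
  wl <- suppressWarnings(as.numeric(hdr[-1]))
  if (anyNA(wl)) wl <- NULL
  new_spectral_dictionary(atoms, labels, wavelengths_nm = wl)
}
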