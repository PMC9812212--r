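# Detector-image export: quantization/scaling of float rasters, an SMV
# (.img) writer/reader pair, and grafting of simulated arrays into an
# existing template file whose surrounding records are preserved.

#' Scale and quantize a photograph to 16-bit
#'
#' `value = round(scale * I)` clamped to the 16-bit ceiling; masked
#' (invalid) pixels are written as a configured sentinel and excluded
#' from the saturation count.
#'
#' @param photo a [photograph()].
#' @param scale positive scale factor.
#' @param sentinel value stored at masked pixels (default 65535, common
#'   SMV practice for untrusted regions).
#' @param header optional named list of header fields (distance,
#'   wavelength, pixel size, beam center, oscillation start/width) carried
#'   through to [write_smv()].
#' @return object of class `quantized_image`: integer raster, scale used,
#'   saturated-pixel count, header fields.
#' @export
scale_and_quantize <- function(photo, scale, sentinel = 65535L,
                               header = list()) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop("scale_and_quantize: scale must be a positive scalar")
  v <- round(scale * photo$intensity)
  saturated <- sum(v > 65535 & photo$mask)
  v[v > 65535] <- 65535
  v[v < 0] <- 0
  v[!photo$mask] <- as.integer(sentinel)
  structure(list(raster = matrix(as.integer(v), nrow(v), ncol(v)),
                 scale = scale, n_saturated = as.integer(saturated),
                 sentinel = as.integer(sentinel), header = header),
            class = "quantized_image")
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image> %dx%d px, scale=%g, %d saturated\n",
              nrow(x$raster), ncol(x$raster), x$scale, x$n_saturated))
  invisible(x)
}

#' Scan scaling constants for uniform image export
#'
#' Applies each candidate scale uniformly to all photographs and reports
#' the saturated fraction and dynamic range; the chosen scale is the
#' largest one whose saturated fraction stays below `max_saturated_frac`.
#' This selection criterion is this package's own stand-in for feeding
#' scaled images to an external integration program and consulting its
#' output. The candidate range follows the 0.1-10.0 scan of the original
#' workflow.
#'
#' @param photos list of [photograph()] objects.
#' @param grid candidate scales (default 25 log-spaced values in
#'   `[0.1, 10]`).
#' @param max_saturated_frac saturation threshold (default 1e-4).
#' @return list with `scale` (chosen), `degenerate` flag, and `report`
#'   (data frame: scale, saturated fraction, max quantized value).
#' @export
scan_scaling <- function(photos, grid = 10^seq(-1, 1, length.out = 25),
                         max_saturated_frac = 1e-4) {
  if (!length(grid)) stop("scan_scaling: empty grid")
  if (!length(photos)) stop("scan_scaling: no photographs")
  grid <- sort(grid)
  vals <- unlist(lapply(photos, function(p) p$intensity[p$mask]))
  n <- length(vals)
  degenerate <- !any(vals > 0)
  rep_df <- data.frame(scale = grid, saturated_frac = NA_real_,
                       max_value = NA_real_)
  for (i in seq_along(grid)) {
    v <- round(grid[i] * vals)
    rep_df$saturated_frac[i] <- sum(v > 65535) / n
    rep_df$max_value[i] <- min(max(v), 65535)
  }
  if (degenerate) {
    chosen <- grid[1]
  } else {
    ok <- which(rep_df$saturated_frac < max_saturated_frac)
    chosen <- if (length(ok)) grid[max(ok)] else grid[1]
  }
  list(scale = chosen, degenerate = degenerate, report = rep_df)
}

.uint16_le_encode <- function(v) {
  v <- as.integer(v)
  as.raw(rbind(v %% 256L, v %/% 256L))
}

.uint16_le_decode <- function(bytes) {
  b <- as.integer(bytes)
  b[c(TRUE, FALSE)] + 256L * b[c(FALSE, TRUE)]
}

#' Write a quantized image in SMV format
#'
#' A 512-byte padded ASCII header (`HEADER_BYTES`, `DIM`, `SIZE1/SIZE2`,
#' `PIXEL_SIZE`, `DISTANCE`, `WAVELENGTH`, `BEAM_CENTER_X/Y`, `OSC_START`,
#' `OSC_RANGE`, `TYPE=unsigned_short`, little-endian byte order) followed
#' by the raster as little-endian 16-bit unsigned integers, fast axis
#' first. [read_smv()] round-trips the raster bit-exactly.
#'
#' @param img a `quantized_image`; its `header` list must provide
#'   `distance` (mm), `wavelength` (angstrom), `pixel_size` (mm),
#'   `beam_center` (pixels, length 2), `osc_start` and `osc_range`
#'   (degrees).
#' @param path output file.
#' @export
write_smv <- function(img, path) {
  h <- img$header
  need <- c("distance", "wavelength", "pixel_size", "beam_center",
            "osc_start", "osc_range")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("write_smv: missing header field(s): ", paste(miss, collapse = ", "))
  n1 <- nrow(img$raster); n2 <- ncol(img$raster)
  head_txt <- paste0(
    "{\nHEADER_BYTES=  512;\nDIM=2;\nBYTE_ORDER=little_endian;\n",
    "TYPE=unsigned_short;\n",
    sprintf("SIZE1=%d;\nSIZE2=%d;\n", n1, n2),
    sprintf("PIXEL_SIZE=%g;\nDISTANCE=%g;\nWAVELENGTH=%g;\n",
            h$pixel_size, h$distance, h$wavelength),
    sprintf("BEAM_CENTER_X=%g;\nBEAM_CENTER_Y=%g;\n",
            h$beam_center[1], h$beam_center[2]),
    sprintf("OSC_START=%g;\nOSC_RANGE=%g;\n", h$osc_start, h$osc_range),
    "}\n")
  hb <- charToRaw(head_txt)
  if (length(hb) > 512) stop("write_smv: header exceeds 512 bytes")
  hb <- c(hb, rep(charToRaw(" "), 512 - length(hb)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hb, con)
  writeBin(.uint16_le_encode(as.vector(img$raster)), con)
  invisible(path)
}

#' @rdname write_smv
#' @return `read_smv` returns a `quantized_image` with the header fields
#'   parsed back.
#' @export
read_smv <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  head_txt <- rawToChar(bytes[1:512])
  getf <- function(key) {
    m <- regmatches(head_txt,
                    regexpr(paste0(key, "= *[^;]+;"), head_txt))
    if (!length(m)) return(NA)
    as.numeric(gsub(";", "", strsplit(m, "=")[[1]][2]))
  }
  n1 <- getf("SIZE1"); n2 <- getf("SIZE2")
  data <- .uint16_le_decode(bytes[513:(512 + 2 * n1 * n2)])
  structure(list(raster = matrix(as.integer(data), n1, n2),
                 scale = NA_real_, n_saturated = NA_integer_,
                 sentinel = NA_integer_,
                 header = list(distance = getf("DISTANCE"),
                               wavelength = getf("WAVELENGTH"),
                               pixel_size = getf("PIXEL_SIZE"),
                               beam_center = c(getf("BEAM_CENTER_X"),
                                               getf("BEAM_CENTER_Y")),
                               osc_start = getf("OSC_START"),
                               osc_range = getf("OSC_RANGE"))),
            class = "quantized_image")
}

#' Graft a simulated raster into a detector-file template
#'
#' Replaces the binary data array of an existing detector file with the
#' simulated raster, leaving every byte outside the declared array
#' untouched; pixels in `preserve_mask` (e.g. beamstop and screen-spacer
#' regions) keep their template values. The template dialect is handled
#' generically as "bytes + data-array descriptor" rather than through a
#' full format parser.
#'
#' @param template raw vector holding the template file.
#' @param img a `quantized_image` whose raster fills the data array.
#' @param descriptor list with `offset` (0-based byte offset of the data
#'   array), `length` (bytes) and `type` (only `"uint16_le"` supported).
#' @param preserve_mask optional logical matrix (raster shape) or integer
#'   vector of 1-based pixel indices whose template values are kept.
#' @return raw vector of the grafted file.
#' @export
graft_into_template <- function(template, img, descriptor,
                                preserve_mask = NULL) {
  stopifnot(is.raw(template))
  if (!identical(descriptor$type, "uint16_le"))
    stop("graft_into_template: unsupported element type ", descriptor$type)
  npx <- length(img$raster)
  if (descriptor$length != 2 * npx)
    stop("graft_into_template: descriptor length does not match raster size")
  if (descriptor$offset < 0 ||
      descriptor$offset + descriptor$length > length(template))
    stop("graft_into_template: descriptor overruns the template")
  vals <- as.vector(img$raster)
  if (!is.null(preserve_mask)) {
    keep <- if (is.logical(preserve_mask)) which(preserve_mask)
            else as.integer(preserve_mask)
    if (length(keep)) {
      span <- (descriptor$offset + 1):(descriptor$offset + descriptor$length)
      tvals <- .uint16_le_decode(template[span])
      vals[keep] <- tvals[keep]
    }
  }
  out <- template
  out[(descriptor$offset + 1):(descriptor$offset + descriptor$length)] <-
    .uint16_le_encode(vals)
  out
}

#' Export per-frame scaling reports as CSV
#'
#' @param scan result of [scan_scaling()].
#' @param path output CSV path.
#' @export
write_scaling_report <- function(scan, path) {
  utils::write.csv(scan$report, path, row.names = FALSE)
  invisible(path)
}
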