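# Raster I/O. Native support covers the portable anymap family (PGM/PPM,
# ASCII and binary at maxval <= 255); PNG/JPEG paths are converted through
# the system Python's Pillow when one is available, purely as a convenience
# for real photographs. All pipeline code and tests use PNM.

pnm_read_tokens <- function(raw, n_tokens) {
  # header tokens, skipping '#' comments; returns tokens and byte offset
  tokens <- character(0)
  i <- 1L
  while (length(tokens) < n_tokens && i <= length(raw)) {
    ch <- rawToChar(raw[i])
    if (ch == "#") {
      while (i <= length(raw) && !rawToChar(raw[i]) %in% c("\n", "\r")) i <- i + 1L
    } else if (grepl("[[:space:]]", ch)) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= length(raw) && !grepl("[[:space:]]", rawToChar(raw[j])) &&
             rawToChar(raw[j]) != "#") j <- j + 1L
      tokens <- c(tokens, rawToChar(raw[i:(j - 1L)]))
      i <- j
    }
  }
  list(tokens = tokens, offset = i)
}

read_pnm <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic: ", magic)
  hdr <- pnm_read_tokens(raw, 4L)
  w <- as.integer(hdr$tokens[2]); h <- as.integer(hdr$tokens[3])
  maxval <- as.integer(hdr$tokens[4])
  nchan <- if (magic %in% c("P3", "P6")) 3L else 1L
  npx <- as.double(w) * h * nchan
  if (magic %in% c("P5", "P6")) {
    if (maxval > 255) stop("16-bit PNM not supported")
    # binary payload begins after the single whitespace ending the header
    vals <- as.integer(raw[hdr$offset + seq_len(npx)])
  } else {
    body <- rawToChar(raw[hdr$offset:length(raw)])
    vals <- as.integer(strsplit(trimws(body), "[[:space:]]+")[[1]])[seq_len(npx)]
  }
  if (nchan == 1L) {
    gray_image(matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE))
  } else {
    px <- array(0, c(h, w, 3))
    for (k in 1:3)
      px[, , k] <- matrix(vals[seq(k, npx, by = 3L)], h, w, byrow = TRUE) *
        (255 / maxval)
    rgb_image(px)
  }
}

write_pnm <- function(values, path, ascii = FALSE) {
  # values: integer matrix (gray) or H x W x 3 array, already in 0..255
  is_rgb <- length(dim(values)) == 3L
  h <- dim(values)[1]; w <- dim(values)[2]
  if (is_rgb) {
    flat <- integer(h * w * 3L)
    for (k in 1:3) flat[seq(k, length(flat), 3L)] <- as.integer(t(values[, , k]))
    magic <- if (ascii) "P3" else "P6"
  } else {
    flat <- as.integer(t(values))
    magic <- if (ascii) "P2" else "P5"
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("%s\n%d %d\n255\n", magic, w, h)), con)
  if (ascii) writeBin(charToRaw(paste0(paste(flat, collapse = "\n"), "\n")), con)
  else writeBin(as.raw(flat), con)
  invisible(path)
}

pillow_convert <- function(from, to) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("PNG/JPEG support requires a system python with Pillow; ",
                     "use .pgm/.ppm for native I/O")
  code <- sprintf(
    "from PIL import Image; im = Image.open(%s); im.convert('RGB').save(%s)",
    deparse(from), deparse(to))
  status <- system2(py, c("-c", shQuote(code)))
  if (status != 0) stop("Pillow conversion failed for ", from)
  invisible(to)
}

#' Read a raster image
#'
#' Reads PGM (returns a [gray_image]) or PPM (returns an [rgb_image])
#' natively; `.png` / `.jpg` / `.jpeg` files are converted via the system
#' Python's Pillow library when available.
#'
#' @param path file path.
#' @return A `gray_image` or `rgb_image` depending on channel count.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pgm", "ppm", "pnm")) return(read_pnm(path))
  if (ext %in% c("png", "jpg", "jpeg")) {
    tmp <- tempfile(fileext = ".ppm")
    on.exit(unlink(tmp))
    pillow_convert(path, tmp)
    return(read_pnm(tmp))
  }
  stop("unsupported image format: .", ext)
}

#' Write a binary mask
#'
#' Writes the mask as an 8-bit graymap with values 0 (background) and 255
#' (mask). A write-then-read round trip is the identity.
#'
#' @param mask a [binary_mask] or logical matrix.
#' @param path output path (`.pgm` native; `.png` via Pillow).
#' @param ascii write plain-text (P2) rather than binary (P5) PGM.
#' @export
write_mask <- function(mask, path, ascii = FALSE) {
  mask <- binary_mask(unclass(mask))
  write_raster(matrix(ifelse(mask, 255L, 0L), nrow(mask)), path, ascii)
}

#' Write a grayscale image
#'
#' Intensities are clamped to \[0, 1\] and quantized to the nearest of 256
#' levels (`round(v * 255)`, ties to even, so 0.5 maps to byte 128).
#'
#' @inheritParams write_mask
#' @param img a [gray_image] or numeric matrix.
#' @export
write_gray <- function(img, path, ascii = FALSE) {
  img <- as_gray_image(img)
  q <- round(pmin(pmax(unclass(img), 0), 1) * 255)
  write_raster(matrix(as.integer(q), nrow(img)), path, ascii)
}

write_raster <- function(bytes, path, ascii = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pgm", "ppm", "pnm")) return(write_pnm(bytes, path, ascii))
  if (ext %in% c("png", "jpg", "jpeg")) {
    tmp <- tempfile(fileext = ".pgm")
    on.exit(unlink(tmp))
    write_pnm(bytes, tmp)
    return(pillow_convert(tmp, path))
  }
  stop("unsupported image format: .", ext)
}

#' Read a mask written by [write_mask]
#'
#' @param path file path; pixels >= 50% intensity become mask pixels.
#' @return A [binary_mask].
#' @export
read_mask <- function(path) {
  g <- read_image(path)
  if (inherits(g, "rgb_image")) g <- to_gray(g)
  binary_mask(unclass(g) >= 0.5)
}
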