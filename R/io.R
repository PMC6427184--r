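## Raster I/O.  PNG and TIFF go through the png and tiff packages; PGM
## (P2/P5) has a small built-in reader/writer.  All images come back as
## numeric matrices in [0, 1]; color inputs are reduced to gray with the
## ITU-R BT.601 luma weights.

#' Read a grayscale image
#'
#' PNG, TIFF and PGM (P2 ASCII / P5 binary) are supported; 8- and 16-bit
#' samples are normalized to [0, 1] and color channels collapsed with the
#' BT.601 weights (0.299, 0.587, 0.114).
#'
#' @param path file path; format chosen by extension.
#' @return M x N numeric matrix in [0, 1].
#' @export
readImageGray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pgm = return(.read_pgm(path)),
    stop("unsupported image format: .", ext))
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3)
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a <- a[, , 1]
  }
  pmin(pmax(a, 0), 1)
}

#' Write a grayscale image
#'
#' @param img matrix in [0, 1].
#' @param path output path (.png, .tif/.tiff or .pgm); PGM is written as
#'   ASCII P2, 8-bit.
#' @export
writeImageGray <- function(img, path) {
  .check_image(img)
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path),
    pgm = .write_pgm(img, path),
    stop("unsupported image format: .", ext))
  invisible(path)
}

.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # read header tokens, skipping comments
  while (length(tok) < 4) {
    line <- readLines(con, n = 1)
    line <- sub("#.*", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxv <- as.integer(tok[4])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    if (maxv > 255) {
      vals <- readBin(con, "integer", n = n, size = 2, signed = FALSE,
                      endian = "big")
    } else {
      vals <- as.integer(readBin(con, "raw", n = n))
    }
  }
  matrix(vals / maxv, nrow = h, ncol = w, byrow = TRUE)
}

.write_pgm <- function(img, path) {
  v <- round(t(img) * 255)  # row-major order
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  write(as.integer(v), con, ncolumns = 16)
}
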