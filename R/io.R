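#' Read and write ASCII PGM images
#'
#' Plain-text P2 portable graymap I/O for frames and masks.  Intensities
#' are mapped between [0, 1] and the integer range \code{0..maxval}
#' (quantization is lossy at 8 bits).
#'
#' @param path File path.
#' @param img Numeric matrix in [0, 1].
#' @param maxval Integer maximum gray value.
#' @return \code{read_pgm} returns a numeric matrix in [0, 1];
#'   \code{write_pgm} returns \code{path} invisibly.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE,
               comment.char = "#")
  if (toks[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  n <- as.integer(toks[2]); m <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != m * n) stop("corrupt PGM: wrong pixel count")
  ## PGM stores row-major (rows of the image as written lines)
  matrix(vals, nrow = m, ncol = n, byrow = TRUE) / maxval
}

#' @rdname read_pgm
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)),
             con)
  ## one image row per line
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a binary mask from a PGM file
#'
#' @param path File path.
#' @param threshold Intensity cut in [0, 1]; pixels at or above it are
#'   foreground.
#' @return Logical matrix.
#' @export
read_mask_pgm <- function(path, threshold = 0.5) {
  read_pgm(path) >= threshold
}

#' List and read a directory of numbered PGM frames
#'
#' @param dir Directory containing \code{*.pgm} files; lexicographic order.
#' @return List of numeric matrices.
#' @export
read_frame_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.pgm$", full.names = TRUE))
  if (!length(files)) stop("no .pgm frames in ", dir)
  lapply(files, read_pgm)
}
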