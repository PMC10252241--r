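# Plain-text PGM (P2) image I/O. The portable graymap is the interchange
# format for generated radiographs: grayscale, trivially diffable, and
# readable without any imaging library. Pixels are stored 0..maxval and
# exposed in R as doubles in [0, 1], image[row, col].

#' Write a grayscale image as plain PGM (P2)
#'
#' @param image numeric matrix in `[0, 1]`, `image[row, col]`.
#' @param path output file.
#' @param maxval maximum gray value (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  stopifnot(is.matrix(image), maxval >= 1)
  px <- round(pmin(pmax(image, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  # one image row per line
  writeLines(apply(px, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a plain PGM (P2) image
#'
#' @param path PGM file written by [write_pgm()] (or any plain-format P2).
#' @return numeric matrix in `[0, 1]`, `image[row, col]`.
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  toks <- unlist(strsplit(paste(lines, collapse = " "), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  if (toks[1] != "P2") stop("only plain (P2) PGM is supported: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  px <- as.numeric(toks[-(1:4)])
  if (length(px) != w * h) stop("corrupt PGM: ", path)
  matrix(px, nrow = h, ncol = w, byrow = TRUE) / maxval
}
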