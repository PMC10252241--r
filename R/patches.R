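# ViT-style patch extraction: an optional, off-by-default preprocessing
# representation. The default pipeline feeds images straight to the
# convolutional plan; patching is exposed for experimentation only.

#' Number of fixed-size patches tiling an image
#'
#' `N = W * H / P^2` for an `H x W` image cut into `P x P` patches; both
#' dimensions must tile exactly.
#'
#' @param H,W image height and width in pixels.
#' @param P patch side length.
#' @return positive integer patch count.
#' @export
#' @examples
#' patch_count(224, 224, 16)  # 196
patch_count <- function(H, W, P) {
  stopifnot(H >= 1, W >= 1, P >= 1)
  if (H %% P != 0L || W %% P != 0L) {
    stop("image dimensions must be divisible by the patch size")
  }
  as.integer(W * H / P^2)
}

#' Extract non-overlapping patches from an image
#'
#' Tiles the image row-major (left-to-right, top-to-bottom over the patch
#' grid); each patch is flattened row-major with the channel index slowest,
#' so a 4x4 image holding 1..16 row-major yields `[1, 2, 5, 6]` as its first
#' patch. The tiling is a partition: concatenating the patches in position
#' order reconstructs the image exactly (see [reconstruct_patches()]).
#'
#' @param image `H x W` matrix or `H x W x C` array; `image[r, c, ch]` is the
#'   pixel at row r, column c.
#' @param P patch side length; must divide both H and W.
#' @return object of class `patch_set`: list with `patches` (`N x P*P*C`
#'   matrix), `positions` (`0..N-1`), `patch_size`, `source_shape`.
#' @export
extract_patches <- function(image, P) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  N <- patch_count(d[1], d[2], P)
  nr <- d[1] %/% P
  nc <- d[2] %/% P
  patches <- matrix(NA_real_, N, P * P * d[3])
  pos <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      blk <- image[((i - 1L) * P + 1L):(i * P),
                   ((j - 1L) * P + 1L):(j * P), , drop = FALSE]
      # row-major flatten within each channel, channels last
      patches[pos + 1L, ] <- as.vector(aperm(blk, c(2, 1, 3)))
      pos <- pos + 1L
    }
  }
  structure(list(patches = patches, positions = 0:(N - 1L),
                 patch_size = as.integer(P), source_shape = d),
            class = "patch_set")
}

#' Reassemble an image from its patch set
#'
#' Inverse of [extract_patches()]; exact round-trip.
#'
#' @param ps a `patch_set`.
#' @return the source array `H x W x C` (matrix if C = 1 on input is kept as
#'   a 3-D array with C = 1).
#' @export
reconstruct_patches <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  d <- ps$source_shape
  P <- ps$patch_size
  nc <- d[2] %/% P
  img <- array(NA_real_, d)
  for (n in seq_len(nrow(ps$patches))) {
    pos <- ps$positions[n]
    i <- pos %/% nc
    j <- pos %% nc
    blk <- aperm(array(ps$patches[n, ], c(P, P, d[3])), c(2, 1, 3))
    img[(i * P + 1L):((i + 1L) * P), (j * P + 1L):((j + 1L) * P), ] <- blk
  }
  img
}

#' Linear + positional embedding of a patch set
#'
#' Maps every flattened patch through one shared seeded linear projection and
#' adds a per-position embedding vector, yielding the `N x dim` sequence a
#' transformer encoder would consume. Deterministic per seed.
#'
#' @param ps a `patch_set`.
#' @param dim embedding width (>= 1).
#' @param seed integer seed for the projection and positional table.
#' @param pos_scale standard deviation of the positional initialisation; 0
#'   gives purely linear embeddings.
#' @return `N x dim` numeric matrix.
#' @export
embed_patches <- function(ps, dim, seed, pos_scale = 0.02) {
  stopifnot(inherits(ps, "patch_set"))
  if (dim < 1) stop("embedding dimension must be >= 1")
  D <- ncol(ps$patches)
  N <- nrow(ps$patches)
  withr::with_seed(as.integer(seed), {
    W <- matrix(stats::rnorm(D * dim, sd = 1 / sqrt(D)), D, dim)
    pos <- matrix(stats::rnorm(N * dim, sd = pos_scale), N, dim)
  })
  ps$patches %*% W + pos
}
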