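#' Convolution output size
#'
#' Spatial size of a convolution (or pooling) output:
#' `floor((l - m + 2p) / s) + 1` for input side `l`, kernel `m`, stride `s`
#' and padding `p`. With `s = 1, p = 0` this reduces to the valid-convolution
#' rule `l - m + 1`.
#'
#' @param in_size input side length in pixels.
#' @param kernel kernel side length.
#' @param stride stride (>= 1).
#' @param padding zero-padding per side (>= 0).
#' @return output side length in pixels.
#' @export
#' @examples
#' conv_output_size(224, 7, 2, 3)  # 112
conv_output_size <- function(in_size, kernel, stride = 1L, padding = 0L) {
  stopifnot(stride >= 1, padding >= 0, in_size >= 1, kernel >= 1)
  if (kernel > in_size + 2 * padding) {
    stop("kernel larger than padded input")
  }
  as.integer(floor((in_size - kernel + 2 * padding) / stride) + 1)
}

#' Max-pooling element count (literal textbook form)
#'
#' The literal pooled-tensor size formula
#' \eqn{n_c (n_h - f + 1)(n_w - f + 1) / s^2}. It is a valid-pooling,
#' idealised count and is not guaranteed to be integral; for 112x112 input
#' with f = 3, s = 2 it yields 3025 (55x55) per channel whereas the padded
#' convention used by the model builder produces 56x56. Both are exposed on
#' purpose: this calculator documents the idealisation, the builder
#' reproduces the reference layer table.
#'
#' @param n_h,n_w feature-map height and width.
#' @param n_c channels.
#' @param f pooling filter size (f <= n_h, f <= n_w).
#' @param s stride.
#' @return element count (real number).
#' @export
maxpool_size_literal <- function(n_h, n_w, n_c, f, s) {
  stopifnot(s >= 1)
  if (f > n_h || f > n_w) stop("filter larger than feature map")
  n_c * (n_h - f + 1) * (n_w - f + 1) / s^2
}

#' Plain SGD parameter update
#'
#' \eqn{\phi \leftarrow \phi - \alpha\, d\phi}, applied elementwise; the same
#' rule serves weights and biases. This is the update used by the training
#' loop.
#'
#' @param param numeric vector/matrix/array of parameters.
#' @param grad gradient of the loss w.r.t. `param`, same shape.
#' @param lr learning rate alpha.
#' @return updated parameters, same shape as `param`.
#' @export
sgd_update <- function(param, grad, lr) {
  if (!all(is.finite(param)) || !all(is.finite(grad)) || !is.finite(lr)) {
    stop("sgd_update(): non-finite input")
  }
  if (length(param) != length(grad)) stop("param/grad shape mismatch")
  param - lr * grad
}

#' Build the DenseNet-169 layer plan
#'
#' Produces the ten-row symbolic plan of the DenseNet-169 stack used for
#' radiograph grading: a 7x7 stride-2 convolution, a 3x3 stride-2 max-pool,
#' four dense blocks (6/12/32/32 composite layers, dropout 0.2) separated by
#' 1x1-conv + 2x2 stride-2 average-pool transitions, and a global-average-
#' pool + softmax classification head. Spatial sizes are computed with the
#' "same"-padded convention (p = 3 for the 7x7 convolution, p = 1 for the
#' 3x3 pool) so that a 224x224 input reproduces the canonical tensor-size
#' column 112, 56, 56, 28, 28, 14, 14, 7, 7, 1.
#'
#' @param input_size integer vector `(H, W, C)`; H must equal W and be
#'   divisible by 32.
#' @param num_classes number of output classes (softmax width).
#' @return object of class `layer_plan`: a list with `layers` (data.frame:
#'   name, kind, kernel, stride, dropout, activation, out_spatial),
#'   `input_size`, `num_classes`, `block_layers`.
#' @export
#' @examples
#' plan <- build_layer_plan(c(224, 224, 3), 5)
#' plan$layers$out_spatial  # 112 56 56 28 28 14 14 7 7 1
build_layer_plan <- function(input_size, num_classes) {
  if (length(input_size) < 2L) stop("input_size must be (H, W, C)")
  H <- as.integer(input_size[1]); W <- as.integer(input_size[2])
  C <- if (length(input_size) >= 3L) as.integer(input_size[3]) else 1L
  if (H != W) stop("input must be square (H == W)")
  if (H %% 32L != 0L) stop("input side must be divisible by 32")
  stopifnot(num_classes >= 2)

  block_layers <- c(6L, 12L, 32L, 32L)
  s_conv <- conv_output_size(H, 7L, 2L, 3L)
  s_pool <- conv_output_size(s_conv, 3L, 2L, 1L)
  s <- s_pool
  rows <- list(
    list("Convolution", "convolution", "7x7", 2L, 0, "relu", s_conv),
    list("Pooling", "maxpool", "3x3", 2L, 0, "relu", s_pool)
  )
  for (b in 1:4) {
    rows[[length(rows) + 1L]] <- list(
      sprintf("Dense %d", b), "dense_block",
      sprintf("1x1x%d 3x3x%d", block_layers[b], block_layers[b]),
      1L, 0.2, "relu", s
    )
    if (b < 4L) {
      s <- conv_output_size(s, 2L, 2L, 0L)
      rows[[length(rows) + 1L]] <- list(
        sprintf("Transition %d", b), "transition", "1x1 2x2", 2L, 0, "relu", s
      )
    }
  }
  rows[[length(rows) + 1L]] <- list(
    "Classification", "classification", sprintf("%dx%d global avg", s, s),
    1L, 0, "softmax", 1L
  )
  layers <- do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], kind = r[[2]], kernel = r[[3]], stride = r[[4]],
               dropout = r[[5]], activation = r[[6]], out_spatial = r[[7]],
               stringsAsFactors = FALSE)
  }))
  if (any(diff(layers$out_spatial) > 0)) {
    stop("internal: spatial sizes must be non-increasing")  # invariant guard
  }
  structure(
    list(layers = layers, input_size = c(H, W, C),
         num_classes = as.integer(num_classes), block_layers = block_layers),
    class = "layer_plan"
  )
}

#' @export
print.layer_plan <- function(x, ...) {
  cat(sprintf("<layer_plan> input %dx%dx%d -> %d classes\n",
              x$input_size[1], x$input_size[2], x$input_size[3], x$num_classes))
  print(x$layers, row.names = FALSE)
  invisible(x)
}

#' Serialize a layer plan to JSON
#'
#' Writes the plan's rows (layer, kernel, parameters, tensor size) as a
#' human-readable JSON table.
#'
#' @param plan a [`layer_plan`][build_layer_plan].
#' @param path output file; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
plan_to_json <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "layer_plan"))
  obj <- list(input_size = plan$input_size, num_classes = plan$num_classes,
              layers = plan$layers)
  js <- jsonlite::toJSON(obj, pretty = TRUE, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
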