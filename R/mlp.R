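#' Hyperbolic tangent activation
#'
#' The hidden-layer activation `g(y) = (1 - exp(-2y)) / (1 + exp(-2y))`,
#' algebraically identical to `tanh(y)` and evaluated as such for
#' numerical stability (saturates to +/-1 without overflow).
#'
#' @param y numeric scalar, vector or matrix.
#' @return `tanh(y)`, same shape as `y`.
#' @export
tanh_act <- function(y) tanh(y)

#' Three-layer perceptron parameters
#'
#' Container for the weights and biases `w1` (hidden x input), `b1`
#' (hidden), `w2` (output x hidden), `b2` (output) of the three-layer
#' feed-forward network used for the nonparametric kinetic rates, plus
#' an optional per-input `tanh` flag (inputs such as absolute time are
#' squashed through the activation before entering the linear input
#' layer) and a fixed per-output scale.
#'
#' The flattening order of the parameter vector is fixed:
#' `c(w1 column-major, b1, w2 column-major, b2)`.
#'
#' @param w1,b1,w2,b2 weight matrices / bias vectors.
#' @param input_tanh logical vector, length = input dim; entries flagged
#'   TRUE are passed through [tanh_act()] before the input layer.
#' @param output_scale fixed (non-trained) multiplicative scale per
#'   output.
#' @return an object of class `mlp_params`.
#' @export
mlp_params <- function(w1, b1, w2, b2, input_tanh = NULL, output_scale = NULL) {
  w1 <- as.matrix(w1); w2 <- as.matrix(w2)
  b1 <- as.numeric(b1); b2 <- as.numeric(b2)
  if (nrow(w1) != length(b1)) stop("w1/b1 hidden dimension mismatch")
  if (ncol(w2) != nrow(w1)) stop("w2 hidden dimension mismatch")
  if (nrow(w2) != length(b2)) stop("w2/b2 output dimension mismatch")
  if (is.null(input_tanh)) input_tanh <- rep(FALSE, ncol(w1))
  if (length(input_tanh) != ncol(w1)) stop("input_tanh length mismatch")
  if (is.null(output_scale)) output_scale <- rep(1, nrow(w2))
  if (length(output_scale) == 1L) output_scale <- rep(output_scale, nrow(w2))
  structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2,
                 input_tanh = as.logical(input_tanh),
                 output_scale = as.numeric(output_scale)),
            class = "mlp_params")
}

#' @export
print.mlp_params <- function(x, ...) {
  cat(sprintf("MLP %d-%d-%d (%d parameters)\n",
              ncol(x$w1), nrow(x$w1), nrow(x$w2), n_weights(x)))
  if (any(x$input_tanh))
    cat("  tanh-squashed inputs:", which(x$input_tanh), "\n")
  invisible(x)
}

#' Number of trainable parameters
#' @param p an [mlp_params()] object.
#' @return integer count `n_w = |w1| + |b1| + |w2| + |b2|`.
#' @export
n_weights <- function(p)
  length(p$w1) + length(p$b1) + length(p$w2) + length(p$b2)

#' Flatten / restore the parameter vector
#'
#' The fixed flattening order is `c(w1, b1, w2, b2)` with matrices in
#' column-major order; it round-trips exactly.
#'
#' @param p an [mlp_params()] object.
#' @param w flat numeric vector of length [n_weights()].
#' @return `flatten_params`: numeric vector; `unflatten_params`: an
#'   [mlp_params()] with the same shape metadata as `p`.
#' @export
flatten_params <- function(p) c(as.numeric(p$w1), p$b1, as.numeric(p$w2), p$b2)

#' @rdname flatten_params
#' @export
unflatten_params <- function(p, w) {
  n1 <- length(p$w1); n2 <- length(p$b1); n3 <- length(p$w2); n4 <- length(p$b2)
  if (length(w) != n1 + n2 + n3 + n4) stop("parameter vector length mismatch")
  p$w1 <- matrix(w[seq_len(n1)], nrow(p$w1), ncol(p$w1))
  p$b1 <- w[n1 + seq_len(n2)]
  p$w2 <- matrix(w[n1 + n2 + seq_len(n3)], nrow(p$w2), ncol(p$w2))
  p$b2 <- w[n1 + n2 + n3 + seq_len(n4)]
  p
}

#' Random initialization of network parameters
#'
#' Weights and biases are drawn uniformly on `[-0.5, 0.5]` scaled by
#' `1/sqrt(fan-in)` of the receiving layer, which keeps hidden units in
#' the active region of the activation. Reproducible given `seed`.
#'
#' @param seed integer seed.
#' @param d_in,d_hidden,d_out layer widths (positive).
#' @param input_tanh,output_scale passed to [mlp_params()].
#' @return an [mlp_params()] object.
#' @export
mlp_init <- function(seed, d_in, d_hidden, d_out,
                     input_tanh = NULL, output_scale = NULL) {
  if (d_in < 1 || d_hidden < 1 || d_out < 1) stop("layer widths must be positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  u <- function(n, fan_in) (stats::runif(n) - 0.5) / sqrt(fan_in)
  mlp_params(w1 = matrix(u(d_hidden * d_in, d_in), d_hidden, d_in),
             b1 = u(d_hidden, d_in),
             w2 = matrix(u(d_out * d_hidden, d_hidden), d_out, d_hidden),
             b2 = u(d_out, d_hidden),
             input_tanh = input_tanh, output_scale = output_scale)
}

# Apply the per-input tanh flag to a raw input vector.
mlp_transform_input <- function(p, X) {
  if (any(p$input_tanh)) X[p$input_tanh] <- tanh(X[p$input_tanh])
  X
}

#' Network forward pass
#'
#' Computes the kinetic rate vector
#' `rho = scale * (w2 . g(w1 . X + b1) + b2)`, with flagged inputs
#' squashed through the activation first.
#'
#' @param p an [mlp_params()] object.
#' @param X input vector (length = input dim).
#' @return numeric rate vector (length = output dim).
#' @export
mlp_forward <- function(p, X) {
  if (length(X) != ncol(p$w1))
    stop("input vector length ", length(X), " does not match network input dim ",
         ncol(p$w1))
  Xt <- mlp_transform_input(p, X)
  h <- tanh(drop(p$w1 %*% Xt) + p$b1)
  p$output_scale * (drop(p$w2 %*% h) + p$b2)
}

#' Analytic Jacobian of the network output w.r.t. its inputs
#'
#' `d rho / d X = scale * w2 . diag(1 - g(h)^2) . w1`, corrected by
#' `(1 - tanh(X_k)^2)` for tanh-flagged inputs. Matches central finite
#' differences.
#'
#' @inheritParams mlp_forward
#' @return matrix (output dim x input dim).
#' @export
mlp_jac_inputs <- function(p, X) {
  Xt <- mlp_transform_input(p, X)
  h <- tanh(drop(p$w1 %*% Xt) + p$b1)
  J <- (p$w2 * rep(1 - h^2, each = nrow(p$w2))) %*% p$w1
  if (any(p$input_tanh)) {
    d <- rep(1, length(X))
    d[p$input_tanh] <- 1 - tanh(X[p$input_tanh])^2
    J <- J * rep(d, each = nrow(J))
  }
  p$output_scale * J
}

#' Analytic Jacobian of the network output w.r.t. its parameters
#'
#' Derivative of the forward pass with respect to the flattened
#' parameter vector (order `c(w1, b1, w2, b2)`). Matches central finite
#' differences.
#'
#' @inheritParams mlp_forward
#' @return matrix (output dim x [n_weights()]).
#' @export
mlp_jac_weights <- function(p, X) {
  Xt <- mlp_transform_input(p, X)
  a <- drop(p$w1 %*% Xt) + p$b1
  h <- tanh(a)
  dh <- 1 - h^2
  n_out <- nrow(p$w2); n_hid <- nrow(p$w1); n_in <- ncol(p$w1)
  J <- matrix(0, n_out, n_weights(p))
  # w1 (column-major): entry (i,j) at (j-1)*n_hid + i
  M <- p$w2 * rep(dh, each = n_out)            # n_out x n_hid
  for (j in seq_len(n_in))
    J[, (j - 1L) * n_hid + seq_len(n_hid)] <- M * Xt[j]
  off <- n_hid * n_in
  J[, off + seq_len(n_hid)] <- M               # b1
  off <- off + n_hid
  # w2 (column-major): entry (o,k) at (k-1)*n_out + o
  for (k in seq_len(n_hid))
    J[, off + (k - 1L) * n_out + seq_len(n_out)] <- diag(h[k], n_out)
  off <- off + n_out * n_hid
  J[, off + seq_len(n_out)] <- diag(1, n_out)  # b2
  p$output_scale * J
}

#' Serialize / restore network parameters as JSON
#'
#' Bit-exact round trip (17 significant digits) of weights, biases,
#' dimensions, input-tanh flags and output scales.
#'
#' @param p an [mlp_params()] object.
#' @param txt JSON string produced by `mlp_to_json`.
#' @return `mlp_to_json`: JSON string; `mlp_from_json`: [mlp_params()].
#' @export
mlp_to_json <- function(p) {
  jsonlite::toJSON(list(
    dims = c(ncol(p$w1), nrow(p$w1), nrow(p$w2)),
    w1 = as.numeric(p$w1), b1 = p$b1, w2 = as.numeric(p$w2), b2 = p$b2,
    input_tanh = p$input_tanh, output_scale = p$output_scale),
    auto_unbox = TRUE, digits = I(17))
}

#' @rdname mlp_to_json
#' @export
mlp_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  d <- as.integer(x$dims)
  mlp_params(w1 = matrix(as.numeric(x$w1), d[2], d[1]),
             b1 = as.numeric(x$b1),
             w2 = matrix(as.numeric(x$w2), d[3], d[2]),
             b2 = as.numeric(x$b2),
             input_tanh = as.logical(x$input_tanh),
             output_scale = as.numeric(x$output_scale))
}
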