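# LSTM primitives. The cell follows the standard gated update: forget,
# input and output gates are sigmoids of an affine map of the concatenated
# [h(t-1), x(t)]; the candidate cell state is a tanh of the same
# concatenation; c(t) = f * c(t-1) + i * c_tilde; h(t) = o * tanh(c(t)).
# Gate rows in the stacked weight matrix are ordered f, i, o, c.

#' Initialise parameters for one LSTM layer
#'
#' Weights are drawn uniformly scaled by fan-in (`+/- 1/sqrt(hidden + input)`)
#' from the current RNG stream; biases start at zero.
#'
#' @param input_size Width of the layer input x(t).
#' @param hidden_size Width of the hidden/cell state.
#' @return List with `W` (`4*hidden x (hidden + input)`) and `b`
#'   (`4*hidden`).
#' @export
init_lstm_params <- function(input_size, hidden_size) {
  ncols <- hidden_size + input_size
  s <- 1 / sqrt(ncols)
  list(W = matrix(runif(4 * hidden_size * ncols, -s, s),
                  nrow = 4 * hidden_size),
       b = numeric(4 * hidden_size))
}

#' One LSTM cell update
#'
#' Applies the gated cell update to a single input vector and previous
#' state. Returned intermediates (`f`, `i`, `o`, `c_tilde`) are exposed so
#' the gate algebra can be verified directly: gates lie in (0, 1), the
#' candidate state in (-1, 1), and with the input gate at zero the cell
#' update is exactly `c(t) = f * c(t-1)`.
#'
#' @param x Input vector (length = input size).
#' @param state List with previous `h` and `c` vectors (length = hidden
#'   size).
#' @param params List with `W` (`4H x (H + D)`) and `b` (`4H`), gate rows
#'   ordered f, i, o, c.
#' @return List with new `h`, `c` and intermediates `f`, `i`, `o`,
#'   `c_tilde`.
#' @examples
#' p <- list(W = matrix(0, 4, 2), b = numeric(4))
#' st <- lstm_cell_step(0, list(h = 0, c = 2), p)
#' st$c            # 1:   c = sigmoid(0) * 2 + sigmoid(0) * tanh(0)
#' st$h            # 0.5 * tanh(1)
#' @export
lstm_cell_step <- function(x, state, params) {
  h_prev <- state$h
  c_prev <- state$c
  hh <- length(h_prev)
  if (length(c_prev) != hh) {
    stop_nibgm("h and c must have the same length", "nibgm_model_error")
  }
  if (nrow(params$W) != 4L * hh ||
      ncol(params$W) != hh + length(x) ||
      length(params$b) != 4L * hh) {
    stop_nibgm(sprintf(
      "weight shape (%d x %d) inconsistent with hidden %d and input %d",
      nrow(params$W), ncol(params$W), hh, length(x)), "nibgm_model_error")
  }
  a <- drop(params$W %*% c(h_prev, x)) + params$b
  f <- sigmoid(a[seq_len(hh)])
  i <- sigmoid(a[hh + seq_len(hh)])
  o <- sigmoid(a[2L * hh + seq_len(hh)])
  g <- tanh(a[3L * hh + seq_len(hh)])
  c_new <- f * c_prev + i * g
  list(h = o * tanh(c_new), c = c_new, f = f, i = i, o = o, c_tilde = g)
}

# Batched LSTM layer step: H_prev/C_prev/inp are matrices with one column
# per sequence. Returns new states plus the cache needed for
# backpropagation through time.
lstm_layer_step_batch <- function(layer, inp, h_prev, c_prev) {
  hh <- nrow(h_prev)
  z <- rbind(h_prev, inp)
  a <- layer$W %*% z + layer$b
  f <- sigmoid(a[seq_len(hh), , drop = FALSE])
  i <- sigmoid(a[hh + seq_len(hh), , drop = FALSE])
  o <- sigmoid(a[2L * hh + seq_len(hh), , drop = FALSE])
  g <- tanh(a[3L * hh + seq_len(hh), , drop = FALSE])
  c_new <- f * c_prev + i * g
  tc <- tanh(c_new)
  list(h = o * tc, c = c_new,
       cache = list(z = z, f = f, i = i, o = o, g = g,
                    c_prev = c_prev, c = c_new, tc = tc))
}

# Backward pass for one batched layer step. dh/dc are the gradients flowing
# into h(t) and c(t). Returns parameter gradients plus gradients for the
# previous state and the layer input.
lstm_layer_step_backward <- function(layer, cache, dh, dc_carry) {
  hh <- nrow(dh)
  do <- dh * cache$tc
  da_o <- do * cache$o * (1 - cache$o)
  dc <- dc_carry + dh * cache$o * (1 - cache$tc^2)
  df <- dc * cache$c_prev
  da_f <- df * cache$f * (1 - cache$f)
  di <- dc * cache$g
  da_i <- di * cache$i * (1 - cache$i)
  dg <- dc * cache$i
  da_c <- dg * (1 - cache$g^2)
  da <- rbind(da_f, da_i, da_o, da_c)
  dz <- crossprod(layer$W, da)
  list(gW = tcrossprod(da, cache$z),
       gb = rowSums(da),
       dh_prev = dz[seq_len(hh), , drop = FALSE],
       dc_prev = dc * cache$f,
       dx = dz[-seq_len(hh), , drop = FALSE])
}
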