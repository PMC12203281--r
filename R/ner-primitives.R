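# Building blocks of the sequence-labeling stack, exposed directly so each can
# be checked against hand arithmetic: scaled dot-product attention, the
# receptive field of a stack of dilated convolutions, and a single LSTM cell
# update.

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, row-wise: each output row is a convex
#' combination of the rows of `V` with weights from the softmax-normalized
#' query-key similarities.
#'
#' @param Q Query matrix (n_q x d_k).
#' @param K Key matrix (n_k x d_k).
#' @param V Value matrix (n_k x d_v).
#' @param d_k Key dimension used for the `1/sqrt(d_k)` scaling
#'   (default `ncol(K)`).
#' @param weights If `TRUE`, also return the attention-weight matrix.
#' @return The (n_q x d_v) output matrix, or a list `(output, weights)`.
#' @examples
#' attention(matrix(1), matrix(1), matrix(1)) # 1x1 case: softmax of a scalar
#' @export
attention <- function(Q, K, V, d_k = ncol(K), weights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) {
    stop_hichds("Q and K must share the key dimension (%d vs %d)",
                ncol(Q), ncol(K), class = "hichds_shape_error")
  }
  if (nrow(K) != nrow(V)) {
    stop_hichds("K and V must have the same number of rows (%d vs %d)",
                nrow(K), nrow(V), class = "hichds_shape_error")
  }
  if (d_k <= 0) stop_hichds("d_k must be positive", class = "hichds_shape_error")
  S <- Q %*% t(K) / sqrt(d_k)
  W <- exp(S - apply(S, 1, max))
  W <- W / rowSums(W)
  out <- W %*% V
  if (weights) list(output = out, weights = W) else out
}

#' Dilation schedule for a stacked dilated-convolution encoder
#'
#' @param kernel Odd positive kernel width (default 3).
#' @param dilations Positive integer dilation width per layer (default
#'   `c(1, 2, 4)`, the doubling schedule under which the receptive field of
#'   layer i is `2^(i+2) - 1` for kernel 3).
#' @return An object of class `dilation_schedule`.
#' @export
dilation_schedule <- function(kernel = 3, dilations = c(1, 2, 4)) {
  if (kernel < 1 || kernel %% 2 != 1) {
    stop_hichds("kernel width must be odd and positive", class = "hichds_contract_error")
  }
  if (length(dilations) == 0 || any(dilations < 1)) {
    stop_hichds("dilations must be positive integers", class = "hichds_contract_error")
  }
  structure(list(kernel = as.integer(kernel), dilations = as.integer(dilations)),
            class = "dilation_schedule")
}

#' Receptive field of a stacked dilated convolution
#'
#' The number of input positions that influence one output position after
#' `layer` stacked convolutions of the schedule's kernel width and dilations:
#' each layer of dilation d adds `(kernel - 1) * d` positions.
#'
#' @param schedule A [dilation_schedule()].
#' @param layer Layer index (1-based) up to `length(schedule$dilations)`.
#' @return Integer receptive-field width.
#' @examples
#' receptive_field(dilation_schedule(3, c(1, 2, 4)), 3) # 15
#' @export
receptive_field <- function(schedule, layer = length(schedule$dilations)) {
  stopifnot(inherits(schedule, "dilation_schedule"))
  if (layer < 1 || layer > length(schedule$dilations)) {
    stop_hichds("layer %d outside schedule of depth %d", layer,
                length(schedule$dilations), class = "hichds_range_error")
  }
  half <- (schedule$kernel - 1L) %/% 2L
  support <- 0L
  for (l in seq_len(layer)) {
    offsets <- schedule$dilations[l] * seq.int(-half, half)
    support <- sort(unique(rep(support, each = length(offsets)) + offsets))
  }
  # for contiguous-support schedules (dilation 1 first, then doubling) this
  # equals the span 1 + (kernel - 1) * sum(dilations)
  length(support)
}

#' An LSTM cell
#'
#' Gate weights act on the concatenation `[h_prev, u_t]`; the gate
#' nonlinearity is the logistic function and the state nonlinearity is tanh.
#'
#' @param W_f,W_i,W_o,W_c Gate weight matrices, each `hidden x (hidden + input)`.
#' @param b_f,b_i,b_o,b_c Gate bias vectors of length `hidden`.
#' @return An object of class `lstm_cell`.
#' @export
lstm_cell <- function(W_f, W_i, W_o, W_c, b_f = 0, b_i = 0, b_o = 0, b_c = 0) {
  Ws <- lapply(list(W_f = W_f, W_i = W_i, W_o = W_o, W_c = W_c), as.matrix)
  H <- nrow(Ws$W_f)
  for (nm in names(Ws)) {
    if (!all(dim(Ws[[nm]]) == dim(Ws$W_f))) {
      stop_hichds("%s does not match the other gate weights", nm, class = "hichds_shape_error")
    }
  }
  bs <- lapply(list(b_f = b_f, b_i = b_i, b_o = b_o, b_c = b_c), function(b) {
    if (length(b) == 1) rep(as.numeric(b), H) else as.numeric(b)
  })
  if (any(vapply(bs, length, 1L) != H)) {
    stop_hichds("bias length must equal the hidden size %d", H, class = "hichds_shape_error")
  }
  structure(c(Ws, bs, list(hidden = H, input = ncol(Ws$W_f) - H)), class = "lstm_cell")
}

#' One LSTM time step
#'
#' Computes the forget, input and output gates from `[h_prev, u_t]`, the
#' candidate cell state, the updated cell state
#' `C_t = f_t * C_prev + i_t * C~_t`, and the hidden state
#' `h_t = O_t * tanh(C_t)`.
#'
#' @param cell An [lstm_cell()].
#' @param u_t Input vector of length `cell$input`.
#' @param h_prev,C_prev Previous hidden and cell state vectors of length
#'   `cell$hidden`.
#' @return List with `h`, `C` and a `gates` list (`f`, `i`, `o`, `c_tilde`).
#' @export
lstm_step <- function(cell, u_t, h_prev, C_prev) {
  stopifnot(inherits(cell, "lstm_cell"))
  if (length(u_t) != cell$input || length(h_prev) != cell$hidden ||
      length(C_prev) != cell$hidden) {
    stop_hichds("input/state dimensions do not match the cell", class = "hichds_shape_error")
  }
  x <- c(h_prev, u_t)
  sig <- function(z) 1 / (1 + exp(-z))
  f <- sig(drop(cell$W_f %*% x) + cell$b_f)
  i <- sig(drop(cell$W_i %*% x) + cell$b_i)
  o <- sig(drop(cell$W_o %*% x) + cell$b_o)
  c_tilde <- tanh(drop(cell$W_c %*% x) + cell$b_c)
  C <- f * C_prev + i * c_tilde
  h <- o * tanh(C)
  list(h = h, C = C, gates = list(f = f, i = i, o = o, c_tilde = c_tilde))
}
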