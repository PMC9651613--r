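# Global pooling: SortPooling (fixed-size K x d selection by continuous
# WL-style colors) and AlphaMEX (trainable log-mean-exp pooling).

#' SortPooling: fixed-size selection of node states
#'
#' Sorts the rows of a node-state matrix in descending order by the last
#' channel (the continuous Weisfeiler-Lehman-color convention: the deepest
#' feature channel acts as the refinement color), breaking ties by the
#' preceding channels right-to-left and finally by the canonical row order,
#' then keeps the top K rows. If fewer than K rows exist, zero rows are
#' appended so the output shape is always K x d.
#'
#' @param states Numeric matrix N x d, N >= 1.
#' @param K Number of output rows.
#' @return A K x d matrix with attribute `"indices"`: the selected input row
#'   indices (NA for zero-padded rows), used by the training backward pass.
#' @export
sort_pooling <- function(states, K) {
  states <- as.matrix(states)
  if (nrow(states) == 0L) stop("sort_pooling requires at least one row")
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  d <- ncol(states); N <- nrow(states)
  last <- states[, d]
  if (anyDuplicated(last)) {
    keys <- lapply(rev(seq_len(d)), function(j) -states[, j])
    ord <- do.call(order, c(keys, list(seq_len(N))))
  } else {
    ord <- order(-last)    # no ties in the color channel: single key
  }
  take <- ord[seq_len(min(K, N))]
  out <- matrix(0, K, d)
  out[seq_along(take), ] <- states[take, , drop = FALSE]
  attr(out, "indices") <- c(take, rep(NA_integer_, K - length(take)))
  out
}

#' Trainable pooling sharpness parameter
#'
#' AlphaMEX's alpha is kept strictly inside (0.5, 1) via a scaled logistic
#' squash of an unconstrained parameter theta: below 0.5 the log-mean-exp
#' temperature log(alpha/(1-alpha)) turns negative and the pooling flips
#' toward a soft minimum, so only the soft-max branch is exposed.
#'
#' @param theta Unconstrained scalar.
#' @return alpha in (0.5, 1) (clamped away from both endpoints so the
#'   pooling temperature stays finite in floating point).
#' @export
alpha_from_theta <- function(theta) {
  pmin(pmax(0.5 + 0.5 * stats::plogis(theta), 0.5 + 1e-12), 1 - 1e-12)
}

#' @rdname alpha_from_theta
#' @param alpha Value in (0.5, 1).
#' @export
theta_from_alpha <- function(alpha) {
  if (any(alpha <= 0.5 | alpha >= 1)) stop("alpha must lie in (0.5, 1)")
  stats::qlogis((alpha - 0.5) * 2)
}

#' AlphaMEX global pooling (trainable log-mean-exp)
#'
#' Per channel c, computes
#' \deqn{\frac{1}{\log\frac{\alpha}{1-\alpha}}
#'       \log\Big(\frac{1}{n}\sum_{i=1}^n
#'       \big(\tfrac{\alpha}{1-\alpha}\big)^{h_{ic}}\Big)}
#' over the n rows of the input. As alpha approaches 1 the result approaches
#' the channel maximum; at constant input it returns that constant. The
#' exponentials are computed in log space with a max shift, so inputs with
#' |h| up to hundreds are safe; results match the literal formula to 1e-9
#' for |h| <= 50.
#'
#' @param states Numeric matrix M x d (or a vector, treated as M x 1).
#' @param alpha Pooling sharpness in (0.5, 1); see [alpha_from_theta()].
#' @return Numeric vector of length d.
#' @examples
#' alphamex(matrix(c(0, 1), 2, 1), 0.9)  # log(5)/log(9) ~ 0.7325
#' @export
alphamex <- function(states, alpha) {
  if (is.vector(states)) states <- matrix(states, ncol = 1L)
  if (nrow(states) < 1L) stop("alphamex requires at least one row")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0.5 || alpha >= 1)
    stop("alpha must be a scalar in (0.5, 1)")
  beta <- log(alpha / (1 - alpha))     # > 0 on the allowed branch
  z <- beta * states
  m <- col_maxs(z)
  lse <- m + log(colMeans(exp(sweep(z, 2L, m))))
  lse / beta
}

col_maxs <- function(z) {
  if (nrow(z) == 1L) return(z[1L, ])
  z[cbind(max.col(t(z), ties.method = "first"), seq_len(ncol(z)))]
}

# backward: given upstream gradient dy (length d), return gradients wrt the
# input rows and wrt alpha. Softmax weights over rows give d y / d h.
alphamex_backward <- function(states, alpha, dy) {
  if (is.vector(states)) states <- matrix(states, ncol = 1L)
  beta <- log(alpha / (1 - alpha))
  z <- beta * states
  m <- col_maxs(z)
  ez <- exp(sweep(z, 2L, m))
  wgt <- sweep(ez, 2L, colSums(ez), "/")          # M x d softmax weights
  dstates <- sweep(wgt, 2L, dy, "*")
  y <- (m + log(colMeans(ez))) / beta
  dy_dbeta <- (colSums(wgt * states) - y) / beta  # per channel
  dbeta_dalpha <- 1 / (alpha * (1 - alpha))
  list(dstates = dstates, dalpha = sum(dy * dy_dbeta) * dbeta_dalpha)
}
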