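#' Scaled dot-product self-attention over a group's feature tokens
#'
#' Computes `weights = row_softmax(X %*% t(X) / scale)` and
#' `context = weights %*% X`, where `X` is an `n x d` token matrix (one
#' token per clinical feature in a group, embedding dimension `d`).  The
#' scale is `sqrt(d)` by default, or `d` with `score_scale = "linear"`.
#' The softmax is stabilized by row-max subtraction, so weights are strictly
#' positive and every row sums to 1: each context row is a convex
#' combination of the input tokens.
#'
#' @param X Numeric matrix, `n` tokens by `d` embedding dimensions, finite.
#' @param score_scale `"sqrt"` (divide scores by `sqrt(d)`) or `"linear"`
#'   (divide by `d`).
#' @return An `ad_attention` list with `weights` (`n x n`, row-stochastic)
#'   and `context` (`n x d`).
#' @examples
#' att <- scaled_dot_attention(diag(2))
#' rowSums(att$weights)
#' @export
scaled_dot_attention <- function(X, score_scale = c("sqrt", "linear")) {
  score_scale <- match.arg(score_scale)
  X <- as.matrix(X)
  if (!is.numeric(X) || !all(is.finite(X))) {
    abort("Attention input must be a finite numeric matrix.")
  }
  d <- ncol(X)
  if (nrow(X) < 1L || d < 1L) abort("Attention input must have at least one token and one dimension.")
  scl <- if (score_scale == "sqrt") sqrt(d) else d
  S <- tcrossprod(X) / scl
  W <- softmax_rows(S)
  out <- list(weights = W, context = W %*% X, score_scale = score_scale)
  class(out) <- "ad_attention"
  out
}

#' Embed a group's normalized feature values as tokens
#'
#' Maps each scalar feature value `v_i` in \[0, 1\] to a `d`-dimensional
#' token `w_i * v_i + b_i` using the group's learnable per-feature weight
#' and bias vectors.  This is what lets self-attention act across a group's
#' features: a raw `1 x n` value vector would make `X %*% t(X)` a scalar and
#' the attention an identity.
#'
#' @param values Numeric vector of normalized feature values (length = group
#'   size, entries in \[0, 1\]).
#' @param params List with matrices `W` and `B`, each `n x d` (row `i` is
#'   the weight/bias vector of feature `i`).
#' @return An `n x d` token matrix.
#' @export
embed_group <- function(values, params) {
  W <- params$W
  B <- params$B
  if (length(values) != nrow(W)) {
    abort(sprintf("Group has %d embedding rows but %d values were given.",
                  nrow(W), length(values)))
  }
  W * values + B  # row i scaled by values[i] (column-major recycling over d)
}

#' Pool an attention result into a group context vector
#'
#' The group's fixed-length summary is the mean over the `n` context rows,
#' giving a length-`d` vector independent of group size.
#'
#' @param result An `ad_attention` from [scaled_dot_attention()].
#' @return Numeric vector of length `d`.
#' @export
pool_context <- function(result) {
  if (!inherits(result, "ad_attention")) abort("`result` must be an `ad_attention`.")
  colMeans(result$context)
}
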