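# Shared numerical helpers. All probabilistic computation in the package is
# done in log space (nats); probabilities are materialised only at API
# boundaries.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed with max-subtraction.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# softmax of a log-scale vector; errors when all entries are -Inf rather than
# silently renormalising garbage.
softmax_log <- function(x) {
  m <- max(x)
  if (m == -Inf) {
    stop("all log-odds are -Inf: the evidence assigns zero probability to every state")
  }
  e <- exp(x - m)
  e / sum(e)
}

# row-wise logsumexp / softmax for a matrix of log-scale values
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

row_softmax_log <- function(x) {
  p <- exp(x - apply(x, 1L, max))
  p / rowSums(p)
}

# Shannon entropy in nats with the 0 log 0 = 0 convention
entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# KL(p || q) in nats; terms with p = 0 contribute 0. q is floored at
# 1e-300 so that beliefs that underflowed to exactly zero yield a large
# finite divergence rather than Inf (which would poison score differences).
kl_div <- function(p, q) {
  keep <- p > 0
  sum(p[keep] * (log(p[keep]) - log(pmax(q[keep], 1e-300))))
}

# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# random Dirichlet draw (symmetric unless alpha is a vector)
rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = rep_len(alpha, k), rate = 1)
  if (all(g == 0)) g <- rep(1, k)
  g / sum(g)
}
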