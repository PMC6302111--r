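# Sequential Bayesian posterior maintenance over the finite category set.
# Beliefs are probability vectors chained across saccades: the posterior of
# one step becomes the prior of the next, so the final belief is invariant to
# the order in which disjoint viewpoint batches are consumed.

#' Construct a belief (probability vector over categories)
#'
#' @param probs non-negative numeric vector summing to 1 (within 1e-12 before
#'   renormalisation).
#' @param classes optional character labels.
#' @return an object of class `belief`.
#' @export
belief <- function(probs, classes = NULL) {
  stopifnot(is.numeric(probs), all(probs >= 0), length(probs) >= 1L)
  s <- sum(probs)
  if (abs(s - 1) > 1e-6) stop("belief does not sum to 1 (sum = ", s, ")")
  probs <- probs / s
  if (!is.null(classes)) names(probs) <- classes
  structure(probs, class = "belief")
}

#' @export
print.belief <- function(x, ...) {
  cat("<belief>", sprintf("H = %.4f nats\n", belief_entropy(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Initial belief from the root approximation coefficient
#'
#' Before any saccade, a loose first guess is formed from the single root
#' coefficient of the pyramid: the softmax over categories of the root
#' Gaussian log-likelihood plus the log class prior.
#'
#' @param pyramid a `wavelet_pyramid`; @param bank a `model_bank`.
#' @return a `belief`.
#' @export
init_prior <- function(pyramid, bank) {
  if (is.null(bank$root_mean)) stop("model bank has no root models")
  ll <- root_loglik_vector(bank, pyramid$root)
  belief(softmax_log(ll + log(bank$prior)), bank$classes)
}

#' Bayesian belief update from a multiscale field
#'
#' Posterior proportional to `exp(field log-likelihood) * prior`, computed in
#' log space with max-subtraction. An empty field returns the prior
#' unchanged.
#'
#' @param prior a `belief`; @param field a `multiscale_field`;
#' @param bank a `model_bank`.
#' @return the posterior `belief`.
#' @export
update_belief <- function(prior, field, bank) {
  stopifnot(inherits(prior, "belief"))
  ll <- field_loglik_vector(field, bank)
  belief(softmax_log(ll + log(unclass(prior))), names(prior) %||% bank$classes)
}

#' Belief entropy in nats
#'
#' @param b a `belief` (or bare probability vector).
#' @return entropy in `[0, log K]`.
#' @export
belief_entropy <- function(b) entropy_nats(as.numeric(b))

#' Single-view posterior over categories
#'
#' The posterior `p(Z | x, u)` of one field alone, i.e. a belief update from
#' a uniform prior over the categories. This is the quantity entering the
#' IGLB/IGUB scores; the uniform prior makes their bound identities exact.
#'
#' @param field a `multiscale_field`; @param bank a `model_bank`.
#' @return a `belief`.
#' @export
one_view_posterior <- function(field, bank) {
  ll <- field_loglik_vector(field, bank)
  belief(softmax_log(ll), bank$classes)
}
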