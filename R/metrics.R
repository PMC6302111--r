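# Action-selection metrics.
#
# All metrics are expressed as scores of a candidate observation (x | u)
# against the belief history, and all are returned on a "higher is
# preferred" scale (the free-energy loss is negated). Writing l_cand(z) =
# log p(x | z, u) for the candidate and l_prev(z) for the previous
# observation, with beliefs q_prev (one step back) and q_prev2 (two steps
# back):
#
#   q_next  ~ exp(l_cand) * q_prev          (Bayes update)
#   p(z|x,u) = softmax(l_cand)              (single-view posterior, uniform prior)
#   q_skip  ~ p(z|x,u) * q_prev2            (update skipping the previous step)
#
#   infomax   = H(q_prev) - H(q_next)
#   saliency  = KL(q_next || q_prev)                  (Bayesian surprise)
#   vfe       = -(-log p(x|u; q_prev) + KL(q_prev || q_next))   (negated loss)
#   iglb      = E_{z ~ q_prev}[log p(z|x,u)]          (additive constant dropped)
#   igub      = E_{z ~ q_next}[log p(z|x,u)]          (additive constant dropped)
#   ci        = full two-term compression-improvement difference of
#               reconstruction costs at the exact posteriors
#
# The IGLB underestimates and the IGUB overestimates the exact sequential
# information gain by exactly the epistemic cost KL(q_prev||q_next) and the
# Salience KL(q_next||q_prev) respectively; these identities are verified by
# enumeration in the test suite.

#' Metric identifiers
#' @return character vector of the supported metric ids.
#' @export
metric_ids <- function() {
  c("random", "infomax", "saliency", "vfe", "ci", "iglb", "iglb_sharp", "igub")
}

#' Assemble the scoring context for one candidate observation
#'
#' @param loglik_cand per-category log-likelihood vector of the candidate
#'   observation, `log p(x | z, u)`.
#' @param q_prev belief one step back (`q^(n-1)`).
#' @param q_prev2 belief two steps back (`q^(n-2)`); needed by `ci` and the
#'   exact information gain. On the first saccade, seed it with the class
#'   prior.
#' @param loglik_prev per-category log-likelihood vector of the previous
#'   observation; needed by `ci` / exact IG.
#' @param q_next,q_skip optional externally computed posteriors; when
#'   supplied they are validated against the Bayes updates implied by the
#'   likelihoods and a contract violation is raised on mismatch.
#' @return an object of class `metric_context`.
#' @export
metric_context <- function(loglik_cand, q_prev, q_prev2 = NULL,
                           loglik_prev = NULL, q_next = NULL, q_skip = NULL) {
  q_prev <- as.numeric(q_prev)
  K <- length(q_prev)
  stopifnot(length(loglik_cand) == K)
  log_post_one <- loglik_cand - logsumexp(loglik_cand)
  q_next0 <- softmax_log(loglik_cand + log(q_prev))
  if (!is.null(q_next) && max(abs(as.numeric(q_next) - q_next0)) > 1e-8) {
    stop("contract violation: q_next is not the Bayes update of q_prev")
  }
  q_skip0 <- NULL
  if (!is.null(q_prev2)) {
    q_prev2 <- as.numeric(q_prev2)
    stopifnot(length(q_prev2) == K)
    q_skip0 <- softmax_log(log_post_one + log(q_prev2))
    if (!is.null(q_skip) && max(abs(as.numeric(q_skip) - q_skip0)) > 1e-8) {
      stop("contract violation: q_skip is not the single-view update of q_prev2")
    }
  }
  structure(list(loglik_cand = loglik_cand, log_post_one = log_post_one,
                 q_prev = q_prev, q_prev2 = q_prev2,
                 loglik_prev = loglik_prev,
                 q_next = q_next0, q_skip = q_skip0),
            class = "metric_context")
}

#' Score a candidate observation under an action-selection metric
#'
#' Higher scores are preferred for every metric; losses are negated
#' internally. `"random"` ignores the context and returns a seeded uniform
#' draw. `"iglb_sharp"` replaces the expectation over `q_prev` by its single
#' argmax category.
#'
#' @param metric one of [metric_ids()].
#' @param ctx a [metric_context()].
#' @param seed integer seed, required for `metric = "random"`.
#' @return scalar score.
#' @export
score_candidate <- function(metric, ctx, seed = NULL) {
  metric <- match.arg(metric, metric_ids())
  stopifnot(inherits(ctx, "metric_context"))
  qp <- ctx$q_prev; qn <- ctx$q_next; lp <- ctx$log_post_one
  switch(metric,
    random = {
      if (is.null(seed)) stop("random metric requires a seed")
      withr::with_seed(as.integer(seed), stats::runif(1))
    },
    infomax = entropy_nats(qp) - entropy_nats(qn),
    saliency = kl_div(qn, qp),
    vfe = {
      log_evidence <- logsumexp(ctx$loglik_cand + log(qp))
      -(-log_evidence + kl_div(qp, qn))
    },
    iglb = sum(qp * lp),
    iglb_sharp = lp[which.max(qp)],
    igub = sum(qn * lp),
    ci = {
      if (is.null(ctx$loglik_prev) || is.null(ctx$q_prev2)) {
        stop("ci requires loglik_prev and q_prev2 in the context")
      }
      f_before <- sum(qp * (-ctx$loglik_prev)) + kl_div(qp, ctx$q_prev2)
      f_after <- sum(qn * (-ctx$loglik_prev)) + kl_div(qn, ctx$q_skip)
      f_before - f_after
    })
}

#' Approximate compression improvement in KL-difference form
#'
#' The KL-difference form of the approximate compression improvement for an
#' arbitrary reference belief `q`: `KL(q || q^(n-2)) - KL(q || q^(n;n-2))`.
#' With `q = q_prev` this is the IGLB including its action-dependent
#' normalising term (the term dropped as "constant" in the score form); with
#' `q = q_next` it is the corresponding IGUB form. The score-form and
#' KL-form rankings over candidate actions coincide only when that term is
#' flat across actions.
#'
#' @param ctx a [metric_context()] with `q_prev2` populated.
#' @param q reference belief (defaults to `ctx$q_prev`).
#' @return scalar.
#' @export
approximate_ci_kl_form <- function(ctx, q = ctx$q_prev) {
  stopifnot(inherits(ctx, "metric_context"), !is.null(ctx$q_prev2))
  q <- as.numeric(q)
  kl_div(q, ctx$q_prev2) - kl_div(q, ctx$q_skip)
}

#' Exact sequential information gain
#'
#' The improvement in retrospective log evidence for the previous observation
#' brought by the candidate observation:
#' `log p(x_prev | u_prev; q_skip) - log p(x_prev | u_prev; q_prev2)`,
#' where `q_skip` is the belief two steps back updated with the candidate's
#' single-view posterior. Requires an enumerable (or Gaussian) observation
#' model so the log evidences are computable; exact in the discrete toy
#' worlds used for bound verification.
#'
#' @param ctx a [metric_context()] with `loglik_prev` and `q_prev2`.
#' @return scalar information gain (nats).
#' @export
exact_sequential_ig <- function(ctx) {
  stopifnot(inherits(ctx, "metric_context"))
  if (is.null(ctx$loglik_prev) || is.null(ctx$q_prev2)) {
    stop("exact information gain requires loglik_prev and q_prev2")
  }
  logsumexp(ctx$loglik_prev + log(ctx$q_skip)) -
    logsumexp(ctx$loglik_prev + log(ctx$q_prev2))
}
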