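# Saccadic exploration policies.
#
# select_action implements prediction-based action selection: for every
# category z and candidate gaze u, a visual field is imagined from the
# generative model (restricted to the gaze's not-yet-consumed triplets), the
# chosen metric scores it against the belief history, and the gaze
# maximising the belief-weighted score is returned. explore_scene wraps this
# in the evidence-accumulation loop: read the field, update the belief,
# retire the consumed coordinates (inhibition of return), stop once the
# belief entropy drops below H_ref or the action set is exhausted.
#
# The pre-processed shortcut bypasses the per-step prediction entirely: for
# each category, the expected log posterior of a mode-predicted field is
# tabulated per gaze once (an "action map"), gazes are sorted by descending
# map value into per-category trajectories, and at run time the next gaze is
# read off the current guess's list in O(1), switching lists on the fly when
# the guess is revised.

safe_log <- function(x) log(pmax(x, 1e-300))

#' Initialise the mutable state of a scene exploration
#'
#' Forms the initial belief from the root coefficient (counted as 1
#' coefficient read), seeds the two-step belief history with the class prior
#' and the root observation (so history-based metrics are defined on the
#' first saccade), and opens the full 16x16 action set.
#'
#' @param pyramid a `wavelet_pyramid`; @param bank a `model_bank`.
#' @return an object of class `exploration_state`.
#' @export
exploration_state <- function(pyramid, bank) {
  structure(list(
    belief = init_prior(pyramid, bank),
    belief_prev = belief(bank$prior, bank$classes),
    loglik_prev = root_loglik_vector(bank, pyramid$root),
    live = rep(TRUE, .N_GAZES),
    consumed = rep(FALSE, .N_VIEWPOINTS),
    step = 0L, triplets_read = 0L, coefficients_read = 1L,
    n_predictions = 0L), class = "exploration_state")
}

# metric scores for all 256 candidate gazes given one predicting category's
# log-likelihood table G (256 x K rows: candidate-field loglik per gaze)
metric_scores_rows <- function(metric, G, qp, q_prev2 = NULL,
                               loglik_prev = NULL) {
  LP <- G - row_logsumexp(G)                 # log single-view posterior
  A <- sweep(G, 2L, safe_log(qp), "+")
  lev <- row_logsumexp(A)                    # log evidence rows
  Qn <- exp(A - lev)                         # q_next rows
  lQn <- safe_log(Qn)
  switch(metric,
    infomax = entropy_nats(qp) + rowSums(Qn * lQn),
    saliency = rowSums(Qn * sweep(lQn, 2L, safe_log(qp))),
    vfe = lev - (sum(qp * safe_log(qp)) - drop(lQn %*% qp)),
    iglb = drop(LP %*% qp),
    iglb_sharp = LP[, which.max(qp)],
    igub = rowSums(Qn * LP),
    ci = {
      if (is.null(q_prev2) || is.null(loglik_prev)) {
        stop("ci requires the belief and observation history")
      }
      B <- sweep(LP, 2L, safe_log(q_prev2), "+")
      lQs <- B - row_logsumexp(B)            # log q_skip rows
      f_before <- -sum(qp * loglik_prev) + kl_div(qp, q_prev2)
      f_after <- -drop(Qn %*% loglik_prev) + rowSums(Qn * (lQn - lQs))
      f_before - f_after
    },
    stop("unknown metric: ", metric))
}

# belief-weighted candidate scores over all 256 gazes (NA on retired gazes);
# uses the current RNG state for sampling predictions
candidate_scores <- function(bank, state, metric, predict = "sample") {
  K <- length(bank$classes)
  qp <- as.numeric(state$belief)
  M <- gaze_incidence()
  M[, state$consumed] <- 0
  zset <- if (metric == "iglb_sharp") which.max(qp) else seq_len(K)
  w <- if (metric == "iglb_sharp") 1 else qp
  total <- numeric(.N_GAZES)
  for (zi in seq_along(zset)) {
    X <- predict_table(bank, zset[zi], mode = predict)
    G <- M %*% loglik_table(bank, X)
    total <- total + w[zi] *
      metric_scores_rows(metric, G, qp, as.numeric(state$belief_prev),
                         state$loglik_prev)
  }
  total[!state$live] <- NA_real_
  attr(total, "n_predictions") <- length(zset) * sum(state$live)
  total
}

#' Prediction-based selection of the next saccade
#'
#' For each category `z` and available gaze `u`, predicts the visual field
#' over `u`'s unconsumed triplets (stochastic draw or distribution mode),
#' scores it with the requested metric, and returns the gaze maximising the
#' belief-weighted score, ties broken toward the lowest `(i, j)` in
#' row-major order. `metric = "random"` draws a gaze uniformly from the
#' remaining action set.
#'
#' @param bank a `model_bank`; @param state an [exploration_state()];
#' @param metric one of [metric_ids()];
#' @param predict `"sample"` (stochastic imagination) or `"mode"`;
#' @param seed integer seed, required whenever randomness is involved
#'   (sampling predictions or the random metric).
#' @return gaze `c(i, j)`, with attributes `score` and `n_predictions`.
#' @export
select_action <- function(bank, state, metric = "iglb",
                          predict = c("sample", "mode"), seed = NULL) {
  predict <- match.arg(predict)
  metric <- match.arg(metric, metric_ids())
  if (!any(state$live)) stop("action set exhausted")
  needs_rng <- metric == "random" || predict == "sample"
  if (needs_rng && is.null(seed)) {
    stop("seed is required for stochastic action selection")
  }
  run <- function() {
    if (metric == "random") {
      g <- which(state$live)[sample.int(sum(state$live), 1L)]
      out <- c((g - 1L) %/% 16L, (g - 1L) %% 16L)
      attr(out, "n_predictions") <- 0L
      return(out)
    }
    s <- candidate_scores(bank, state, metric, predict)
    g <- which.max(s)           # first maximum = lowest row-major (i, j)
    out <- c((g - 1L) %/% 16L, (g - 1L) %% 16L)
    attr(out, "score") <- s[g]
    attr(out, "n_predictions") <- attr(s, "n_predictions")
    out
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Sequential scene exploration by saccades
#'
#' Runs the exploration loop: initial belief from the root coefficient, then
#' repeatedly select a gaze (by predictive metric, trajectory table, or at
#' random), read its unconsumed multiscale field, update the belief by
#' Bayes' rule, and retire the consumed coordinates. Stops when the belief
#' entropy falls to `H_ref` (termination `"threshold"`) or no gaze remains
#' (`"exhausted"`).
#'
#' @param pyramid a `wavelet_pyramid` (the scene).
#' @param bank a `model_bank`.
#' @param metric metric driving [select_action()] under the `"metric"`
#'   policy.
#' @param H_ref entropy stopping threshold in nats (> 0).
#' @param policy `"metric"`, `"trajectory"` (guess-specific pre-processed
#'   lists with on-the-fly switching) or `"generic_trajectory"` (the
#'   class-independent list only).
#' @param trajectories a [build_trajectories()] table (trajectory policies).
#' @param predict prediction mode for the metric policy.
#' @param seed integer seed, required when any step is stochastic.
#' @param max_saccades safety cap on the number of saccades.
#' @param use_generic_until_guess under `"trajectory"`, start on the generic
#'   list until the belief commits to a guess (max above
#'   `guess_threshold`).
#' @param guess_threshold belief mass needed to count as a definite guess
#'   (default `2 / K`).
#' @return an object of class `exploration_result`: `predicted`, `saccades`
#'   (n x 2 matrix), `posterior_trace` (length `n_saccades + 1`),
#'   `entropy_trace`, `n_saccades`, `triplets_read`, `coefficients_read`,
#'   `compression` (integer percent, coefficient and triplet conventions),
#'   `terminated_by`, `n_predictions`.
#' @export
explore_scene <- function(pyramid, bank, metric = "iglb", H_ref = 1e-4,
                          policy = c("metric", "trajectory",
                                     "generic_trajectory"),
                          trajectories = NULL,
                          predict = c("sample", "mode"), seed = NULL,
                          max_saccades = 256L,
                          use_generic_until_guess = TRUE,
                          guess_threshold = NULL) {
  policy <- match.arg(policy)
  predict <- match.arg(predict)
  stopifnot(H_ref > 0)
  if (policy != "metric") {
    if (is.null(trajectories)) stop("trajectory policies need a trajectory table")
  }
  needs_rng <- policy == "metric" && (predict == "sample" || metric == "random")
  if (needs_rng && is.null(seed)) stop("seed is required for stochastic exploration")

  state <- exploration_state(pyramid, bank)
  run <- function() {
    trace <- list(state$belief)
    saccades <- matrix(NA_integer_, 0L, 2L)
    terminated <- "threshold"
    while (belief_entropy(state$belief) > H_ref) {
      if (!any(state$live) || state$step >= max_saccades) {
        terminated <- "exhausted"
        break
      }
      gaze <- if (policy == "metric") {
        if (metric == "random") {
          g <- which(state$live)[sample.int(sum(state$live), 1L)]
          c((g - 1L) %/% 16L, (g - 1L) %% 16L)
        } else {
          s <- candidate_scores(bank, state, metric, predict)
          state$n_predictions <- state$n_predictions +
            attr(s, "n_predictions")
          g <- which.max(s)
          c((g - 1L) %/% 16L, (g - 1L) %% 16L)
        }
      } else {
        trajectory_policy_step(trajectories, state,
                               use_generic_until_guess =
                                 (policy == "trajectory" &&
                                    use_generic_until_guess),
                               guess_threshold = guess_threshold,
                               force_generic = policy == "generic_trajectory")
      }
      field <- read_field(pyramid, gaze, consumed = which(state$consumed))
      ll <- field_loglik_vector(field, bank)
      state$belief_prev <- state$belief
      state$loglik_prev <- ll
      state$belief <- belief(softmax_log(ll + safe_log(as.numeric(state$belief))),
                             bank$classes)
      state$consumed[field$viewpoints$vid] <- TRUE
      state$live[gaze[1L] * 16L + gaze[2L] + 1L] <- FALSE
      k <- nrow(field$triplets)
      state$triplets_read <- state$triplets_read + k
      state$coefficients_read <- state$coefficients_read + 3L * k
      state$step <- state$step + 1L
      saccades <- rbind(saccades, gaze)
      trace[[length(trace) + 1L]] <- state$belief
    }
    # computed directly rather than via compression_rates(): an exhausted
    # exploration reads all 341 triplets, overshooting the 256-triplet
    # reference budget (the rate then goes negative under that convention)
    comp <- c(coefficient_rate =
                round_half_up(100 * (1 - state$coefficients_read / 784)),
              triplet_rate =
                round_half_up(100 * (1 - state$triplets_read / 256)))
    structure(list(
      predicted = bank$classes[which.max(state$belief)],
      saccades = unname(saccades),
      posterior_trace = trace,
      entropy_trace = vapply(trace, belief_entropy, numeric(1)),
      n_saccades = state$step,
      triplets_read = state$triplets_read,
      coefficients_read = state$coefficients_read,
      compression = comp,
      compression_exact = c(
        coefficient_rate = 100 * (1 - state$coefficients_read / 784),
        triplet_rate = 100 * (1 - state$triplets_read / 256)),
      terminated_by = terminated,
      n_predictions = state$n_predictions,
      metric = metric, policy = policy, H_ref = H_ref),
      class = "exploration_result")
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' @export
print.exploration_result <- function(x, ...) {
  cat(sprintf(paste0("<exploration_result> predicted %s after %d saccade(s)",
                     " (%s);\n  %d triplets / %d coefficients read;",
                     " compression %d%% (coefficients), %d%% (triplets)\n"),
              x$predicted, x$n_saccades, x$terminated_by, x$triplets_read,
              x$coefficients_read, x$compression[1L], x$compression[2L]))
  invisible(x)
}

# ---- pre-processed action maps and trajectories ----------------------------

#' Pre-process guess-consistent action maps
#'
#' For each category `zhat` and gaze `u`, predicts the full 5-triplet field
#' by the distribution mode and tabulates the log single-view posterior
#' `log p(zhat | mode field, u)` on the 16x16 gaze grid. The generic map
#' averages the per-category maps under a uniform category prior.
#'
#' @param bank a `model_bank`.
#' @return object of class `action_maps`: `classes`, `maps` (list of 16x16
#'   matrices, rows = gaze `i`, columns = gaze `j`), `generic`.
#' @export
precompute_action_maps <- function(bank) {
  K <- length(bank$classes)
  M <- gaze_incidence()
  maps <- lapply(seq_len(K), function(iz) {
    G <- M %*% loglik_table(bank, predict_table(bank, iz, mode = "mode"))
    lp <- (G - row_logsumexp(G))[, iz]
    matrix(lp, 16L, 16L, byrow = TRUE)   # rows = i, cols = j
  })
  names(maps) <- bank$classes
  structure(list(classes = bank$classes, maps = maps,
                 generic = Reduce(`+`, maps) / K),
            class = "action_maps")
}

# order a 16x16 map into a 256 x 2 gaze list (descending value, ties by
# row-major order)
order_map <- function(map) {
  v <- as.vector(t(map))                 # row-major: index = i*16 + j + 1
  ord <- order(-v, seq_along(v))
  cbind(i = (ord - 1L) %/% 16L, j = (ord - 1L) %% 16L)
}

#' Build pre-processed saccade trajectories from action maps
#'
#' Each category's gaze list is its action map sorted by descending value
#' (ties broken row-major); the generic list likewise from the generic map.
#' Every list is a permutation of the 256 gaze points.
#'
#' @param maps an [precompute_action_maps()] result.
#' @return object of class `trajectory_table`: `classes`, `class_lists`
#'   (list of 256 x 2 matrices) and `generic_list`.
#' @export
build_trajectories <- function(maps) {
  stopifnot(inherits(maps, "action_maps"))
  structure(list(classes = maps$classes,
                 class_lists = lapply(maps$maps, order_map),
                 generic_list = order_map(maps$generic)),
            class = "trajectory_table")
}

#' One step of the pre-processed trajectory policy
#'
#' Returns the first not-yet-visited gaze of the current guess's list (or of
#' the generic list while the belief has not committed to a guess). No
#' predictive computation is performed: the readout cost per step is
#' independent of the number of categories and candidate gazes.
#'
#' @param table a [build_trajectories()] table.
#' @param state an [exploration_state()].
#' @param use_generic_until_guess use the generic list while
#'   `max(belief) <= guess_threshold`.
#' @param guess_threshold default `2 / K`.
#' @param force_generic always use the generic list.
#' @return gaze `c(i, j)`.
#' @export
trajectory_policy_step <- function(table, state,
                                   use_generic_until_guess = TRUE,
                                   guess_threshold = NULL,
                                   force_generic = FALSE) {
  stopifnot(inherits(table, "trajectory_table"))
  K <- length(state$belief)
  thr <- guess_threshold %||% (2 / K)
  lst <- if (force_generic ||
             (use_generic_until_guess && max(state$belief) <= thr)) {
    table$generic_list
  } else {
    table$class_lists[[which.max(state$belief)]]
  }
  for (r in seq_len(nrow(lst))) {
    g <- lst[r, 1L] * 16L + lst[r, 2L] + 1L
    if (state$live[g]) return(c(lst[r, 1L], lst[r, 2L]))
  }
  stop("action set exhausted: every gaze of the trajectory has been visited")
}

#' Serialise action maps and trajectories to CSV
#'
#' One row per (class, rank): the gaze visited at that rank of the class's
#' trajectory and its action-map value. The generic map is written under
#' class `"generic"`.
#'
#' @param maps an `action_maps`; @param path output CSV path.
#' @return the written data.frame, invisibly.
#' @export
write_action_maps_csv <- function(maps, path) {
  traj <- build_trajectories(maps)
  rows <- lapply(c(maps$classes, "generic"), function(cl) {
    m <- if (cl == "generic") maps$generic else maps$maps[[cl]]
    lst <- if (cl == "generic") traj$generic_list else traj$class_lists[[cl]]
    data.frame(class = cl, rank = seq_len(nrow(lst)),
               i = lst[, 1L], j = lst[, 2L],
               value = m[cbind(lst[, 1L] + 1L, lst[, 2L] + 1L)])
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Render action maps as PNG heat maps
#'
#' @param maps an `action_maps`; @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_action_maps <- function(maps, path) {
  K <- length(maps$classes)
  grDevices::png(path, width = 160 * (K + 1L), height = 190)
  op <- graphics::par(mfrow = c(1L, K + 1L), mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  pal <- grDevices::hcl.colors(64, "YlOrBr", rev = TRUE)
  for (cl in c(maps$classes, "generic")) {
    m <- if (cl == "generic") maps$generic else maps$maps[[cl]]
    graphics::image(0:16, 0:16, t(m)[, 16:1], col = pal, axes = FALSE,
                    main = cl, xlab = "", ylab = "")
  }
  invisible(path)
}
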