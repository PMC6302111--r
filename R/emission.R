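# Per-(category, viewpoint) generative emission model.
#
# A coefficient triplet x in R^3 observed at viewpoint u under category z is
# modelled as a Bernoulli-gated multivariate Gaussian with parameters
# Theta_{z,u} = (rho, mu, Sigma): with probability 1 - rho the triplet is
# "white" (all three coefficients essentially zero, as happens off-stroke in
# sparse images), otherwise it is a draw from N(mu, Sigma). The gate captures
# the alternating presence/absence of signal in high-frequency and peripheral
# coefficients; white triplets are discarded from the Gaussian moment
# estimates.

.LOG2PI <- log(2 * pi)

#' Fitting configuration for the model bank
#'
#' @param smoothing Laplace smoothing pseudo-count `a` for the presence gate:
#'   `rho = (n_nonwhite + a) / (n + 2a)`.
#' @param epsilon white-triplet threshold: a triplet is white when all three
#'   coefficients have absolute value below `epsilon`. Haar coefficients of
#'   exactly-zero background regions are exactly zero, so a tight threshold
#'   suffices.
#' @param lambda covariance regularisation (diagonal loading `lambda * I`).
#'   `NULL` defaults to `1e-4` times the mean per-pixel variance of the
#'   training images.
#' @param delta underflow guard added inside gate logarithms.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(smoothing = 1, epsilon = 1e-9, lambda = NULL,
                       delta = 1e-12) {
  stopifnot(smoothing >= 0, epsilon > 0, is.null(lambda) || lambda > 0,
            delta > 0)
  structure(list(smoothing = smoothing, epsilon = epsilon, lambda = lambda,
                 delta = delta), class = "fit_config")
}

#' Fit the Bernoulli-gated Gaussian model bank
#'
#' Learns one emission model per (category, viewpoint) over all 341 detail
#' viewpoints, a per-category univariate Gaussian on the root approximation
#' coefficient (used to form the initial belief), and the empirical category
#' prior.
#'
#' @param images list of 28x28 or 32x32 numeric matrices (28x28 inputs are
#'   zero-padded), or a 3D array with items along the third dimension.
#' @param labels vector (coercible to factor) of category labels, one per
#'   image; every category needs at least 2 examples.
#' @param config a [fit_config()].
#' @return an object of class `model_bank` with elements `classes`, `prior`,
#'   `rho` (K x 341), `mu` (K x 341 x 3), `sigma`, `sinv`, `cholL`
#'   (K x 341 x 3 x 3), `logdet` (K x 341), `root_mean`, `root_var` (per
#'   class), and the fitting constants.
#' @export
fit_model_bank <- function(images, labels, config = fit_config()) {
  if (is.array(images) && length(dim(images)) == 3L) {
    images <- lapply(seq_len(dim(images)[3L]), function(k) images[, , k])
  }
  labels <- if (is.factor(labels)) labels else factor(labels)
  classes <- levels(labels)
  K <- length(classes)
  n <- length(images)
  stopifnot(n == length(labels), K >= 1L)
  cnt <- table(labels)
  if (any(cnt < 2L)) {
    stop("category with fewer than 2 examples: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  }

  images <- lapply(images, pad_image)
  pixvar <- mean(apply(vapply(images, as.vector, numeric(1024L)), 1L,
                       stats::var))
  lambda <- config$lambda %||% (1e-4 * max(pixvar, .Machine$double.eps))

  # n x 341 x 3 detail coefficients + root vector
  X <- array(NA_real_, c(n, .N_VIEWPOINTS, 3L))
  root <- numeric(n)
  hashes <- character(n)
  for (k in seq_len(n)) {
    p <- haar_decompose(images[[k]])
    X[k, , ] <- pyramid_detail_matrix(p)
    root[k] <- p$root
    hashes[k] <- image_hash(images[[k]])
  }
  white <- abs(X[, , 1L]) < config$epsilon &
           abs(X[, , 2L]) < config$epsilon &
           abs(X[, , 3L]) < config$epsilon          # n x 341

  rho <- matrix(NA_real_, K, .N_VIEWPOINTS)
  mu <- array(0, c(K, .N_VIEWPOINTS, 3L))
  sigma <- array(0, c(K, .N_VIEWPOINTS, 3L, 3L))
  sinv <- array(0, c(K, .N_VIEWPOINTS, 3L, 3L))
  cholL <- array(0, c(K, .N_VIEWPOINTS, 3L, 3L))
  logdet <- matrix(NA_real_, K, .N_VIEWPOINTS)
  root_mean <- root_var <- numeric(K)

  a <- config$smoothing
  for (z in seq_len(K)) {
    sel <- labels == classes[z]
    nz <- sum(sel)
    Wz <- white[sel, , drop = FALSE]
    nonwhite_cnt <- nz - colSums(Wz)
    rho[z, ] <- (nonwhite_cnt + a) / (nz + 2 * a)
    Xz <- X[sel, , , drop = FALSE]
    for (v in seq_len(.N_VIEWPOINTS)) {
      keep <- !Wz[, v]
      S <- diag(lambda, 3L)
      m <- c(0, 0, 0)
      if (any(keep)) {
        xv <- Xz[keep, v, , drop = TRUE]
        if (is.null(dim(xv))) xv <- matrix(xv, nrow = 1L)
        m <- colMeans(xv)
        if (nrow(xv) >= 2L) S <- stats::cov(xv) + diag(lambda, 3L)
      }
      mu[z, v, ] <- m
      sigma[z, v, , ] <- S
      L <- t(chol(S))
      cholL[z, v, , ] <- L
      sinv[z, v, , ] <- chol2inv(t(L))
      logdet[z, v] <- 2 * sum(log(diag(L)))
    }
    root_mean[z] <- mean(root[sel])
    root_var[z] <- max(stats::var(root[sel]), lambda)
  }

  structure(list(classes = classes,
                 prior = as.numeric(cnt) / n,
                 rho = rho, mu = mu, sigma = sigma, sinv = sinv,
                 cholL = cholL, logdet = logdet,
                 root_mean = root_mean, root_var = root_var,
                 lambda = lambda, epsilon = config$epsilon,
                 delta = config$delta, smoothing = a,
                 n_train = n, train_hashes = hashes),
            class = "model_bank")
}

#' @export
print.model_bank <- function(x, ...) {
  cat(sprintf(paste0("<model_bank> %d categories x %d viewpoints,",
                     " Bernoulli-gated Gaussian emissions (n_train = %d)\n"),
              length(x$classes), ncol(x$rho), x$n_train))
  invisible(x)
}

# order-insensitive content hash of an image (used for train/test overlap
# detection without storing the training set)
image_hash <- function(m) {
  v <- as.vector(m)
  paste(format(c(sum(v), sum(v^2), sum(v * seq_along(v))), digits = 17),
        collapse = "|")
}

# resolve a class label to its index in the bank
class_index <- function(bank, z) {
  if (is.numeric(z) && length(z) == 1L && z >= 1 && z <= length(bank$classes) &&
      z == as.integer(z) && !(as.character(z) %in% bank$classes)) {
    return(as.integer(z))
  }
  iz <- match(as.character(z), bank$classes)
  if (is.na(iz)) stop("unknown class: ", z)
  iz
}

# ---- likelihood ------------------------------------------------------------

#' Log-likelihood of a coefficient triplet under one emission model
#'
#' White triplets (all three coefficients below the white threshold in
#' absolute value) take the gate's closed branch `log(1 - rho + delta)`;
#' others take `log(rho + delta) + log N(x; mu, Sigma)`.
#'
#' @param x numeric vector of length 3.
#' @param params list with `rho`, `mu` (length 3), `sigma` (3x3); e.g. from
#'   [emission_params()].
#' @param epsilon white threshold; @param delta underflow guard.
#' @return scalar log density/mass.
#' @export
triplet_log_likelihood <- function(x, params, epsilon = 1e-9, delta = 1e-12) {
  if (length(x) != 3L || !all(is.finite(x))) {
    stop("triplet must be 3 finite values")
  }
  if (all(abs(x) < epsilon)) return(log(1 - params$rho + delta))
  S <- params$sigma
  d <- x - params$mu
  q <- drop(t(d) %*% solve(S, d))
  log(params$rho + delta) - 0.5 * (q + determinant(S)$modulus[1L] +
                                     3 * .LOG2PI)
}

#' Extract the emission parameters of one (class, viewpoint) cell
#'
#' @param bank a `model_bank`; @param z class label; @param u viewpoint as
#'   `c(i, j, h)` or a `vid` index.
#' @return list with `rho`, `mu`, `sigma`.
#' @export
emission_params <- function(bank, z, u) {
  iz <- class_index(bank, z)
  v <- if (length(u) == 3L) viewpoint_index(u[1L], u[2L], u[3L]) else u
  list(rho = bank$rho[iz, v], mu = bank$mu[iz, v, ],
       sigma = matrix(bank$sigma[iz, v, , ], 3L, 3L))
}

# log-likelihood of every viewpoint-row of X (341 x 3, or subset rows `vids`)
# under class index iz; vectorised over viewpoints
loglik_rows <- function(bank, X, iz, vids = NULL) {
  if (is.null(vids)) vids <- seq_len(nrow(X)) else X <- X[vids, , drop = FALSE]
  white <- abs(X[, 1L]) < bank$epsilon & abs(X[, 2L]) < bank$epsilon &
           abs(X[, 3L]) < bank$epsilon
  d1 <- X[, 1L] - bank$mu[iz, vids, 1L]
  d2 <- X[, 2L] - bank$mu[iz, vids, 2L]
  d3 <- X[, 3L] - bank$mu[iz, vids, 3L]
  Sv <- bank$sinv
  q <- Sv[iz, vids, 1L, 1L] * d1 * d1 + Sv[iz, vids, 2L, 2L] * d2 * d2 +
       Sv[iz, vids, 3L, 3L] * d3 * d3 +
       2 * (Sv[iz, vids, 1L, 2L] * d1 * d2 + Sv[iz, vids, 1L, 3L] * d1 * d3 +
            Sv[iz, vids, 2L, 3L] * d2 * d3)
  out <- log(bank$rho[iz, vids] + bank$delta) -
    0.5 * (q + bank$logdet[iz, vids] + 3 * .LOG2PI)
  out[white] <- log(1 - bank$rho[iz, vids][white] + bank$delta)
  out
}

# 341(or k) x K matrix of per-viewpoint per-class log-likelihoods for a
# coefficient table X
loglik_table <- function(bank, X, vids = NULL) {
  K <- length(bank$classes)
  vapply(seq_len(K), function(iz) loglik_rows(bank, X, iz, vids),
         numeric(if (is.null(vids)) nrow(X) else length(vids)))
}

#' Log-likelihood of a multiscale field under one category
#'
#' Viewpoints are conditionally independent given the category, so the field
#' log-likelihood is the sum of its triplet log-likelihoods; an empty field
#' contributes 0.
#'
#' @param field a `multiscale_field` (or anything [as_readout()] accepts).
#' @param z class label; @param bank a `model_bank`.
#' @return scalar log-likelihood.
#' @export
field_log_likelihood <- function(field, z, bank) {
  iz <- class_index(bank, z)
  r <- as_readout(field)
  if (nrow(r) == 0L) return(0)
  X341 <- matrix(NA_real_, .N_VIEWPOINTS, 3L)
  X341[r$vid, ] <- as.matrix(r[, c("H", "V", "D")])
  sum(loglik_rows(bank, X341, iz, vids = r$vid))
}

# per-class log-likelihood vector of a field (length K)
field_loglik_vector <- function(field, bank) {
  r <- as_readout(field)
  K <- length(bank$classes)
  if (nrow(r) == 0L) return(numeric(K))
  X341 <- matrix(NA_real_, .N_VIEWPOINTS, 3L)
  X341[r$vid, ] <- as.matrix(r[, c("H", "V", "D")])
  ll <- loglik_table(bank, X341, vids = r$vid)
  if (is.matrix(ll)) colSums(ll) else ll
}

# per-class log-likelihood of the root coefficient (length K)
root_loglik_vector <- function(bank, root) {
  -0.5 * ((root - bank$root_mean)^2 / bank$root_var + log(bank$root_var) +
            .LOG2PI)
}

#' Posterior over categories from the complete pyramid (full information)
#'
#' Combines the root coefficient model, all 341 detail triplet likelihoods
#' and the class prior; the reference "no compression" classifier.
#'
#' @param pyramid a `wavelet_pyramid`; @param bank a `model_bank`.
#' @return a `belief`.
#' @export
full_information_posterior <- function(pyramid, bank) {
  X <- pyramid_detail_matrix(pyramid)
  ll <- colSums(loglik_table(bank, X)) + root_loglik_vector(bank, pyramid$root)
  belief(softmax_log(ll + log(bank$prior)), bank$classes)
}

# ---- prediction ------------------------------------------------------------

#' Predict (imagine) a coefficient triplet for a (class, viewpoint) pair
#'
#' In `"sample"` mode the gate is drawn from Bernoulli(rho) and, when open, a
#' triplet from N(mu, Sigma); a seed is mandatory so that predictions are
#' reproducible. In `"mode"` mode the most typical value is returned: `mu`
#' when `rho >= 0.5`, the white triplet `(0, 0, 0)` otherwise (the argmax of
#' a mixed mass/density is ill-posed; this branch rule is the documented
#' convention).
#'
#' @param z class label; @param u viewpoint `c(i, j, h)` or vid;
#' @param bank a `model_bank`;
#' @param mode `"sample"` or `"mode"`; @param seed integer seed, required for
#'   sampling.
#' @return numeric triplet of length 3.
#' @export
predict_view <- function(z, u, bank, mode = c("sample", "mode"), seed = NULL) {
  mode <- match.arg(mode)
  iz <- class_index(bank, z)
  v <- if (length(u) == 3L) viewpoint_index(u[1L], u[2L], u[3L]) else u
  rho <- bank$rho[iz, v]
  if (mode == "mode") {
    return(if (rho >= 0.5) bank$mu[iz, v, ] else c(0, 0, 0))
  }
  if (is.null(seed)) {
    stop("sampling prediction requires an explicit seed (reproducibility contract)")
  }
  withr::with_seed(as.integer(seed), {
    if (stats::runif(1) >= rho) return(c(0, 0, 0))
    L <- matrix(bank$cholL[iz, v, , ], 3L, 3L)
    bank$mu[iz, v, ] + as.vector(L %*% stats::rnorm(3L))
  })
}

# sample (or take the mode of) the full 341-viewpoint prediction table for
# one predicting class; uses the current RNG state in sample mode
predict_table <- function(bank, iz, mode = "sample") {
  mu <- matrix(bank$mu[iz, , ], .N_VIEWPOINTS, 3L)
  if (mode == "mode") {
    open <- bank$rho[iz, ] >= 0.5
    mu[!open, ] <- 0
    return(mu)
  }
  open <- stats::runif(.N_VIEWPOINTS) < bank$rho[iz, ]
  eps <- matrix(stats::rnorm(.N_VIEWPOINTS * 3L), .N_VIEWPOINTS, 3L)
  L <- bank$cholL
  x <- mu
  for (a in 1:3) {
    x[, a] <- mu[, a] + L[iz, , a, 1L] * eps[, 1L] +
      L[iz, , a, 2L] * eps[, 2L] + L[iz, , a, 3L] * eps[, 3L]
  }
  x[!open, ] <- 0
  x
}

# ---- faulty model ----------------------------------------------------------

#' Corrupt a model bank by forcing every presence gate open
#'
#' Sets `rho = 1` for every (category, viewpoint) while leaving means,
#' covariances, root models and the prior untouched. The corrupted model
#' overestimates signal strength in sparse regions, predicting dense signal
#' where the data is typically white -- the controlled model flaw used in the
#' robustness protocol. Idempotent.
#'
#' @param bank a `model_bank`.
#' @return a corrupted copy of the bank.
#' @export
make_faulty <- function(bank) {
  stopifnot(inherits(bank, "model_bank"))
  bank$rho[] <- 1
  bank$faulty <- TRUE
  bank
}
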