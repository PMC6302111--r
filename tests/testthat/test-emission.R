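test_that("fitting validates its inputs and names the offending class", {
  ds <- frozen_pair()
  expect_error(fit_model_bank(ds$images[1:4], factor(rep("a", 4),
                                                     levels = c("a", "b"))),
               "b")
  expect_error(fit_model_bank(ds$images[1:3],
                              factor(c("a", "a", "b"))), "fewer than 2")
})

test_that("the presence gate is Laplace-smoothed on all-white data", {
  ds <- frozen_pair()   # deterministic images, sharp support
  bank <- fit_model_bank(ds$images, ds$labels)
  # a viewpoint far outside the glyph support is white in every example:
  # rho = a / (n + 2a) with a = 1, n = 4
  v <- viewpoint_index(0, 15, 5)
  expect_equal(bank$rho[1, v], 1 / 6)
  expect_equal(bank$rho[2, v], 1 / 6)
})

test_that("identical classes fit identical emission parameters", {
  ds <- frozen_pair()
  imgs <- c(ds$images[ds$labels == "g1"], ds$images[ds$labels == "g1"])
  labels <- factor(rep(c("a", "b"), each = sum(ds$labels == "g1")))
  bank <- fit_model_bank(imgs, labels)
  expect_equal(bank$rho[1, ], bank$rho[2, ])
  expect_equal(bank$mu[1, , ], bank$mu[2, , ])
  expect_equal(bank$sigma[1, , , ], bank$sigma[2, , , ])
  expect_equal(bank$root_mean[1], bank$root_mean[2])
  expect_equal(bank$prior, c(0.5, 0.5))
})

test_that("the gated triplet likelihood follows its branch rule", {
  params <- list(rho = 0.5, mu = c(1, -1, 0.5),
                 sigma = diag(c(0.2, 0.3, 0.1)))
  delta <- 1e-12

  # white observation under a faulty (always-open) gate: bare guard mass
  expect_equal(triplet_log_likelihood(c(0, 0, 0),
                                      list(rho = 1, mu = params$mu,
                                           sigma = params$sigma)),
               log(delta))

  # closed-form Gaussian peak at x = mu
  expect_equal(triplet_log_likelihood(params$mu, params),
               log(0.5 + delta) -
                 0.5 * log((2 * pi)^3 * det(params$sigma)),
               tolerance = 1e-12)

  # the mode of the open branch is mu
  set.seed(2)
  peak <- triplet_log_likelihood(params$mu, params)
  for (k in 1:20) {
    x <- params$mu + rnorm(3, 0, 0.5)
    expect_lt(triplet_log_likelihood(x, params), peak + 1e-12)
  }

  expect_error(triplet_log_likelihood(c(0, Inf, 0), params), "finite")
})

test_that("field log-likelihood sums independent triplets", {
  fx <- small_fixture()
  pyr <- fx$pyramids[[1]]
  empty <- read_field(pyr, c(0, 0), consumed = seq_len(341))
  for (z in fx$bank$classes) {
    expect_identical(field_log_likelihood(empty, z, fx$bank), 0)
  }

  f1 <- read_field(pyr, c(5, 5), consumed = foveate:::gaze_chain(5, 5)[-1])
  expect_equal(nrow(f1$triplets), 1L)
  p <- emission_params(fx$bank, fx$bank$classes[2], f1$viewpoints$vid)
  expect_equal(field_log_likelihood(f1, fx$bank$classes[2], fx$bank),
               triplet_log_likelihood(f1$triplets[1, ], p),
               tolerance = 1e-9)

  f5 <- read_field(pyr, c(5, 5))
  manual <- sum(vapply(seq_len(5), function(k) {
    pk <- emission_params(fx$bank, "g1", f5$viewpoints$vid[k])
    triplet_log_likelihood(f5$triplets[k, ], pk)
  }, numeric(1)))
  expect_equal(field_log_likelihood(f5, "g1", fx$bank), manual,
               tolerance = 1e-9)

  expect_error(field_log_likelihood(f5, "nonexistent", fx$bank), "unknown")
})

test_that("prediction respects the gate and is reproducible", {
  fx <- small_fixture()
  bank <- fx$bank
  u <- c(3, 3, 4)
  v <- viewpoint_index(3, 3, 4)

  b1 <- bank; b1$rho[] <- 1
  expect_equal(predict_view("g1", u, b1, mode = "mode"),
               bank$mu[1, v, ])
  b0 <- bank; b0$rho[] <- 0
  expect_equal(predict_view("g1", u, b0, mode = "mode"), c(0, 0, 0))

  expect_error(predict_view("g1", u, bank, mode = "sample"), "seed")
  s1 <- predict_view("g1", u, bank, mode = "sample", seed = 9)
  s2 <- predict_view("g1", u, bank, mode = "sample", seed = 9)
  expect_identical(s1, s2)

  # binomial concentration of the gate frequency
  bh <- bank; bh$rho[] <- 0.7
  draws <- vapply(1:4000, function(k) {
    any(predict_view("g1", u, bh, mode = "sample", seed = k) != 0)
  }, logical(1))
  expect_equal(mean(draws), 0.7, tolerance = 0.02)
})

test_that("the faulty corruption opens every gate and nothing else", {
  fx <- small_fixture()
  fb <- make_faulty(fx$bank)
  expect_true(all(fb$rho == 1))
  expect_identical(fb$mu, fx$bank$mu)
  expect_identical(fb$sigma, fx$bank$sigma)
  expect_identical(fb$root_mean, fx$bank$root_mean)
  expect_identical(fb$prior, fx$bank$prior)
  expect_identical(make_faulty(fb)$rho, fb$rho)  # idempotent

  # white triplet: guard mass for every class
  white <- c(0, 0, 0)
  for (z in fb$classes) {
    p <- emission_params(fb, z, c(2, 2, 3))
    expect_equal(triplet_log_likelihood(white, p), log(1e-12))
  }

  # non-white triplet: likelihood shifted by -log rho_original
  v <- viewpoint_index(1, 1, 3)
  x <- fx$bank$mu[2, v, ] + 0.05
  base <- triplet_log_likelihood(x, emission_params(fx$bank, "g2", v))
  faulty <- triplet_log_likelihood(x, emission_params(fb, "g2", v))
  expect_equal(faulty - base,
               log(1 + 1e-12) - log(fx$bank$rho[2, v] + 1e-12),
               tolerance = 1e-9)
})

test_that("the gated density integrates to one", {
  # point mass at white plus Gaussian density elsewhere; midpoint quadrature
  # on a grid spanning +/- 6 sd per axis
  for (rho in c(0.3, 0.85)) {
    mu <- c(0.8, -0.5, 0.2)
    sigma <- matrix(c(0.09, 0.02, 0, 0.02, 0.06, 0.01, 0, 0.01, 0.05), 3)
    params <- list(rho = rho, mu = mu, sigma = sigma)
    sd <- sqrt(diag(sigma))
    gr <- lapply(1:3, function(a) seq(mu[a] - 6 * sd[a], mu[a] + 6 * sd[a],
                                      length.out = 35))
    step <- prod(vapply(gr, function(g) g[2] - g[1], numeric(1)))
    pts <- as.matrix(expand.grid(gr))
    d <- sweep(pts, 2, mu)
    si <- solve(sigma)
    q <- rowSums((d %*% si) * d)
    dens <- exp(-0.5 * q) / sqrt((2 * pi)^3 * det(sigma))
    mass <- (1 - rho) + rho * sum(dens) * step
    expect_equal(mass, 1, tolerance = 0.02)
    # and the implementation's branches match the two components
    expect_equal(exp(triplet_log_likelihood(c(0, 0, 0), params)),
                 1 - rho + 1e-12)
  }
})

test_that("held-out classification accuracy grows with the evidence read", {
  # monotone evidence: argmax field likelihood over increasing viewpoint
  # subsets, on a held-out set of >= 500 items
  ds <- generate_glyphs(glyph_spec(n_classes = 4, n_per_class = 400,
                                   seed = 77))
  sp <- split_dataset(ds, 0.65, seed = 8)
  bank <- fit_model_bank(sp$train$images, sp$train$labels)
  test <- sp$test
  expect_gte(length(test$images), 500L)
  pyrs <- lapply(test$images, haar_decompose)
  set.seed(31)
  sizes <- c(15L, 80L, 341L)
  base <- sample.int(341L)   # nested subsets: more triplets = more evidence
  acc <- vapply(sizes, function(s) {
    vids <- sort(base[seq_len(s)])
    hits <- vapply(seq_along(pyrs), function(k) {
      f <- foveate:::field_from_vids(pyrs[[k]], vids)
      ll <- foveate:::field_loglik_vector(f, bank)
      bank$classes[which.max(ll)] == as.character(test$labels[k])
    }, logical(1))
    mean(hits)
  }, numeric(1))
  mc <- 2 * sqrt(0.25 / length(pyrs))
  expect_true(all(diff(acc) >= -mc))
})
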