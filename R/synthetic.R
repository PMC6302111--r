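# Seeded synthetic data.
#
# Two generators support the whole test surface without any external
# download: (i) procedural stroke "glyphs" -- class-conditional sparse 28x28
# images whose off-stroke background is exactly zero, so high-frequency Haar
# triplets are frequently exactly white and the Bernoulli gate is genuinely
# exercised, with class-discriminative structure concentrated near the image
# centre; (ii) tiny finite "toy worlds" (discrete states, actions and
# symbols) small enough for exhaustive enumeration, used as exact oracles
# for the information-gain bound identities. An IDX reader/writer is
# provided for reproduction runs on real handwritten-digit data.

# ---- glyphs ----------------------------------------------------------------

#' Specification of a synthetic glyph dataset
#'
#' @param n_classes number of glyph categories (2..10).
#' @param n_per_class examples per category.
#' @param jitter maximum translation in pixels (continuous, <= 4, keeping
#'   the glyph mass central); also switches on the small rotation and
#'   elastic-warp components of the affine jitter.
#' @param scale_jitter relative scale perturbation (uniform in
#'   `1 +/- scale_jitter`).
#' @param noise_sd standard deviation of the stroke intensity perturbation
#'   (pixel intensity units); the off-stroke background stays exactly 0.
#' @param seed integer seed; the dataset is a deterministic function of the
#'   spec.
#' @return a list of class `glyph_spec`.
#' @export
glyph_spec <- function(n_classes = 10, n_per_class = 1000, jitter = 2,
                       scale_jitter = 0.1, noise_sd = 0.1, seed = 1) {
  if (n_classes < 2 || n_classes > 10) stop("n_classes must be in 2..10")
  if (jitter < 0 || jitter > 4) stop("jitter must be in [0, 4]")
  if (n_per_class < 1 || scale_jitter < 0 || noise_sd < 0) {
    stop("invalid glyph spec")
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 jitter = as.integer(jitter), scale_jitter = scale_jitter,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "glyph_spec")
}

# rasterise a thick segment / ring onto a 28x28 canvas (1-based pixel centres)
stroke_segment <- function(m, r0, c0, r1, c1, w = 1.7) {
  rc <- expand.grid(r = 1:28, c = 1:28)
  dr <- r1 - r0; dc <- c1 - c0
  len2 <- dr^2 + dc^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((rc$r - r0) * dr + (rc$c - c0) * dc) / len2))
  d <- sqrt((rc$r - (r0 + t * dr))^2 + (rc$c - (c0 + t * dc))^2)
  m[d <= w] <- 1
  m
}

stroke_ring <- function(m, cr, cc, radius, w = 1.7) {
  rc <- expand.grid(r = 1:28, c = 1:28)
  d <- abs(sqrt((rc$r - cr)^2 + (rc$c - cc)^2) - radius)
  m[d <= w / 2 + 0.35] <- 1
  m
}

stroke_disc <- function(m, cr, cc, radius) {
  rc <- expand.grid(r = 1:28, c = 1:28)
  m[sqrt((rc$r - cr)^2 + (rc$c - cc)^2) <= radius] <- 1
  m
}

# the seven shared stroke masks (binary 28x28) and the per-digit on-sets of
# the stylised seven-segment alphabet
glyph_segments <- function() {
  z <- matrix(0, 28, 28)
  masks <- list(
    t  = stroke_segment(z, 6, 9.5, 6, 18.5),
    tl = stroke_segment(z, 6, 9, 14.5, 9),
    tr = stroke_segment(z, 6, 19, 14.5, 19),
    m  = stroke_segment(z, 14.5, 9.5, 14.5, 18.5),
    bl = stroke_segment(z, 14.5, 9, 23, 9),
    br = stroke_segment(z, 14.5, 19, 23, 19),
    b  = stroke_segment(z, 23, 9.5, 23, 18.5))
  digits <- list(
    c("t", "tl", "tr", "bl", "br", "b"),            # 0
    c("tr", "br"),                                  # 1
    c("t", "tr", "m", "bl", "b"),                   # 2
    c("t", "tr", "m", "br", "b"),                   # 3
    c("tl", "tr", "m", "br"),                       # 4
    c("t", "tl", "m", "br", "b"),                   # 5
    c("t", "tl", "m", "bl", "br", "b"),             # 6
    c("t", "tr", "br"),                             # 7
    c("t", "tl", "tr", "m", "bl", "br", "b"),       # 8
    c("t", "tl", "tr", "m", "br", "b"))             # 9
  list(masks = masks, digits = digits)
}

# ten procedural stroke templates (binary 28x28, centred mass): stylised
# seven-segment digits. All categories share the same bounding box and the
# same local stroke appearance, so coarse-scale statistics and present-ink
# statistics are similar across categories (as in handwritten digits); the
# discriminative information sits in which medium-scale segments are
# present -- precisely the presence/absence structure the Bernoulli gate is
# meant to capture.
glyph_templates <- function(n_classes = 10) {
  sg <- glyph_segments()
  lapply(sg$digits[seq_len(n_classes)], function(on) {
    Reduce(pmax, sg$masks[on])
  })
}

# bilinear sample of a 28x28 canvas at real-valued source coordinates;
# out-of-range and all-zero neighbourhoods yield exactly 0
bilinear_sample <- function(m, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  at <- function(rr, cc) {
    ok <- rr >= 1 & rr <= 28 & cc >= 1 & cc <= 28
    v <- numeric(length(rr))
    v[ok] <- m[cbind(rr[ok], cc[ok])]
    v
  }
  at(r0, c0) * (1 - fr) * (1 - fc) + at(r0, c0 + 1L) * (1 - fr) * fc +
    at(r0 + 1L, c0) * fr * (1 - fc) + at(r0 + 1L, c0 + 1L) * fr * fc
}

#' Generate a seeded synthetic glyph dataset
#'
#' Each category is a distinct procedural stroke template rendered at 28x28
#' and affine-jittered the way handwritten glyphs vary: continuous
#' translation (up to `jitter` pixels), relative scaling
#' (`1 +/- scale_jitter`) and a small rotation, resampled bilinearly so the
#' within-class coefficient statistics are smooth while the off-stroke
#' background stays exactly zero. Stroke intensity is perturbed per image
#' (contrast) and per pixel by Gaussian noise of sd `noise_sd` and clamped
#' to `[0, 1]`; with `jitter = 0`, `scale_jitter = 0` and `noise_sd = 0`
#' every image of a class is identical. Images are zero-padded to the 32x32
#' working grid.
#'
#' @param spec a [glyph_spec()].
#' @return list with `images` (list of 32x32 matrices, values in `[0, 1]`),
#'   `labels` (factor `g1 ... gK`) and `spec`.
#' @export
generate_glyphs <- function(spec = glyph_spec()) {
  stopifnot(inherits(spec, "glyph_spec"))
  n <- spec$n_classes * spec$n_per_class
  labels <- factor(rep(paste0("g", seq_len(spec$n_classes)),
                       each = spec$n_per_class))
  rc <- expand.grid(r = 1:28, c = 1:28)
  tpl <- glyph_templates(spec$n_classes)
  # stroke-shape variability accompanying the translation jitter: a small
  # rotation plus a smooth elastic warp of the canvas, emulating the local
  # stroke deformations of handwriting (without them, within-class
  # coefficient variance is unrealistically tiny and every read is nearly
  # decisive). Both are disabled together with the translation jitter so a
  # zero-jitter, zero-noise spec renders every image of a class identically.
  max_rot <- if (spec$jitter > 0) 0.15 else 0   # radians
  warp_amp <- if (spec$jitter > 0) 0.8 else 0   # pixels
  images <- withr::with_seed(spec$seed, {
    lapply(seq_len(n), function(k) {
      t0 <- tpl[[as.integer(labels[k])]]
      s <- 1 + stats::runif(1, -spec$scale_jitter, spec$scale_jitter)
      th <- stats::runif(1, -max_rot, max_rot)
      dr <- stats::runif(1, -spec$jitter, spec$jitter)
      dc <- stats::runif(1, -spec$jitter, spec$jitter)
      ph <- stats::runif(4, 0, 2 * pi)
      amp <- warp_amp * stats::runif(2, 0.3, 1)
      wr <- amp[1L] * sin(2 * pi * rc$r / 14 + ph[1L]) *
        cos(2 * pi * rc$c / 17 + ph[2L])
      wc <- amp[2L] * sin(2 * pi * rc$c / 14 + ph[3L]) *
        cos(2 * pi * rc$r / 17 + ph[4L])
      yr <- rc$r - 14.5 - dr + wr; yc <- rc$c - 14.5 - dc + wc
      src_r <- (cos(th) * yr + sin(th) * yc) / s + 14.5
      src_c <- (-sin(th) * yr + cos(th) * yc) / s + 14.5
      img <- matrix(bilinear_sample(t0, src_r, src_c), 28, 28)
      on <- img > 0
      contrast <- 1 + stats::rnorm(1, 0, 2 * spec$noise_sd)
      img[on] <- pmin(1, pmax(0, img[on] * (contrast +
                                stats::rnorm(sum(on), 0, spec$noise_sd))))
      if (spec$noise_sd > 0) {
        # rare stray ink: mostly splatter near the glyph's own strokes
        # (so its spatial statistics are category-dependent, as around real
        # handwriting), plus occasional uniform dust. Most off-stroke
        # coefficients stay exactly white, but presence alternates.
        support <- which(img > 0.05, arr.ind = TRUE)
        for (sp_ in seq_len(stats::rpois(1, 6))) {
          if (nrow(support) > 0 && stats::runif(1) < 0.7) {
            src <- support[sample.int(nrow(support), 1L), ]
            r0 <- src[1L] + round(stats::rnorm(1, 0, 3))
            c0 <- src[2L] + round(stats::rnorm(1, 0, 3))
          } else {
            r0 <- sample.int(27L, 1L); c0 <- sample.int(27L, 1L)
          }
          if (r0 < 1 || r0 > 27 || c0 < 1 || c0 > 27) next
          img[r0:(r0 + 1L), c0:(c0 + 1L)] <-
            pmax(img[r0:(r0 + 1L), c0:(c0 + 1L)],
                 stats::runif(4, 0.05, 0.45) * (stats::runif(4) < 0.6))
        }
      }
      pad_image(img)
    })
  })
  list(images = images, labels = labels, spec = spec)
}

#' Deterministic train/test split of a dataset
#'
#' @param dataset list with `images` and `labels` (e.g. from
#'   [generate_glyphs()]).
#' @param train_frac fraction assigned to the training split.
#' @param seed integer seed for the permutation.
#' @return list with `train` and `test`, each a list of `images`, `labels`.
#' @export
split_dataset <- function(dataset, train_frac = 0.8, seed = 1) {
  n <- length(dataset$images)
  idx <- withr::with_seed(as.integer(seed), sample.int(n))
  ntr <- floor(train_frac * n)
  tr <- sort(idx[seq_len(ntr)]); te <- sort(idx[-seq_len(ntr)])
  list(train = list(images = dataset$images[tr],
                    labels = droplevels(dataset$labels[tr])),
       test = list(images = dataset$images[te],
                   labels = droplevels(dataset$labels[te])))
}

# ---- toy worlds ------------------------------------------------------------

#' Specification of a finite toy world
#'
#' @param n_states number of latent states (<= 5).
#' @param n_actions number of actions/viewpoints (<= 6).
#' @param n_symbols number of observable symbols (<= 8).
#' @param concentration symmetric Dirichlet parameter for the emission
#'   tables (large values approach uniform emissions).
#' @param seed integer seed.
#' @return a list of class `toy_spec`.
#' @export
toy_spec <- function(n_states = 3, n_actions = 4, n_symbols = 5,
                     concentration = 1, seed = 1) {
  stopifnot(n_states >= 2, n_states <= 5, n_actions >= 1, n_actions <= 6,
            n_symbols >= 2, n_symbols <= 8, concentration > 0)
  structure(list(n_states = as.integer(n_states),
                 n_actions = as.integer(n_actions),
                 n_symbols = as.integer(n_symbols),
                 concentration = concentration, seed = as.integer(seed)),
            class = "toy_spec")
}

#' Generate a finite toy world for exact-oracle testing
#'
#' Draws one emission distribution `p(x | z, u)` per (state, action) from a
#' symmetric Dirichlet; the prior over states is uniform. All quantities of
#' the sequential inference and action-selection machinery can be enumerated
#' exactly in such a world.
#'
#' @param spec a [toy_spec()].
#' @return list of class `toy_world` with `prior` (length Z) and `emission`
#'   (array Z x X x U; each `emission[z, , u]` sums to 1).
#' @export
generate_toy_world <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  em <- withr::with_seed(spec$seed, {
    a <- array(0, c(spec$n_states, spec$n_symbols, spec$n_actions))
    for (u in seq_len(spec$n_actions)) for (z in seq_len(spec$n_states)) {
      a[z, , u] <- rdirichlet1(spec$n_symbols, spec$concentration)
    }
    a
  })
  structure(list(prior = rep(1 / spec$n_states, spec$n_states),
                 emission = em, spec = spec),
            class = "toy_world")
}

#' Build a scoring context from a toy-world transition
#'
#' @param world a `toy_world`.
#' @param q_prev2 belief two steps back.
#' @param x_prev,u_prev previous observed symbol and action.
#' @param x,u candidate symbol and action.
#' @return a [metric_context()] with `q_prev` the Bayes update of `q_prev2`
#'   by the previous observation.
#' @export
toy_context <- function(world, q_prev2, x_prev, u_prev, x, u) {
  lpv <- log(world$emission[, x_prev, u_prev])
  q_prev <- softmax_log(lpv + log(as.numeric(q_prev2)))
  metric_context(log(world$emission[, x, u]), q_prev, q_prev2 = q_prev2,
                 loglik_prev = lpv)
}

#' Exact expected metric score of an action in a toy world
#'
#' Enumerates `E_{z ~ q_prev, x ~ p(X|z,u)}[score]` exactly.
#'
#' @param world a `toy_world`; @param q_prev current belief; @param u action
#'   index; @param metric a [metric_ids()] entry (not `"random"`);
#' @param q_prev2,x_prev,u_prev history (needed by `ci`).
#' @return scalar expected score.
#' @export
toy_expected_score <- function(world, q_prev, u, metric, q_prev2 = NULL,
                               x_prev = NULL, u_prev = NULL) {
  stopifnot(metric != "random")
  q_prev <- as.numeric(q_prev)
  px_u <- as.numeric(q_prev %*% world$emission[, , u])  # p(x | u; q_prev)
  lpv <- if (!is.null(x_prev)) log(world$emission[, x_prev, u_prev]) else NULL
  s <- vapply(seq_along(px_u), function(x) {
    ctx <- metric_context(log(world$emission[, x, u]), q_prev,
                          q_prev2 = q_prev2, loglik_prev = lpv)
    score_candidate(metric, ctx)
  }, numeric(1))
  sum(px_u * s)
}

#' Exact prediction-based action selection in a toy world
#'
#' Selects `argmax_u` of the exact expected metric score, ties broken toward
#' the lowest action index.
#'
#' @inheritParams toy_expected_score
#' @param actions candidate action indices (the dynamic action set).
#' @return the selected action index.
#' @export
toy_select_action <- function(world, q_prev, metric,
                              actions = seq_len(dim(world$emission)[3]),
                              q_prev2 = NULL, x_prev = NULL, u_prev = NULL) {
  s <- vapply(actions, function(u) {
    toy_expected_score(world, q_prev, u, metric, q_prev2, x_prev, u_prev)
  }, numeric(1))
  actions[which.max(s)]
}

# ---- IDX container ---------------------------------------------------------

#' Read an IDX (handwritten-digit container) file
#'
#' Supports the standard big-endian unsigned-byte IDX format: 3-dimensional
#' files are read as image batches (pixel values rescaled to `[0, 1]`),
#' 1-dimensional files as label vectors.
#'
#' @param path file path.
#' @return for images, a list of `rows x cols` matrices; for labels, an
#'   integer vector.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 4L, size = 1L, signed = FALSE)
  if (length(magic) < 4L || magic[1L] != 0L || magic[2L] != 0L) {
    stop("bad IDX magic number at byte offset 0")
  }
  if (magic[3L] != 0x08) {
    stop("unsupported IDX data type 0x", sprintf("%02x", magic[3L]),
         " at byte offset 2 (expected 0x08, unsigned byte)")
  }
  ndim <- magic[4L]
  if (!ndim %in% c(1L, 3L)) {
    stop("unsupported IDX dimensionality ", ndim, " at byte offset 3")
  }
  dims <- readBin(con, "integer", ndim, size = 4L, endian = "big")
  if (length(dims) < ndim) stop("truncated IDX header at byte offset 4")
  n_expect <- prod(dims)
  data <- readBin(con, "integer", n_expect, size = 1L, signed = FALSE)
  if (length(data) < n_expect) {
    stop("truncated IDX payload at byte offset ",
         4L + 4L * ndim + length(data), " (expected ", n_expect, " bytes)")
  }
  if (ndim == 1L) return(as.integer(data))
  n <- dims[1L]
  if (n == 0L) return(list())
  per <- dims[2L] * dims[3L]
  lapply(seq_len(n), function(k) {
    matrix(data[(k - 1L) * per + seq_len(per)] / 255,
           dims[2L], dims[3L], byrow = TRUE)
  })
}

#' Write an IDX file (round-trip companion of [read_idx()])
#'
#' @param x list of equal-sized matrices with values in `[0, 1]` (images) or
#'   an integer vector (labels).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.list(x)) {
    d <- if (length(x)) dim(x[[1L]]) else c(28L, 28L)
    writeBin(as.raw(c(0L, 0L, 0x08, 3L)), con)
    writeBin(as.integer(c(length(x), d)), con, size = 4L, endian = "big")
    for (m in x) {
      writeBin(as.raw(round(as.vector(t(m)) * 255)), con)
    }
  } else {
    writeBin(as.raw(c(0L, 0L, 0x08, 1L)), con)
    writeBin(length(x), con, size = 4L, endian = "big")
    writeBin(as.raw(as.integer(x)), con)
  }
  invisible(path)
}
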