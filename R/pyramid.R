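# Foveated pyramidal image codec.
#
# A 32x32 image is decomposed into a five-level orthonormal 2D Haar pyramid:
# one root approximation coefficient plus, at each scale h in 1..5, a
# 2^(h-1) x 2^(h-1) grid of oriented detail triplets (horizontal, vertical,
# oblique), i.e. 3 * (1 + 4 + 16 + 64 + 256) = 1023 detail coefficients and
# 1024 coefficients in total. A gaze orientation (i, j) in {0..15}^2 commands
# a foveated readout of 5 triplets: the finest triplet at (i, j, 5) and its
# ancestors (floor(i/2), floor(j/2), 4), ..., (0, 0, 1) -- full resolution at
# the centre of sight, coarser towards the periphery.

# ---- viewpoint geometry ----------------------------------------------------

.level_sizes <- 2L^(0:4)                       # side length at h = 1..5
.level_offsets <- c(0L, cumsum(.level_sizes^2))  # vid offsets per level
.N_VIEWPOINTS <- 341L
.N_GAZES <- 256L

#' Enumerate all detail viewpoints of the pyramid
#'
#' A viewpoint is a coordinate `(i, j, h)` with `h` the scale level (`h = 5`
#' is the finest, 16x16 positions; `h = 1` the coarsest, a single position)
#' and `i, j` 0-based row/column indices in `{0, ..., 2^(h-1)-1}`. There are
#' 341 distinct detail viewpoints, each carrying one oriented coefficient
#' triplet.
#'
#' @return a data.frame with columns `vid` (1-based linear index), `i`, `j`,
#'   `h`, in linear-index order (levels 1..5, row-major within a level).
#' @export
all_viewpoints <- function() {
  out <- do.call(rbind, lapply(1:5, function(h) {
    n <- .level_sizes[h]
    expand.grid(j = 0:(n - 1L), i = 0:(n - 1L))[, c("i", "j")]
  }))
  data.frame(vid = seq_len(nrow(out)), i = out$i, j = out$j,
             h = rep(1:5, times = .level_sizes^2))
}

#' Linear index of a viewpoint
#'
#' @param i,j 0-based coordinates at level `h`.
#' @param h scale level in 1..5.
#' @return integer index in 1..341 (vectorised).
#' @export
viewpoint_index <- function(i, j, h) {
  n <- .level_sizes[h]
  stopifnot(all(h %in% 1:5), all(i >= 0), all(j >= 0), all(i < n), all(j < n))
  .level_offsets[h] + i * n + j + 1L
}

# the chain of Eq.-36-style viewpoint indices commanded by gaze (i, j)
gaze_chain <- function(i, j) {
  h <- 5:1
  viewpoint_index(i %/% 2L^(5L - h), j %/% 2L^(5L - h), h)
}

# 256 x 341 incidence matrix: row g (gaze, row-major i*16+j+1) marks the 5
# viewpoints in that gaze's readout chain
.gaze_incidence_build <- function() {
  M <- matrix(0, .N_GAZES, .N_VIEWPOINTS)
  for (i in 0:15) for (j in 0:15) {
    M[i * 16L + j + 1L, gaze_chain(i, j)] <- 1
  }
  M
}

# package-local cache (incidence matrix is built on first use)
.pkg <- new.env(parent = emptyenv())

gaze_incidence <- function() {
  if (is.null(.pkg$M)) .pkg$M <- .gaze_incidence_build()
  .pkg$M
}

# ---- padding ---------------------------------------------------------------

#' Pad a 28x28 image to the 32x32 working grid
#'
#' The image is centred with a 2-pixel zero border on every side, keeping the
#' glyph mass in the central part of the grid. A 32x32 input passes through
#' unchanged.
#'
#' @param raw numeric matrix, 28x28 or 32x32, finite values.
#' @return 32x32 numeric matrix.
#' @export
pad_image <- function(raw) {
  if (!is.matrix(raw) || !is.numeric(raw) || !all(is.finite(raw))) {
    stop("image must be a finite numeric matrix")
  }
  if (all(dim(raw) == c(32L, 32L))) return(raw)
  if (!all(dim(raw) == c(28L, 28L))) {
    stop("image must be 28x28 (padded to 32x32) or already 32x32, got ",
         paste(dim(raw), collapse = "x"))
  }
  out <- matrix(0, 32L, 32L)
  out[3:30, 3:30] <- raw
  out
}

# ---- analysis / synthesis --------------------------------------------------

#' Five-level orthonormal Haar decomposition of a 32x32 image
#'
#' Uses the energy-preserving (orthonormal) normalisation, so the sum of
#' squared coefficients equals the sum of squared pixels and Gaussian
#' statistics are comparable across scales. A constant image `c` yields all
#' detail triplets exactly zero and a root coefficient `32 * c`.
#'
#' @param image 32x32 numeric matrix (use [pad_image()] for 28x28 inputs).
#' @return an object of class `wavelet_pyramid`: a list with `root` (scalar
#'   approximation coefficient) and `details`, a list indexed by level
#'   `h = 1..5` of lists with `H`, `V`, `D` matrices (horizontal, vertical,
#'   oblique detail).
#' @export
haar_decompose <- function(image) {
  image <- pad_image(image)
  a <- image
  details <- vector("list", 5L)
  for (h in 5:1) {
    n <- .level_sizes[h]
    o <- seq(1L, 2L * n, by = 2L)
    A <- a[o, o, drop = FALSE];      B <- a[o, o + 1L, drop = FALSE]
    C <- a[o + 1L, o, drop = FALSE]; D <- a[o + 1L, o + 1L, drop = FALSE]
    details[[h]] <- list(H = (A - B + C - D) / 2,
                         V = (A + B - C - D) / 2,
                         D = (A - B - C + D) / 2)
    a <- (A + B + C + D) / 2
  }
  structure(list(root = a[1L, 1L], details = details),
            class = "wavelet_pyramid")
}

#' Inverse Haar transform of a (possibly partial) pyramid
#'
#' @param pyramid a `wavelet_pyramid`.
#' @return 32x32 numeric matrix.
#' @export
haar_reconstruct <- function(pyramid) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"))
  a <- matrix(pyramid$root, 1L, 1L)
  for (h in 1:5) {
    n <- .level_sizes[h]
    H <- pyramid$details[[h]]$H
    V <- pyramid$details[[h]]$V
    D <- pyramid$details[[h]]$D
    out <- matrix(0, 2L * n, 2L * n)
    o <- seq(1L, 2L * n, by = 2L)
    out[o, o]           <- (a + H + V + D) / 2
    out[o, o + 1L]      <- (a - H + V - D) / 2
    out[o + 1L, o]      <- (a + H - V - D) / 2
    out[o + 1L, o + 1L] <- (a - H - V + D) / 2
    a <- out
  }
  a
}

#' Flatten a pyramid to the documented 1024-coefficient serialisation order
#'
#' Order: root first, then levels `h = 1..5`, row-major within a level, each
#' viewpoint contributing its triplet in (H, V, D) order.
#'
#' @param pyramid a `wavelet_pyramid`.
#' @return numeric vector of length 1024.
#' @export
pyramid_flatten <- function(pyramid) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"))
  out <- numeric(1L + 3L * .N_VIEWPOINTS)
  out[1L] <- pyramid$root
  for (h in 1:5) {
    d <- pyramid$details[[h]]
    # row-major over (i, j): transpose since R matrices are column-major
    tri <- rbind(as.vector(t(d$H)), as.vector(t(d$V)), as.vector(t(d$D)))
    idx <- .level_offsets[h] + seq_len(.level_sizes[h]^2)
    out[1L + rep((idx - 1L) * 3L, each = 3L) + 1:3] <- as.vector(tri)
  }
  out
}

#' Rebuild a pyramid from its flat serialisation
#'
#' @param coef numeric vector of length 1024 in [pyramid_flatten()] order.
#' @return a `wavelet_pyramid`.
#' @export
pyramid_unflatten <- function(coef) {
  stopifnot(is.numeric(coef), length(coef) == 1024L)
  details <- vector("list", 5L)
  for (h in 1:5) {
    n <- .level_sizes[h]
    idx <- .level_offsets[h] + seq_len(n^2)
    tri <- matrix(coef[1L + rep((idx - 1L) * 3L, each = 3L) + 1:3], nrow = 3L)
    details[[h]] <- list(H = matrix(tri[1L, ], n, n, byrow = TRUE),
                         V = matrix(tri[2L, ], n, n, byrow = TRUE),
                         D = matrix(tri[3L, ], n, n, byrow = TRUE))
  }
  structure(list(root = coef[1L], details = details),
            class = "wavelet_pyramid")
}

# 341 x 3 matrix of detail triplets (row = vid) for fast vectorised access
pyramid_detail_matrix <- function(pyramid) {
  flat <- pyramid_flatten(pyramid)
  matrix(flat[-1L], ncol = 3L, byrow = TRUE)
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat("<wavelet_pyramid> 5-level orthonormal Haar, 1024 coefficients",
      sprintf("(root = %.4g)\n", x$root))
  invisible(x)
}

# ---- foveated readout ------------------------------------------------------

#' Read the multiscale visual field at a gaze orientation
#'
#' Returns the chain of up-to-5 coefficient triplets commanded by the gaze:
#' `(i, j, 5), (floor(i/2), floor(j/2), 4), ..., (0, 0, 1)`, excluding
#' viewpoints already consumed by previous fixations (inhibition of return at
#' the coefficient level). With an empty consumed set the field carries
#' exactly 15 coefficients.
#'
#' @param pyramid a `wavelet_pyramid`.
#' @param gaze integer vector `c(i, j)` with `i, j` in 0..15.
#' @param consumed integer vector of already-read viewpoint indices (`vid`,
#'   see [all_viewpoints()]), possibly empty.
#' @return an object of class `multiscale_field`: list with `gaze`,
#'   `viewpoints` (data.frame `vid, i, j, h`, level-descending) and
#'   `triplets` (k x 3 matrix, columns H, V, D).
#' @export
read_field <- function(pyramid, gaze, consumed = integer(0)) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"))
  if (length(gaze) != 2L || any(gaze < 0) || any(gaze > 15)) {
    stop("gaze must be c(i, j) with i, j in [0, 15]")
  }
  vids <- gaze_chain(gaze[1L], gaze[2L])
  vids <- vids[!(vids %in% consumed)]
  field_from_vids(pyramid, vids, gaze = gaze)
}

# build a multiscale_field-like readout from an arbitrary viewpoint set
field_from_vids <- function(pyramid, vids, gaze = c(NA_integer_, NA_integer_)) {
  vp <- all_viewpoints()[vids, , drop = FALSE]
  det <- pyramid_detail_matrix(pyramid)[vids, , drop = FALSE]
  colnames(det) <- c("H", "V", "D")
  structure(list(gaze = gaze, viewpoints = vp, triplets = det),
            class = "multiscale_field")
}

#' @export
print.multiscale_field <- function(x, ...) {
  cat(sprintf("<multiscale_field> gaze (%s, %s): %d triplet(s), %d coefficients\n",
              x$gaze[1L], x$gaze[2L], nrow(x$triplets), 3L * nrow(x$triplets)))
  invisible(x)
}

# ---- partial reconstruction ------------------------------------------------

#' Reconstruct an image from a partial coefficient readout
#'
#' Unread coefficients are set to zero before the inverse transform, which is
#' linear: the reconstruction from a union of disjoint readouts is the sum of
#' the individual reconstructions (with the root counted once).
#'
#' @param read a `multiscale_field`, a list of them, or a data.frame with
#'   columns `vid`, `H`, `V`, `D`. Duplicate viewpoints are an error.
#' @param root root approximation coefficient, or `NULL` when unread.
#' @return 32x32 numeric matrix.
#' @export
reconstruct_partial <- function(read, root = NULL) {
  read <- as_readout(read)
  if (anyDuplicated(read$vid)) {
    stop("duplicate viewpoint in readout: vid ",
         paste(unique(read$vid[duplicated(read$vid)]), collapse = ", "))
  }
  coef <- numeric(1024L)
  coef[1L] <- root %||% 0
  if (nrow(read) > 0L) {
    pos <- 1L + rep((read$vid - 1L) * 3L, each = 3L) + 1:3
    coef[pos] <- as.vector(rbind(read$H, read$V, read$D))
  }
  haar_reconstruct(pyramid_unflatten(coef))
}

# coerce field(s) to a data.frame(vid, H, V, D)
as_readout <- function(read) {
  if (inherits(read, "multiscale_field")) read <- list(read)
  if (is.data.frame(read)) {
    stopifnot(all(c("vid", "H", "V", "D") %in% names(read)))
    return(read)
  }
  stopifnot(is.list(read))
  if (length(read) == 0L) {
    return(data.frame(vid = integer(0), H = numeric(0), V = numeric(0),
                      D = numeric(0)))
  }
  do.call(rbind, lapply(read, function(f) {
    stopifnot(inherits(f, "multiscale_field"))
    data.frame(vid = f$viewpoints$vid, H = f$triplets[, 1L],
               V = f$triplets[, 2L], D = f$triplets[, 3L])
  }))
}

# ---- compression accounting ------------------------------------------------

#' Decoding compression rates
#'
#' Two bookkeeping conventions are reported side by side: the coefficient
#' rate references the 784 pixels of the original (pre-padding) image, the
#' triplet rate references the 256-triplet gaze budget (one finest-scale
#' triplet per gaze orientation). For example, reading the 60 coefficients of
#' the four central gaze fields gives a 92% coefficient compression, and
#' reading 25 of 256 triplets gives a 90% triplet compression. Percentages
#' are rounded half-up to integers.
#'
#' @param n_coefficients number of wavelet coefficients read (>= 0).
#' @param n_triplets number of coefficient triplets read (0..256).
#' @return named numeric vector `c(coefficient_rate, triplet_rate)` in
#'   integer percent.
#' @export
compression_rates <- function(n_coefficients, n_triplets) {
  if (n_coefficients < 0 || n_triplets < 0 || n_triplets > 256) {
    stop("counts out of range: n_coefficients >= 0, n_triplets in [0, 256]")
  }
  c(coefficient_rate = round_half_up(100 * (1 - n_coefficients / 784)),
    triplet_rate     = round_half_up(100 * (1 - n_triplets / 256)))
}

# ---- image file input ------------------------------------------------------

#' Read a grayscale image file (PNG or PGM)
#'
#' Accepts 28x28 or 32x32 grayscale images; colour PNGs are averaged to
#' grayscale. PGM supports both the ASCII (P2) and binary (P5) variants.
#'
#' @param path file path ending in `.png` or `.pgm`.
#' @return 32x32 numeric matrix in `[0, 1]` (28x28 inputs are padded).
#' @export
read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package")
    }
    a <- png::readPNG(path)
    m <- if (length(dim(a)) == 3L) apply(a[, , 1:3, drop = FALSE], c(1, 2),
                                         mean) else a
  } else if (ext == "pgm") {
    m <- read_pgm(path)
  } else {
    stop("unsupported image format: .", ext)
  }
  pad_image(m)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens (magic, width, height, maxval), '#' comments allowed
  tokens <- character(0)
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      next
    } else {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  magic <- tokens[1L]
  w <- as.integer(tokens[2L]); h <- as.integer(tokens[3L])
  maxval <- as.integer(tokens[4L])
  if (!magic %in% c("P2", "P5") || anyNA(c(w, h, maxval))) {
    stop("not a PGM file: ", path)
  }
  vals <- if (magic == "P5") {
    readBin(con, "integer", w * h, size = 1L, signed = FALSE)
  } else {
    scan(con, integer(), n = w * h, quiet = TRUE)
  }
  if (length(vals) < w * h) stop("truncated PGM payload")
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale matrix as an ASCII PGM file
#'
#' @param m numeric matrix in `[0, 1]`; @param path destination.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  write(t(round(m * 255)), con, ncolumns = ncol(m))
  invisible(path)
}
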