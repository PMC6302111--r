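# Shared fixtures, built once per test file and memoised. The small
# fixture (4 categories, 60 examples each) keeps unit tests fast; policy
# and calibration tests at the full default study conditions live in
# test-acceptance.R.

small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_glyphs(glyph_spec(n_classes = 4, n_per_class = 60,
                                       seed = 42))
      sp <- split_dataset(ds, 0.8, seed = 7)
      bank <- fit_model_bank(sp$train$images, sp$train$labels)
      cache <<- list(
        split = sp, bank = bank,
        pyramids = lapply(sp$test$images, haar_decompose),
        truth = as.character(sp$test$labels))
    }
    cache
  }
})

# a frozen deterministic two-class dataset (no jitter/noise): every image of
# a class is identical, handy for exact symmetry checks
frozen_pair <- function() {
  generate_glyphs(glyph_spec(n_classes = 2, n_per_class = 4, jitter = 0,
                             scale_jitter = 0, noise_sd = 0, seed = 3))
}

# random transition context in a toy world (uses the current RNG state)
random_toy_context <- function(world) {
  ns <- world$spec$n_states
  q2 <- stats::rgamma(ns, 1); q2 <- q2 / sum(q2)
  nu <- world$spec$n_actions; nx <- world$spec$n_symbols
  toy_context(world, q2,
              x_prev = sample.int(nx, 1), u_prev = sample.int(nu, 1),
              x = sample.int(nx, 1), u = sample.int(nu, 1))
}
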