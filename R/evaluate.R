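# Experiment runner: recognition accuracy vs. decoding compression across
# action-selection metrics, stopping thresholds, policies and model
# variants, on a held-out dataset disjoint from the training split.

#' Experiment configuration
#'
#' @param metrics character vector of [metric_ids()] entries (used with the
#'   `"metric"`/`"sharp"` policies).
#' @param h_refs entropy stopping thresholds in nats.
#' @param variant `"baseline"` or `"faulty"` (all presence gates forced
#'   open).
#' @param policies subset of `"smooth"` (predictive metric policy),
#'   `"sharp"` (single-guess IGLB), `"trajectories"`, `"generic_trajectory"`,
#'   `"random"`.
#' @param predict prediction mode for the predictive policies.
#' @param n_items number of test items per cell (`NULL` = all).
#' @param seed integer seed (mandatory).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(metrics = "iglb",
                              h_refs = c(1e-1, 1e-2, 1e-3, 1e-4, 1e-5),
                              variant = c("baseline", "faulty"),
                              policies = "smooth",
                              predict = c("sample", "mode"),
                              n_items = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory in an experiment config")
  variant <- match.arg(variant)
  predict <- match.arg(predict)
  stopifnot(all(metrics %in% metric_ids()),
            all(policies %in% c("smooth", "sharp", "trajectories",
                                "generic_trajectory", "random")),
            all(h_refs > 0))
  structure(list(metrics = metrics, h_refs = h_refs, variant = variant,
                 policies = policies, predict = predict,
                 n_items = n_items, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the accuracy-versus-compression comparison protocol
#'
#' For every (policy, metric, H_ref) cell, decodes each test item by
#' [explore_scene()] and aggregates the classification rate, the mean
#' decoding compression under both bookkeeping conventions, and the mean
#' saccade count. The test set must be disjoint from the bank's training
#' set (checked by item content hash). Deterministic given the config seed.
#'
#' @param config an [experiment_config()].
#' @param bank a fitted `model_bank` (corrupted internally when
#'   `config$variant == "faulty"`).
#' @param dataset list with `images` and `labels`.
#' @param trajectories optional [build_trajectories()] table; computed from
#'   the (possibly corrupted) bank when a trajectory policy asks for one.
#' @return a data.frame of class `result_table` with one row per cell:
#'   `metric, policy, variant, H_ref, classification_rate,
#'   coefficient_compression, triplet_compression, mean_saccades, n_items`.
#' @export
run_experiment <- function(config, bank, dataset, trajectories = NULL) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(bank, "model_bank"))
  test_hashes <- vapply(dataset$images,
                        function(m) image_hash(pad_image(m)), "")
  if (any(test_hashes %in% bank$train_hashes)) {
    stop("protocol error: ", sum(test_hashes %in% bank$train_hashes),
         " test item(s) also appear in the bank's training set")
  }
  if (config$variant == "faulty") bank <- make_faulty(bank)

  n_all <- length(dataset$images)
  idx <- if (is.null(config$n_items) || config$n_items >= n_all) {
    seq_len(n_all)
  } else {
    withr::with_seed(config$seed, sort(sample.int(n_all, config$n_items)))
  }
  pyramids <- lapply(dataset$images[idx], haar_decompose)
  truth <- as.character(dataset$labels[idx])

  cells <- expand.grid(policy = config$policies, metric = config$metrics,
                       H_ref = config$h_refs, stringsAsFactors = FALSE)
  # non-metric policies ignore the metric axis: collapse duplicates
  cells$metric[cells$policy %in% c("random", "trajectories",
                                   "generic_trajectory")] <- "-"
  cells$metric[cells$policy == "sharp"] <- "iglb_sharp"
  cells <- unique(cells)
  need_traj <- any(cells$policy %in% c("trajectories", "generic_trajectory"))
  if (need_traj && is.null(trajectories)) {
    trajectories <- build_trajectories(precompute_action_maps(bank))
  }

  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    pol <- cells$policy[ci]; met <- cells$metric[ci]; href <- cells$H_ref[ci]
    res <- lapply(seq_along(pyramids), function(k) {
      seed_k <- (config$seed + 7919L * ci + k) %% .Machine$integer.max
      args <- list(pyramid = pyramids[[k]], bank = bank, H_ref = href,
                   seed = seed_k, predict = config$predict)
      args <- switch(pol,
        smooth = c(args, list(metric = met, policy = "metric")),
        sharp = c(args, list(metric = "iglb_sharp", policy = "metric")),
        random = c(args, list(metric = "random", policy = "metric")),
        trajectories = c(args, list(policy = "trajectory",
                                    trajectories = trajectories)),
        generic_trajectory = c(args, list(policy = "generic_trajectory",
                                          trajectories = trajectories)))
      do.call(explore_scene, args)
    })
    data.frame(
      metric = met, policy = pol, variant = config$variant, H_ref = href,
      classification_rate = 100 *
        mean(vapply(res, `[[`, "", "predicted") == truth),
      coefficient_compression = mean(vapply(res, function(r)
        r$compression_exact[1L], numeric(1))),
      triplet_compression = mean(vapply(res, function(r)
        r$compression_exact[2L], numeric(1))),
      mean_saccades = mean(vapply(res, `[[`, integer(1), "n_saccades")),
      n_items = length(res))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("result_table", "data.frame")
  attr(out, "config") <- config
  out
}

#' Write experiment outputs: CSV table, curves, run manifest
#'
#' Writes `results.csv` (the result table), one accuracy-versus-compression
#' PNG curve per policy/metric, and `manifest.json` recording the
#' configuration, seed and library versions for reproduction.
#'
#' @param table a `result_table`; @param out_dir output directory (created
#'   if missing).
#' @return invisible character vector of written paths.
#' @export
summarize_results <- function(table, out_dir) {
  stopifnot(inherits(table, "result_table"), nrow(table) > 0L)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  csv <- file.path(out_dir, "results.csv")
  df <- as.data.frame(table)
  utils::write.csv(df, csv, row.names = FALSE)

  png_path <- file.path(out_dir, "accuracy_vs_compression.png")
  grDevices::png(png_path, width = 720, height = 540)
  keys <- unique(paste(df$policy, df$metric, sep = ":"))
  graphics::plot(NA, xlim = range(df$coefficient_compression) + c(-2, 2),
                 ylim = c(0, 100),
                 xlab = "mean coefficient compression (%)",
                 ylab = "classification rate (%)",
                 main = "Scene decoding: accuracy vs. compression")
  for (ki in seq_along(keys)) {
    sub <- df[paste(df$policy, df$metric, sep = ":") == keys[ki], ]
    sub <- sub[order(sub$coefficient_compression), ]
    graphics::lines(sub$coefficient_compression, sub$classification_rate,
                    type = "b", col = ki, pch = 19)
  }
  graphics::legend("bottomleft", legend = keys, col = seq_along(keys),
                   lty = 1, pch = 19, cex = 0.8)
  grDevices::dev.off()

  manifest <- file.path(out_dir, "manifest.json")
  cfg <- attr(table, "config")
  jsonlite::write_json(list(
    config = if (!is.null(cfg)) unclass(cfg) else NULL,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("foveate")),
    created = format(Sys.time(), tz = "UTC")),
    manifest, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(c(csv, png_path, manifest))
}
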