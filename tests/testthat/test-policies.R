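test_that("exploration state starts from the root observation", {
  fx <- small_fixture()
  st <- exploration_state(fx$pyramids[[1]], fx$bank)
  expect_equal(unclass(st$belief),
               unclass(init_prior(fx$pyramids[[1]], fx$bank)))
  expect_equal(unclass(st$belief_prev), fx$bank$prior,
               ignore_attr = TRUE)
  expect_equal(st$coefficients_read, 1L)
  expect_true(all(st$live))
  expect_false(any(st$consumed))
})

test_that("action selection is seeded, tie-broken row-major, and guarded", {
  fx <- small_fixture()
  st <- exploration_state(fx$pyramids[[1]], fx$bank)

  expect_error(select_action(fx$bank, st, "iglb", predict = "sample"),
               "seed")
  g1 <- select_action(fx$bank, st, "random", seed = 5)
  g2 <- select_action(fx$bank, st, "random", seed = 5)
  expect_identical(g1, g2)

  s1 <- select_action(fx$bank, st, "iglb", predict = "sample", seed = 7)
  s2 <- select_action(fx$bank, st, "iglb", predict = "sample", seed = 7)
  expect_identical(s1, s2)

  st$live[] <- FALSE
  expect_error(select_action(fx$bank, st, "iglb", predict = "mode"),
               "exhausted")
})

test_that("a single-category world makes selection follow its action map", {
  ds <- frozen_pair()
  imgs <- ds$images[ds$labels == "g1"]
  # degenerate two-level factor would be refused; use two identical classes
  # and a one-hot belief instead, which reduces the expectation to one row
  bank <- fit_model_bank(c(imgs, imgs),
                         factor(rep(c("a", "b"), each = length(imgs))))
  st <- exploration_state(haar_decompose(imgs[[1]]), bank)
  st$belief <- belief(c(1, 0), c("a", "b"))
  sel <- select_action(bank, st, "iglb", predict = "mode")
  maps <- precompute_action_maps(bank)
  traj <- build_trajectories(maps)
  expect_equal(unname(sel[1:2]), unname(traj$class_lists[["a"]][1, ]))
})

test_that("scene exploration respects inhibition of return and accounting", {
  fx <- small_fixture()
  for (m in c("iglb", "random", "saliency")) {
    r <- explore_scene(fx$pyramids[[1]], fx$bank, metric = m, H_ref = 1e-6,
                       seed = 12)
    # no gaze revisited
    expect_equal(anyDuplicated(r$saccades), 0L)
    # triplet accounting: 5 on the first saccade, 1..4 after, root = 1 coeff
    expect_equal(r$coefficients_read, 1L + 3L * r$triplets_read)
    expect_equal(length(r$posterior_trace), r$n_saccades + 1L)
    if (r$n_saccades >= 2) {
      per <- diff(vapply(seq_len(r$n_saccades), function(s) {
        sum(vapply(1:s, function(ss) {
          f <- read_field(fx$pyramids[[1]], r$saccades[ss, ],
                          consumed = integer(0))
          nrow(f$triplets)
        }, integer(1)))
      }, numeric(1)))
      # raw chains always have 5; consumption means 1..4 new after the first
      expect_true(all(per <= 5))
    }
  }
})

test_that("exploration is deterministic given its seed", {
  fx <- small_fixture()
  r1 <- explore_scene(fx$pyramids[[2]], fx$bank, metric = "iglb",
                      H_ref = 1e-4, seed = 77)
  r2 <- explore_scene(fx$pyramids[[2]], fx$bank, metric = "iglb",
                      H_ref = 1e-4, seed = 77)
  expect_identical(r1$saccades, r2$saccades)
  expect_identical(r1$predicted, r2$predicted)
  expect_equal(r1$posterior_trace, r2$posterior_trace)
})

test_that("threshold and exhaustion terminations behave as specified", {
  fx <- small_fixture()
  K <- length(fx$bank$classes)
  # threshold at the maximum entropy: no saccade is needed
  r0 <- explore_scene(fx$pyramids[[1]], fx$bank, metric = "iglb",
                      H_ref = log(K) + 1, seed = 1)
  expect_equal(r0$n_saccades, 0L)
  expect_equal(r0$terminated_by, "threshold")
  expect_equal(unclass(r0$posterior_trace[[1]]),
               unclass(init_prior(fx$pyramids[[1]], fx$bank)))

  # an irreducibly ambiguous scene (two indistinguishable categories) never
  # accumulates discriminating evidence: full exhaustion, all 341 triplets
  # consumed
  ds <- frozen_pair()
  imgs <- ds$images[ds$labels == "g1"]
  twin <- fit_model_bank(c(imgs, imgs),
                         factor(rep(c("a", "b"), each = length(imgs))))
  rx <- explore_scene(haar_decompose(imgs[[1]]), twin, metric = "iglb",
                      H_ref = 1e-9, seed = 2, predict = "mode")
  expect_equal(rx$terminated_by, "exhausted")
  expect_equal(rx$n_saccades, 256L)
  expect_equal(rx$triplets_read, 341L)
})

test_that("action maps are symmetric for identical classes and averaged", {
  ds <- frozen_pair()
  imgs <- ds$images[ds$labels == "g1"]
  bank <- fit_model_bank(c(imgs, imgs),
                         factor(rep(c("a", "b"), each = length(imgs))))
  maps <- precompute_action_maps(bank)
  expect_equal(maps$maps[["a"]], maps$maps[["b"]])
  expect_equal(maps$generic, (maps$maps[["a"]] + maps$maps[["b"]]) / 2)
  expect_true(all(is.finite(unlist(maps$maps))))
  expect_equal(dim(maps$generic), c(16L, 16L))
})

test_that("trajectories sort gazes by map value with row-major ties", {
  flat <- structure(list(classes = "a",
                         maps = list(a = matrix(0, 16, 16)),
                         generic = matrix(0, 16, 16)),
                    class = "action_maps")
  tr <- build_trajectories(flat)
  expect_equal(tr$class_lists[["a"]][1:3, ],
               cbind(i = c(0, 0, 0), j = c(0, 1, 2)))

  peaked <- flat
  peaked$maps[["a"]][6, 4] <- 1   # gaze (5, 3)
  peaked$generic[6, 4] <- 1
  tr2 <- build_trajectories(peaked)
  expect_equal(unname(tr2$class_lists[["a"]][1, ]), c(5, 3))

  fx <- small_fixture()
  tr3 <- build_trajectories(precompute_action_maps(fx$bank))
  for (lst in c(tr3$class_lists, list(tr3$generic_list))) {
    expect_equal(sort(lst[, 1] * 16 + lst[, 2]), 0:255)
  }
})

test_that("the trajectory step is an O(1) readout with guess switching", {
  fx <- small_fixture()
  maps <- precompute_action_maps(fx$bank)
  traj <- build_trajectories(maps)
  st <- exploration_state(fx$pyramids[[1]], fx$bank)

  K <- length(fx$bank$classes)
  st$belief <- belief(rep(1 / K, K), fx$bank$classes)
  g_gen <- trajectory_policy_step(traj, st)   # uniform belief: generic list
  expect_equal(unname(g_gen), unname(traj$generic_list[1, ]))

  st$belief <- belief(c(1, rep(0, K - 1)), fx$bank$classes)
  g_a <- trajectory_policy_step(traj, st)
  expect_equal(unname(g_a), unname(traj$class_lists[[1]][1, ]))

  # consumed head entries are skipped
  head_g <- traj$class_lists[[1]][1, ]
  st$live[head_g[1] * 16 + head_g[2] + 1] <- FALSE
  expect_equal(unname(trajectory_policy_step(traj, st)),
               unname(traj$class_lists[[1]][2, ]))

  # a guess flip switches lists on the fly
  st$belief <- belief(c(0, 1, rep(0, K - 2)), fx$bank$classes)
  expect_equal(unname(trajectory_policy_step(traj, st)),
               unname(traj$class_lists[[2]][1, ]))

  st$live[] <- FALSE
  expect_error(trajectory_policy_step(traj, st), "exhausted")

  # per-step cost independence: a trajectory exploration performs zero
  # predictive scorings, a metric exploration performs |Z| x |U| per step
  r_tr <- explore_scene(fx$pyramids[[1]], fx$bank, policy = "trajectory",
                        trajectories = traj, H_ref = 1e-4)
  expect_equal(r_tr$n_predictions, 0L)
  r_sm <- explore_scene(fx$pyramids[[1]], fx$bank, metric = "iglb",
                        H_ref = 1e-4, seed = 3)
  expect_gt(r_sm$n_predictions, 0L)
})

test_that("exact toy-world selection under Infomax minimises expected entropy", {
  set.seed(61)
  for (w in 1:8) {
    world <- generate_toy_world(toy_spec(n_states = 3, n_actions = 5,
                                         n_symbols = 4, seed = 500 + w))
    q <- stats::rgamma(3, 1); q <- q / sum(q)
    chosen <- toy_select_action(world, q, "infomax")
    # independent oracle: direct enumeration of expected posterior entropy
    eh <- vapply(1:5, function(u) {
      px <- as.numeric(q %*% world$emission[, , u])
      sum(vapply(seq_along(px), function(x) {
        if (px[x] == 0) return(0)
        px[x] * entropy_nats(softmax_log(log(world$emission[, x, u]) +
                                           log(q)))
      }, numeric(1)))
    }, numeric(1))
    expect_equal(chosen, which.min(eh))
  }
})

test_that("action maps serialise to CSV and PNG", {
  fx <- small_fixture()
  maps <- precompute_action_maps(fx$bank)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "maps.csv")
  out <- write_action_maps_csv(maps, csv)
  expect_true(file.exists(csv))
  expect_equal(nrow(out), 256L * (length(fx$bank$classes) + 1L))
  expect_named(out, c("class", "rank", "i", "j", "value"))
  png <- file.path(dir, "maps.png")
  plot_action_maps(maps, png)
  expect_true(file.exists(png))
})
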