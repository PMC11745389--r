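make_path <- function(codes, L = 4) mutational_path(codes, L)

test_that("mutational paths validate their genotype sequences", {
  p <- make_path(c(0, 1, 3, 7), 3)
  expect_equal(p$events$site, c(1, 2, 3))
  expect_equal(p$events$direction, c(1, 1, 1))
  # reversions are labelled as backward events
  pr <- make_path(c(0, 1, 3, 2, 6), 3)
  expect_equal(pr$events$direction, c(1, 1, -1, 1))
  expect_error(make_path(c(0, 3), 3), "exactly one site")
})

test_that("line_of_descent reconstructs lineages including reversions", {
  # hand-built trajectory: 3 nodes, 3 generations; node 1's lineage
  # acquires site 1, then site 2, then reverts site 1
  pop_hist <- cbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(3L, 1L, 0L), c(2L, 3L, 0L))
  parent_hist <- cbind(c(0L, 0L, 0L), c(1L, 2L, 3L), c(1L, 1L, 3L), c(1L, 1L, 3L))
  events <- data.frame(gen = c(1L, 2L, 3L), node = c(1L, 1L, 1L),
                       site = c(1L, 2L, 1L))
  traj <- structure(list(pop_history = pop_hist, parent_history = parent_hist,
                         events = events, fmax = 2L, L = 2L),
                    class = "wf_trajectory")
  p <- line_of_descent(traj, target = 2L)
  expect_equal(p$codes, c(0L, 1L, 3L, 2L))
  expect_equal(p$events$site, c(1L, 2L, 1L))
  expect_equal(p$events$direction, c(1L, 1L, -1L))
  expect_null(line_of_descent(traj, target = 7L))
})

test_that("lines of descent from real simulations are valid paths", {
  ls <- make_additive_landscape(c(0.9, 1.1, 1.0))
  cfg <- wf_config(npop = 40, tmax = 400, r = 40, seed = 17)
  traj <- wf_simulate(ls, cfg, record = TRUE, stop_at_threshold = TRUE)
  p <- line_of_descent(traj)
  expect_equal(p$codes[1], 0L)
  expect_equal(p$codes[length(p$codes)], 7L)
  expect_true(all(hamming_distance(p$codes[-length(p$codes)], p$codes[-1]) == 1))
})

test_that("scaled path entropy has exact boundary cases", {
  one <- path_ensemble(list(make_path(c(0, 1))))
  expect_identical(path_entropy(one), 0)
  expect_equal(path_entropy(rep(1 / 5, 5)), 1)
  expect_equal(path_entropy(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 0.5 * log(0.25)) / log(3))
  expect_error(path_entropy(c(0.5, 0.2)), "sum to 1")
  set.seed(8)
  for (rep in 1:20) {
    w <- runif(sample(2:8, 1))
    s <- path_entropy(w / sum(w))
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("path weights are replicate frequencies", {
  paths <- c(replicate(3, make_path(c(0, 1, 3)), simplify = FALSE),
             list(make_path(c(0, 2, 3))))
  ens <- path_ensemble(paths)
  expect_equal(sum(ens$weights), 1)
  expect_setequal(ens$weights, c(0.75, 0.25))
  expect_equal(ens$n_total, 4)
})

test_that("ordering probabilities are complementary weight averages", {
  # two paths with opposite (1,2) order and weights 0.75 / 0.25
  paths <- c(replicate(3, make_path(c(0, 1, 3)), simplify = FALSE),
             list(make_path(c(0, 2, 3))))
  ens <- path_ensemble(paths)
  op <- ordering_probabilities(ens, required_sites = 1:2)
  expect_equal(op$P["1", "2"], 0.75)
  expect_equal(op$P["2", "1"], 0.25)
  single <- path_ensemble(list(make_path(c(0, 1, 3, 7), 3)))
  ops <- ordering_probabilities(single, 1:3)
  expect_true(all(ops$P %in% c(0, 1) | is.na(ops$P)))
  # P[i<j] + P[j<i] = 1 off the diagonal
  expect_true(all(abs(op$P + t(op$P) - 1)[row(op$P) != col(op$P)] < 1e-12))
  # duplicating every replicate leaves the matrix unchanged
  ens2 <- path_ensemble(c(paths, paths))
  expect_equal(ordering_probabilities(ens2, 1:2)$P, op$P)
  # a path missing a required site is excluded with a warning
  mixed <- path_ensemble(c(paths, list(make_path(c(0, 2)))))
  expect_warning(opm <- ordering_probabilities(mixed, 1:2), "missing")
  expect_equal(opm$P["1", "2"], 0.75)
})

test_that("hotspot-step classification partitions the ensemble", {
  paths <- list(make_path(c(0, 2, 3, 7), 3),     # hotspot (site 1) at step 2
                make_path(c(0, 1, 3, 7), 3),     # step 1
                make_path(c(0, 2, 6, 7), 3))     # step 3
  ens <- path_ensemble(paths)
  cls <- classify_by_hotspot_step(ens, hotspot_site = 1)
  agg <- attr(cls, "by_class")
  expect_equal(agg$class, c(1, 2, 3))
  expect_equal(agg$n_paths, c(1L, 1L, 1L))
  expect_equal(sum(agg$total_weight), 1)
  expect_equal(agg$cumulative_weight[3], 1)
  # ensemble where the hotspot always mutates first
  first <- path_ensemble(list(make_path(c(0, 1, 3)), make_path(c(0, 1, 5), 3)))
  aggf <- attr(classify_by_hotspot_step(first, 1), "by_class")
  expect_equal(aggf$class, 1)
  expect_equal(aggf$total_weight, 1)
})

test_that("sampled SSWM path weights converge to exact path probabilities", {
  for (seed in c(2, 13)) {
    ls <- random_landscape(4, seed)
    tm <- build_transition_matrix(ls)
    fmax <- global_optimum(ls)
    exact <- enumerate_sswm_paths(tm, 0L, fmax)
    n <- 4000
    ens <- sswm_path_ensemble(ls, n = n, seed = 31)
    total_p <- sum(vapply(exact, `[[`, 0, "prob"))
    for (e in exact) {
      key <- paste(e$path, collapse = "-")
      idx <- match(key, vapply(ens$paths, epiland:::.path_key, ""))
      w_exact <- e$prob / total_p
      w_obs <- if (is.na(idx)) 0 else ens$weights[idx]
      se <- sqrt(w_exact * (1 - w_exact) / ens$n_total)
      expect_lt(abs(w_obs - w_exact), 3 * se + 2e-3)
    }
  }
})

test_that("stepwise DFE is positive along SSWM walks and flat on additive truth", {
  ls <- random_landscape(4, 6)
  ens <- sswm_path_ensemble(ls, n = 200, seed = 5)
  df <- stepwise_dfe(ens, ls)
  expect_true(all(df$delta_f > 0))
  # equal-weight ensemble of all mutation orderings on an additive
  # landscape: the mean effect at every step equals mean(h)
  h <- c(0.3, 0.9, 1.5)
  la <- make_additive_landscape(h)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  paths <- lapply(perms, function(p) {
    codes <- Reduce(function(c0, s) bitwXor(c0, bitwShiftL(1L, s - 1L)),
                    p, accumulate = TRUE, init = 0L)
    make_path(codes, 3)
  })
  dfa <- stepwise_dfe(path_ensemble(paths), la)
  means <- tapply(dfa$delta_f, dfa$step, mean)
  expect_equal(as.numeric(means), rep(mean(h), 3))
})
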