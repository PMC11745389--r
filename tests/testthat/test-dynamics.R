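test_that("SSWM transitions are DeltaF-proportional and stochastic", {
  ls <- fitness_landscape(c(0, 2, 1, 3))
  tm <- build_transition_matrix(ls)
  expect_equal(tm$P[1, 2], 2 / 3)            # 00 -> 10
  expect_equal(tm$P[1, 3], 1 / 3)            # 00 -> 01
  expect_equal(rowSums(tm$P), rep(1, 4))
  expect_identical(tm$absorbing, 3L)         # the single peak 11
  # uniform kernel variant
  tu <- build_transition_matrix(ls, kernel = "uniform")
  expect_equal(tu$P[1, 2], 1 / 2)
  # tie plateaus are absorbing with a warning (the census also warns)
  lt <- fitness_landscape(c(1, 1, 0, 0))
  expect_warning(expect_warning(build_transition_matrix(lt), "plateau"), "tie")
})

test_that("single-peak landscapes absorb at the peak from every start", {
  la <- make_additive_landscape(c(0.6, 1.1, 0.9))
  tm <- build_transition_matrix(la)
  B <- absorbing_probabilities(tm)
  expect_equal(ncol(B), 1)
  expect_equal(unname(B[, 1]), rep(1, 8))
  expect_equal(static_accessibility(la), 1)
})

test_that("absorption probabilities agree with Monte-Carlo sampling", {
  for (seed in c(5, 21)) {
    ls <- random_landscape(5, seed)
    tm <- build_transition_matrix(ls)
    B <- absorbing_probabilities(tm)
    expect_equal(unname(rowSums(B)), rep(1, 32), tolerance = 1e-10)
    n_walks <- 10000
    for (start in c(0L, 5L, 12L)) {
      freq <- mc_absorbing(tm, start, n_walks, seed = 100 + start)
      p <- B[start + 1, names(freq)]
      se <- pmax(sqrt(p * (1 - p) / n_walks), 1e-4)
      expect_true(all(abs(freq - p) <= 3 * se + 3e-3))
    }
  }
})

test_that("replacement probabilities are a softmax over the neighborhood", {
  # flat landscape: replacement uniform over the 2r + 1 neighborhood
  flat <- fitness_landscape(rep(1.5, 8))
  cfg <- wf_config(npop = 40, mu = 0, r = 2, tmax = 1, seed = 1)
  set.seed(2)
  pop <- sample(0:7, 40, replace = TRUE)
  counts <- matrix(0L, 40, 40)
  set.seed(3)
  for (rep in 1:3000) {
    stp <- wf_step(pop, flat, cfg)
    counts[cbind(seq_len(40), stp$parents)] <- counts[cbind(seq_len(40), stp$parents)] + 1L
  }
  probs <- counts / 3000
  for (i in c(1, 17, 40)) {
    nbhd <- ((i - 1) + (-2:2)) %% 40 + 1
    expect_true(all(abs(probs[i, nbhd] - 0.2) < 0.05))
    expect_equal(sum(probs[i, -nbhd]), 0)
  }
})

test_that("mu = 0 isogenic populations are invariant", {
  ls <- random_landscape(4, 3)
  cfg <- wf_config(npop = 30, mu = 0, r = 2, tmax = 25, seed = 8)
  traj <- wf_simulate(ls, cfg)
  expect_identical(unique(traj$final_pop), 0L)
})

test_that("strong selection fixes the fitter of two genotypes within 5 generations", {
  ls <- fitness_landscape(c(0, 10, 0, 10))     # site 1 confers DeltaF = 10
  cfg <- wf_config(npop = 50, mu = 0, r = 50, tmax = 5, seed = 0)
  fixed <- vapply(1:100, function(k) {
    set.seed(k)
    pop <- rep(c(0L, 1L), 25)                  # half mutant start
    setup <- epiland:::.wf_setup(ls, cfg)
    for (t in 1:5) pop <- wf_step(pop, ls, cfg, setup)$pop
    all(pop == 1L)
  }, TRUE)
  expect_gte(sum(fixed), 99)
})

test_that("wf_simulate honors tmax, seeds and occupancy accounting", {
  ls <- random_landscape(5, 12)
  cfg0 <- wf_config(npop = 40, tmax = 0, seed = 5)
  t0 <- wf_simulate(ls, cfg0)
  expect_equal(t0$generations, 0)
  expect_equal(nrow(t0$occupancy), 1)
  cfg <- wf_config(npop = 40, tmax = 60, r = 2, seed = 99)
  a <- wf_simulate(ls, cfg, record = TRUE)
  b <- wf_simulate(ls, cfg, record = TRUE)
  expect_identical(a$final_pop, b$final_pop)
  expect_identical(a$events, b$events)
  expect_true(all(a$occupancy >= 0 & a$occupancy <= 1))
  expect_true(all(rowSums(a$occupancy) <= 1 + 1e-12))
})

test_that("smooth landscapes are reliably climbed by well-mixed populations", {
  wins <- vapply(1:50, function(k) {
    nk <- generate_nk(10, 0, seed = 400 + k)
    cfg <- wf_config(r = 500, tmax = 2000, seed = 10 + k)
    traj <- wf_simulate(nk, cfg, stop_at_threshold = TRUE)
    max(traj$occupancy[nrow(traj$occupancy), ]) > 0.5
  }, TRUE)
  expect_gte(mean(wins), 0.8)
})

test_that("well-mixed dynamics are invariant to node relabeling", {
  ls <- random_landscape(4, 44)
  cfg <- wf_config(npop = 60, r = 60, tmax = 40, seed = 13)
  base <- wf_simulate(ls, cfg)
  # with r = npop the ring is panmictic: occupancies do not depend on
  # where genotypes sit, and the same seed reproduces the same summary
  again <- wf_simulate(ls, cfg)
  expect_identical(base$occupancy, again$occupancy)
  expect_true(epiland:::.wf_setup(ls, cfg)$well_mixed)
})

test_that("success decisions are conservative and configurable", {
  expect_error(wf_config(threshold = 1.5), "threshold")
  expect_error(wf_config(r = 0), "r")
  # an exactly flat landscape has only tie plateaus, hence no optimum set
  flat <- fitness_landscape(rep(0, 16))
  expect_warning(opt <- find_local_optima(flat), "tie")
  expect_length(opt, 0)
  # threshold 1 under negligible selection: mutational load keeps the
  # nominal optimum from fixating the whole population
  set.seed(14)
  nearly_flat <- fitness_landscape(rnorm(16, sd = 1e-4))
  cfg <- wf_config(npop = 60, tmax = 150, r = 60, threshold = 1, seed = 3)
  res <- success_rate(nearly_flat, cfg, n_replicates = 5)
  expect_equal(res$success_rate, 0)
  ls <- make_additive_landscape(c(0.8, 0.9, 1.0, 1.1))
  # threshold 0.5 on the same single-peak landscape succeeds routinely
  cfg2 <- wf_config(npop = 60, tmax = 400, r = 60, threshold = 0.5, seed = 3)
  res2 <- success_rate(ls, cfg2, n_replicates = 5)
  expect_gt(res2$success_rate, 0.5)
  expect_named(res2$records, c("replicate", "success", "t_hit"))
})

test_that("max_occupancy_profile summarizes trajectories", {
  ls <- make_additive_landscape(c(1, 1, 1))
  cfg <- wf_config(npop = 30, tmax = 120, r = 30, seed = 21)
  traj <- wf_simulate(ls, cfg)
  mx <- max_occupancy_profile(traj)
  expect_true(all(mx >= traj$occupancy[nrow(traj$occupancy), ]))
  # an isogenic static population at an optimum keeps occupancy 1
  cfg0 <- wf_config(npop = 10, mu = 0, tmax = 4, r = 10, seed = 2)
  opt_ls <- fitness_landscape(c(3, 1, 1, 0))   # germline is the optimum
  tr0 <- wf_simulate(opt_ls, cfg0)
  expect_equal(unname(max_occupancy_profile(tr0)[as.character(0)]), 1)
})
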