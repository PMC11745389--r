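test_that("Walsh-Hadamard transform is orthogonal and order-resolved", {
  # constant landscape: only the order-0 coefficient survives
  lc <- fitness_landscape(rep(2.5, 16))
  spc <- wh_transform(lc)
  expect_equal(spc$coef[1], 2.5)
  expect_equal(max(abs(spc$coef[-1])), 0)
  # round trip on a random L = 6 landscape
  ls <- random_landscape(6, 42)
  rt <- inverse_wh_transform(wh_transform(ls))
  expect_lt(max(abs(rt$fitness - ls$fitness)) / max(abs(ls$fitness)), 1e-10)
  # purely additive landscape has no coefficients of order >= 2
  la <- make_additive_landscape(c(1, -0.5, 0.3, 2, -1.2))
  spa <- wh_transform(la)
  expect_equal(max(abs(spa$coef[spa$order >= 2])), 0)
  expect_gt(min(abs(spa$coef[spa$order == 1])), 0)
  expect_error(wh_transform(rnorm(12)), "power of two")
})

test_that("Parseval holds under the 2^-L normalization", {
  for (seed in c(2, 9)) {
    ls <- random_landscape(5, seed)
    sp <- wh_transform(ls)
    expect_equal(sum(ls$fitness^2), 2^5 * sum(sp$coef^2))
  }
})

test_that("Taylor/Fourier basis conversion round-trips and preserves support", {
  ls <- random_landscape(5, 13)
  sp <- wh_transform(ls)
  rt <- convert_spectrum(convert_spectrum(sp, "taylor"), "fourier")
  expect_equal(rt$coef, sp$coef, tolerance = 1e-12)
  # order-3-limited support is preserved by the basis change both ways
  set.seed(14)
  co <- epistasis_coefficients(
    rnorm(5),
    {J <- matrix(0, 5, 5); J[upper.tri(J)] <- rnorm(10, sd = .3); J},
    {K <- array(0, c(5, 5, 5)); K[1, 2, 3] <- .4; K[2, 4, 5] <- -.2; K})
  lb <- landscape_from_coefficients(co)
  spf <- wh_transform(lb)
  expect_lt(max(abs(spf$coef[spf$order > 3])), 1e-12)
  spt <- convert_spectrum(spf, "taylor")
  expect_lt(max(abs(spt$coef[spt$order > 3])), 1e-12)
})

test_that("band-pass denoising is a projection that removes high orders", {
  set.seed(31)
  co <- epistasis_coefficients(
    rnorm(6),
    {J <- matrix(0, 6, 6); J[upper.tri(J)] <- rnorm(15, sd = .3); J},
    {K <- array(0, c(6, 6, 6)); K[1, 2, 3] <- .5; K})
  ls <- landscape_from_coefficients(co)
  # already band-limited: returned unchanged (germline is already 0)
  expect_equal(bandpass_denoise(ls, 3)$fitness, ls$fitness, tolerance = 1e-12)
  # inject one known order-4 Fourier component and verify exact removal
  sp <- wh_transform(ls)
  idx <- which(sp$order == 4)[1]
  sp$coef[idx] <- sp$coef[idx] + 0.8
  contaminated <- inverse_wh_transform(sp)
  dn <- bandpass_denoise(contaminated, 3)
  expect_equal(dn$fitness, ls$fitness, tolerance = 1e-12)
  # idempotence
  noisy <- random_landscape(6, 5)
  once <- bandpass_denoise(noisy, 3)
  twice <- bandpass_denoise(once, 3)
  expect_equal(twice$fitness, once$fitness, tolerance = 1e-12)
  expect_error(bandpass_denoise(noisy, 7), "invalid cutoff")
})

test_that("denoising two replicates raises inter-replicate R2", {
  truth <- landscape_from_coefficients(epistasis_coefficients(
    rnorm(8, sd = 0.5),
    {J <- matrix(0, 8, 8); J[upper.tri(J)] <- rnorm(28, sd = .2); J}))
  reps <- make_noisy_replicates(truth, sigma = 0.3, n_rep = 2, seed = 77)
  r2 <- function(a, b) cor(a, b)^2
  raw <- r2(reps[[1]]$fitness, reps[[2]]$fitness)
  dn1 <- bandpass_denoise(reps[[1]], 3)
  dn2 <- bandpass_denoise(reps[[2]], 3)
  expect_gt(r2(dn1$fitness, dn2$fitness), raw)
})

test_that("noiseless order-3 coefficients are recovered exactly", {
  set.seed(19)
  L <- 6
  h <- rnorm(L)
  J <- matrix(0, L, L); J[upper.tri(J)] <- rnorm(15, sd = 0.3)
  K <- array(0, c(L, L, L))
  for (i in 1:4) for (j in (i + 1):5) for (k in (j + 1):6) {
    K[i, j, k] <- rnorm(1, sd = 0.2)
  }
  truth <- epistasis_coefficients(h, J, K)
  fit <- fit_specific_ml(landscape_from_coefficients(truth), cv_folds = 5)
  expect_lt(max(abs(fit$coefficients$h - h)), 1e-8)
  expect_lt(max(abs(fit$coefficients$J - truth$J)), 1e-8)
  expect_lt(max(abs(fit$coefficients$K - truth$K)), 1e-8)
  expect_equal(fit$report$selected_order, 3)
})

test_that("a complete-order fit interpolates any noiseless germline-zero table", {
  ls <- random_landscape(4, 55)
  # the model class fixes F(germline) = 0, so exact reproduction is only
  # defined for tables in that class
  ls$fitness <- ls$fitness - ls$fitness[1]
  fit <- fit_specific_ml(ls, max_order = 4, candidate_orders = 1:4,
                         cv_folds = 0)
  expect_equal(fit$landscape$fitness, ls$fitness, tolerance = 1e-9)
})

test_that("cross-validation selects order 3 for order-3 truth at moderate noise", {
  fx <- fixture_ls()
  votes <- vapply(1:10, function(s) {
    reps <- make_noisy_replicates(fx$landscape, sigma = 0.2, n_rep = 2,
                                  seed = 100 + s)
    fit_specific_ml(reps, cv_folds = 10, seed = s)$report$selected_order
  }, 0)
  expect_equal(as.integer(names(which.max(table(votes)))), 3L)
})

test_that("fitted epistasis shrinks to zero with vanishing noise on additive truth", {
  truth <- make_additive_landscape(c(0.8, -0.4, 0.6, 1.1, -0.9, 0.3))
  mags <- vapply(c(0.5, 0.1, 0.01), function(sig) {
    reps <- make_noisy_replicates(truth, sigma = sig, n_rep = 2, seed = 7)
    fit <- fit_specific_ml(reps, max_order = 3, cv_folds = 0)
    sum(abs(fit$coefficients$J)) + sum(abs(fit$coefficients$K))
  }, 0)
  expect_true(all(diff(mags) < 0))
})

test_that("coefficient recovery error decreases monotonically with noise", {
  fx <- fixture_ls()
  truth <- c(fx$coefficients$h, fx$coefficients$J[upper.tri(fx$coefficients$J)],
             fx$coefficients$K[fx$coefficients$K != 0])
  med_err <- vapply(c(0.8, 0.2, 0.05), function(sig) {
    errs <- vapply(1:20, function(s) {
      reps <- make_noisy_replicates(fx$landscape, sigma = sig, n_rep = 2,
                                    seed = 1000 * s)
      fit <- fit_specific_ml(reps, max_order = 3, cv_folds = 0)
      est <- c(fit$coefficients$h,
               fit$coefficients$J[upper.tri(fit$coefficients$J)],
               fit$coefficients$K[fx$coefficients$K != 0])
      sqrt(sum((est - truth)^2) / sum(truth^2))
    }, 0)
    median(errs)
  }, 0)
  expect_true(all(diff(med_err) < 0))
})

test_that("global-epistasis fit recovers a linear transform exactly", {
  set.seed(61)
  h <- rnorm(7)
  ls <- make_additive_landscape(h)
  gf <- fit_global(ls)
  expect_gt(gf$report$r2, 1 - 1e-6)
  # h recovered up to the unit-norm normalization (orientation follows
  # the increasing relationship, which for F = phi is h's natural sign)
  expect_equal(gf$model$h, h / sqrt(sum(h^2)), tolerance = 1e-6)
  expect_equal(sum(gf$model$h^2), 1, tolerance = 1e-9)
})

test_that("global-epistasis fit recovers latent ranks under saturation", {
  set.seed(62)
  h <- rnorm(7)
  phi <- as.numeric(genotype_bits(0:(2^7 - 1), 7) %*% h)
  ls <- fitness_landscape(tanh(phi))
  gf <- fit_global(ls)
  expect_gt(cor(gf$model$phi, phi, method = "spearman"), 0.99)
  # predictions are a nondecreasing function of the fitted phi
  ord <- order(gf$model$phi)
  pred <- predict(gf$model)
  expect_true(all(diff(pred[ord]) >= -1e-12))
  # g knots are nondecreasing by construction
  expect_true(all(diff(gf$model$g_knots[, "value"]) >= -1e-12))
})
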