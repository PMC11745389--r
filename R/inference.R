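# Maximum-likelihood inference of specific- and global-epistasis models
# from (possibly replicated, noisy) complete genotype tables.  Under
# i.i.d. Gaussian noise of equal variance the ML fit of the interaction
# expansion is ordinary least squares on the subset-product design; the
# model has no intercept, so the germline prediction is exactly 0.

# Subset bitmask codes of interaction order 1..max_order, sorted by order.
#' @keywords internal
.design_subsets <- function(L, max_order) {
  codes <- 0:(2^L - 1)
  ord <- .popcount(codes)
  keep <- codes[ord >= 1 & ord <= max_order]
  keep[order(.popcount(keep), keep)]
}

# Design matrix over all 2^L genotypes: X[s, T] = prod_{i in T} s_i.
#' @keywords internal
.design_matrix <- function(L, subsets) {
  codes <- 0:(2^L - 1)
  m <- vapply(subsets,
              function(T) as.numeric(bitwAnd(codes, T) == T),
              numeric(2^L))
  matrix(m, nrow = 2^L)
}

#' @keywords internal
.as_replicate_list <- function(data) {
  if (inherits(data, "fitness_landscape")) return(list(data))
  if (inherits(data, "landscape_replicates")) return(unclass(data))
  if (is.list(data) && all(vapply(data, inherits, TRUE, "fitness_landscape"))) {
    return(data)
  }
  stop("data must be a fitness_landscape or a list of replicate landscapes")
}

#' Fit the specific-epistasis model by maximum likelihood
#'
#' Ordinary least squares on the interaction design (Gaussian noise ML),
#' with k-fold cross-validation over genotypes to select the interaction
#' order among `candidate_orders`.  Selection takes the lowest mean
#' held-out squared error with a one-standard-error tie-break toward the
#' lower order.  The germline is constrained to zero fitness by the
#' absence of an intercept.
#'
#' @param data A `fitness_landscape`, a list of replicate landscapes, or
#'   the result of [read_genotype_table()] on a replicated table.
#' @param max_order Fit exactly this order and skip selection; `NULL`
#'   (default) selects by cross-validation.
#' @param candidate_orders Orders scored by cross-validation.
#' @param cv_folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return A list with elements `coefficients` (an
#'   `epistasis_coefficients`) and `report` (a `fit_report`: CV table,
#'   `selected_order`, per-replicate R2 and raw/denoised inter-replicate
#'   R2).
#' @export
fit_specific_ml <- function(data, max_order = NULL, candidate_orders = 1:4,
                            cv_folds = 10, seed = 1) {
  reps <- .as_replicate_list(data)
  L <- reps[[1]]$L
  n <- 2^L
  stopifnot(all(vapply(reps, function(r) r$L, 0L) == L))
  Y <- vapply(reps, function(r) r$fitness, numeric(n))   # n x n_rep
  ybar <- rowMeans(Y)
  orders <- sort(unique(pmin(candidate_orders, L)))
  Xfull <- .design_matrix(L, .design_subsets(L, max(orders)))
  n_terms <- vapply(orders, function(o) sum(choose(L, seq_len(o))), 0)

  cv <- NULL
  if (cv_folds > 1) {
    folds <- .with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
    err <- matrix(NA_real_, cv_folds, length(orders))
    for (f in seq_len(cv_folds)) {
      test <- folds == f
      for (oi in seq_along(orders)) {
        cols <- seq_len(n_terms[oi])
        # stacking replicates is equivalent to fitting the replicate mean
        fit <- stats::lm.fit(Xfull[!test, cols, drop = FALSE], ybar[!test])
        pred <- Xfull[test, cols, drop = FALSE] %*% fit$coefficients
        err[f, oi] <- mean((Y[test, , drop = FALSE] - as.numeric(pred))^2)
      }
    }
    cv <- data.frame(order = orders,
                     cv_mse = colMeans(err),
                     cv_se = apply(err, 2, stats::sd) / sqrt(cv_folds))
    best <- which.min(cv$cv_mse)
    within <- which(cv$cv_mse <= cv$cv_mse[best] + cv$cv_se[best])
    selected <- orders[min(within)]
  } else {
    selected <- max(orders)
  }
  if (!is.null(max_order)) selected <- max_order

  cols <- seq_len(sum(choose(L, seq_len(selected))))
  subsets <- .design_subsets(L, selected)[cols]
  fit <- stats::lm.fit(Xfull[, cols, drop = FALSE], ybar)
  tay <- numeric(n)
  tay[subsets + 1L] <- fit$coefficients
  denoised <- fitness_landscape(.zeta_transform(tay, L),
                                site_labels = reps[[1]]$site_labels)
  coef <- coefficients_from_landscape(denoised, max_order = max(selected, 3),
                                      drop_higher = TRUE)

  pred <- denoised$fitness
  r2 <- function(a, b) {
    1 - sum((a - b)^2) / sum((b - mean(b))^2)
  }
  r2_fit <- apply(Y, 2, function(y) r2(pred, y))
  r2_raw <- r2_denoised <- NA_real_
  if (length(reps) >= 2) {
    r2_raw <- stats::cor(Y[, 1], Y[, 2])^2
    dn <- vapply(reps, function(r) bandpass_denoise(r, max_order = min(selected, L))$fitness,
                 numeric(n))
    r2_denoised <- stats::cor(dn[, 1], dn[, 2])^2
  }
  report <- structure(list(cv = cv, selected_order = selected,
                           r2_fit = r2_fit, r2_between_raw = r2_raw,
                           r2_between_denoised = r2_denoised),
                      class = "fit_report")
  list(coefficients = coef, report = report, landscape = denoised)
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Specific-epistasis fit report\n")
  if (!is.null(x$cv)) {
    cat("  cross-validated MSE by order:\n")
    print(x$cv, row.names = FALSE)
  }
  cat("  selected order:", x$selected_order, "\n")
  if (!anyNA(x$r2_between_raw)) {
    cat(sprintf("  inter-replicate R2: %.3f raw, %.3f denoised\n",
                x$r2_between_raw, x$r2_between_denoised))
  }
  invisible(x)
}

#' Fit the global-epistasis model
#'
#' Fits `F(s) = g(sum_i h_i s_i)` with `g` monotone nondecreasing, by
#' alternating maximization: initialize `g` as the identity, fit `h` by
#' least squares on pseudo-observations `g^{-1}(F)`, then refit `g` by
#' isotonic regression of `F` on the latent phenotype `phi = sum h_i s_i`,
#' iterating to convergence of the squared error.  Identifiability:
#' `||h||_2 = 1`, oriented so that the latent phenotype correlates
#' positively with fitness (the sign is not free once `g` is constrained
#' nondecreasing); `g` absorbs scale and offset and is reported as 50
#' equally spaced knot/value pairs with linear interpolation.
#'
#' @param data A `fitness_landscape` (replicates are averaged first).
#' @param n_knots Number of knots used to discretize `g`.
#' @param max_iter,tol Convergence controls for the alternating loop.
#' @return A list with `model` (class `global_epistasis_model`: `h`,
#'   `g_knots`, `phi`) and `report` (iterations, convergence flag, R2).
#' @export
fit_global <- function(data, n_knots = 50, max_iter = 100, tol = 1e-8) {
  reps <- .as_replicate_list(data)
  L <- reps[[1]]$L
  F <- rowMeans(vapply(reps, function(r) r$fitness, numeric(2^L)))
  X <- genotype_bits(0:(2^L - 1), L)

  fit_h <- function(target) stats::lm.fit(X, target)$coefficients
  h <- fit_h(F)                                  # g = identity to start
  sse_prev <- Inf
  converged <- FALSE
  iter <- 0
  g_fun <- NULL
  knots_from_iso <- function(phi, F) {
    ord <- order(phi)
    iso <- stats::isoreg(phi[ord], F[ord])     # yf aligned with sorted phi
    gx <- seq(min(phi), max(phi), length.out = n_knots)
    gy <- stats::approx(phi[ord], iso$yf, xout = gx, rule = 2, ties = mean)$y
    cbind(phi = gx, value = cummax(gy))
  }
  for (iter in seq_len(max_iter)) {
    phi <- as.numeric(X %*% h)
    kn <- knots_from_iso(phi, F)
    gx <- kn[, "phi"]
    gy <- kn[, "value"]
    g_fun <- stats::approxfun(gx, gy, rule = 2)
    pred <- g_fun(phi)
    sse <- sum((F - pred)^2)
    if (is.finite(sse_prev) &&
        abs(sse_prev - sse) <= tol * max(sse_prev, 1e-12)) {
      converged <- TRUE
      sse_prev <- sse
      break
    }
    sse_prev <- sse
    # invert g (flats broken by a vanishing slope) for pseudo-observations
    gy_strict <- gy + seq_along(gy) * 1e-9 * max(diff(range(gy)), 1e-12)
    phi_target <- stats::approx(gy_strict, gx, xout = F, rule = 2, ties = mean)$y
    h <- fit_h(phi_target)
  }
  # normalization: unit-norm h; the sign is not free under a
  # nondecreasing g, so orient h along the increasing relationship
  h <- unname(h)
  s <- sqrt(sum(h^2))
  h <- h / s
  if (stats::cor(as.numeric(X %*% h), F) < 0) h <- -h
  phi <- as.numeric(X %*% h)
  kn <- knots_from_iso(phi, F)
  gx <- kn[, "phi"]
  gy <- kn[, "value"]
  g_fun <- stats::approxfun(gx, gy, rule = 2)
  pred <- g_fun(phi)
  r2 <- 1 - sum((F - pred)^2) / sum((F - mean(F))^2)
  model <- structure(list(h = h, g_knots = cbind(phi = gx, value = gy),
                          phi = phi, site_labels = reps[[1]]$site_labels,
                          normalization = "unit_h_norm"),
                     class = "global_epistasis_model")
  report <- list(iterations = iter, converged = converged, sse = sse_prev, r2 = r2)
  if (!converged) warning("global-epistasis fit did not converge in ",
                          max_iter, " iterations; best iterate returned")
  list(model = model, report = report)
}

#' Predict fitness from a fitted global-epistasis model
#'
#' @param object A `global_epistasis_model`.
#' @param g Genotype matrix (rows) or vector; defaults to all genotypes.
#' @param ... Unused.
#' @export
predict.global_epistasis_model <- function(object, g = NULL, ...) {
  L <- length(object$h)
  if (is.null(g)) g <- genotype_bits(0:(2^L - 1), L)
  if (!is.matrix(g)) g <- matrix(g, nrow = 1)
  phi <- as.numeric(g %*% object$h)
  stats::approx(object$g_knots[, "phi"], object$g_knots[, "value"],
                xout = phi, rule = 2)$y
}

#' Serialize a global-epistasis model to JSON
#' @param model A `global_epistasis_model`.
#' @param path Output path.
#' @export
write_global_model <- function(model, path) {
  obj <- list(h = model$h,
              g_knots = unname(apply(model$g_knots, 1, as.list)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
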