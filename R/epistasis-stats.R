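# Ruggedness and heterogeneity metrics: directed gamma statistics, the
# generalized gamma(n, d) over pinned subspaces, pairwise |K| summaries,
# the slope-to-roughness funneling ratio and distributions of fitness
# effects.  gamma -> 1 indicates additivity; gamma <= 0 signals sign
# epistasis and hence local ruggedness.

#' Directed correlation of fitness effects, gamma_{i -> j}
#'
#' For each ordered site pair (i, j), the Pearson correlation between the
#' fitness effect of mutation j on background s, `F(s[j]) - F(s)`, and the
#' same effect in the presence of mutation i, `F(s[ij]) - F(s[i])`, over
#' all backgrounds with `s_i = s_j = 0`.  Degenerate (zero-variance)
#' entries are reported as `NA`, never imputed.
#'
#' @param ls A `fitness_landscape` with `L >= 2`.
#' @param bidirectional Also pool backgrounds with site i mutated (flip of
#'   i in either direction); default `FALSE`, reading "the presence of
#'   mutation i" as the 0 -> 1 flip.
#' @return An `L x L` matrix with `NA` diagonal, entries in `[-1, 1]`.
#' @export
gamma_directed <- function(ls, bidirectional = FALSE) {
  stopifnot(inherits(ls, "fitness_landscape"), ls$L >= 2)
  L <- ls$L
  f <- ls$fitness
  codes <- 0:(2^L - 1)
  gm <- matrix(NA_real_, L, L,
               dimnames = list(ls$site_labels, ls$site_labels))
  for (i in seq_len(L)) {
    mi <- bitwShiftL(1L, i - 1L)
    for (j in seq_len(L)) {
      if (i == j) next
      mj <- bitwShiftL(1L, j - 1L)
      b <- codes[bitwAnd(codes, mi) == 0L & bitwAnd(codes, mj) == 0L]
      x <- f[b + mj + 1L] - f[b + 1L]
      y <- f[b + mi + mj + 1L] - f[b + mi + 1L]
      if (bidirectional) {
        # pool both flip directions of i (symmetrized estimator)
        x <- c(x, y)
        y <- c(y, x[seq_along(y)])
      }
      if (length(x) >= 2 && !.degenerate(x) && !.degenerate(y)) {
        gm[i, j] <- stats::cor(x, y)
      }
    }
  }
  gm
}

#' Generalized ruggedness statistic gamma(n, d) over pinned subspaces
#'
#' For each choice of `n` pinned sites and their 0/1 states, restricts the
#' landscape to the `(L - n)`-dimensional subspace and computes the pooled
#' Pearson correlation of fitness effects `Delta_j(s)` vs `Delta_j(s')`
#' over all free sites j and all background pairs (s, s') at Hamming
#' distance `d` within the subspace with `s_j = s'_j = 0`.
#'
#' @param ls A `fitness_landscape`.
#' @param n Number of pinned sites, `0 <= n <= L - 2`.
#' @param d Background separation, `1 <= d <= L - n - 1`.
#' @param pinned_sets Optional list of integer site vectors restricting
#'   which pinned-site choices are evaluated (default: all `choose(L, n)`).
#' @return A data frame with one row per (pinned set, pinned state):
#'   columns `n`, `d`, `pinned_sites`, `pinned_states` (comma strings) and
#'   `gamma` (`NA` when degenerate).
#' @export
gamma_generalized <- function(ls, n, d, pinned_sets = NULL) {
  stopifnot(inherits(ls, "fitness_landscape"))
  L <- ls$L
  if (n < 0 || n > L - 2) stop("invalid n: need 0 <= n <= L - 2")
  if (d < 1 || d > L - n - 1) stop("invalid (n, d): need 1 <= d <= L - n - 1")
  if (is.null(pinned_sets)) {
    pinned_sets <- if (n == 0) list(integer(0))
                   else asplit(utils::combn(L, n), 2)
  }
  out <- list()
  for (set in pinned_sets) {
    set <- as.integer(set)
    states_mat <- if (n == 0) matrix(0L, 1, 0) else genotype_bits(0:(2^n - 1), n)
    for (si in seq_len(nrow(states_mat))) {
      st <- states_mat[si, ]
      gamma <- .gamma_pooled(ls, set, st, d)
      out[[length(out) + 1L]] <- data.frame(
        n = n, d = d,
        pinned_sites = paste(ls$site_labels[set], collapse = ","),
        pinned_states = paste(st, collapse = ","),
        gamma = gamma)
    }
  }
  do.call(rbind, out)
}

# Pooled correlation of effects within one pinned subspace.
#' @keywords internal
.gamma_pooled <- function(ls, set, states, d) {
  L <- ls$L
  f <- ls$fitness
  free <- setdiff(seq_len(L), set)
  m <- length(free)
  base <- if (length(set) > 0) sum(2^(set - 1L) * states) else 0L
  sub_codes <- if (m > 0) {
    as.integer(genotype_bits(0:(2^m - 1), m) %*% 2^(free - 1L)) + as.integer(base)
  } else integer(0)
  xs <- list()
  ys <- list()
  for (j in free) {
    mj <- bitwShiftL(1L, j - 1L)
    b <- sub_codes[bitwAnd(sub_codes, mj) == 0L]
    others <- setdiff(free, j)
    if (length(others) < d) next
    choice <- utils::combn(length(others), d)   # indices, not values
    for (ci in seq_len(ncol(choice))) {
      dm <- sum(bitwShiftL(1L, others[choice[, ci]] - 1L))
      b2 <- bitwXor(b, dm)
      xs[[length(xs) + 1L]] <- f[b + mj + 1L] - f[b + 1L]
      ys[[length(ys) + 1L]] <- f[b2 + mj + 1L] - f[b2 + 1L]
    }
  }
  if (length(xs) == 0) stop("empty pair set for gamma(n, d)")
  x <- unlist(xs)
  y <- unlist(ys)
  if (.degenerate(x) || .degenerate(y)) return(NA_real_)
  stats::cor(x, y)
}

# Effect vectors whose variation is pure rounding noise count as
# constant, so degenerate correlations are reported missing.
#' @keywords internal
.degenerate <- function(x) {
  stats::sd(x) <= 1e-9 * max(abs(x), 1e-300)
}

#' Slope-to-roughness funneling ratio
#'
#' Fits the closest additive landscape `F_a(s) = sum_i h_i^(a) s_i` by
#' least squares (after re-referencing so the wild-type genotype has zero
#' fitness), and returns the mean slope `s = L^-1 sum_i |h_i^(a)|`, the
#' roughness `r = sqrt(2^-L sum_s (F - F_a)^2)` and the ratio `s/r`
#' (`Inf` when the landscape is exactly additive).  A large s/r indicates
#' a smooth, Mt. Fuji-like (inverted-funnel) global shape.
#'
#' @param ls A `fitness_landscape`.
#' @param re_reference Shift fitness so the germline is 0 before fitting
#'   (default `TRUE`).
#' @return A list with `slope`, `roughness`, `ratio` and the additive fit
#'   `h_additive`.
#' @export
slope_roughness <- function(ls, re_reference = TRUE) {
  stopifnot(inherits(ls, "fitness_landscape"))
  L <- ls$L
  f <- ls$fitness
  if (re_reference) f <- f - f[1]
  X <- genotype_bits(0:(2^L - 1), L)
  fit <- stats::lm.fit(X, f)
  h <- fit$coefficients
  s <- mean(abs(h))
  r <- sqrt(mean(fit$residuals^2))
  # exact additive fits leave only rounding noise in the residuals
  exact <- r <= 1e-10 * max(diff(range(f)), 1e-300)
  list(slope = s, roughness = r,
       ratio = if (exact) Inf else s / r,
       h_additive = as.numeric(h))
}

#' Distribution of fitness effects of single mutations from a genotype
#'
#' @param ls A `fitness_landscape`.
#' @param g Genotype as bits (length L) or a single integer code.
#' @return Numeric vector of length L: `Delta F` for flipping each site.
#' @export
dfe <- function(ls, g) {
  stopifnot(inherits(ls, "fitness_landscape"))
  L <- ls$L
  code <- if (length(g) == L && all(g %in% c(0, 1))) genotype_code(g)
          else if (length(g) == 1L) as.integer(g)
          else stop("g must be a length-L 0/1 vector or a single genotype code")
  stats::setNames(ls$fitness[.neighbor_codes(code, L) + 1L] - ls$fitness[code + 1L],
                  ls$site_labels)
}

#' Pairwise summary of triplet interactions, K_ij.
#'
#' `K_ij. = (L - 2)^-1 sum_{k != i,j} |K_ijk|`, a symmetric nonnegative
#' matrix, plus the per-site row mean used to locate hotspots of
#' third-order epistasis.
#'
#' @param coef An `epistasis_coefficients` object.
#' @return A list with matrix `K_pair` (L x L, `NA` diagonal) and vector
#'   `K_site` of row means.
#' @export
kij_summary <- function(coef) {
  stopifnot(inherits(coef, "epistasis_coefficients"))
  L <- coef$L
  Kfull <- array(0, dim = c(L, L, L))
  idx <- which(coef$K != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- sort(idx[r, ])
    v <- abs(coef$K[idx[r, 1], idx[r, 2], idx[r, 3]])
    perms <- rbind(c(p[1], p[2], p[3]), c(p[1], p[3], p[2]), c(p[2], p[1], p[3]),
                   c(p[2], p[3], p[1]), c(p[3], p[1], p[2]), c(p[3], p[2], p[1]))
    Kfull[perms] <- v
  }
  K_pair <- matrix(NA_real_, L, L,
                   dimnames = list(coef$site_labels, coef$site_labels))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    ks <- setdiff(seq_len(L), c(i, j))
    K_pair[i, j] <- mean(Kfull[i, j, ks])
  }
  list(K_pair = K_pair,
       K_site = rowMeans(K_pair, na.rm = TRUE))
}

#' Tidy table of a gamma matrix
#'
#' @param gm Matrix from [gamma_directed()].
#' @return Data frame with columns `i`, `j`, `gamma` (missing entries
#'   excluded).
#' @export
gamma_table <- function(gm) {
  df <- expand.grid(i = rownames(gm), j = colnames(gm),
                    stringsAsFactors = FALSE)
  df$gamma <- as.vector(gm)
  df[!is.na(df$gamma), , drop = FALSE]
}
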