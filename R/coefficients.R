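# Specific-epistasis (Ising-type) coefficient sets: additive fields h_i,
# pairwise couplings J_ij and triplet couplings K_ijk acting on {0,1} spins,
# so the germline (all-wild-type) genotype always has zero fitness.

#' Construct a specific-epistasis coefficient set
#'
#' Represents the truncated interaction expansion
#' `F(s) = sum_i h_i s_i + sum_{i<j} J_ij s_i s_j + sum_{i<j<k} K_ijk s_i s_j s_k`
#' over biallelic sites (`s_i = 1` when site i is mutated).
#'
#' @param h Numeric vector of L additive effects.
#' @param J Optional pairwise couplings: an `L x L` matrix (upper triangle
#'   used) or NULL for none.
#' @param K Optional triplet couplings: an `L x L x L` array (entries with
#'   `i < j < k` used) or NULL for none.
#' @param site_labels Optional site labels.
#' @param extra Optional data frame with columns `code`, `value` carrying
#'   interaction terms of order > 3 (subset bitmask codes); used when a
#'   cross-validated fit selects order 4.
#' @return An object of class `epistasis_coefficients`.
#' @export
epistasis_coefficients <- function(h, J = NULL, K = NULL, site_labels = NULL,
                                   extra = NULL) {
  L <- length(h)
  if (is.null(J)) J <- matrix(0, L, L)
  if (is.null(K)) K <- array(0, dim = c(L, L, L))
  stopifnot(identical(dim(J), c(L, L)), identical(dim(K), c(L, L, L)))
  # canonicalize: keep only strictly increasing index tuples
  Jc <- matrix(0, L, L)
  Jc[upper.tri(Jc)] <- J[upper.tri(J)]
  Kc <- array(0, dim = c(L, L, L))
  for (i in seq_len(L)) for (j in seq_len(L)) for (k in seq_len(L)) {
    if (i < j && j < k) Kc[i, j, k] <- K[i, j, k]
  }
  if (is.null(site_labels)) site_labels <- as.character(seq_len(L))
  max_order <- if (!is.null(extra) && nrow(extra) > 0) {
    max(.popcount(extra$code))
  } else if (any(Kc != 0)) 3L else if (any(Jc != 0)) 2L else 1L
  structure(list(L = L, site_labels = as.character(site_labels),
                 h = as.numeric(h), J = Jc, K = Kc, extra = extra,
                 max_order = as.integer(max_order)),
            class = "epistasis_coefficients")
}

#' @export
print.epistasis_coefficients <- function(x, ...) {
  cat(sprintf("Specific-epistasis coefficients: L = %d, max order %d\n",
              x$L, x$max_order))
  cat(sprintf("  nonzero terms: %d h, %d J, %d K\n",
              sum(x$h != 0), sum(x$J != 0), sum(x$K != 0)))
  invisible(x)
}

#' Evaluate the specific-epistasis model at genotypes
#'
#' @param coef An `epistasis_coefficients` object.
#' @param g A genotype (0/1 vector of length L) or a matrix of genotypes,
#'   one per row.
#' @return Numeric fitness value(s); the germline evaluates to exactly 0.
#' @export
evaluate_specific <- function(coef, g) {
  stopifnot(inherits(coef, "epistasis_coefficients"))
  L <- coef$L
  if (!is.matrix(g)) g <- matrix(g, nrow = 1)
  if (ncol(g) != L) stop("corrupt coefficients or genotype: expected ", L, " sites")
  tay <- .taylor_vector(coef)
  codes <- genotype_code(g)
  f <- .zeta_transform(tay, L)
  f[codes + 1L]
}

#' Dense Taylor ({0,1}-basis) coefficient vector indexed by subset code.
#' @keywords internal
.taylor_vector <- function(coef) {
  L <- coef$L
  tay <- numeric(2^L)
  tay[bitwShiftL(1L, seq_len(L) - 1L) + 1L] <- coef$h
  ij <- which(coef$J != 0, arr.ind = TRUE)
  if (nrow(ij) > 0) {
    codes <- bitwShiftL(1L, ij[, 1] - 1L) + bitwShiftL(1L, ij[, 2] - 1L)
    tay[codes + 1L] <- coef$J[ij]
  }
  ijk <- which(coef$K != 0, arr.ind = TRUE)
  if (nrow(ijk) > 0) {
    codes <- bitwShiftL(1L, ijk[, 1] - 1L) + bitwShiftL(1L, ijk[, 2] - 1L) +
      bitwShiftL(1L, ijk[, 3] - 1L)
    tay[codes + 1L] <- coef$K[ijk]
  }
  if (!is.null(coef$extra) && nrow(coef$extra) > 0) {
    tay[coef$extra$code + 1L] <- coef$extra$value
  }
  tay
}

# Zeta transform over the subset lattice: given Taylor coefficients c_T,
# returns f(S) = sum_{T subseteq S} c_T, i.e. the fitness table.
#' @keywords internal
.zeta_transform <- function(a, L) {
  for (b in seq_len(L) - 1L) {
    bit <- bitwShiftL(1L, b)
    pos <- which(bitwAnd(0:(length(a) - 1L), bit) > 0L)
    a[pos] <- a[pos] + a[pos - bit]
  }
  a
}

# Moebius transform (inverse of .zeta_transform): Taylor coefficients from
# a complete fitness table.
#' @keywords internal
.mobius_transform <- function(f, L) {
  for (b in seq_len(L) - 1L) {
    bit <- bitwShiftL(1L, b)
    pos <- which(bitwAnd(0:(length(f) - 1L), bit) > 0L)
    f[pos] <- f[pos] - f[pos - bit]
  }
  f
}

#' Build a complete landscape from specific-epistasis coefficients
#'
#' @param coef An `epistasis_coefficients` object.
#' @return A `fitness_landscape` with `F(germline) = 0`.
#' @export
landscape_from_coefficients <- function(coef) {
  stopifnot(inherits(coef, "epistasis_coefficients"))
  f <- .zeta_transform(.taylor_vector(coef), coef$L)
  fitness_landscape(f, site_labels = coef$site_labels)
}

#' Exact interaction coefficients of a complete landscape
#'
#' Moebius-inverts the fitness table into the {0,1}-basis (Taylor)
#' interaction expansion.  The germline fitness appears as the order-0
#' constant and is dropped with a warning when nonzero.
#'
#' @param ls A `fitness_landscape`.
#' @param max_order Keep terms up to this order; higher-order terms above
#'   `tol` raise an error unless `drop_higher = TRUE`.
#' @param drop_higher Silently discard terms of order > `max_order`.
#' @param tol Magnitude below which higher-order terms count as zero.
#' @return An `epistasis_coefficients` object.
#' @export
coefficients_from_landscape <- function(ls, max_order = 3, drop_higher = FALSE,
                                        tol = 1e-9) {
  stopifnot(inherits(ls, "fitness_landscape"))
  L <- ls$L
  tay <- .mobius_transform(ls$fitness, L)
  ord <- .popcount(0:(2^L - 1))
  if (abs(tay[1]) > tol) {
    warning("germline fitness ", signif(tay[1], 4),
            " is nonzero; constant term dropped")
  }
  hi <- which(ord > max_order & abs(tay) > tol)
  if (length(hi) > 0 && !drop_higher) {
    stop("landscape has ", length(hi), " interaction term(s) above order ",
         max_order, "; rerun with drop_higher = TRUE to truncate")
  }
  h <- tay[bitwShiftL(1L, seq_len(L) - 1L) + 1L]
  J <- matrix(0, L, L)
  K <- array(0, dim = c(L, L, L))
  for (code in which(ord == 2L) - 1L) {
    s <- which(genotype_bits(code, L)[1, ] == 1L)
    J[s[1], s[2]] <- tay[code + 1L]
  }
  if (max_order >= 3) {
    for (code in which(ord == 3L) - 1L) {
      s <- which(genotype_bits(code, L)[1, ] == 1L)
      K[s[1], s[2], s[3]] <- tay[code + 1L]
    }
  }
  extra <- NULL
  if (max_order >= 4) {
    sel <- which(ord >= 4L & ord <= max_order & abs(tay) > tol)
    if (length(sel) > 0) {
      extra <- data.frame(code = sel - 1L, value = tay[sel])
    }
  }
  epistasis_coefficients(h, J, K, site_labels = ls$site_labels, extra = extra)
}

#' Serialize coefficients to structured text (JSON)
#'
#' Writes `{"L":..., "site_labels":[...], "h":{site:val}, "J":{"i,j":val},
#' "K":{"i,j,k":val}}` keyed by site labels.
#'
#' @param coef An `epistasis_coefficients` object.
#' @param path Output file path.
#' @export
write_coefficients <- function(coef, path) {
  stopifnot(inherits(coef, "epistasis_coefficients"))
  lab <- coef$site_labels
  hj <- as.list(coef$h)
  names(hj) <- lab
  ij <- which(coef$J != 0, arr.ind = TRUE)
  Jl <- as.list(coef$J[ij])
  names(Jl) <- apply(ij, 1, function(r) paste(lab[r], collapse = ","))
  ijk <- which(coef$K != 0, arr.ind = TRUE)
  Kl <- as.list(coef$K[ijk])
  names(Kl) <- apply(ijk, 1, function(r) paste(lab[r], collapse = ","))
  obj <- list(L = coef$L, site_labels = lab, h = hj, J = Jl, K = Kl)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read coefficients written by [write_coefficients()]
#'
#' @param path Input file path.
#' @return An `epistasis_coefficients` object.
#' @export
read_coefficients <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  L <- obj$L
  lab <- unlist(obj$site_labels)
  h <- numeric(L)
  h[match(names(obj$h), lab)] <- unlist(obj$h)
  J <- matrix(0, L, L)
  for (key in names(obj$J)) {
    s <- sort(match(strsplit(key, ",")[[1]], lab))
    J[s[1], s[2]] <- obj$J[[key]]
  }
  K <- array(0, dim = c(L, L, L))
  for (key in names(obj$K)) {
    s <- sort(match(strsplit(key, ",")[[1]], lab))
    K[s[1], s[2], s[3]] <- obj$K[[key]]
  }
  epistasis_coefficients(h, J, K, site_labels = lab)
}
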