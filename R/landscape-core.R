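# Genotype-space combinatorics and containers for combinatorially complete
# biallelic fitness landscapes.
#
# Genotypes over L sites (0 = wild-type, 1 = mutated) are represented either
# as a 0/1 integer vector of length L ("bits", site 1 first) or as the
# integer code sum(bits * 2^(site - 1)) in [0, 2^L).  Site 1 is the least
# significant bit, so the fitness table of a complete landscape is a plain
# numeric vector indexed by code + 1.  Bitstrings in files list sites
# left-to-right in site_labels order, i.e. character p is site p.

#' Convert genotype bits to an integer code
#'
#' Site 1 maps to the least significant bit.
#'
#' @param bits Integer (0/1) vector of length L, or a matrix with one
#'   genotype per row.
#' @return Integer code(s) in `[0, 2^L)`.
#' @export
genotype_code <- function(bits) {
  if (is.matrix(bits)) {
    L <- ncol(bits)
    return(as.integer(bits %*% 2^(seq_len(L) - 1)))
  }
  as.integer(sum(bits * 2^(seq_along(bits) - 1)))
}

#' Convert integer codes to genotype bits
#'
#' @param code Integer vector of genotype codes.
#' @param L Number of sites.
#' @return An integer matrix with `length(code)` rows and `L` columns.
#' @export
genotype_bits <- function(code, L) {
  stopifnot(all(code >= 0), all(code < 2^L))
  m <- vapply(seq_len(L) - 1L,
              function(b) bitwAnd(bitwShiftR(as.integer(code), b), 1L),
              integer(length(code)))
  matrix(as.integer(m), nrow = length(code), ncol = L)
}

#' @keywords internal
.popcount <- function(x) {
  x <- as.integer(x)
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Hamming distance between genotype codes
#'
#' @param a,b Integer genotype codes (vectorized).
#' @return Integer vector of distances.
#' @export
hamming_distance <- function(a, b) .popcount(bitwXor(as.integer(a), as.integer(b)))

#' All Hamming-1 neighbors of a genotype
#'
#' @param g Genotype as a 0/1 vector of length `L`.
#' @param L Number of sites (defaults to `length(g)`).
#' @return An `L x L` integer matrix, one neighbor per row (row i flips
#'   site i).
#' @export
mutational_neighbors <- function(g, L = length(g)) {
  if (length(g) != L) {
    stop("malformed genotype: length ", length(g), " does not match L = ", L)
  }
  if (!all(g %in% c(0L, 1L))) stop("malformed genotype: entries must be 0 or 1")
  nb <- matrix(rep(as.integer(g), each = L), nrow = L, ncol = L)
  idx <- cbind(seq_len(L), seq_len(L))
  nb[idx] <- 1L - nb[idx]
  nb
}

#' @keywords internal
.neighbor_codes <- function(code, L) {
  bitwXor(as.integer(code), bitwShiftL(1L, seq_len(L) - 1L))
}

#' Neighbor index matrix for a complete landscape
#'
#' Row g+1, column i holds 1-based index of the genotype obtained by
#' flipping site i of code g.
#' @keywords internal
.neighbor_matrix <- function(L) {
  codes <- 0:(2^L - 1)
  m <- vapply(seq_len(L) - 1L,
              function(b) bitwXor(codes, bitwShiftL(1L, b)),
              integer(2^L))
  matrix(m + 1L, nrow = 2^L, ncol = L)
}

#' Construct a complete fitness landscape
#'
#' @param fitness Numeric vector of length `2^L`; element `code + 1` is the
#'   fitness of the genotype with that integer code.  The germline
#'   (all-wild-type) genotype is code 0.
#' @param site_labels Optional character labels for the L sites (defaults to
#'   `"1"..."L"`).
#' @param L Number of sites; inferred from `length(fitness)` by default.
#' @return An object of class `fitness_landscape`.
#' @export
fitness_landscape <- function(fitness, site_labels = NULL, L = NULL) {
  n <- length(fitness)
  if (is.null(L)) L <- as.integer(round(log2(n)))
  if (n != 2^L || n < 2) {
    stop("incomplete landscape: fitness table has ", n,
         " entries, expected 2^L = ", 2^L)
  }
  if (anyNA(fitness) || !is.numeric(fitness)) {
    stop("fitness values must be numeric and non-missing")
  }
  if (is.null(site_labels)) site_labels <- as.character(seq_len(L))
  if (length(site_labels) != L) stop("site_labels must have length L")
  structure(list(L = L, site_labels = as.character(site_labels),
                 fitness = as.numeric(fitness)),
            class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("Complete fitness landscape: L = %d (%d genotypes)\n",
              x$L, 2^x$L))
  cat("  sites:    ", paste(x$site_labels, collapse = " "), "\n")
  cat(sprintf("  germline: F = %.4g\n", x$fitness[1]))
  gm <- which.max(x$fitness) - 1L
  cat(sprintf("  Fmax:     F = %.4g at %s (%d mutations)\n",
              max(x$fitness), paste(genotype_bits(gm, x$L)[1, ], collapse = ""),
              .popcount(gm)))
  invisible(x)
}

#' Genotype code of the global fitness maximum
#'
#' @param ls A `fitness_landscape`.
#' @return Integer code of the fittest genotype (first one on exact ties).
#' @export
global_optimum <- function(ls) {
  stopifnot(inherits(ls, "fitness_landscape"))
  which.max(ls$fitness) - 1L
}

#' Census of local fitness optima
#'
#' A local optimum is a genotype strictly fitter than each of its L
#' Hamming-1 neighbors ("no gain or loss of a mutation is able to increase
#' fitness").  Exact ties with a neighbor disqualify a genotype and raise a
#' warning, since for continuous fitness they indicate a degenerate table.
#'
#' @param ls A `fitness_landscape`.
#' @return Sorted integer vector of genotype codes of all local optima
#'   (the global optimum is always among them when it is unique).
#' @export
find_local_optima <- function(ls) {
  stopifnot(inherits(ls, "fitness_landscape"))
  L <- ls$L
  f <- ls$fitness
  nb <- .neighbor_matrix(L)
  fn <- matrix(f[nb], nrow = 2^L, ncol = L)
  nb_max <- do.call(pmax, as.data.frame(fn))
  strict <- f > nb_max
  weak <- !strict & f >= nb_max
  if (any(weak)) {
    warning(sum(weak), " genotype(s) tie a neighbor's fitness; ",
            "excluded from the optimum census")
  }
  sort(which(strict) - 1L)
}

#' Project a landscape onto a sublandscape by pinning sites
#'
#' Pins `n` sites to fixed states and returns the induced landscape over
#' the remaining `L - n` free sites.  The induced fitness of a free-site
#' genotype equals the parent fitness of the composed genotype.
#'
#' @param ls A `fitness_landscape`.
#' @param pinned Named integer vector mapping site index (1-based, or site
#'   label if names are labels) to state 0/1.  An empty vector returns a
#'   copy of the parent.
#' @return A `fitness_landscape` over the free sites with class
#'   `c("sublandscape", "fitness_landscape")` and fields `parent_L`,
#'   `pinned_sites`, `pinned_states`, `free_sites`.
#' @export
project_sublandscape <- function(ls, pinned) {
  stopifnot(inherits(ls, "fitness_landscape"))
  L <- ls$L
  if (length(pinned) == 0) return(ls)
  sites <- names(pinned)
  if (is.null(sites)) stop("pinned must be a named vector (site -> state)")
  idx <- suppressWarnings(as.integer(sites))
  if (anyNA(idx) || !all(idx %in% seq_len(L))) {
    idx <- match(sites, ls$site_labels)
    if (anyNA(idx)) stop("unknown pinned site(s): ", paste(sites, collapse = ", "))
  }
  if (anyDuplicated(idx)) stop("pinned sites must be distinct")
  states <- as.integer(pinned)
  if (!all(states %in% c(0L, 1L))) stop("pinned states must be 0 or 1")
  if (length(idx) >= L) stop("degenerate subspace: all ", L, " sites pinned")
  free <- setdiff(seq_len(L), idx)
  base_code <- sum(2^(idx - 1L) * states)
  m <- length(free)
  sub_codes <- genotype_bits(0:(2^m - 1), m) %*% 2^(free - 1L) + base_code
  out <- fitness_landscape(ls$fitness[sub_codes + 1L],
                           site_labels = ls$site_labels[free])
  out$parent_L <- L
  out$pinned_sites <- idx
  out$pinned_states <- states
  out$free_sites <- free
  class(out) <- c("sublandscape", "fitness_landscape")
  out
}

#' Purely additive landscape from single-site effects
#'
#' @param h Numeric vector of additive effects (length L).
#' @param site_labels Optional site labels.
#' @return A `fitness_landscape` with `F(s) = sum_i h_i s_i`.
#' @export
make_additive_landscape <- function(h, site_labels = NULL) {
  L <- length(h)
  bits <- genotype_bits(0:(2^L - 1), L)
  fitness_landscape(as.numeric(bits %*% h), site_labels = site_labels)
}
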