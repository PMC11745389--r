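# Strong-selection weak-mutation (SSWM) adaptive walks as an absorbing
# Markov chain over genotype space.  From each non-optimal genotype the
# walk moves to a Hamming-1 neighbor with probability proportional to the
# positive fitness increment (local optima are absorbing), and absorption
# probabilities follow from the fundamental matrix.

#' Build the SSWM transition matrix of a landscape
#'
#' Transition probability from genotype s to neighbor s' is
#' `max(F(s') - F(s), 0)` normalized over the beneficial neighbors of s;
#' local optima are absorbing.  Genotypes with no beneficial neighbor that
#' are not strict optima (tie plateaus) are treated as absorbing with a
#' warning.
#'
#' @param ls A `fitness_landscape`.
#' @param kernel `"delta"` (default, probability proportional to the
#'   fitness increment) or `"uniform"` (uniform over beneficial
#'   neighbors).
#' @return An object of class `sswm_chain`: dense matrix `P` (rows sum to
#'   1), integer codes `absorbing` and `transient`, and the landscape.
#' @export
build_transition_matrix <- function(ls, kernel = c("delta", "uniform")) {
  stopifnot(inherits(ls, "fitness_landscape"))
  kernel <- match.arg(kernel)
  L <- ls$L
  n <- 2^L
  f <- ls$fitness
  nb <- .neighbor_matrix(L)
  gain <- matrix(f[nb], n, L) - f          # DeltaF to each neighbor
  gain[gain < 0] <- 0
  if (kernel == "uniform") gain <- (gain > 0) * 1
  tot <- rowSums(gain)
  absorbing <- which(tot == 0)             # optima and tie plateaus
  strict <- find_local_optima(ls) + 1L
  plateau <- setdiff(absorbing, strict)
  if (length(plateau) > 0) {
    warning(length(plateau), " non-optimum genotype(s) without beneficial ",
            "neighbors treated as absorbing (fitness-tie plateau)")
  }
  P <- matrix(0, n, n)
  trans <- which(tot > 0)
  for (i in trans) {
    P[i, nb[i, ]] <- gain[i, ] / tot[i]
  }
  P[cbind(absorbing, absorbing)] <- 1
  structure(list(P = P, absorbing = absorbing - 1L, transient = trans - 1L,
                 L = L, landscape = ls, kernel = kernel),
            class = "sswm_chain")
}

#' Absorption probabilities of the SSWM chain
#'
#' Solves `(I - Q) B = R` for the absorption matrix, where Q connects the
#' transient states and R links them to the absorbing states.
#'
#' @param tm An `sswm_chain`.
#' @return Numeric matrix with one row per genotype (all `2^L`) and one
#'   column per absorbing state (named by its code): probability of
#'   absorbing there from that start.  Rows of absorbing states are
#'   indicator rows.
#' @export
absorbing_probabilities <- function(tm) {
  stopifnot(inherits(tm, "sswm_chain"))
  n <- 2^tm$L
  a <- tm$absorbing + 1L
  t_ <- tm$transient + 1L
  B <- matrix(0, n, length(a), dimnames = list(NULL, as.character(tm$absorbing)))
  B[cbind(a, seq_along(a))] <- 1
  if (length(t_) > 0) {
    Q <- tm$P[t_, t_, drop = FALSE]
    R <- tm$P[t_, a, drop = FALSE]
    B[t_, ] <- solve(diag(length(t_)) - Q, R)
  }
  B
}

#' Static accessibility of the global optimum
#'
#' The probability that an SSWM adaptive walk started at `from` absorbs at
#' the global fitness maximum rather than any other local optimum.
#'
#' @param ls A `fitness_landscape` or `sswm_chain`.
#' @param from Starting genotype code (default 0, the germline).
#' @return A single probability.
#' @export
static_accessibility <- function(ls, from = 0L) {
  tm <- if (inherits(ls, "sswm_chain")) ls else build_transition_matrix(ls)
  B <- absorbing_probabilities(tm)
  fmax <- global_optimum(tm$landscape)
  col <- match(as.character(fmax), colnames(B))
  if (is.na(col)) stop("global optimum is not an absorbing state")
  unname(B[from + 1L, col])
}

#' Sample SSWM adaptive walks
#'
#' @param tm An `sswm_chain`.
#' @param start Starting genotype code.
#' @param n Number of walks.
#' @param seed Seed.
#' @return A list of integer code sequences, each ending at an absorbing
#'   state.
#' @export
sswm_sample_walks <- function(tm, start = 0L, n = 1, seed = 1) {
  stopifnot(inherits(tm, "sswm_chain"))
  abs_set <- tm$absorbing
  .with_seed(seed, {
    lapply(seq_len(n), function(k) {
      path <- as.integer(start)
      cur <- as.integer(start)
      while (!(cur %in% abs_set)) {
        cur <- sample.int(2^tm$L, 1, prob = tm$P[cur + 1L, ]) - 1L
        path <- c(path, cur)
      }
      path
    })
  })
}

#' SSWM path ensemble to a target optimum
#'
#' Samples adaptive walks from `start` and collects those absorbed at
#' `target` into a weighted path ensemble (weights = relative frequency
#' among the retained walks).
#'
#' @param ls A `fitness_landscape` or `sswm_chain`.
#' @param target Target genotype code (default the global optimum).
#' @param n Number of sampled walks.
#' @param start Starting code (default germline).
#' @param seed Seed.
#' @return A `path_ensemble` (see [path_ensemble()]); `NULL` if no walk
#'   reaches the target.
#' @export
sswm_path_ensemble <- function(ls, target = NULL, n = 1000, start = 0L, seed = 1) {
  tm <- if (inherits(ls, "sswm_chain")) ls else build_transition_matrix(ls)
  if (is.null(target)) target <- global_optimum(tm$landscape)
  walks <- sswm_sample_walks(tm, start = start, n = n, seed = seed)
  hits <- Filter(function(p) p[length(p)] == target, walks)
  if (length(hits) == 0) return(NULL)
  path_ensemble(lapply(hits, mutational_path, L = tm$L),
                provenance = "sswm")
}
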