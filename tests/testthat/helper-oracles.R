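# Independent brute-force oracles and shared fixtures for the test suite.
# Oracles deliberately use naive enumeration, not the package's vectorized
# code paths.

random_landscape <- function(L, seed) {
  set.seed(seed)
  fitness_landscape(rnorm(2^L))
}

# Local optima by naive per-genotype neighbor comparison.
brute_force_optima <- function(ls) {
  L <- ls$L
  opt <- integer(0)
  for (code in 0:(2^L - 1)) {
    bits <- genotype_bits(code, L)[1, ]
    fn <- vapply(seq_len(L), function(i) {
      b <- bits
      b[i] <- 1L - b[i]
      ls$fitness[genotype_code(b) + 1]
    }, 0)
    if (all(ls$fitness[code + 1] > fn)) opt <- c(opt, code)
  }
  opt
}

# Directed gamma by naive loops over ordered pairs and backgrounds.
brute_force_gamma <- function(ls) {
  L <- ls$L
  f <- ls$fitness
  gm <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    xs <- ys <- numeric(0)
    for (code in 0:(2^L - 1)) {
      bits <- genotype_bits(code, L)[1, ]
      if (bits[i] != 0 || bits[j] != 0) next
      bj <- bits; bj[j] <- 1L
      bi <- bits; bi[i] <- 1L
      bij <- bi; bij[j] <- 1L
      xs <- c(xs, f[genotype_code(bj) + 1] - f[code + 1])
      ys <- c(ys, f[genotype_code(bij) + 1] - f[genotype_code(bi) + 1])
    }
    defined <- function(v) sd(v) > 1e-9 * max(abs(v), 1e-300)
    if (length(xs) >= 2 && defined(xs) && defined(ys)) gm[i, j] <- cor(xs, ys)
  }
  gm
}

# Pooled gamma(n, d) for one pinned choice, by naive loops.
brute_force_gamma_nd <- function(ls, set, states, d) {
  L <- ls$L
  f <- ls$fitness
  free <- setdiff(seq_len(L), set)
  xs <- ys <- numeric(0)
  for (code in 0:(2^L - 1)) {
    bits <- genotype_bits(code, L)[1, ]
    if (length(set) > 0 && !all(bits[set] == states)) next
    for (code2 in 0:(2^L - 1)) {
      bits2 <- genotype_bits(code2, L)[1, ]
      if (length(set) > 0 && !all(bits2[set] == states)) next
      if (sum(bits != bits2) != d) next
      for (j in free) {
        if (bits[j] != 0 || bits2[j] != 0) next
        bj <- bits; bj[j] <- 1L
        b2j <- bits2; b2j[j] <- 1L
        xs <- c(xs, f[genotype_code(bj) + 1] - f[code + 1])
        ys <- c(ys, f[genotype_code(b2j) + 1] - f[code2 + 1])
      }
    }
  }
  cor(xs, ys)
}

# Monte-Carlo absorption frequencies, walking all chains in lockstep.
mc_absorbing <- function(tm, start, n_walks, seed) {
  set.seed(seed)
  state <- rep(start, n_walks)
  absorbed <- state %in% tm$absorbing
  while (!all(absorbed)) {
    for (s in unique(state[!absorbed])) {
      idx <- which(state == s & !absorbed)
      state[idx] <- sample.int(2^tm$L, length(idx), replace = TRUE,
                               prob = tm$P[s + 1, ]) - 1L
    }
    absorbed <- state %in% tm$absorbing
  }
  table(factor(state, levels = tm$absorbing)) / n_walks
}

# All fitness-increasing self-avoiding paths start -> target with their
# exact SSWM probabilities (product of transition-matrix entries).
enumerate_sswm_paths <- function(tm, start, target) {
  out <- list()
  recurse <- function(path, prob) {
    cur <- path[length(path)]
    if (cur == target) {
      out[[length(out) + 1]] <<- list(path = path, prob = prob)
      return(invisible())
    }
    nxt <- which(tm$P[cur + 1, ] > 0) - 1L
    for (s in nxt) {
      if (s == cur) next
      recurse(c(path, s), prob * tm$P[cur + 1, s + 1])
    }
  }
  recurse(start, 1)
  out
}

# Shared heavyweight objects, computed once per test session.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

fixture_ls <- function() cached("fixture", antibody_fixture())

# The constrained NK(K=2) reference ensemble matched to the fixture
# topography (7 optima, germline-Fmax distance 8), shared between the
# slope/roughness comparison and the evolvability criterion.
nk_reference_ensemble <- function() {
  cached("nk_ens", constrained_nk_ensemble(10, 2, n_optima = 7, distance = 8,
                                           size = 50, seed = 20260901))
}
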