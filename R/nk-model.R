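# NK model landscapes: each of L sites interacts with K others, giving
# statistically homogeneous ruggedness tuned by K, plus rejection-sampled
# ensembles constrained to match a target topography (number of optima and
# germline-to-Fmax distance).

# Run code with a temporary RNG state seeded by `seed`.
#' @keywords internal
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Generate an NK landscape
#'
#' Each site i receives K interaction partners (sampled uniformly without
#' replacement by default) and a contribution table of i.i.d. uniform
#' `[0, 1)` values over the `2^(K+1)` local states.  Fitness is the mean
#' of site contributions, shifted so the germline (all-zeros) genotype has
#' zero fitness.  Deterministic given the seed.
#'
#' @param L Number of sites.
#' @param K Number of interaction partners per site, `0 <= K <= L - 1`.
#' @param seed Integer seed.
#' @param neighborhoods `"random"` (default) or `"adjacent"` (cyclic).
#' @param values `"uniform"` (default) or `"gaussian"` contribution draws.
#' @return A `fitness_landscape` with an `nk_spec` attribute recording the
#'   neighborhoods, contribution tables and seed.
#' @export
generate_nk <- function(L, K, seed, neighborhoods = c("random", "adjacent"),
                        values = c("uniform", "gaussian")) {
  if (K < 0 || K > L - 1) stop("invalid K: need 0 <= K <= L - 1")
  neighborhoods <- match.arg(neighborhoods)
  values <- match.arg(values)
  spec <- .with_seed(seed, {
    nb <- lapply(seq_len(L), function(i) {
      others <- setdiff(seq_len(L), i)
      if (K == 0) integer(0)
      else if (neighborhoods == "random") sort(others[sample.int(length(others), K)])
      else sort(((i - 1 + seq_len(K)) %% L) + 1L)
    })
    tabs <- lapply(seq_len(L), function(i) {
      if (values == "uniform") stats::runif(2^(K + 1)) else stats::rnorm(2^(K + 1))
    })
    list(L = L, K = K, neighborhoods = nb, tables = tabs, seed = seed,
         neighborhood_type = neighborhoods, value_type = values)
  })
  ls <- .nk_evaluate(spec)
  attr(ls, "nk_spec") <- spec
  ls
}

#' @keywords internal
.nk_evaluate <- function(spec) {
  L <- spec$L
  K <- spec$K
  bits <- genotype_bits(0:(2^L - 1), L)
  contrib <- matrix(0, nrow = 2^L, ncol = L)
  for (i in seq_len(L)) {
    loc <- bits[, c(i, spec$neighborhoods[[i]]), drop = FALSE]
    idx <- as.integer(loc %*% 2^(0:K)) + 1L
    contrib[, i] <- spec$tables[[i]][idx]
  }
  f <- rowMeans(contrib)
  fitness_landscape(f - f[1])
}

#' Serialize an NK specification for exact reproducibility
#' @param ls A landscape from [generate_nk()] (or its `nk_spec` attribute).
#' @param path Output JSON path.
#' @export
write_nk_spec <- function(ls, path) {
  spec <- if (inherits(ls, "fitness_landscape")) attr(ls, "nk_spec") else ls
  if (is.null(spec)) stop("no nk_spec attached to this landscape")
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rebuild an NK landscape from a serialized specification
#' @param path JSON path written by [write_nk_spec()].
#' @export
read_nk_spec <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_rows <- function(x, f) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) f(x[i, ]))
    else if (length(x) == 0) replicate(spec$L, f(integer(0)), simplify = FALSE)
    else lapply(x, f)
  }
  spec$neighborhoods <- as_rows(spec$neighborhoods, as.integer)
  spec$tables <- as_rows(spec$tables, as.numeric)
  ls <- .nk_evaluate(spec)
  attr(ls, "nk_spec") <- spec
  ls
}

#' Constrained NK ensemble by rejection sampling
#'
#' Draws NK landscapes and keeps those whose local-optima count and
#' germline-to-Fmax Hamming distance exactly match the targets, so that
#' only the location and height of optima may differ from the reference
#' topography.  Per-attempt seeds derive from `seed + attempt`, making the
#' accepted set reproducible and order-independent.
#'
#' @param L,K NK parameters.
#' @param n_optima Required number of local optima.
#' @param distance Required Hamming distance from germline to Fmax.
#' @param size Number of accepted landscapes.
#' @param seed Master seed.
#' @param max_attempts Attempt budget before giving up.
#' @param ... Passed to [generate_nk()].
#' @return A list of class `constrained_nk_ensemble`: `landscapes`,
#'   `attempts`, `acceptance_rate`, `complete` flag and the targets.
#' @export
constrained_nk_ensemble <- function(L, K, n_optima, distance, size,
                                    seed = 1, max_attempts = 1e5, ...) {
  kept <- vector("list", size)
  n_kept <- 0L
  attempt <- 0L
  while (n_kept < size && attempt < max_attempts) {
    attempt <- attempt + 1L
    ls <- generate_nk(L, K, seed = seed + attempt, ...)
    opt <- find_local_optima(ls)
    if (length(opt) != n_optima) next
    if (.popcount(global_optimum(ls)) != distance) next
    n_kept <- n_kept + 1L
    kept[[n_kept]] <- ls
  }
  complete <- n_kept == size
  if (!complete) {
    warning("constrained ensemble incomplete: ", n_kept, "/", size,
            " accepted in ", attempt, " attempts")
  }
  structure(list(landscapes = kept[seq_len(n_kept)],
                 target_optima = n_optima, target_distance = distance,
                 attempts = attempt,
                 acceptance_rate = n_kept / attempt,
                 complete = complete, L = L, K = K, seed = seed),
            class = "constrained_nk_ensemble")
}

#' @export
print.constrained_nk_ensemble <- function(x, ...) {
  cat(sprintf("Constrained NK ensemble: %d landscapes (L=%d, K=%d)\n",
              length(x$landscapes), x$L, x$K))
  cat(sprintf("  targets: %d optima, germline-Fmax distance %d\n",
              x$target_optima, x$target_distance))
  cat(sprintf("  acceptance: %.4f (%d attempts)%s\n", x$acceptance_rate,
              x$attempts, if (x$complete) "" else "  [INCOMPLETE]"))
  invisible(x)
}
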