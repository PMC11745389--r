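# Seeded 2D embeddings of genotype space.  Landscapes are embedded with a
# force-directed layout of the hypercube graph whose edge weights are
# inversely related to the fitness difference of mutational neighbors,
# w_ss' = (0.001 + |F(s) - F(s')|)^-1, so genotypes of similar fitness
# cluster together.  Realized paths are embedded with t-SNE on the
# Hamming-distance matrix.

#' Fitness-similarity graph of a complete landscape
#'
#' Nodes are the 2^L genotypes; edges connect mutational neighbors with
#' weight `(0.001 + |Delta F|)^-1`.
#'
#' @param ls A `fitness_landscape`.
#' @param eps Offset guarding against division by zero (default 0.001).
#' @return An `igraph` graph with vertex attribute `code` and `fitness`
#'   and edge attribute `weight`.
#' @export
build_similarity_graph <- function(ls, eps = 0.001) {
  stopifnot(inherits(ls, "fitness_landscape"))
  L <- ls$L
  n <- 2^L
  codes <- 0:(n - 1)
  from <- integer(0)
  to <- integer(0)
  for (b in seq_len(L) - 1L) {
    lo <- codes[bitwAnd(codes, bitwShiftL(1L, b)) == 0L]
    from <- c(from, lo)
    to <- c(to, bitwXor(lo, bitwShiftL(1L, b)))
  }
  w <- 1 / (eps + abs(ls$fitness[from + 1L] - ls$fitness[to + 1L]))
  g <- igraph::graph_from_edgelist(cbind(from + 1L, to + 1L), directed = FALSE)
  igraph::E(g)$weight <- w
  igraph::V(g)$code <- codes
  igraph::V(g)$fitness <- ls$fitness
  g
}

#' Seeded force-directed layout
#'
#' Runs a weighted Fruchterman-Reingold layout under a fixed seed;
#' identical inputs and seed give identical coordinates within a run
#' environment.
#'
#' @param graph An `igraph` graph with edge weights (see
#'   [build_similarity_graph()]).
#' @param seed Integer seed fixing the layout's randomness.
#' @param niter Iterations of the layout engine.
#' @return An `embedding_layout`: data frame (`code`, `x`, `y`) plus
#'   `method` and `seed` fields.
#' @export
force_directed_layout <- function(graph, seed = 1, niter = 500) {
  xy <- .with_seed(seed, igraph::layout_with_fr(graph, niter = niter,
                                                weights = igraph::E(graph)$weight))
  code <- igraph::V(graph)$code
  if (is.null(code)) code <- seq_len(igraph::vcount(graph)) - 1L
  structure(list(coords = data.frame(code = code, x = xy[, 1], y = xy[, 2]),
                 method = "force_directed", seed = seed),
            class = "embedding_layout")
}

#' @export
print.embedding_layout <- function(x, ...) {
  cat(sprintf("2D embedding (%s, seed %d): %d nodes\n",
              x$method, x$seed, nrow(x$coords)))
  invisible(x)
}

#' Rigid alignment of one layout onto another
#'
#' Least-squares translation + rotation (2D orthogonal Procrustes
#' restricted to proper rotations; no reflection, no scaling) of layout B
#' onto layout A over a shared node set.  For reflection-related clouds
#' the residual stays positive since no reflection is applied.
#'
#' @param A,B `embedding_layout` objects.
#' @param shared Codes present in both layouts (default: intersection).
#' @param allow_reflection Permit an improper rotation (default `FALSE`).
#' @return A list: `layout` (B transformed, all nodes), `rotation`,
#'   `translation`, `residual` (RMS distance over shared nodes).
#' @export
align_layouts <- function(A, B, shared = NULL, allow_reflection = FALSE) {
  stopifnot(inherits(A, "embedding_layout"), inherits(B, "embedding_layout"))
  if (is.null(shared)) shared <- intersect(A$coords$code, B$coords$code)
  if (length(shared) < 2) stop("underdetermined alignment: fewer than 2 shared nodes")
  pa <- as.matrix(A$coords[match(shared, A$coords$code), c("x", "y")])
  pb <- as.matrix(B$coords[match(shared, B$coords$code), c("x", "y")])
  ca <- colMeans(pa)
  cb <- colMeans(pb)
  H <- crossprod(sweep(pb, 2, cb), sweep(pa, 2, ca))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- if (allow_reflection) diag(2) else diag(c(1, d))
  R <- sv$v %*% D %*% t(sv$u)
  all_b <- as.matrix(B$coords[, c("x", "y")])
  newxy <- sweep(sweep(all_b, 2, cb) %*% t(R), 2, ca, "+")
  out <- B
  out$coords$x <- newxy[, 1]
  out$coords$y <- newxy[, 2]
  res <- sqrt(mean(rowSums((sweep(sweep(pb, 2, cb) %*% t(R), 2, ca, "+") - pa)^2)))
  list(layout = out, rotation = R, translation = ca - as.numeric(cb %*% t(R)),
       residual = res)
}

#' t-SNE embedding of genotypes visited by paths
#'
#' Embeds the distinct genotypes of a path collection in 2D by t-SNE with
#' the Hamming distance as the metric.  Seeded and deterministic.
#'
#' @param paths A `path_ensemble`, list of `mutational_path` objects, or
#'   integer vector of genotype codes.
#' @param L Number of sites (required when `paths` is a bare code vector).
#' @param perplexity t-SNE perplexity (default 30, capped at
#'   `(n - 1) / 3`).
#' @param seed Integer seed.
#' @param max_iter Gradient-descent iterations.
#' @return An `embedding_layout` with one row per distinct genotype.
#' @export
tsne_paths <- function(paths, L = NULL, perplexity = 30, seed = 1,
                       max_iter = 400) {
  if (inherits(paths, "path_ensemble")) {
    L <- paths$paths[[1]]$L
    codes <- sort(unique(unlist(lapply(paths$paths, `[[`, "codes"))))
  } else if (is.list(paths)) {
    L <- paths[[1]]$L
    codes <- sort(unique(unlist(lapply(paths, `[[`, "codes"))))
  } else {
    if (is.null(L)) stop("L is required for a bare code vector")
    codes <- sort(unique(as.integer(paths)))
  }
  n <- length(codes)
  if (n < 3) stop("degenerate input: need at least 3 distinct genotypes")
  D <- outer(codes, codes, function(a, b) hamming_distance(a, b))
  xy <- .with_seed(seed, .tsne(D, perplexity = min(perplexity, (n - 1) / 3),
                               max_iter = max_iter))
  structure(list(coords = data.frame(code = codes, x = xy[, 1], y = xy[, 2]),
                 method = "tsne", seed = seed),
            class = "embedding_layout")
}

# Minimal exact t-SNE on a precomputed distance matrix (Barnes-Hut is
# unnecessary at the ensemble sizes used here).
#' @keywords internal
.tsne <- function(D, perplexity = 30, max_iter = 400, eta = 100) {
  n <- nrow(D)
  D2 <- D^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf
    hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p[] <- 1 / length(p) else p <- p / sp
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100) 4 else 1          # early exaggeration
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    G <- 0.8 * G - eta * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Write a layout table
#'
#' Tidy table `genotype, x, y, method, seed` in the package's bitstring
#' convention.
#'
#' @param layout An `embedding_layout`.
#' @param L Number of sites (for the genotype strings).
#' @param path Output TSV path.
#' @export
write_layout <- function(layout, L, path) {
  bits <- genotype_bits(layout$coords$code, L)
  df <- data.frame(genotype = apply(bits, 1, paste, collapse = ""),
                   x = layout$coords$x, y = layout$coords$y,
                   method = layout$method, seed = layout$seed)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
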