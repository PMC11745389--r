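# Mutational paths (lines of descent) and path-ensemble statistics:
# weights, scaled Gibbs-Shannon entropy, mutation-ordering probabilities,
# classification by the step of a focal (hotspot) mutation, and the
# stepwise distribution of fitness effects.

#' Construct a mutational path
#'
#' @param codes Integer genotype codes from germline to target; consecutive
#'   codes must differ at exactly one site.
#' @param L Number of sites.
#' @return An object of class `mutational_path` with fields `codes` and
#'   `events` (data frame: step, site, direction +1 forward / -1
#'   reversion).
#' @export
mutational_path <- function(codes, L) {
  codes <- as.integer(codes)
  if (length(codes) >= 2) {
    d <- hamming_distance(codes[-length(codes)], codes[-1])
    if (any(d != 1L)) stop("consecutive path genotypes must differ at exactly one site")
  }
  events <- if (length(codes) >= 2) {
    x <- bitwXor(codes[-length(codes)], codes[-1])
    site <- as.integer(log2(x)) + 1L
    dir <- ifelse(bitwAnd(codes[-1], x) > 0L, 1L, -1L)
    data.frame(step = seq_along(site), site = site, direction = dir)
  } else {
    data.frame(step = integer(0), site = integer(0), direction = integer(0))
  }
  structure(list(codes = codes, L = as.integer(L), events = events),
            class = "mutational_path")
}

#' @export
print.mutational_path <- function(x, ...) {
  cat(sprintf("Mutational path: %d steps (%d -> %d)\n",
              length(x$codes) - 1L, x$codes[1], x$codes[length(x$codes)]))
  invisible(x)
}

#' @keywords internal
.path_key <- function(path) paste(path$codes, collapse = "-")

#' Extract the line of descent to a target genotype
#'
#' Finds the first individual carrying `target`, follows parent pointers
#' back to generation 0, applies the lineage's mutation events in forward
#' order from the germline, and collapses consecutive identical genotypes.
#' Generations in which a lineage acquired several mutations are expanded
#' into consecutive single-site steps (in increasing site order); acquired
#' and later reverted mutations are retained as separate steps, so
#' indirect paths keep both flip events.
#'
#' @param traj A recorded `wf_trajectory` (`record = TRUE`).
#' @param target Target genotype code (default the landscape Fmax stored
#'   in the trajectory).
#' @return A `mutational_path`, or `NULL` if the target never appears.
#' @export
line_of_descent <- function(traj, target = NULL) {
  stopifnot(inherits(traj, "wf_trajectory"))
  if (is.null(traj$pop_history)) {
    stop("corrupted or absent event log: rerun wf_simulate(record = TRUE)")
  }
  if (is.null(target)) target <- traj$fmax
  hit <- which(traj$pop_history == target, arr.ind = TRUE)
  if (nrow(hit) == 0) return(NULL)
  first <- hit[which.min(hit[, 2]), ]
  node <- first[1]
  gen <- first[2] - 1L                       # column g+1 = generation g
  # walk back to generation 0 collecting this lineage's node index per gen
  lineage <- integer(gen + 1L)
  lineage[gen + 1L] <- node
  if (gen > 0) {
    for (g in gen:1) {
      node <- traj$parent_history[node, g + 1L]
      if (node < 1 || node > nrow(traj$parent_history)) {
        stop("corrupted event log: broken parent chain")
      }
      lineage[g] <- node
    }
  }
  ev <- traj$events
  codes <- as.integer(traj$pop_history[lineage[1], 1])
  cur <- codes
  if (gen > 0) {
    for (g in seq_len(gen)) {
      hits <- ev[ev$gen == g & ev$node == lineage[g + 1L], , drop = FALSE]
      for (site in sort(hits$site)) {
        cur <- bitwXor(cur, bitwShiftL(1L, site - 1L))
        codes <- c(codes, cur)
      }
    }
  }
  if (cur != target) stop("corrupted event log: lineage does not end at target")
  # collapse consecutive identical genotypes (no-op here since every event
  # flips, but kept for robustness)
  keep <- c(TRUE, diff(codes) != 0)
  mutational_path(codes[keep], traj$L)
}

#' Build a weighted path ensemble
#'
#' Distinct paths are identified by their exact genotype sequence; the
#' weight of a path is its relative frequency among the supplied paths.
#'
#' @param paths List of `mutational_path` objects (one per replicate that
#'   reached the target).
#' @param provenance Optional tag recording which dynamics generated the
#'   ensemble ("sswm", "wf", ...).
#' @return A `path_ensemble`: `paths` (unique), `weights` (sum to 1),
#'   `counts`, `n_total`, `provenance`.
#' @export
path_ensemble <- function(paths, provenance = NA_character_) {
  stopifnot(length(paths) > 0,
            all(vapply(paths, inherits, TRUE, "mutational_path")))
  keys <- vapply(paths, .path_key, "")
  tab <- table(keys)
  uniq <- paths[match(names(tab), keys)]
  structure(list(paths = uniq,
                 weights = as.numeric(tab) / length(paths),
                 counts = as.integer(tab),
                 n_total = length(paths),
                 provenance = provenance),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf("Path ensemble: %d distinct paths from %d replicates (%s)\n",
              length(x$paths), x$n_total, x$provenance))
  cat(sprintf("  scaled entropy: %.3f\n", path_entropy(x)))
  invisible(x)
}

#' Scaled Gibbs-Shannon path entropy
#'
#' `S = -sum_pi w_pi ln w_pi`, scaled by the maximum entropy `ln(m)`
#' attained when all `m` distinct realized paths have equal weight;
#' defined as 0 for a single path.
#'
#' @param ens A `path_ensemble`, or a bare numeric weight vector.
#' @return Scaled entropy in `[0, 1]`.
#' @export
path_entropy <- function(ens) {
  w <- if (inherits(ens, "path_ensemble")) ens$weights else as.numeric(ens)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("path weights must be nonnegative and sum to 1")
  }
  w <- w[w > 0]
  m <- length(w)
  if (m <= 1) return(0)
  -sum(w * log(w)) / log(m)
}

# First forward (0 -> 1) event step of each required site along a path,
# counting only forward events on required sites.
#' @keywords internal
.forward_order <- function(path, required_sites) {
  ev <- path$events
  fw <- ev[ev$direction == 1L & ev$site %in% required_sites, , drop = FALSE]
  fw <- fw[!duplicated(fw$site), , drop = FALSE]    # first forward per site
  ord <- fw$site[order(fw$step)]
  pos <- match(required_sites, ord)
  stats::setNames(pos, required_sites)
}

#' Mutation-ordering probability matrix P[t(i) < t(j)]
#'
#' Weight-averaged probability that site i's first forward mutation
#' precedes site j's along paths of the ensemble.  Paths missing a forward
#' event for any required site are excluded with a warning and the
#' remaining weights renormalized.
#'
#' @param ens A `path_ensemble`.
#' @param required_sites Integer site indices that every path must mutate.
#' @return A list: `P` (matrix with `NA` diagonal, `P[i,j] + P[j,i] = 1`)
#'   and `off_diagonal` (vector of the off-diagonal entries, for
#'   histogram summaries).
#' @export
ordering_probabilities <- function(ens, required_sites) {
  stopifnot(inherits(ens, "path_ensemble"))
  k <- length(required_sites)
  orders <- lapply(ens$paths, .forward_order, required_sites = required_sites)
  ok <- !vapply(orders, anyNA, TRUE)
  if (!all(ok)) {
    warning(sum(!ok), " path(s) missing a required site's forward mutation; ",
            "excluded and weights renormalized")
  }
  if (!any(ok)) stop("no path contains all required mutations")
  w <- ens$weights[ok] / sum(ens$weights[ok])
  orders <- orders[ok]
  P <- matrix(0, k, k, dimnames = list(required_sites, required_sites))
  for (p in seq_along(orders)) {
    o <- orders[[p]]
    P <- P + w[p] * outer(o, o, "<")
  }
  diag(P) <- NA_real_
  list(P = P, off_diagonal = P[row(P) != col(P)])
}

#' Classify paths by the step of the hotspot mutation
#'
#' The class of a path is the 1-based index of the step at which the
#' hotspot site first mutates forward, counted among the path's forward
#' mutation events on the required sites.
#'
#' @param ens A `path_ensemble`.
#' @param hotspot_site Integer site index of the hotspot.
#' @param required_sites Sites whose forward events define the step count
#'   (defaults to all sites mutated forward anywhere in the ensemble).
#' @return A data frame (one row per distinct path): `class`, `weight`,
#'   `n_paths` per class summary attached as attribute `by_class`
#'   (class, n_paths, total_weight, cumulative_weight).
#' @export
classify_by_hotspot_step <- function(ens, hotspot_site, required_sites = NULL) {
  stopifnot(inherits(ens, "path_ensemble"))
  if (is.null(required_sites)) {
    required_sites <- sort(unique(unlist(lapply(ens$paths, function(p) {
      p$events$site[p$events$direction == 1L]
    }))))
  }
  cls <- vapply(ens$paths, function(p) {
    ev <- p$events
    fw <- ev[ev$direction == 1L & ev$site %in% required_sites, , drop = FALSE]
    fw <- fw[!duplicated(fw$site), , drop = FALSE]
    pos <- which(fw$site[order(fw$step)] == hotspot_site)
    if (length(pos) == 0) NA_integer_ else as.integer(pos[1])
  }, 0L)
  if (anyNA(cls)) stop("hotspot must be mutated forward in every path")
  df <- data.frame(class = cls, weight = ens$weights)
  agg <- stats::aggregate(cbind(total_weight = weight) ~ class, df, sum)
  agg$n_paths <- as.integer(table(factor(df$class, levels = agg$class)))
  agg <- agg[order(agg$class), ]
  agg$cumulative_weight <- cumsum(agg$total_weight)
  attr(df, "by_class") <- agg
  df
}

#' Stepwise distribution of fitness effects along paths
#'
#' For each step index, collects `F(next) - F(current)` across the
#' ensemble's paths together with the path weights.
#'
#' @param ens A `path_ensemble`.
#' @param ls The `fitness_landscape` the paths live on.
#' @return A data frame: `step`, `delta_f`, `weight` (one row per path and
#'   step).
#' @export
stepwise_dfe <- function(ens, ls) {
  stopifnot(inherits(ens, "path_ensemble"), inherits(ls, "fitness_landscape"))
  rows <- lapply(seq_along(ens$paths), function(p) {
    codes <- ens$paths[[p]]$codes
    if (length(codes) < 2) return(NULL)
    df <- diff(ls$fitness[codes + 1L])
    data.frame(step = seq_along(df), delta_f = df, weight = ens$weights[p])
  })
  do.call(rbind, rows)
}

#' Wright-Fisher path ensemble from replicate simulations
#'
#' Runs `n_replicates` recorded simulations (per-replicate seeds derived
#' from the master seed), keeps those in which the target appears, and
#' builds the ensemble of lines of descent.
#'
#' @param ls A `fitness_landscape`.
#' @param cfg A `wf_config`.
#' @param n_replicates Number of replicate populations.
#' @param target Target genotype code (default Fmax).
#' @param require_success Only keep replicates that meet the success
#'   criterion of [success_rate()] (default `TRUE`: successful paths).
#' @return A `path_ensemble`, or `NULL` if no replicate qualifies.
#' @export
wf_path_ensemble <- function(ls, cfg, n_replicates = 100, target = NULL,
                             require_success = TRUE) {
  optima <- find_local_optima(ls)
  fmax <- global_optimum(ls)
  if (is.null(target)) target <- fmax
  fcol <- match(as.character(fmax), as.character(optima))
  paths <- list()
  for (k in seq_len(n_replicates)) {
    cfg_k <- cfg
    cfg_k$seed <- as.integer((cfg$seed + 7919 * k) %% 2147483647)
    traj <- wf_simulate(ls, cfg_k, record = TRUE,
                        stop_at_threshold = require_success, optima = optima)
    if (require_success) {
      last <- traj$occupancy[nrow(traj$occupancy), ]
      crossed <- which(last >= cfg$threshold)
      if (!(length(crossed) == 1 && crossed[1] == fcol)) next
    }
    p <- line_of_descent(traj, target)
    if (!is.null(p)) paths[[length(paths) + 1L]] <- p
  }
  if (length(paths) == 0) return(NULL)
  path_ensemble(paths, provenance = "wf")
}
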