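# Wright-Fisher dynamics on a ring lattice.  Each generation alternates
# (i) selection and migration: the individual at node i is replaced by a
# copy of node j in its r-neighborhood with probability
# exp(F(s_j)) / sum_k exp(F(s_k)), k in [i - r, i + r] (softmax computed
# with a global shift for overflow safety), and (ii) a mutation sweep in
# which every locus of every individual flips with probability mu.
# r = 2 gives a structured population, r = Npop a well-mixed one.

#' Wright-Fisher configuration
#'
#' @param npop Population size = number of ring nodes (default 500).
#' @param mu Per-locus per-generation flip probability (default 1e-3).
#' @param r Migration/competition neighborhood radius; 2 = structured,
#'   `npop` = well-mixed.
#' @param tmax Number of generations (default 2000).
#' @param threshold Occupancy fraction a genotype must reach for the
#'   success criterion, in (0, 1] (default 0.5).
#' @param seed Master seed.
#' @return A validated list of class `wf_config`.
#' @export
wf_config <- function(npop = 500, mu = 1e-3, r = 2, tmax = 2000,
                      threshold = 0.5, seed = 1) {
  if (r < 1 || r > npop) stop("config error: need 1 <= r <= npop")
  if (mu < 0 || mu > 1) stop("config error: need 0 <= mu <= 1")
  if (threshold <= 0 || threshold > 1) {
    stop("config error: threshold must be in (0, 1]")
  }
  if (tmax < 0) stop("config error: tmax must be >= 0")
  structure(list(npop = as.integer(npop), mu = mu, r = as.integer(r),
                 tmax = as.integer(tmax), threshold = threshold,
                 seed = as.integer(seed)),
            class = "wf_config")
}

# Precomputed per-run constants.
#' @keywords internal
.wf_setup <- function(ls, cfg) {
  npop <- cfg$npop
  r <- cfg$r
  well_mixed <- (2 * r + 1) >= npop
  NI <- NULL
  CUM <- NULL
  if (!well_mixed) {
    w <- 2 * r + 1
    NI <- outer(seq_len(npop) - 1L, -r:r, function(i, o) (i + o) %% npop) + 1L
    CUM <- upper.tri(matrix(0, w, w), diag = TRUE) * 1   # row-cumsum helper
  }
  list(wexp = exp(ls$fitness - max(ls$fitness)), NI = NI, CUM = CUM,
       well_mixed = well_mixed)
}

#' One Wright-Fisher generation
#'
#' Applies synchronous selection/migration then the mutation sweep, using
#' the current RNG state.  Exposed mainly for testing; simulations should
#' use [wf_simulate()].
#'
#' @param pop Integer vector of genotype codes, one per ring node.
#' @param ls A `fitness_landscape`.
#' @param cfg A `wf_config`.
#' @param setup Optional precomputed constants (internal).
#' @return A list: `pop` (next generation), `parents` (source node per
#'   node) and `events` (matrix with columns node, site of this
#'   generation's mutations).
#' @export
wf_step <- function(pop, ls, cfg, setup = NULL) {
  if (is.null(setup)) setup <- .wf_setup(ls, cfg)
  npop <- cfg$npop
  L <- ls$L
  w <- setup$wexp[pop + 1L]
  if (setup$well_mixed) {
    parents <- sample.int(npop, npop, replace = TRUE, prob = w)
  } else {
    W <- matrix(w[setup$NI], nrow = npop)
    cw <- W %*% setup$CUM
    u <- stats::runif(npop) * cw[, ncol(cw)]
    col <- rowSums(cw < u) + 1L
    parents <- setup$NI[cbind(seq_len(npop), col)]
  }
  pop <- pop[parents]
  events <- NULL
  if (cfg$mu > 0) {
    nmut <- stats::rbinom(1L, npop * L, cfg$mu)
    if (nmut > 0) {
      idx <- sample.int(npop * L, nmut)
      node <- (idx - 1L) %% npop + 1L
      site <- (idx - 1L) %/% npop + 1L
      pop[node] <- bitwXor(pop[node], bitwShiftL(1L, site - 1L))
      events <- cbind(node = node, site = site)
    }
  }
  list(pop = pop, parents = parents, events = events)
}

#' Simulate Wright-Fisher dynamics from an isogenic germline population
#'
#' Iterates [wf_step()] for `tmax` generations (or until an optimum first
#' reaches the occupancy threshold, if `stop_at_threshold`), recording the
#' occupancy of every local optimum each generation.  Deterministic given
#' `cfg$seed`.
#'
#' @param ls A `fitness_landscape`.
#' @param cfg A `wf_config`.
#' @param record Keep the full per-generation population, parent pointers
#'   and mutation-event log (needed for lines of descent).
#' @param stop_at_threshold Stop at the first generation where any local
#'   optimum (or Fmax) reaches `cfg$threshold` occupancy.
#' @param optima Optional precomputed codes from [find_local_optima()].
#' @return A `wf_trajectory`: `occupancy` matrix (generations + 1 rows,
#'   one column per optimum, Fmax column named), `optima`, `fmax`,
#'   `generations`, `final_pop`, and when recorded, `pop_history`,
#'   `parent_history`, `events` (data frame gen/node/site).
#' @export
wf_simulate <- function(ls, cfg, record = FALSE, stop_at_threshold = FALSE,
                        optima = NULL) {
  stopifnot(inherits(ls, "fitness_landscape"), inherits(cfg, "wf_config"))
  if (is.null(optima)) optima <- find_local_optima(ls)
  fmax <- global_optimum(ls)
  .with_seed(cfg$seed, .wf_run(ls, cfg, record, stop_at_threshold, optima, fmax))
}

#' @keywords internal
.wf_run <- function(ls, cfg, record, stop_at_threshold, optima, fmax) {
  npop <- cfg$npop
  setup <- .wf_setup(ls, cfg)
  pop <- rep(0L, npop)
  n_opt <- length(optima)
  occ <- matrix(NA_real_, cfg$tmax + 1L, n_opt,
                dimnames = list(NULL, as.character(optima)))
  occupancy_of <- function(pop) {
    tabulate(match(pop, optima), nbins = n_opt) / npop
  }
  occ[1L, ] <- occupancy_of(pop)
  pop_hist <- if (record) matrix(0L, npop, cfg$tmax + 1L) else NULL
  par_hist <- if (record) matrix(0L, npop, cfg$tmax + 1L) else NULL
  ev_list <- if (record) vector("list", cfg$tmax) else NULL
  t_end <- 0L
  if (cfg$tmax > 0) {
    for (t in seq_len(cfg$tmax)) {
      stp <- wf_step(pop, ls, cfg, setup)
      pop <- stp$pop
      occ[t + 1L, ] <- occupancy_of(pop)
      if (record) {
        pop_hist[, t + 1L] <- pop
        par_hist[, t + 1L] <- stp$parents
        if (!is.null(stp$events)) {
          ev_list[[t]] <- cbind(gen = t, stp$events)
        }
      }
      t_end <- t
      if (stop_at_threshold && any(occ[t + 1L, ] >= cfg$threshold)) break
    }
  }
  occ <- occ[seq_len(t_end + 1L), , drop = FALSE]
  events <- NULL
  if (record) {
    pop_hist <- pop_hist[, seq_len(t_end + 1L), drop = FALSE]
    par_hist <- par_hist[, seq_len(t_end + 1L), drop = FALSE]
    ev <- do.call(rbind, ev_list[seq_len(max(t_end, 1L))])
    events <- if (is.null(ev)) {
      data.frame(gen = integer(0), node = integer(0), site = integer(0))
    } else as.data.frame(ev)
  }
  structure(list(occupancy = occ, optima = optima, fmax = fmax,
                 generations = t_end, final_pop = pop,
                 pop_history = pop_hist, parent_history = par_hist,
                 events = events, L = ls$L, config = cfg),
            class = "wf_trajectory")
}

#' Maximum occupancy reached by each optimum over a trajectory
#'
#' @param traj A `wf_trajectory`.
#' @return Named numeric vector (one entry per optimum code).
#' @export
max_occupancy_profile <- function(traj) {
  stopifnot(inherits(traj, "wf_trajectory"))
  apply(traj$occupancy, 2, max)
}

#' Wright-Fisher success rate of enriching the global optimum
#'
#' A replicate succeeds iff Fmax occupancy reaches `cfg$threshold` at some
#' generation `t <= tmax` strictly before any local optimum's occupancy
#' does; ties in the same generation count as failure (conservative).
#' Replicates stop at the first success/failure decision.  Replicate k
#' runs with seed derived from `(cfg$seed, k)` so the set is reproducible
#' and order-independent.
#'
#' @param ls A `fitness_landscape`.
#' @param cfg A `wf_config`.
#' @param n_replicates Number of replicate populations.
#' @param optima Optional precomputed optima codes.
#' @return A list: `success_rate`, and `records` data frame (replicate,
#'   success, t_hit = first generation any optimum crossed the threshold
#'   or NA).
#' @export
success_rate <- function(ls, cfg, n_replicates = 100, optima = NULL) {
  stopifnot(inherits(ls, "fitness_landscape"), inherits(cfg, "wf_config"))
  if (is.null(optima)) optima <- find_local_optima(ls)
  fmax <- global_optimum(ls)
  fcol <- match(as.character(fmax), as.character(optima))
  if (is.na(fcol)) stop("global optimum is not a local optimum; malformed landscape")
  recs <- lapply(seq_len(n_replicates), function(k) {
    cfg_k <- cfg
    cfg_k$seed <- as.integer((cfg$seed + 7919 * k) %% 2147483647)
    traj <- wf_simulate(ls, cfg_k, record = FALSE, stop_at_threshold = TRUE,
                        optima = optima)
    last <- traj$occupancy[nrow(traj$occupancy), ]
    crossed <- which(last >= cfg$threshold)
    success <- length(crossed) == 1 && crossed[1] == fcol
    t_hit <- if (length(crossed) > 0) traj$generations else NA_integer_
    data.frame(replicate = k, success = success, t_hit = t_hit)
  })
  records <- do.call(rbind, recs)
  list(success_rate = mean(records$success), records = records)
}
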