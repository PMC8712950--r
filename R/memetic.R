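# The memetic optimizer: genetic global search over clusterings plus a
# per-cluster local optimization of FF. All randomness is drawn from R's
# global RNG in a fixed order; run_ima() seeds it once from the config, so
# identical seeds give identical outputs.

#' Configuration for the memetic search
#'
#' @param max_iter number of generations (fixed budget).
#' @param pop_size number of individuals kept in the population.
#' @param local_opt_gate fraction of the current maximum population fitness
#'   a child must exceed to earn local optimization.
#' @param local_opt_cap maximum remove/add passes per cluster during local
#'   optimization.
#' @param min_cluster_size smallest complex size kept in the initial
#'   population and the final output.
#' @param rng_seed integer seed for the run.
#' @return an `ima_config` list.
#' @export
ima_config <- function(max_iter = 60L, pop_size = 24L, local_opt_gate = 0.8,
                       local_opt_cap = 20L, min_cluster_size = 3L, rng_seed = 1L) {
  stopifnot(pop_size >= 2L, max_iter >= 1L,
            local_opt_gate >= 0, local_opt_gate <= 1,
            local_opt_cap >= 1L, min_cluster_size >= 2L)
  structure(list(max_iter = as.integer(max_iter), pop_size = as.integer(pop_size),
                 local_opt_gate = local_opt_gate,
                 local_opt_cap = as.integer(local_opt_cap),
                 min_cluster_size = as.integer(min_cluster_size),
                 rng_seed = as.integer(rng_seed)),
            class = "ima_config")
}

#' Build the initial population from candidate clusterings
#'
#' Each supplied clustering becomes one individual: members absent from the
#' network are dropped, then clusters below `min_cluster_size`. The
#' population is padded to `pop_size` by cycling through the individuals in
#' decreasing fitness order (or truncated to the `pop_size` fittest).
#'
#' @param init_sets a [complex_set()] or list of them (e.g. outputs of
#'   several seed-expansion detectors, or perturbed gold standards).
#' @param net an `igraph` network.
#' @param cfg an [ima_config()].
#' @return list of `ima_individual`s of length `cfg$pop_size`.
#' @export
init_population <- function(init_sets, net, cfg = ima_config()) {
  if (inherits(init_sets, "complex_set")) init_sets <- list(init_sets)
  nodes <- igraph::V(net)$name
  inds <- list()
  for (cs in init_sets) {
    cl <- lapply(cs, function(m) intersect(m, nodes))
    cl <- cl[lengths(cl) >= cfg$min_cluster_size]
    if (length(cl)) inds[[length(inds) + 1L]] <- new_individual(net, cl)
  }
  if (!length(inds)) stop("no usable clusters after filtering against the network")
  ord <- order(vapply(inds, `[[`, numeric(1L), "fitness"), decreasing = TRUE)
  inds <- inds[ord]
  inds[rep_len(seq_along(inds), cfg$pop_size)]
}

#' Binary tournament selection
#'
#' Samples two individuals uniformly with replacement and returns the one
#' with higher fitness (the first sampled on a tie).
#'
#' @param pop list of `ima_individual`s.
#' @return one `ima_individual`.
#' @export
binary_tournament <- function(pop) {
  stopifnot(length(pop) >= 1L)
  i <- sample.int(length(pop), 2L, replace = TRUE)
  if (pop[[i[2L]]]$fitness > pop[[i[1L]]]$fitness) pop[[i[2L]]] else pop[[i[1L]]]
}

# Tournament over composite-parent clusters: pick two of the still
# available cluster indices uniformly with replacement, keep the one with
# the higher FF (first sampled on a tie).
cluster_tournament <- function(avail, ff) {
  if (length(avail) == 1L) return(avail)
  j <- avail[sample.int(length(avail), 2L, replace = TRUE)]
  if (ff[[j[2L]]] > ff[[j[1L]]]) j[2L] else j[1L]
}

#' Fitness-guided recombination
#'
#' Merges both parents' clusters into a composite parent (exact duplicate
#' sets collapsed to one copy), draws each child's length uniformly from
#' `[min, max]` of the parent lengths (clamped to the composite size), and
#' fills each child by repeated binary tournaments on the composite
#' clusters ranked by their `FF` — without re-selecting a cluster already
#' in that child. High-FF clusters are therefore inherited preferentially
#' while child composition stays stochastic.
#'
#' @param p1,p2 parent `ima_individual`s.
#' @param net an `igraph` network (kept for interface symmetry; cached FF
#'   values are reused).
#' @return list of two child `ima_individual`s.
#' @export
recombine <- function(p1, p2, net = NULL) {
  stopifnot(length(p1$clusters) >= 1L, length(p2$clusters) >= 1L)
  clusters <- c(p1$clusters, p2$clusters)
  ff <- c(p1$ff, p2$ff)
  key <- vapply(clusters, function(m) paste(sort(m), collapse = "\r"), character(1L))
  keep <- !duplicated(key)
  clusters <- clusters[keep]
  ff <- ff[keep]
  ord <- order(ff, decreasing = TRUE) # rank composite clusters by FF
  clusters <- clusters[ord]
  ff <- ff[ord]

  len_low <- min(length(p1$clusters), length(p2$clusters))
  len_up <- max(length(p1$clusters), length(p2$clusters))
  make_child <- function() {
    len <- if (len_low == len_up) len_low else
      len_low + sample.int(len_up - len_low + 1L, 1L) - 1L
    len <- min(len, length(clusters))
    avail <- seq_along(clusters)
    chosen <- integer(len)
    for (j in seq_len(len)) {
      pick <- cluster_tournament(avail, ff)
      chosen[[j]] <- pick
      avail <- avail[avail != pick]
    }
    structure(list(clusters = clusters[chosen], ff = ff[chosen],
                   fitness = sum(ff[chosen])),
              class = "ima_individual")
  }
  list(make_child(), make_child())
}

# One cluster's local optimization: alternate best-removal / best-addition
# moves while they strictly improve FF, up to `cap` passes. Removal
# candidates are members connected to at least one other protein in the
# network (isolated nodes are not movable); addition candidates are the
# cluster neighbourhood N(C). Ties between equally scoring candidates
# break to the lexicographically smallest protein name, for determinism.
local_opt_cluster_idx <- function(idx, members, cap = 20L) {
  members <- sort.int(members)
  iteration <- 0L
  cur_ff <- ff_idx(idx, members)
  repeat {
    iteration <- iteration + 1L
    changed <- FALSE

    if (length(members) > 1L) {
      cand <- members[lengths(idx$adj[members]) > 0L]
      cand <- cand[order(idx$names[cand])]
      if (length(cand)) {
        ffs <- vapply(cand, function(v) ff_idx(idx, members[members != v]), numeric(1L))
        b <- which.max(ffs)
        if (ffs[[b]] > cur_ff) {
          members <- members[members != cand[[b]]]
          cur_ff <- ffs[[b]]
          changed <- TRUE
        }
      }
    }

    in_c <- logical(idx$n); in_c[members] <- TRUE
    boundary <- unique(unlist(idx$adj[members]))
    boundary <- boundary[!in_c[boundary]]
    boundary <- boundary[order(idx$names[boundary])]
    if (length(boundary)) {
      ffs <- vapply(boundary, function(v) ff_idx(idx, c(members, v)), numeric(1L))
      b <- which.max(ffs)
      if (ffs[[b]] > cur_ff) {
        members <- sort.int(c(members, boundary[[b]]))
        cur_ff <- ffs[[b]]
        changed <- TRUE
      }
    }

    if (!changed || iteration >= cap) break
  }
  members
}

local_optimize_idx <- function(ind, idx, cfg) {
  clusters <- lapply(ind$clusters, function(m) match(m, idx$names))
  opt <- lapply(clusters, local_opt_cluster_idx, idx = idx, cap = cfg$local_opt_cap)
  # Optimization can converge near-duplicate clusters of the individual onto
  # the same set; a complex found twice in one individual is redundant, so
  # only one copy is kept before the accept/revert test.
  key <- vapply(opt, function(m) paste(m, collapse = ","), character(1L))
  keep <- !duplicated(key)
  opt <- opt[keep]
  ff <- vapply(opt, function(m) ff_idx(idx, m), numeric(1L))
  if (sum(ff) > ind$fitness) { # revert unless strictly better
    structure(list(clusters = lapply(opt, function(m) idx$names[sort.int(m)]),
                   ff = ff, fitness = sum(ff)),
              class = "ima_individual")
  } else {
    ind
  }
}

#' Local optimization of an individual
#'
#' Refines every cluster of the individual by alternating two greedy moves
#' while they strictly improve the cluster's `FF`: remove the member (among
#' those connected to at least one other protein in the network) whose
#' removal gains most, then add the neighbourhood protein whose addition
#' gains most. Each cluster is capped at `cfg$local_opt_cap` passes. If the
#' optimized individual's total fitness is not strictly greater than the
#' input's, the optimization is deemed invalid and the input is returned
#' unchanged — so the result never has lower fitness than the input.
#'
#' @param ind an `ima_individual`.
#' @param net an `igraph` network.
#' @param cfg an [ima_config()].
#' @return an `ima_individual` with fitness `>=` that of `ind`.
#' @export
local_optimize <- function(ind, net, cfg = ima_config()) {
  local_optimize_idx(ind, net_index(net), cfg)
}

# Fitness-proportional sampling without replacement of `k` indices from
# `fits`; non-positive fitnesses are shifted so the minimum maps to eps.
roulette_select <- function(fits, k) {
  p <- fits
  if (min(p) <= 0) p <- p - min(p) + 1e-9
  sample.int(length(p), k, replace = FALSE, prob = p)
}

#' Roulette-wheel population update
#'
#' Pools the current population with one new child and draws
#' `length(pop)` survivors by fitness-proportional sampling without
#' replacement (fitnesses shifted to a small positive floor if any are
#' non-positive), so fitter individuals are more likely to survive without
#' the update becoming purely elitist.
#'
#' @param pop list of `ima_individual`s.
#' @param child a scored `ima_individual`.
#' @return an updated population of the same size as `pop`.
#' @export
roulette_update <- function(pop, child) {
  pool <- c(pop, list(child))
  fits <- vapply(pool, `[[`, numeric(1L), "fitness")
  pool[roulette_select(fits, length(pop))]
}

#' Detect protein complexes with the memetic algorithm
#'
#' Runs the full search: the population is initialized from the supplied
#' clusterings, then for `max_iter` generations two parents are chosen by
#' binary tournament, recombined, the fitter child is locally optimized if
#' its fitness exceeds `local_opt_gate` times the current maximum
#' population fitness, and the population is updated by roulette-wheel
#' selection over the pool of population plus child. The best individual
#' ever seen is recorded each generation and returned with clusters below
#' `min_cluster_size` dropped and exact duplicate clusters removed.
#'
#' @param net an `igraph` network (typically from
#'   [build_weighted_network()]).
#' @param init_sets a [complex_set()] or list of them.
#' @param cfg an [ima_config()]; `cfg$rng_seed` fixes the whole run.
#' @return an `ima_result`: list with `complexes` (a [complex_set()]),
#'   `fitness`, `best` (the untrimmed best individual) and `trace` (a data
#'   frame of per-generation best and mean fitness).
#' @export
run_ima <- function(net, init_sets, cfg = ima_config()) {
  set.seed(cfg$rng_seed)
  idx <- net_index(net)
  pop <- init_population(init_sets, net, cfg)
  fits <- vapply(pop, `[[`, numeric(1L), "fitness")
  best <- pop[[which.max(fits)]]
  trace_best <- trace_mean <- numeric(cfg$max_iter)

  for (gen in seq_len(cfg$max_iter)) {
    p1 <- binary_tournament(pop)
    p2 <- binary_tournament(pop)
    children <- recombine(p1, p2)
    child <- if (children[[1L]]$fitness >= children[[2L]]$fitness)
      children[[1L]] else children[[2L]]
    if (child$fitness > cfg$local_opt_gate * max(fits)) {
      child <- local_optimize_idx(child, idx, cfg)
    }
    pool <- c(pop, list(child))
    pool_fits <- c(fits, child$fitness)
    keep <- roulette_select(pool_fits, length(pop))
    pop <- pool[keep]
    fits <- pool_fits[keep]
    if (max(pool_fits) > best$fitness) best <- pool[[which.max(pool_fits)]]
    trace_best[[gen]] <- best$fitness
    trace_mean[[gen]] <- mean(fits)
  }

  clusters <- best$clusters[lengths(best$clusters) >= cfg$min_cluster_size]
  key <- vapply(clusters, function(m) paste(sort(m), collapse = "\r"), character(1L))
  clusters <- clusters[!duplicated(key)]
  structure(list(
    complexes = complex_set(clusters),
    fitness = best$fitness,
    best = best,
    trace = data.frame(generation = seq_len(cfg$max_iter),
                       best_fitness = trace_best, mean_fitness = trace_mean),
    config = cfg
  ), class = "ima_result")
}

#' @export
print.ima_result <- function(x, ...) {
  cat("ima_result:", length(x$complexes), "complexes, best fitness",
      format(x$fitness, digits = 6), "after", nrow(x$trace), "generations\n")
  invisible(x)
}
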