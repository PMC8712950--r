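# Cluster fitness: five topological objectives combined into one score.
#
# The memetic search evaluates candidate clusters millions of times, so the
# scorer runs on a prebuilt integer adjacency index (`net_index`) rather
# than on the igraph object; the exported functions build the index on the
# fly and accept protein names.

# Integer adjacency cache for a network: node names plus, per node, the
# integer neighbour ids and corresponding edge weights (1 when unweighted).
net_index <- function(net) {
  n <- igraph::vcount(net)
  nm <- igraph::V(net)$name
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  src <- c(el[, 1L], el[, 2L])
  dst <- c(el[, 2L], el[, 1L])
  ww <- c(w, w)
  adj <- rep(list(integer()), n)
  wts <- rep(list(numeric()), n)
  if (length(src)) {
    o <- order(src)
    runs <- split(seq_along(src)[o], src[o])
    for (k in names(runs)) {
      i <- as.integer(k)
      adj[[i]] <- dst[runs[[k]]]
      wts[[i]] <- ww[runs[[k]]]
    }
  }
  list(n = n, names = nm, adj = adj, w = wts)
}

# Raw sums for one cluster (integer member ids): internal weight/edge count
# and border weight/edge count.
cluster_sums_idx <- function(idx, members) {
  in_c <- logical(idx$n)
  in_c[members] <- TRUE
  win2 <- 0; ein2 <- 0L; wout <- 0; eout <- 0L
  for (v in members) {
    inside <- in_c[idx$adj[[v]]]
    wv <- idx$w[[v]]
    win2 <- win2 + sum(wv[inside])
    ein2 <- ein2 + sum(inside)
    wout <- wout + sum(wv[!inside])
    eout <- eout + sum(!inside)
  }
  list(w_in = win2 / 2, e_in = ein2 %/% 2L, w_out = wout, e_border = eout)
}

cluster_score_idx <- function(idx, members) {
  s <- cluster_sums_idx(idx, members)
  n_c <- length(members)
  coh <- if (s$w_in + s$w_out > 0) s$w_in / (s$w_in + s$w_out) else 0
  dens <- if (n_c > 1L) 2 * s$w_in / (n_c * (n_c - 1)) else 0
  aiew <- if (s$e_in > 0L) s$w_in / s$e_in else 0
  abew <- if (s$e_border > 0L) s$w_out / s$e_border else 0
  awm <- if (aiew + abew > 0) aiew / (aiew + abew) else 0
  list(cohesiveness = coh, density = dens, aiew = aiew, abew = abew,
       awm = awm, ff = coh + dens + aiew - abew + awm)
}

ff_idx <- function(idx, members) cluster_score_idx(idx, members)$ff

#' Score one candidate cluster
#'
#' Computes the five topological objectives of a cluster `C` on a weighted
#' network and their combination:
#' * cohesiveness `W_in / (W_in + W_out)` — internal weight relative to all
#'   weight touching the cluster;
#' * weighted density `2 W_in / (|V_C| (|V_C| - 1))`;
#' * AIEW `W_in / |E_C|` — average inner edge weight;
#' * ABEW `W_out / |BE_C|` — average border edge weight;
#' * AWM `AIEW / (AIEW + ABEW)` — weight-based modularity of the cluster;
#' * `FF = cohesiveness + density + AIEW - ABEW + AWM`.
#'
#' Degenerate cases score 0: a singleton has density 0; a cluster without
#' internal edges has AIEW 0; one without border edges has ABEW 0 (and so
#' cohesiveness 1 when `W_in > 0`); `AIEW + ABEW = 0` gives AWM 0 and
#' `W_in + W_out = 0` gives cohesiveness 0. On an unweighted network every
#' edge counts with weight 1.
#'
#' @param net an `igraph` network (weighted or unweighted).
#' @param members character vector of cluster member proteins.
#' @return a list with components `cohesiveness`, `density`, `aiew`,
#'   `abew`, `awm` and `ff`.
#' @export
score_cluster <- function(net, members) {
  idx <- net_index(net)
  ids <- match(unique(members), idx$names)
  if (anyNA(ids)) {
    stop("cluster member not in network: ", unique(members)[which(is.na(ids))[1L]])
  }
  cluster_score_idx(idx, ids)
}

#' Construct a scored individual
#'
#' An individual is an ordered collection of clusters (one candidate
#' clustering of the network) with a cached per-cluster `FF` and total
#' fitness. The cache is recomputed from scratch here, so it can never be
#' stale with respect to `clusters`.
#'
#' @param net an `igraph` network.
#' @param clusters list of character vectors, one per cluster.
#' @return an `ima_individual`: list with `clusters`, `ff` (numeric vector)
#'   and `fitness` (their sum).
#' @export
new_individual <- function(net, clusters) {
  stopifnot(length(clusters) >= 1L)
  idx <- net_index(net)
  clusters <- lapply(clusters, function(m) sort(unique(as.character(m))))
  ff <- vapply(clusters, function(m) {
    ids <- match(m, idx$names)
    if (anyNA(ids)) stop("cluster member not in network: ", m[which(is.na(ids))[1L]])
    ff_idx(idx, ids)
  }, numeric(1L))
  structure(list(clusters = clusters, ff = ff, fitness = sum(ff)),
            class = "ima_individual")
}

#' @export
print.ima_individual <- function(x, ...) {
  cat("ima_individual:", length(x$clusters), "clusters, fitness",
      format(x$fitness, digits = 6), "\n")
  invisible(x)
}

#' Total fitness of an individual
#'
#' The fitness of an individual is the sum of the `FF` scores of its
#' clusters; the per-cluster cache is refreshed as a side effect of the
#' recomputation.
#'
#' @param net an `igraph` network.
#' @param ind an `ima_individual` (or bare list of character clusters).
#' @return the summed `FF` over all clusters.
#' @export
individual_fitness <- function(net, ind) {
  clusters <- if (inherits(ind, "ima_individual")) ind$clusters else ind
  new_individual(net, clusters)$fitness
}
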