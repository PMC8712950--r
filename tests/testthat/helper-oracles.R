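# Fixture builders and independent oracles. The oracles re-derive
# quantities from raw edge tables / exhaustive enumeration and share no
# code with the package internals they check.

# 5-node weighted path/triangle used throughout the fitness tests
worked_net <- function() {
  suppressMessages(ppi_network(
    rbind(c("a", "b"), c("a", "c"), c("b", "c"), c("c", "d"), c("d", "e")),
    weights = c(0.8, 0.6, 0.9, 0.2, 0.5)
  ))
}

# Erdos-Renyi graph with uniform random weights, as an edge data frame
# plus the corresponding network object
random_weighted_instance <- function(n, p = 0.4, weighted = TRUE) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  w <- if (weighted) stats::runif(nrow(edges)) else rep(1, nrow(edges))
  net <- suppressMessages(ppi_network(edges, weights = w, nodes = nodes))
  list(net = net, edges = data.frame(u = edges[, 1L], v = edges[, 2L], w = w,
                                     stringsAsFactors = FALSE),
       nodes = nodes)
}

# FF re-derived from a raw edge table with plain set arithmetic
oracle_ff <- function(edges, members) {
  members <- unique(members)
  internal <- edges$u %in% members & edges$v %in% members
  border <- xor(edges$u %in% members, edges$v %in% members)
  w_in <- sum(edges$w[internal])
  w_out <- sum(edges$w[border])
  n_in <- sum(internal)
  n_border <- sum(border)
  k <- length(members)
  coh <- if (w_in + w_out > 0) w_in / (w_in + w_out) else 0
  dens <- if (k > 1) 2 * w_in / (k * (k - 1)) else 0
  aiew <- if (n_in > 0) w_in / n_in else 0
  abew <- if (n_border > 0) w_out / n_border else 0
  awm <- if (aiew + abew > 0) aiew / (aiew + abew) else 0
  coh + dens + aiew - abew + awm
}

# HCN re-derived with plain set arithmetic from an edge table
oracle_hcn <- function(edges, v, u) {
  nb <- function(x) unique(c(edges$v[edges$u == x], edges$u[edges$v == x]))
  nv <- setdiff(nb(v), v)
  nu <- setdiff(nb(u), u)
  ncn <- length(intersect(nv, nu))
  den <- length(nv) * length(nu) * length(union(nv, nu))
  if (ncn == 0 || den == 0) 0 else ncn^2 / den
}

# Maximum-weight one-to-one matching by exhaustive recursion over all
# assignments of detected complexes to standard complexes
oracle_matching_weight <- function(os) {
  # os: detected x standard matrix
  best <- 0
  recurse <- function(d, used, acc) {
    if (d > nrow(os)) {
      best <<- max(best, acc)
      return(invisible())
    }
    recurse(d + 1L, used, acc) # leave detected complex d unmatched
    for (s in seq_len(ncol(os))) {
      if (!used[s] && os[d, s] > 0) {
        used[s] <- TRUE
        recurse(d + 1L, used, acc + os[d, s])
        used[s] <- FALSE
      }
    }
  }
  recurse(1L, logical(ncol(os)), 0)
  best
}

# Upper-tail hypergeometric probability by direct summation of the mass
# function with choose()
oracle_hyper_p <- function(N, F_ann, C, K) {
  if (K == 0) return(1)
  ks <- K:min(F_ann, C)
  sum(choose(F_ann, ks) * choose(N - F_ann, C - ks)) / choose(N, C)
}

# Random small complex set over an alphabet
random_complexes <- function(n_complexes, alphabet, min_size = 2L, max_size = 4L) {
  complex_set(lapply(seq_len(n_complexes), function(i) {
    sample(alphabet, sample(min_size:max_size, 1L))
  }))
}

# Small planted benchmark reused by the optimizer-contract tests
small_benchmark <- function(seed = 11L) {
  spec <- synthetic_spec(n_complexes = 4L, size_range = c(4L, 6L),
                         p_within = 0.9, p_between = 0.02,
                         n_background_nodes = 15L, rng_seed = seed)
  b <- suppressMessages(generate_benchmark(spec))
  w <- suppressMessages(build_weighted_network(b$network, b$attributes))
  list(bench = b, weighted = w, spec = spec)
}
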