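# Planted-complex benchmark generator. Produces a PPI network with known
# complexes plus attribute tables statistically correlated with the planted
# complexes, so the whole weighting + detection + evaluation pipeline can be
# exercised without external data.

#' Specification of a synthetic planted-complex benchmark
#'
#' Defines a planted-partition graph — non-overlapping complexes whose
#' internal edges appear with probability `p_within` while every other
#' protein pair connects with probability `p_between` — together with
#' attribute data that mimics the biological correlations the edge
#' weighting relies on: co-complex proteins share a latent expression
#' profile, a dominant GO term set and a dominant compartment.
#'
#' @param n_complexes number of planted complexes.
#' @param size_range integer vector `c(min, max)` of complex sizes (each
#'   size drawn uniformly); sizes must lie in `[3, 30]`.
#' @param p_within intra-complex edge probability.
#' @param p_between background edge probability (any pair not inside one
#'   complex); must be `< p_within`.
#' @param n_background_nodes number of proteins outside every complex.
#' @param expr_timepoints length of the expression time course.
#' @param expr_noise_sd per-protein Gaussian noise around the complex's
#'   latent expression profile.
#' @param go_terms_per_complex size of each complex's dominant GO term set.
#' @param loc_compartments number of compartments in the localization pool.
#' @param perturbation_rate membership edit rate used by [perturb_gold()]
#'   when deriving initial clusterings.
#' @param rng_seed integer seed; generation is fully deterministic given
#'   the specification object.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_complexes = 8L, size_range = c(5L, 8L),
                           p_within = 0.9, p_between = 0.02,
                           n_background_nodes = 40L, expr_timepoints = 12L,
                           expr_noise_sd = 0.25, go_terms_per_complex = 3L,
                           loc_compartments = 6L, perturbation_rate = 0.3,
                           rng_seed = 1L) {
  stopifnot(n_complexes >= 1L,
            length(size_range) == 2L, size_range[1L] <= size_range[2L],
            size_range[1L] >= 3L, size_range[2L] <= 30L,
            p_between >= 0, p_between < p_within, p_within <= 1,
            perturbation_rate >= 0, perturbation_rate <= 1)
  structure(list(n_complexes = as.integer(n_complexes),
                 size_range = as.integer(size_range),
                 p_within = p_within, p_between = p_between,
                 n_background_nodes = as.integer(n_background_nodes),
                 expr_timepoints = as.integer(expr_timepoints),
                 expr_noise_sd = expr_noise_sd,
                 go_terms_per_complex = as.integer(go_terms_per_complex),
                 loc_compartments = as.integer(loc_compartments),
                 perturbation_rate = perturbation_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Generate a planted-complex benchmark
#'
#' Draws the planted-partition graph and correlated attributes defined by
#' `spec`. Each complex gets a latent expression base vector (standard
#' normal per time point) that members reproduce up to additive Gaussian
#' noise, a dominant GO term set shared by all members, and a dominant
#' compartment (members occasionally carry one extra random compartment).
#' Background proteins get independent expression, sparse random terms and
#' a random compartment. Byte-identical under the same `rng_seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (unweighted `igraph`, isolated nodes
#'   retained), `attributes` (an [attribute_bundle()]) and `gold` (a
#'   [complex_set()] of the planted complexes).
#' @export
generate_benchmark <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$rng_seed)

  sizes <- spec$size_range[1L] +
    sample.int(spec$size_range[2L] - spec$size_range[1L] + 1L,
               spec$n_complexes, replace = TRUE) - 1L
  n_in <- sum(sizes)
  n <- n_in + spec$n_background_nodes
  proteins <- sprintf("P%04d", seq_len(n))
  membership <- rep(c(seq_len(spec$n_complexes), 0L),
                    c(sizes, spec$n_background_nodes))
  gold <- complex_set(
    split(proteins[membership > 0L],
          factor(membership[membership > 0L], levels = seq_len(spec$n_complexes))),
    labels = sprintf("complex%02d", seq_len(spec$n_complexes))
  )

  pairs <- utils::combn(n, 2L)
  same <- membership[pairs[1L, ]] == membership[pairs[2L, ]] &
    membership[pairs[1L, ]] > 0L
  p_edge <- ifelse(same, spec$p_within, spec$p_between)
  drawn <- stats::runif(ncol(pairs)) < p_edge
  net <- ppi_network(cbind(proteins[pairs[1L, drawn]], proteins[pairs[2L, drawn]]),
                     nodes = proteins)

  # expression: shared latent base per complex + per-protein noise
  expression <- vector("list", n)
  names(expression) <- proteins
  bases <- lapply(seq_len(spec$n_complexes),
                  function(i) stats::rnorm(spec$expr_timepoints))
  for (i in seq_len(n)) {
    expression[[i]] <- if (membership[i] > 0L) {
      bases[[membership[i]]] + stats::rnorm(spec$expr_timepoints, 0, spec$expr_noise_sd)
    } else {
      stats::rnorm(spec$expr_timepoints)
    }
  }

  # GO terms: one dominant block of terms per complex; background proteins
  # draw sparsely from a shared background pool
  background_pool <- sprintf("GO:B%03d", seq_len(10L))
  go_terms <- vector("list", n)
  names(go_terms) <- proteins
  for (i in seq_len(n)) {
    go_terms[[i]] <- if (membership[i] > 0L) {
      sprintf("GO:C%02d_%02d", membership[i], seq_len(spec$go_terms_per_complex))
    } else {
      sample(background_pool, sample(1:2, 1L))
    }
  }

  compartments <- sprintf("compartment%02d", seq_len(spec$loc_compartments))
  dominant <- sample(compartments, spec$n_complexes, replace = TRUE)
  locations <- vector("list", n)
  names(locations) <- proteins
  for (i in seq_len(n)) {
    locations[[i]] <- if (membership[i] > 0L) {
      loc <- dominant[[membership[i]]]
      if (stats::runif(1L) < 0.2) loc <- union(loc, sample(compartments, 1L))
      loc
    } else {
      sample(compartments, 1L)
    }
  }

  list(network = net,
       attributes = attribute_bundle(expression = expression,
                                     go_terms = go_terms, locations = locations),
       gold = gold)
}

#' Perturb a gold standard into noisy initial clusterings
#'
#' Stand-in for the outputs of external seed-expansion detectors: each
#' complex member is independently dropped with probability `rate`, and for
#' each original member a uniformly random protein from the complex's
#' network neighbourhood is added with probability `rate`. Complexes shrunk
#' below 3 members are removed. Uses the current RNG state unless
#' `rng_seed` is given.
#'
#' @param gold a [complex_set()].
#' @param rate membership edit probability in `[0, 1]`.
#' @param net the `igraph` network the complexes live in.
#' @param rng_seed optional integer seed.
#' @return a perturbed [complex_set()].
#' @export
perturb_gold <- function(gold, rate, net, rng_seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  nm <- igraph::V(net)$name
  adj <- lapply(igraph::as_adj_list(net), function(x) nm[x])
  names(adj) <- nm
  out <- lapply(gold, function(members) {
    members <- intersect(members, nm)
    kept <- members[stats::runif(length(members)) >= rate]
    n_add <- sum(stats::runif(length(members)) < rate)
    if (n_add > 0L) {
      nbhd <- setdiff(unique(unlist(adj[members])), members)
      if (length(nbhd)) {
        kept <- union(kept, sample(nbhd, min(n_add, length(nbhd))))
      }
    }
    kept
  })
  out <- out[lengths(out) >= 3L]
  if (!length(out)) return(structure(list(), class = "complex_set"))
  complex_set(out)
}
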