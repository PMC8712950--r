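# Evaluation suite for comparing detected complexes against a gold
# standard, plus hypergeometric enrichment and co-localization scoring.

#' Overlap score between two complexes
#'
#' Neighbourhood-affinity match score
#' \eqn{OS(A,B) = |A \cap B|^2 / (|A| \cdot |B|)}; 1 iff the sets are
#' identical, 0 iff disjoint, symmetric.
#'
#' @param a,b non-empty character vectors of protein IDs.
#' @return the overlap score in `[0, 1]`.
#' @export
overlap_score <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("overlap_score: empty complex")
  length(intersect(a, b))^2 / (length(a) * length(b))
}

# detected x standard matrix of overlap scores
os_matrix <- function(detected, standard) {
  outer(seq_along(detected), seq_along(standard),
        Vectorize(function(i, j) overlap_score(detected[[i]], standard[[j]])))
}

# standard x detected matrix of raw overlap counts |s cap t|
overlap_counts <- function(standard, detected) {
  outer(seq_along(standard), seq_along(detected),
        Vectorize(function(s, t) length(intersect(standard[[s]], detected[[t]]))))
}

#' Precision, recall and F-measure of a prediction
#'
#' A detected complex matches a standard complex when their overlap score
#' is at least `lambda` (default 0.2). Precision is the fraction of
#' detected complexes matching at least one standard complex, recall the
#' fraction of standard complexes matched by at least one detected
#' complex, and the F-measure their harmonic mean (0 when both are 0).
#'
#' @param detected,standard [complex_set()]s (or lists of character
#'   vectors).
#' @param lambda overlap-score match threshold in `(0, 1]`.
#' @return list with `precision`, `recall`, `f_measure`, and the counts
#'   `n_detected_matched`, `n_standard_matched`.
#' @export
f_measure <- function(detected, standard, lambda = 0.2) {
  stopifnot(lambda > 0, lambda <= 1)
  if (!length(detected) || !length(standard)) {
    return(list(precision = 0, recall = 0, f_measure = 0,
                n_detected_matched = 0L, n_standard_matched = 0L))
  }
  os <- os_matrix(detected, standard)
  ndm <- sum(apply(os >= lambda, 1L, any))
  nsm <- sum(apply(os >= lambda, 2L, any))
  precision <- ndm / length(detected)
  recall <- nsm / length(standard)
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f_measure = f,
       n_detected_matched = ndm, n_standard_matched = nsm)
}

#' Coverage rate of the standard complexes
#'
#' \eqn{CR = \sum_s \max_t T_{st} / \sum_s N_s} where `T_st` is the overlap
#' count between standard complex `s` and detected complex `t` and `N_s`
#' the size of `s`: the fraction of gold-standard protein slots covered by
#' each standard complex's best-overlapping prediction.
#'
#' @inheritParams f_measure
#' @return the coverage rate in `[0, 1]`.
#' @export
coverage_rate <- function(detected, standard) {
  if (!length(standard)) return(0)
  n_s <- sum(lengths(lapply(standard, unique)))
  if (!length(detected)) return(0)
  tc <- overlap_counts(standard, detected)
  sum(apply(tc, 1L, max)) / n_s
}

#' Clustering-wise sensitivity, PPV and accuracy
#'
#' `Sn = sum_s max_t T_st / sum_s N_s`,
#' `PPV = sum_t max_s T_st / sum_t sum_s T_st` and
#' `ACC = sqrt(Sn * PPV)` (the Brohee & van Helden clustering-wise
#' formulation). Terms with zero denominators contribute 0; in particular
#' `PPV = 0` when no detected complex intersects any standard complex.
#'
#' @inheritParams f_measure
#' @return list with `sn`, `ppv`, `acc`.
#' @export
sn_ppv_acc <- function(detected, standard) {
  if (!length(detected) || !length(standard)) return(list(sn = 0, ppv = 0, acc = 0))
  tc <- overlap_counts(standard, detected)
  n_s <- sum(lengths(lapply(standard, unique)))
  sn <- if (n_s > 0) sum(apply(tc, 1L, max)) / n_s else 0
  tot <- sum(tc)
  ppv <- if (tot > 0) sum(apply(tc, 2L, max)) / tot else 0
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Maximum matching ratio
#'
#' Builds the bipartite graph between standard and detected complexes with
#' edge weights equal to their overlap scores (all `OS > 0` edges, no
#' threshold), computes an exact maximum-weight matching and divides its
#' weight by the number of standard complexes. Because the matching is
#' one-to-one, a standard complex split across several predictions is
#' credited for only one of the parts.
#'
#' @inheritParams f_measure
#' @return the maximum matching ratio in `[0, 1]`.
#' @export
mmr <- function(detected, standard) {
  if (!length(standard) || !length(detected)) return(0)
  os <- os_matrix(detected, standard)
  ij <- which(os > 0, arr.ind = TRUE)
  if (!nrow(ij)) return(0)
  nd <- length(detected); ns <- length(standard)
  # vertices 1..nd are detected, nd+1..nd+ns standard
  g <- igraph::make_empty_graph(n = nd + ns, directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, nd), rep(TRUE, ns))
  g <- igraph::add_edges(g, rbind(ij[, 1L], nd + ij[, 2L]))
  m <- igraph::max_bipartite_match(g, weights = os[ij])
  m$matching_weight / ns
}

#' Jaccard agreement between prediction and standard
#'
#' Per-pair Jaccard `J(A,B) = |A∩B| / |A∪B|`; `JaccardC` averages, over
#' detected complexes, each one's best `J` against the standard;
#' `JaccardG` averages, over standard complexes, each one's best `J`
#' against the detection; `Jaccard` is their harmonic mean (0 when both
#' are 0).
#'
#' @inheritParams f_measure
#' @return list with `jaccard_c`, `jaccard_g`, `jaccard`.
#' @export
jaccard_metric <- function(detected, standard) {
  stopifnot(length(detected) >= 1L, length(standard) >= 1L)
  jmat <- outer(seq_along(detected), seq_along(standard),
                Vectorize(function(i, j) {
                  a <- unique(detected[[i]]); b <- unique(standard[[j]])
                  length(intersect(a, b)) / length(union(a, b))
                }))
  jc <- mean(apply(jmat, 1L, max))
  jg <- mean(apply(jmat, 2L, max))
  j <- if (jc + jg > 0) 2 * jc * jg / (jc + jg) else 0
  list(jaccard_c = jc, jaccard_g = jg, jaccard = j)
}

#' Total score of an evaluation
#'
#' The sum `F-measure + CR + ACC + MMR + Jaccard`, used as a single
#' composite ranking of detection methods; 5 for a perfect prediction.
#'
#' @param report an evaluation report from [evaluate_complexes()], or a
#'   list with fields `f_measure`, `cr`, `acc`, `mmr`, `jaccard`.
#' @return the total score in `[0, 5]`.
#' @export
total_score <- function(report) {
  report$f_measure + report$cr + report$acc + report$mmr + report$jaccard
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of seeing `K` or more annotated proteins in a cluster of
#' size `C` drawn from a universe of `N` proteins of which `F` carry the
#' annotation: \eqn{p = 1 - \sum_{k=0}^{K-1} \binom{F}{k}\binom{N-F}{C-k} /
#' \binom{N}{C}}. Computed via [stats::phyper()] (log-gamma based, stable
#' for large arguments). `K = 0` gives 1.
#'
#' @param N universe size.
#' @param F_ann number of annotated proteins in the universe.
#' @param C cluster size.
#' @param K number of annotated proteins in the cluster.
#' @return the p-value in `[0, 1]`.
#' @export
hypergeometric_pvalue <- function(N, F_ann, C, K) {
  if (any(c(N, F_ann, C, K) < 0) || F_ann > N || C > N || K > min(F_ann, C)) {
    stop("impossible hypergeometric arguments")
  }
  stats::phyper(K - 1, F_ann, N - F_ann, C, lower.tail = FALSE)
}

#' Functional enrichment of detected complexes
#'
#' Scores each detected complex by the smallest upper-tail hypergeometric
#' p-value over the annotation terms carried by its members, against a
#' user-supplied term map (no live GO download). The annotation universe
#' `N` defaults to the set of proteins in the analyzed network.
#'
#' @param detected a [complex_set()].
#' @param annotations named list mapping protein ID to a character vector
#'   of annotation terms.
#' @param universe character vector of proteins forming the universe
#'   (default: all proteins appearing in `annotations`).
#' @param thresholds p-value cutoffs at which significant complexes are
#'   counted.
#' @return list with `p_values` (best p per complex, `best_term`
#'   attribute-free), and `counts` (named vector of complexes significant
#'   at each threshold).
#' @export
enrichment <- function(detected, annotations, universe = names(annotations),
                       thresholds = c(1e-2, 1e-5, 1e-10, 1e-15, 1e-20)) {
  universe <- unique(universe)
  n_univ <- length(universe)
  ann <- annotations[names(annotations) %in% universe]
  term_to_prot <- list()
  for (p in names(ann)) {
    for (term in ann[[p]]) term_to_prot[[term]] <- c(term_to_prot[[term]], p)
  }
  term_sizes <- lengths(lapply(term_to_prot, unique))

  p_values <- vapply(detected, function(cmplx) {
    cmplx <- intersect(unique(cmplx), universe)
    if (!length(cmplx)) return(1)
    terms <- unique(unlist(ann[cmplx]))
    if (!length(terms)) return(1)
    min(vapply(terms, function(term) {
      k <- length(intersect(cmplx, term_to_prot[[term]]))
      hypergeometric_pvalue(n_univ, term_sizes[[term]], length(cmplx), k)
    }, numeric(1L)))
  }, numeric(1L))

  counts <- vapply(thresholds, function(th) sum(p_values < th), numeric(1L))
  names(counts) <- format(thresholds, scientific = TRUE)
  list(p_values = p_values, counts = counts)
}

#' Co-localization score of detected complexes
#'
#' For each detected complex `j`, `l_ij` counts its members allocated to
#' localization group `i`; the complex's score is the maximal fraction of
#' members found in one group. The aggregate score is
#' \eqn{CL = \sum_j \max_i l_{ij} / \sum_j N_j}; members without
#' localization data count toward `N_j` but toward no group.
#'
#' @param detected a [complex_set()].
#' @param locations named list mapping protein ID to a character vector of
#'   compartments.
#' @return list with `per_complex` (max fraction per complex) and `cl`.
#' @export
colocalization <- function(detected, locations) {
  if (!length(detected)) return(list(per_complex = numeric(), cl = 0))
  max_l <- vapply(detected, function(cmplx) {
    cmplx <- unique(cmplx)
    groups <- unlist(lapply(cmplx, function(p) unique(locations[[p]])))
    if (!length(groups)) return(0)
    max(table(groups))
  }, numeric(1L))
  n_j <- lengths(lapply(detected, unique))
  list(per_complex = max_l / n_j, cl = sum(max_l) / sum(n_j))
}

#' Evaluate a detection against a gold standard
#'
#' Runs the whole metric suite and returns one report: precision, recall,
#' F-measure, coverage rate, Sn/PPV/ACC, maximum matching ratio, Jaccard
#' components and the total score, plus (when attribute data is supplied)
#' enrichment counts and the co-localization score.
#'
#' @param detected,standard [complex_set()]s.
#' @param lambda overlap-score match threshold for the F-measure.
#' @param locations optional named list of compartment sets.
#' @param annotations optional named list of annotation term sets.
#' @param universe optional universe for enrichment (e.g. network node
#'   names).
#' @return an `eval_report` list.
#' @export
evaluate_complexes <- function(detected, standard, lambda = 0.2,
                               locations = NULL, annotations = NULL,
                               universe = NULL) {
  fm <- f_measure(detected, standard, lambda)
  spa <- sn_ppv_acc(detected, standard)
  rep <- list(
    n_detected = length(detected),
    n_matched = fm$n_detected_matched,
    precision = fm$precision, recall = fm$recall, f_measure = fm$f_measure,
    cr = coverage_rate(detected, standard),
    sn = spa$sn, ppv = spa$ppv, acc = spa$acc,
    mmr = mmr(detected, standard)
  )
  jm <- if (length(detected) && length(standard)) jaccard_metric(detected, standard)
        else list(jaccard_c = 0, jaccard_g = 0, jaccard = 0)
  rep <- c(rep, jm)
  rep$total_score <- total_score(rep)
  if (!is.null(locations)) rep$cl <- colocalization(detected, locations)$cl
  if (!is.null(annotations)) {
    rep$enrichment <- enrichment(detected, annotations,
                                 universe = if (is.null(universe)) names(annotations) else universe)
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: %d detected (%d matched)\n  F=%.4f CR=%.4f ACC=%.4f MMR=%.4f Jaccard=%.4f total=%.4f\n",
    x$n_detected, x$n_matched, x$f_measure, x$cr, x$acc, x$mmr, x$jaccard,
    x$total_score))
  if (!is.null(x$cl)) cat(sprintf("  CL=%.4f\n", x$cl))
  invisible(x)
}
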