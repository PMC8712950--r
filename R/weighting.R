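# Multi-evidence edge weighting: four similarity components combined into a
# single interaction confidence in [0, 1].

#' Higher-order common neighbour similarity
#'
#' Topological confidence of the interaction between proteins `v` and `u`:
#' \deqn{HCN(v,u) = \frac{|N(v) \cap N(u)|^2}{|N(v)| \cdot |N(u)| \cdot |N(v) \cup N(u)|}}
#' where neighbourhoods are open (a protein is not its own neighbour). The
#' squared common-neighbour count rewards pairs whose neighbourhoods overlap
#' strongly relative to the combined connectivity of both endpoints. Returns
#' 0 when the pair has no common neighbour or either endpoint is isolated.
#'
#' @param net an `igraph` PPI network.
#' @param v,u protein identifiers (must be nodes of `net`).
#' @return similarity in `[0, 1]`.
#' @export
hcn <- function(net, v, u) {
  nm <- igraph::V(net)$name
  if (!(v %in% nm) || !(u %in% nm)) stop("protein not in network: ", if (v %in% nm) u else v)
  nv <- nm[igraph::neighbors(net, v)]
  nu <- nm[igraph::neighbors(net, u)]
  ncn <- length(intersect(nv, nu))
  den <- length(nv) * length(nu) * length(union(nv, nu))
  if (ncn == 0L || den == 0) return(0)
  ncn^2 / den
}

#' Co-expression similarity
#'
#' Pearson correlation of two expression profiles rescaled from
#' `[-1, 1]` to `[0, 1]` via `(r + 1) / 2`. Missing profiles (`NULL`) and
#' zero-variance profiles carry no co-expression evidence and score 0.
#'
#' @param expr_v,expr_u numeric expression vectors of equal length (or
#'   `NULL` for missing data).
#' @return similarity in `[0, 1]`.
#' @export
pcc <- function(expr_v, expr_u) {
  if (is.null(expr_v) || is.null(expr_u)) return(0)
  if (length(expr_v) != length(expr_u)) stop("expression vectors differ in length")
  if (length(expr_v) < 2L) stop("expression vectors need at least 2 time points")
  if (stats::sd(expr_v) == 0 || stats::sd(expr_u) == 0) return(0)
  (stats::cor(expr_v, expr_u) + 1) / 2
}

#' GO-slim attribute similarity
#'
#' Cosine similarity of the binary GO-slim attribute vectors of two
#' proteins, \eqn{|T_v \cap T_u| / \sqrt{|T_v| \cdot |T_u|}}. An empty term
#' set carries no evidence and scores 0.
#'
#' @param terms_v,terms_u character vectors of GO-slim term IDs.
#' @return similarity in `[0, 1]`.
#' @export
fs <- function(terms_v, terms_u) {
  terms_v <- unique(terms_v); terms_u <- unique(terms_u)
  if (!length(terms_v) || !length(terms_u)) return(0)
  length(intersect(terms_v, terms_u)) / sqrt(length(terms_v) * length(terms_u))
}

#' Subcellular co-localization similarity
#'
#' \deqn{SL(v,u) = \frac{|SL(v) \cap SL(u)|^2}{|SL(v)| \cdot |SL(u)|}}
#' over the compartment sets of the two proteins; 0 when either set is
#' empty.
#'
#' @param loc_v,loc_u character vectors of compartment labels.
#' @return similarity in `[0, 1]`.
#' @export
sl <- function(loc_v, loc_u) {
  loc_v <- unique(loc_v); loc_u <- unique(loc_u)
  if (!length(loc_v) || !length(loc_u)) return(0)
  length(intersect(loc_v, loc_u))^2 / (length(loc_v) * length(loc_u))
}

#' Build the weighted PPI network
#'
#' Weights every edge of `net` with the arithmetic mean of the four
#' evidence components (HCN, PCC, FS, SL); missing evidence contributes 0
#' and the divisor stays 4. Edges whose combined weight is exactly 0 (all
#' four components zero) carry no supporting evidence, are treated as noise
#' and removed; isolated nodes are retained. The four components are kept
#' as edge attributes `hcn`, `pcc`, `fs`, `sl` for audit.
#'
#' @param net an unweighted (or weighted; existing weights are ignored)
#'   `igraph` PPI network.
#' @param attrs an [attribute_bundle()].
#' @return a weighted `igraph` network with the same node set and an edge
#'   subset of `net`.
#' @export
build_weighted_network <- function(net, attrs = attribute_bundle()) {
  stopifnot(inherits(attrs, "attribute_bundle"))
  nm <- igraph::V(net)$name
  el <- igraph::as_edgelist(net)
  if (!nrow(el)) return(net)

  nbrs <- lapply(igraph::as_adj_list(net), function(x) nm[x])
  names(nbrs) <- nm
  deg <- lengths(nbrs)

  n_e <- nrow(el)
  h <- p <- f <- s <- numeric(n_e)
  for (i in seq_len(n_e)) {
    v <- el[i, 1L]; u <- el[i, 2L]
    nv <- nbrs[[v]]; nu <- nbrs[[u]]
    ncn <- length(intersect(nv, nu))
    den <- deg[[v]] * deg[[u]] * length(union(nv, nu))
    h[i] <- if (ncn > 0L && den > 0) ncn^2 / den else 0
    p[i] <- pcc(attrs$expression[[v]], attrs$expression[[u]])
    f[i] <- fs(attrs$go_terms[[v]], attrs$go_terms[[u]])
    s[i] <- sl(attrs$locations[[v]], attrs$locations[[u]])
  }
  w <- (h + p + f + s) / 4
  keep <- h > 0 | p > 0 | f > 0 | s > 0 # exact-zero comparison, no tolerance
  if (any(!keep)) message("removed ", sum(!keep), " zero-weight edge(s)")

  g <- igraph::graph_from_data_frame(
    data.frame(from = el[keep, 1L], to = el[keep, 2L], stringsAsFactors = FALSE),
    directed = FALSE, vertices = nm
  )
  igraph::E(g)$weight <- w[keep]
  igraph::E(g)$hcn <- h[keep]
  igraph::E(g)$pcc <- p[keep]
  igraph::E(g)$fs <- f[keep]
  igraph::E(g)$sl <- s[keep]
  g
}

#' Per-edge evidence components of a weighted network
#'
#' Returns the audit trail left by [build_weighted_network()]: one row per
#' edge with the four evidence components and the combined weight.
#'
#' @param net a network produced by [build_weighted_network()].
#' @return a data frame with columns `u`, `v`, `hcn`, `pcc`, `fs`, `sl`,
#'   `weight`.
#' @export
edge_evidence <- function(net) {
  el <- igraph::as_edgelist(net)
  data.frame(
    u = el[, 1L], v = el[, 2L],
    hcn = igraph::E(net)$hcn, pcc = igraph::E(net)$pcc,
    fs = igraph::E(net)$fs, sl = igraph::E(net)$sl,
    weight = igraph::E(net)$weight,
    stringsAsFactors = FALSE
  )
}
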