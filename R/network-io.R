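#' Build a PPI network from an edge table
#'
#' Constructs an undirected [igraph][igraph::igraph-package] graph from a
#' two-column table of protein identifiers. Protein IDs are treated as
#' case-sensitive opaque strings. Self-loops are dropped and duplicate edges
#' collapsed (the last weight wins); both removals are reported with a
#' message.
#'
#' @param edges two-column character matrix or data frame of interacting
#'   protein pairs.
#' @param weights optional numeric vector of edge weights in `[0, 1]`, one
#'   per row of `edges`. When `NULL` the network is unweighted.
#' @param nodes optional character vector of additional node names to retain
#'   (e.g. isolated proteins).
#' @return an undirected `igraph` object; weighted edges carry a `weight`
#'   edge attribute.
#' @examples
#' net <- ppi_network(rbind(c("a", "b"), c("b", "c")))
#' igraph::vcount(net)
#' @export
ppi_network <- function(edges, weights = NULL, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("`edges` must have two columns")
  u <- as.character(edges[, 1L])
  v <- as.character(edges[, 2L])
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(u)) stop("`weights` must match the number of edges")
  }
  all_nodes <- unique(c(u, v, as.character(nodes)))

  loop <- u == v
  if (any(loop)) {
    message("dropped ", sum(loop), " self-loop(s)")
    u <- u[!loop]; v <- v[!loop]
    if (!is.null(weights)) weights <- weights[!loop]
  }
  a <- pmin(u, v); b <- pmax(u, v)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    message("collapsed ", sum(dup), " duplicate edge(s)")
    a <- a[!dup]; b <- b[!dup]
    if (!is.null(weights)) weights <- weights[!dup]
  }

  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE, vertices = all_nodes
  )
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  g
}

#' Read a PPI edge list file
#'
#' Parses a whitespace/TSV edge list with two protein identifiers per line
#' and an optional numeric third column holding the edge weight. Lines
#' starting with `comment_prefix` and blank lines are skipped.
#'
#' @param path path to the edge list file.
#' @param comment_prefix lines starting with this string are ignored.
#' @return an undirected `igraph` network (see [ppi_network()]).
#' @export
read_edge_list <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines) & !startsWith(lines, comment_prefix)
  lineno <- which(keep)
  toks <- strsplit(lines[keep], "[ \t]+")
  if (!length(toks)) return(ppi_network(matrix(character(), ncol = 2L)))

  nt <- lengths(toks)
  if (any(nt == 1L)) {
    stop("malformed edge list line ", lineno[which(nt == 1L)[1L]],
         ": expected at least two fields")
  }
  u <- vapply(toks, `[`, character(1L), 1L)
  v <- vapply(toks, `[`, character(1L), 2L)
  w_tok <- vapply(toks, function(t) if (length(t) >= 3L) t[[3L]] else NA_character_,
                  character(1L))
  has_w <- !is.na(w_tok)
  weights <- NULL
  if (any(has_w)) {
    w <- suppressWarnings(as.numeric(w_tok))
    bad <- has_w & is.na(w)
    if (any(bad)) {
      stop("non-numeric weight on edge list line ", lineno[which(bad)[1L]])
    }
    w[!has_w] <- 1 # unweighted lines in a weighted file default to full confidence
    weights <- w
  }
  ppi_network(cbind(u, v), weights = weights)
}

#' Write a weighted network as a three-column TSV
#'
#' Edges are written as `u<TAB>v<TAB>weight` with weights at 10 significant
#' digits, endpoints ordered lexicographically within each pair and lines
#' sorted, so output is deterministic. Unweighted networks are written with
#' weight 1.
#'
#' @param net an `igraph` network.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_weighted_network <- function(net, path) {
  el <- igraph::as_edgelist(net)
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  if (nrow(el)) {
    a <- pmin(el[, 1L], el[, 2L])
    b <- pmax(el[, 1L], el[, 2L])
    o <- order(a, b)
    lines <- sprintf("%s\t%s\t%.10g", a[o], b[o], w[o])
  } else {
    lines <- character()
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a set of protein complexes
#'
#' A `complex_set` is a list of non-empty character vectors of protein IDs,
#' optionally named. It carries both predicted clusterings and gold-standard
#' complex catalogues.
#'
#' @param complexes list of character vectors, each a complex.
#' @param labels optional character vector of complex names.
#' @return a `complex_set` object.
#' @export
complex_set <- function(complexes, labels = NULL) {
  complexes <- lapply(complexes, function(m) unique(as.character(m)))
  if (any(lengths(complexes) == 0L)) stop("complexes must be non-empty")
  if (!is.null(labels)) {
    if (length(labels) != length(complexes)) stop("one label per complex required")
    names(complexes) <- labels
  }
  structure(complexes, class = "complex_set")
}

#' @export
`[.complex_set` <- function(x, i) {
  structure(unclass(x)[i], class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  cat("complex_set with", length(x), "complexes;",
      length(unique(unlist(x))), "proteins; sizes",
      if (length(x)) paste(range(lengths(x)), collapse = "-") else "NA", "\n")
  invisible(x)
}

#' Read complexes from a one-complex-per-line file
#'
#' Each non-blank line holds one complex as whitespace-separated protein IDs
#' (the de-facto format of complex detection tools). Within-line duplicate
#' IDs are removed; duplicated complexes (identical sets) are kept but
#' flagged with a warning.
#'
#' @param path path to the cluster file.
#' @return a [complex_set()].
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop("cluster file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty cluster file: ", path)
    return(structure(list(), class = "complex_set"))
  }
  complexes <- lapply(strsplit(lines, "[ \t]+"), unique)
  key <- vapply(complexes, function(m) paste(sort(m), collapse = "\r"), character(1L))
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate complex(es) in ", path)
  }
  complex_set(complexes)
}

#' Write complexes one per line
#'
#' Members are sorted within each line and lines sorted lexicographically,
#' so output is deterministic and round-trips through [read_clusters()] up
#' to line order.
#'
#' @param cs a [complex_set()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_clusters <- function(cs, path) {
  lines <- vapply(cs, function(m) paste(sort(m), collapse = "\t"), character(1L))
  writeLines(sort(lines), path)
  invisible(path)
}

#' Bundle per-protein attribute data
#'
#' Holds the three evidence sources used for edge weighting: gene-expression
#' time courses, GO-slim term sets and subcellular localization sets. Any
#' component may be empty; proteins absent from a component simply carry no
#' evidence of that kind.
#'
#' @param expression named list of numeric vectors (one expression profile
#'   per protein; all profiles must share the same length).
#' @param go_terms named list of character vectors of GO-slim term IDs.
#' @param locations named list of character vectors of compartment labels.
#' @return an `attribute_bundle` object.
#' @export
attribute_bundle <- function(expression = list(), go_terms = list(), locations = list()) {
  if (length(expression)) {
    lens <- lengths(expression)
    if (length(unique(lens)) > 1L) {
      bad <- names(expression)[lens != lens[[1L]]][1L]
      stop("inconsistent expression vector length for protein ", bad)
    }
  }
  structure(list(expression = expression, go_terms = go_terms, locations = locations),
            class = "attribute_bundle")
}

#' @export
print.attribute_bundle <- function(x, ...) {
  cat("attribute_bundle:",
      length(x$expression), "expression profiles,",
      length(x$go_terms), "GO term sets,",
      length(x$locations), "localization sets\n")
  invisible(x)
}

#' Read protein attribute files
#'
#' Reads any subset of the three attribute tables used for edge weighting.
#' `expr_path` is a TSV with a protein ID followed by numeric expression
#' values; all rows must have the same number of time points. `go_path`
#' follows the SGD `go_slim_mapping.tab` dialect: tab-separated, protein in
#' column 1 and the GO term ID in column `go_id_col` (default 6); multiple
#' rows per protein are unioned. `loc_path` holds a protein ID followed by
#' one compartment label per token, rows unioned per protein.
#'
#' @param expr_path,go_path,loc_path file paths, each optional (`NULL` to skip).
#' @param go_id_col 1-based column index of the GO term ID in `go_path`.
#' @return an [attribute_bundle()].
#' @export
read_attributes <- function(expr_path = NULL, go_path = NULL, loc_path = NULL,
                            go_id_col = 6L) {
  expression <- list()
  if (!is.null(expr_path)) {
    if (!file.exists(expr_path)) stop("expression file not found: ", expr_path)
    lines <- trimws(readLines(expr_path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    toks <- strsplit(lines, "[ \t]+")
    for (t in toks) {
      vals <- suppressWarnings(as.numeric(t[-1L]))
      if (anyNA(vals)) stop("non-numeric expression value for protein ", t[[1L]])
      expression[[t[[1L]]]] <- vals
    }
    lens <- lengths(expression)
    if (length(lens) && length(unique(lens)) > 1L) {
      stop("inconsistent expression vector length for protein ",
           names(expression)[lens != lens[[1L]]][1L])
    }
  }

  go_terms <- list()
  if (!is.null(go_path)) {
    if (!file.exists(go_path)) stop("GO mapping file not found: ", go_path)
    lines <- readLines(go_path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "!") & !startsWith(lines, "#")]
    toks <- strsplit(lines, "\t", fixed = TRUE)
    short <- lengths(toks) < go_id_col
    if (any(short)) message("skipped ", sum(short), " GO mapping line(s) without column ", go_id_col)
    for (t in toks[!short]) {
      p <- trimws(t[[1L]]); term <- trimws(t[[go_id_col]])
      if (!nzchar(p) || !nzchar(term)) next
      go_terms[[p]] <- union(go_terms[[p]], term)
    }
  }

  locations <- list()
  if (!is.null(loc_path)) {
    if (!file.exists(loc_path)) stop("localization file not found: ", loc_path)
    lines <- trimws(readLines(loc_path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    toks <- strsplit(lines, "[ \t]+")
    for (t in toks) {
      if (length(t) < 2L) next
      locations[[t[[1L]]]] <- union(locations[[t[[1L]]]], t[-1L])
    }
  }

  attribute_bundle(expression = expression, go_terms = go_terms, locations = locations)
}

#' Density of an undirected simple graph
#'
#' Computes `2E / (N (N - 1))`, either from a network object or directly
#' from node and edge counts.
#'
#' @param net an `igraph` network, or the number of nodes.
#' @param n_edges number of edges (only when `net` is a count).
#' @return the density as a real number.
#' @examples
#' network_density(2674, 7075)
#' @export
network_density <- function(net, n_edges = NULL) {
  if (inherits(net, "igraph")) {
    n <- igraph::vcount(net)
    m <- igraph::ecount(net)
  } else {
    n <- as.numeric(net)
    m <- as.numeric(n_edges)
  }
  2 * m / (n * (n - 1))
}
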