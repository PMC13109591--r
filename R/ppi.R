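#' Construct a PPI graph object
#'
#' Undirected weighted graph; edge weights are combined_score / 1000, so
#' weights lie in (0, 1]. Self-loops are disallowed (the Markov clustering
#' step adds its own).
#'
#' @param nodes character vector of node ids.
#' @param edges data.frame(node1, node2, combined_score) restricted to
#'   `nodes`.
#' @return list of class `ppi_graph` with `nodes` and `edges` (node1, node2,
#'   weight).
#' @export
ppi_graph <- function(nodes, edges) {
  stopifnot(all(edges$node1 %in% nodes), all(edges$node2 %in% nodes))
  if (any(edges$node1 == edges$node2)) stop("self-loop in edges", call. = FALSE)
  e <- data.frame(node1 = edges$node1, node2 = edges$node2,
                  weight = edges$combined_score / 1000)
  structure(list(nodes = sort(unique(nodes)), edges = e), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("<ppi_graph> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Induced DEG-seeded interaction network
#'
#' Filters the edge list at `threshold` (0-1000 scale) and takes the induced
#' subgraph on the seed genes. Seeds with no qualifying edges stay as
#' isolated nodes; if no seed appears anywhere in the edge list the call is
#' an error.
#'
#' @param edges edge-list data.frame (node1, node2, combined_score).
#' @param seeds seed gene ids.
#' @param threshold minimum combined score (e.g. 400 or 700).
#' @return a [ppi_graph()] on the seed set.
#' @export
build_seeded_network <- function(edges, seeds, threshold = 400) {
  seeds <- unique(seeds)
  present <- seeds %in% c(edges$node1, edges$node2)
  if (!any(present))
    stop("no seed gene present in the edge list", call. = FALSE)
  keep <- edges$combined_score >= threshold &
    edges$node1 %in% seeds & edges$node2 %in% seeds
  ppi_graph(seeds, edges[keep, , drop = FALSE])
}

#' Expand a network by first- and second-order interactors
#'
#' Candidate interactors are the neighbors of the current node set (order 1)
#' and neighbors-of-neighbors (order 2) in the full edge list, ranked by the
#' number of connections into the current node set (ties broken by summed
#' edge score into the set, then node name) and truncated at `max_added`.
#' All edges among retained nodes are included.
#'
#' @param graph a [ppi_graph()].
#' @param edges full edge-list data.frame.
#' @param order 1 or 2 (neighborhood depth).
#' @param max_added maximum number of nodes to add (Inf = all).
#' @param threshold minimum combined score for traversed/induced edges.
#' @return expanded [ppi_graph()].
#' @export
expand_network <- function(graph, edges, order = 2, max_added = Inf,
                           threshold = 0) {
  stopifnot(order %in% c(1, 2))
  if (max_added == 0) return(graph)
  e <- edges[edges$combined_score >= threshold, , drop = FALSE]
  current <- graph$nodes
  frontier <- current
  candidates <- character()
  for (d in seq_len(order)) {
    nb <- unique(c(e$node2[e$node1 %in% frontier],
                   e$node1[e$node2 %in% frontier]))
    nb <- setdiff(nb, c(current, candidates))
    candidates <- c(candidates, nb)
    frontier <- nb
  }
  if (length(candidates)) {
    touches <- (e$node1 %in% candidates & e$node2 %in% current) |
      (e$node2 %in% candidates & e$node1 %in% current)
    cand_end <- ifelse(e$node1[touches] %in% candidates,
                       e$node1[touches], e$node2[touches])
    n_conn <- table(factor(cand_end, levels = candidates))
    s_sum <- tapply(e$combined_score[touches],
                    factor(cand_end, levels = candidates), sum)
    s_sum[is.na(s_sum)] <- 0
    ord <- order(-as.numeric(n_conn), -as.numeric(s_sum), candidates)
    candidates <- candidates[ord][seq_len(min(max_added, length(candidates)))]
  }
  nodes <- union(current, candidates)
  keep <- e$node1 %in% nodes & e$node2 %in% nodes
  ppi_graph(nodes, e[keep, , drop = FALSE])
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Adds per-node self-loops (weight = maximum incident edge weight, 1 for
#' isolated nodes), column-normalizes, then alternates expansion (matrix
#' squaring) and inflation (elementwise power `inflation`, renormalize) with
#' pruning of entries below `prune`, until the matrix changes by less than
#' `tol` or `max_iter` is reached (then a warning flag is set). Clusters are
#' read from the attractor structure: attractor rows grouped by the
#' connected components of their mutual support; every node joins the
#' attractor cluster holding the largest share of its column mass (ties go
#' to the lexicographically first cluster).
#'
#' @param graph a [ppi_graph()].
#' @param inflation inflation exponent.
#' @param prune entries below this are zeroed each iteration.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance (max absolute change).
#' @return list of class `module_partition`: `modules` (named list of node
#'   vectors), `membership` (named integer), `converged`, `params`.
#' @export
mcl <- function(graph, inflation = 2, prune = 1e-5, max_iter = 100,
                tol = 1e-6) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) stop("empty graph", call. = FALSE)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$node1, nodes)
    j <- match(graph$edges$node2, nodes)
    A[cbind(i, j)] <- graph$edges$weight
    A[cbind(j, i)] <- graph$edges$weight
  }
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), `/`)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, `/`)
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  if (!converged)
    warning("MCL did not converge within max_iter; returning current state",
            call. = FALSE)
  attractors <- which(diag(M) > prune)
  if (!length(attractors)) attractors <- seq_len(n)
  sup <- M[attractors, , drop = FALSE] > prune
  adj <- (sup %*% t(sup)) > 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max", diag = FALSE)
  comp <- igraph::components(g)$membership
  n_cl <- max(comp)
  mass <- matrix(0, n_cl, n)
  for (c_id in seq_len(n_cl)) {
    rows <- attractors[comp == c_id]
    mass[c_id, ] <- colSums(M[rows, , drop = FALSE])
  }
  membership <- apply(mass, 2, which.max)  # ties: first (lexicographic id)
  names(membership) <- nodes
  modules <- split(nodes, membership)
  names(modules) <- sprintf("M%02d", as.integer(names(modules)))
  structure(list(modules = modules, membership = membership,
                 converged = converged,
                 params = list(inflation = inflation, prune = prune)),
            class = "module_partition")
}

#' Validate PPI modules as gene sets via pre-ranked GSEA
#'
#' Treats every module of at least `min_size` nodes as a custom gene set and
#' runs [gsea_prerank()] against each supplied ranked list, adjusting FDR
#' within each contrast. Modules with no overlap with a ranked universe are
#' skipped with a warning.
#'
#' @param partition a `module_partition` from [mcl()].
#' @param ranked_lists named list of ranked score vectors (one per contrast).
#' @param min_size minimum module size to test.
#' @param n_perm,seed,weight passed to [gsea_prerank()].
#' @return data.frame with a `contrast` column prepended to the GSEA output.
#' @export
validate_modules_gsea <- function(partition, ranked_lists, min_size = 5,
                                  n_perm = 1000, seed = 1L, weight = 1) {
  sets <- partition$modules[lengths(partition$modules) >= min_size]
  if (!length(sets)) stop("no module of size >= min_size", call. = FALSE)
  out <- lapply(names(ranked_lists), function(ct) {
    res <- gsea_prerank(ranked_lists[[ct]], sets, weight = weight,
                        n_perm = n_perm, seed = seed, min_size = min_size)
    if (nrow(res)) cbind(contrast = ct, res) else NULL
  })
  do.call(rbind, out)
}
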