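#' Directed weighted graph from a dyadic interaction matrix
#'
#' @param mat square count matrix (zero diagonal) from
#'   [build_dyad_matrix()].
#' @return an igraph directed graph with edge attribute `weight`.
#' @export
dyad_graph <- function(mat) {
  if (nrow(mat) != ncol(mat)) stop("dyad matrix must be square")
  igraph::graph_from_adjacency_matrix(mat, mode = "directed",
                                      weighted = TRUE, diag = FALSE)
}

#' @keywords internal
as_dyad_matrix <- function(net) {
  if (igraph::is_igraph(net))
    as.matrix(igraph::as_adjacency_matrix(net, attr = "weight", sparse = FALSE))
  else as.matrix(net)
}

#' Network density
#'
#' Proportion of possible directed ties that exist in the network; weights
#' define edge existence only.
#'
#' @param net dyadic count matrix or igraph graph.
#' @return density in `[0, 1]`.
#' @export
network_density <- function(net) {
  m <- as_dyad_matrix(net)
  n <- nrow(m)
  if (n < 2) stop("density requires at least 2 nodes")
  sum(m > 0) / (n * (n - 1))
}

#' Average path length
#'
#' Mean unweighted shortest-path length over all ordered pairs of distinct
#' nodes that are reachable in the directed network; NA if no pair is
#' reachable.
#'
#' @param net dyadic count matrix or igraph graph.
#' @return mean number of steps (>= 1), or NA.
#' @export
average_path_length <- function(net) {
  m <- as_dyad_matrix(net)
  if (nrow(m) < 2) stop("average path length requires at least 2 nodes")
  g <- dyad_graph(m)
  d <- igraph::distances(g, mode = "out", weights = NA)
  d <- d[upper.tri(d) | lower.tri(d)]
  d <- d[is.finite(d)]
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Freeman out-degree centralization
#'
#' How concentrated initiated connections are on few individuals:
#' `sum(max(outdeg) - outdeg) / (n - 1)^2` on binary out-degrees, 1 for an
#' out-star and 0 when all out-degrees are equal.
#'
#' @param net dyadic count matrix or igraph graph.
#' @return centralization in `[0, 1]`.
#' @export
outdegree_centralization <- function(net) {
  m <- as_dyad_matrix(net)
  n <- nrow(m)
  if (n < 2) stop("centralization requires at least 2 nodes")
  deg <- rowSums(m > 0)
  sum(max(deg) - deg) / (n - 1)^2
}

#' Individual network metrics
#'
#' Per-node roles in the directed network: in-/out-degree (counts of
#' distinct received/initiated ties), betweenness and closeness on the
#' directed unweighted graph, Bonacich power centrality with attenuation
#' `beta` (default 0.9 / largest eigenvalue of the binary adjacency), and
#' hub centrality from the mutually reinforcing hub/authority iteration on
#' the weighted adjacency, scaled to maximum 1.
#'
#' Closeness uses outgoing distances and excludes unreachable nodes; nodes
#' that reach no one get NA. An edgeless network yields all-zero hub scores.
#'
#' @param net dyadic count matrix or igraph graph.
#' @param beta Bonacich attenuation; NULL for the default.
#' @return data.frame, one row per node: `in_degree`, `out_degree`,
#'   `betweenness`, `closeness`, `bonacich_power`, `hub_centrality`.
#' @export
node_metrics <- function(net, beta = NULL) {
  m <- as_dyad_matrix(net)
  n <- nrow(m)
  if (n < 2) stop("node metrics require at least 2 nodes")
  g <- dyad_graph(m)
  bin <- (m > 0) + 0
  if (is.null(beta)) {
    lam <- max(abs(eigen(bin, only.values = TRUE)$values))
    beta <- if (lam > 0) 0.9 / lam else 0
  }
  bp <- tryCatch(igraph::power_centrality(g, exponent = beta),
                 error = function(e) rep(NA_real_, n))
  hub <- if (any(m > 0)) {
    suppressWarnings(igraph::hits_scores(g)$hub)
  } else rep(0, n)
  cl <- suppressWarnings(igraph::closeness(g, mode = "out", weights = NA))
  data.frame(
    row.names = rownames(m),
    in_degree = colSums(bin),
    out_degree = rowSums(bin),
    betweenness = igraph::betweenness(g, directed = TRUE, weights = NA),
    closeness = cl,
    bonacich_power = bp,
    hub_centrality = hub
  )
}

#' Global and daily network metric table for one behavior category
#'
#' Builds the per-day directed weighted networks (scored dark+light windows
#' of each day) and the pooled 4-day network for a behavior category and
#' returns the global metrics.
#'
#' @param events validated event table of one housing group.
#' @param category dyadic behavior category (grouped label).
#' @param animals ordered animal ids.
#' @param days days analyzed (default 1:4).
#' @return data.frame with one row per day plus a pooled `"all"` row:
#'   `day`, `density`, `average_path_length`, `outdegree_centralization`.
#' @export
network_metrics_by_day <- function(events, category, animals = NULL,
                                   days = 1:4) {
  one <- function(d, label) {
    m <- build_dyad_matrix(events, category, animals = animals, days = d)
    data.frame(day = label, density = network_density(m),
               average_path_length = average_path_length(m),
               outdegree_centralization = outdegree_centralization(m))
  }
  out <- do.call(rbind, lapply(days, function(d) one(d, as.character(d))))
  rbind(out, one(days, "all"))
}
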