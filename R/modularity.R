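# Resolution-parameterized weighted modularity and the incremental gain of a
# single node move.
#
# For a partition C of a weighted graph with adjacency w_ij, weighted degrees
# k_i and half-total weight a = (1/2) sum_ij w_ij, the quality function is
#
#   M_lambda(C) = (1/2a) * sum_ij [ lambda * w_ij - k_i k_j / (2a) ] * [Ci == Cj]
#
# which reduces to standard weighted modularity at lambda = 1. The resolution
# lambda multiplies the observed-weight term, so a LOWER lambda makes the
# degree-null term relatively stronger and yields more, smaller clusters.

#' Weighted modularity of a partition, with resolution
#'
#' Evaluates the resolution-parameterized modularity above. At `resolution
#' = 1` the all-in-one partition scores exactly 0 and the value lies in
#' \eqn{[-1, 1]}.
#'
#' @param g Weighted igraph (edge attribute `weight`; absent weights count
#'   as 1). Self-loops are supported (their weight enters the degree twice,
#'   the igraph convention), although a DDSN has none.
#' @param partition A `ddsn_partition`, or a membership vector named by node.
#' @param resolution Positive resolution \eqn{\lambda}.
#' @return Scalar modularity value.
#' @export
weighted_modularity <- function(g, partition, resolution = 1) {
  if (igraph::ecount(g) == 0) {
    stop("modularity is undefined on an edgeless graph", call. = FALSE)
  }
  memb <- partition_membership(partition)
  vn <- igraph::V(g)$name
  if (!all(vn %in% names(memb))) {
    stop("partition does not cover all nodes", call. = FALSE)
  }
  m <- memb[vn]
  w <- edge_weights(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  deg <- igraph::strength(g, weights = w, loops = TRUE)
  a <- sum(deg) / 2
  same <- m[el[, 1]] == m[el[, 2]]
  loop <- el[, 1] == el[, 2]
  # each non-loop edge contributes w to both ordered pairs (i,j) and (j,i);
  # a self-loop (i,i) contributes 2w to the single ordered pair
  w_in <- sum(w[same & !loop]) + sum(w[loop])
  k_tot <- tapply(deg, m, sum)
  resolution * w_in / a - sum((k_tot / (2 * a))^2)
}

#' Aggregates needed to score a single node move
#'
#' Collects, for a proposal to move `node` into cluster `dest`, the
#' quantities the incremental gain formula consumes: the node's weighted
#' degree `k_i`; its link weights into the destination (`k_i_dest`) and into
#' its current cluster excluding itself (`k_i_src`); and the total weighted
#' degrees of destination and source clusters excluding the node
#' (`k_tot_dest`, `k_tot_src`). Also reports each cluster's internal weight
#' `k_in` for inspection.
#'
#' @param g Weighted igraph.
#' @param partition Partition covering `g`.
#' @param node Node name to move.
#' @param dest Cluster index to move it into.
#' @return A list of class `cluster_aggregates`.
#' @export
cluster_aggregates <- function(g, partition, node, dest) {
  memb <- partition_membership(partition)
  vn <- igraph::V(g)$name
  stopifnot(node %in% vn)
  m <- memb[vn]
  w <- edge_weights(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  deg <- igraph::strength(g, weights = w, loops = TRUE)
  src <- unname(memb[node])

  inc <- el[, 1] == node | el[, 2] == node
  other <- ifelse(el[inc, 1] == node, el[inc, 2], el[inc, 1])
  wi <- w[inc]
  not_self <- other != node
  other <- other[not_self]; wi <- wi[not_self]

  in_weight <- function(cl) {
    keep <- m[el[, 1]] == cl & m[el[, 2]] == cl
    sum(w[keep])
  }
  k_tot_cl <- function(cl, excl) {
    sum(deg[m == cl & vn != excl])
  }
  structure(list(
    node = node, src = src, dest = dest,
    k_i = unname(deg[node]),
    k_i_dest = sum(wi[m[other] == dest]),
    k_i_src = sum(wi[m[other] == src]),
    k_tot_dest = k_tot_cl(dest, node),
    k_tot_src = k_tot_cl(src, node),
    k_in_dest = in_weight(dest),
    k_in_src = in_weight(src)
  ), class = "cluster_aggregates")
}

#' Modularity gain of moving one node between clusters
#'
#' Returns \eqn{\Delta M} such that it equals
#' `weighted_modularity(after move) - weighted_modularity(before move)`
#' exactly. With the shorthand of [cluster_aggregates()]:
#'
#' \deqn{\Delta M = \lambda (k_{i,dest} - k_{i,src})/a
#'       - k_i (K_{dest} - K_{src}) / (2 a^2)}
#'
#' where the cluster degree totals exclude the moving node. Moving a
#' zero-degree node gains 0; the gain of merging two nodes joined by a unit
#' edge out of singletons at \eqn{\lambda = 1} is 0.5.
#'
#' @param agg A `cluster_aggregates`.
#' @param a Half the total weight of the graph, \eqn{a = \frac12\sum_{ij} w_{ij}}.
#' @param resolution Resolution \eqn{\lambda}.
#' @return Scalar gain.
#' @export
modularity_gain <- function(agg, a, resolution = 1) {
  stopifnot(inherits(agg, "cluster_aggregates"))
  if (identical(agg$src, agg$dest)) return(0)
  resolution * (agg$k_i_dest - agg$k_i_src) / a -
    agg$k_i * (agg$k_tot_dest - agg$k_tot_src) / (2 * a^2)
}
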