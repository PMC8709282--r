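# Resolution-parameterized Louvain-style optimizer: greedy local moves
# (accept a move only for a strictly positive modularity gain) alternating
# with graph aggregation, restarted from several seeds, best partition kept.
# Cluster indices are renumbered 0,1,2,... by decreasing size so that C0 is
# (one of) the largest cluster(s).

#' Partition object
#'
#' Bundles a cluster assignment with the settings that produced it. Clusters
#' are indexed 0,1,2,... by decreasing size (ties broken by the smallest
#' member id), so `C0` is always a largest cluster.
#'
#' @param membership Integer vector of 0-based cluster indices named by node.
#' @param resolution,seed,restarts Settings recorded for provenance.
#' @param modularity Modularity value of the assignment (NA for an edgeless
#'   graph).
#' @return An object of class `ddsn_partition`.
#' @export
ddsn_partition <- function(membership, resolution = NA_real_, seed = NA_integer_,
                           restarts = NA_integer_, modularity = NA_real_) {
  stopifnot(!is.null(names(membership)))
  membership <- stats::setNames(as.integer(membership), names(membership))
  ids <- sort(unique(membership))
  if (!identical(ids, seq_along(ids) - 1L)) {
    stop("cluster indices must be contiguous from 0", call. = FALSE)
  }
  structure(
    list(membership = membership, resolution = resolution, seed = seed,
         restarts = restarts, modularity = modularity,
         n_clusters = length(ids)),
    class = "ddsn_partition"
  )
}

partition_membership <- function(partition) {
  if (inherits(partition, "ddsn_partition")) return(partition$membership)
  if (is.null(names(partition))) {
    stop("membership vector must be named by node", call. = FALSE)
  }
  stats::setNames(as.integer(partition), names(partition))
}

#' @export
print.ddsn_partition <- function(x, ...) {
  cat(sprintf("<ddsn_partition> %d nodes in %d clusters | resolution %s | modularity %s\n",
              length(x$membership), x$n_clusters,
              format(x$resolution), format(round(x$modularity, 4))))
  invisible(x)
}

#' @export
as.data.frame.ddsn_partition <- function(x, ...) {
  data.frame(drug_id = names(x$membership), cluster = unname(x$membership),
             stringsAsFactors = FALSE)
}

#' Cluster a weighted graph by resolution-parameterized modularity
#'
#' Runs the Louvain-style optimizer: starting from all-singletons, nodes are
#' visited in a seeded random order and moved to the neighboring cluster with
#' the largest strictly positive modularity gain (gains are exact
#' quality-function differences; ties never trigger a move, and "positive" means
#' `> 1e-12`). When a pass makes no move, clusters are collapsed into an
#' aggregated graph (internal weights become self-loops) and the local-move
#' phase repeats, until aggregation no longer changes the graph. The whole
#' procedure is repeated from `restarts` derived seeds and the partition with
#' the highest modularity is kept.
#'
#' @param g Weighted igraph (edge attribute `weight`; absent weights count
#'   as 1). Isolated nodes remain singleton clusters.
#' @param resolution Resolution \eqn{\lambda > 0}; lower values give more,
#'   smaller clusters.
#' @param seed Integer seed; the run is fully deterministic given
#'   `(g, resolution, seed, restarts)`.
#' @param restarts Number of independent seeded runs.
#' @return A [ddsn_partition()].
#' @export
louvain_cluster <- function(g, resolution = 1, seed = 42L, restarts = 5L) {
  stopifnot(igraph::vcount(g) > 0, resolution > 0, restarts >= 1)
  vn <- igraph::V(g)$name
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(g)))
  n <- length(vn)
  if (igraph::ecount(g) == 0) {
    memb <- stats::setNames(seq_len(n) - 1L, vn)
    return(ddsn_partition(renumber_membership(memb), resolution, seed,
                          restarts, NA_real_))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- edge_weights(g)
  # drop self-loops from the input; internally they only arise by aggregation
  keep <- el[, 1] != el[, 2]
  el <- el[keep, , drop = FALSE]; w <- w[keep]

  best <- NULL
  for (r in seq_len(restarts)) {
    memb <- louvain_once(n, el, w, resolution, seed = seed + (r - 1L))
    mod <- modularity_flat(n, el, w, memb, resolution)
    if (is.null(best) || mod > best$mod + 1e-12) {
      best <- list(memb = memb, mod = mod)
    }
  }
  memb <- stats::setNames(best$memb - 1L, vn)
  ddsn_partition(renumber_membership(memb), resolution, seed, restarts,
                 best$mod)
}

# modularity from a flat edge list (no self-loops), 1-based membership
modularity_flat <- function(n, el, w, memb, resolution) {
  deg <- numeric(n)
  for (col in 1:2) {
    s <- tapply(w, el[, col], sum)
    deg[as.integer(names(s))] <- deg[as.integer(names(s))] + s
  }
  a <- sum(w)
  w_in <- sum(w[memb[el[, 1]] == memb[el[, 2]]])
  k_tot <- tapply(deg, memb, sum)
  resolution * w_in / a - sum((k_tot / (2 * a))^2)
}

louvain_once <- function(n, el, w, resolution, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  flat <- seq_len(n)
  cur_n <- n; cur_el <- el; cur_w <- w; cur_self <- numeric(n)
  repeat {
    lvl <- louvain_one_level(cur_n, cur_el, cur_w, cur_self, resolution)
    flat <- lvl$comm[flat]
    n_comm <- max(lvl$comm)
    if (!lvl$improved || n_comm == cur_n) break
    agg <- aggregate_communities(cur_el, cur_w, cur_self, lvl$comm, n_comm)
    cur_n <- n_comm; cur_el <- agg$el; cur_w <- agg$w; cur_self <- agg$self
    if (cur_n == 1) break
  }
  flat
}

# One local-move phase. Edge list has no self-loops; `selfw` carries the
# aggregated internal weight of each node (counts twice in its degree).
louvain_one_level <- function(n, el, w, selfw, resolution) {
  nb <- vector("list", n); nw <- vector("list", n)
  if (nrow(el) > 0) {
    both <- rbind(el, el[, 2:1, drop = FALSE])
    ww <- c(w, w)
    o <- order(both[, 1])
    both <- both[o, , drop = FALSE]; ww <- ww[o]
    idx <- split(seq_len(nrow(both)), both[, 1])
    for (k in names(idx)) {
      i <- as.integer(k)
      nb[[i]] <- both[idx[[k]], 2]
      nw[[i]] <- ww[idx[[k]]]
    }
  }
  deg <- vapply(nw, sum, numeric(1)) + 2 * selfw
  a <- sum(w) + sum(selfw)
  comm <- seq_len(n)
  comm_tot <- deg
  improved <- FALSE
  repeat {
    moved <- 0L
    for (i in sample.int(n)) {
      if (length(nb[[i]]) == 0) next
      c_old <- comm[i]
      comm_tot[c_old] <- comm_tot[c_old] - deg[i]
      nbc <- comm[nb[[i]]]
      links <- tapply(nw[[i]], nbc, sum)
      cand <- as.integer(names(links))
      gains <- resolution * as.numeric(links) / a -
        deg[i] * comm_tot[cand] / (2 * a^2)
      stay <- match(c_old, cand)
      gain_stay <- if (is.na(stay)) {
        # no links back into the (depleted) current community
        -deg[i] * comm_tot[c_old] / (2 * a^2)
      } else {
        gains[stay]
      }
      # best candidate; ties resolved to the smallest community index
      o <- order(-gains, cand)
      b <- o[1]
      if (cand[b] != c_old && gains[b] - gain_stay > 1e-12) {
        comm[i] <- cand[b]
        comm_tot[cand[b]] <- comm_tot[cand[b]] + deg[i]
        moved <- moved + 1L
        improved <- TRUE
      } else {
        comm_tot[c_old] <- comm_tot[c_old] + deg[i]
      }
    }
    if (moved == 0L) break
  }
  # relabel contiguously 1..k
  ids <- sort(unique(comm))
  list(comm = match(comm, ids), improved = improved)
}

aggregate_communities <- function(el, w, selfw, comm, n_comm) {
  self_new <- numeric(n_comm)
  s <- tapply(selfw, comm, sum)
  self_new[as.integer(names(s))] <- s
  if (nrow(el) > 0) {
    c1 <- comm[el[, 1]]; c2 <- comm[el[, 2]]
    internal <- c1 == c2
    if (any(internal)) {
      s <- tapply(w[internal], c1[internal], sum)
      self_new[as.integer(names(s))] <- self_new[as.integer(names(s))] + s
    }
    lo <- pmin(c1[!internal], c2[!internal])
    hi <- pmax(c1[!internal], c2[!internal])
    if (length(lo) > 0) {
      key <- paste(lo, hi)
      ws <- tapply(w[!internal], key, sum)
      ends <- do.call(rbind, strsplit(names(ws), " ", fixed = TRUE))
      el_new <- cbind(as.integer(ends[, 1]), as.integer(ends[, 2]))
      return(list(el = el_new, w = as.numeric(ws), self = self_new))
    }
  }
  list(el = matrix(integer(0), 0, 2), w = numeric(0), self = self_new)
}

# renumber a 0-based named membership: clusters sorted by decreasing size,
# ties by lexicographically smallest member
renumber_membership <- function(memb) {
  sizes <- table(memb)
  smallest <- vapply(split(names(memb), memb), min, character(1))
  ord <- order(-as.integer(sizes), smallest[names(sizes)])
  new_id <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
  stats::setNames(new_id[as.character(memb)], names(memb))
}
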