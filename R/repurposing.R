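# Repurposing layer: label each DDSN cluster with its dominant level-1 ATC
# letter, tune the clustering resolution by maximizing repositionings
# confirmed between two dated ATC tables, and emit repositioning hints.

#' Level-1 ATC histogram of a drug cluster
#'
#' Counts, per level-1 letter, the drugs in the cluster carrying at least one
#' ATC code with that letter. A drug contributes at most 1 to each letter, no
#' matter how many of its codes share it; drugs without any ATC code are
#' tallied separately.
#'
#' @param cluster_drugs Character vector of drug ids in one cluster.
#' @param atc An `atc_table`.
#' @return A list of class `cluster_histogram` with elements `letters`
#'   (named integer vector, count-descending then letter-ascending),
#'   `n_drugs`, `n_no_atc`.
#' @export
cluster_histogram <- function(cluster_drugs, atc) {
  sets <- atc_level1_sets(atc)
  per_drug <- sets[intersect(cluster_drugs, names(sets))]
  letters <- unlist(per_drug, use.names = FALSE)
  counts <- if (length(letters) > 0) {
    tab <- table(letters)
    cnt <- as.integer(tab)
    nmv <- names(tab)
    o <- order(-cnt, nmv)
    stats::setNames(cnt[o], nmv[o])
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(
    list(letters = counts,
         n_drugs = length(cluster_drugs),
         n_no_atc = length(cluster_drugs) - length(per_drug)),
    class = "cluster_histogram"
  )
}

#' Dominant level-1 letter(s) of a cluster histogram
#'
#' The dominant property of a cluster is the level-1 ATC letter carried by
#' the most drugs in it; ties are broken alphabetically. `k = 1` (the
#' default) reproduces the labeling the confirmation and hint algorithms use;
#' larger `k` exposes the runner-up letters for exploration.
#'
#' @param h A `cluster_histogram`.
#' @param k Number of top letters to return.
#' @return Character vector of up to `k` letters, most frequent first.
#' @export
dominant_property <- function(h, k = 1) {
  stopifnot(inherits(h, "cluster_histogram"), k >= 1)
  if (length(h$letters) == 0) {
    stop("cluster has no ATC-coded drugs: no dominant property", call. = FALSE)
  }
  utils::head(names(h$letters), k)
}

# list: cluster index (as character) -> member drug ids
cluster_members <- function(partition) {
  memb <- partition_membership(partition)
  split(names(memb), memb)
}

# per-cluster dominant letters at top-k; clusters with no ATC-coded drugs
# are dropped (they can label nothing)
cluster_dominants <- function(partition, atc, k = 1) {
  members <- cluster_members(partition)
  doms <- lapply(members, function(ds) {
    h <- cluster_histogram(ds, atc)
    if (length(h$letters) == 0) return(NULL)
    dominant_property(h, k)
  })
  doms[!vapply(doms, is.null, logical(1))]
}

#' Repositionings confirmed between two dated ATC tables
#'
#' For each cluster's dominant letter(s) `Pi` (computed from the OLD table)
#' and each member drug `Dj`, the pair is a confirmed repositioning iff `Pi`
#' is absent from `Dj`'s old level-1 letters and present in its new ones --
#' i.e. the drug gained, in the newer database release, exactly the
#' anatomical group its cluster predicted.
#'
#' @param partition A `ddsn_partition` over the DDSN.
#' @param atc_old,atc_new `atc_table`s from the older and newer release.
#' @param k Number of dominant letters per cluster considered (1 = the
#'   algorithmic default).
#' @return A list of class `confirmed_set`: `records` tibble
#'   (`drug_id`, `cluster`, `predicted_letter`), `n`, `resolution`.
#' @export
confirmed_repositionings <- function(partition, atc_old, atc_new, k = 1) {
  old_sets <- atc_level1_sets(atc_old)
  new_sets <- atc_level1_sets(atc_new)
  members <- cluster_members(partition)
  doms <- cluster_dominants(partition, atc_old, k)

  rows <- list()
  for (ci in names(doms)) {
    for (p in doms[[ci]]) {
      for (dj in members[[ci]]) {
        old_l <- old_sets[[dj]]
        new_l <- new_sets[[dj]]
        if (!(p %in% old_l) && (p %in% new_l)) {
          rows[[length(rows) + 1L]] <-
            data.frame(drug_id = dj, cluster = as.integer(ci),
                       predicted_letter = p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  records <- if (length(rows) > 0) {
    tibble::as_tibble(do.call(rbind, rows))
  } else {
    tibble::tibble(drug_id = character(0), cluster = integer(0),
                   predicted_letter = character(0))
  }
  res <- if (inherits(partition, "ddsn_partition")) partition$resolution else NA_real_
  structure(list(records = records, n = nrow(records), resolution = res),
            class = "confirmed_set")
}

#' @export
print.confirmed_set <- function(x, ...) {
  cat(sprintf("<confirmed_set> %d confirmed repositioning(s) at resolution %s\n",
              x$n, format(x$resolution)))
  invisible(x)
}

#' Tune the clustering resolution by confirmed repositionings
#'
#' Sweeps the resolution grid, clusters the DDSN at each value with the same
#' seed/restart policy (so counts are comparable across the grid), counts
#' repositionings confirmed between the two ATC tables, and selects the
#' resolution with the highest count. When several grid values tie at the
#' maximum, the largest resolution is reported.
#'
#' @param g DDSN igraph built from the OLDER release's interactions.
#' @param atc_old,atc_new `atc_table`s of the older and newer release.
#' @param grid Resolutions to try; default 0.1 to 5.0 in steps of 0.1.
#' @param seed,restarts Passed to [louvain_cluster()] at every grid point.
#' @param k Dominant letters per cluster (see [dominant_property()]).
#' @return A list of class `ddsn_sweep`: `sweep` tibble
#'   (`lambda`, `n_clusters`, `n_confirmed`), `lambda_max`, `best`
#'   (the `confirmed_set` at `lambda_max`).
#' @export
tune_resolution <- function(g, atc_old, atc_new,
                            grid = seq(0.1, 5.0, by = 0.1),
                            seed = 42L, restarts = 5L, k = 1) {
  stopifnot(length(grid) > 0)
  grid <- sort(grid)
  n_clusters <- integer(length(grid))
  n_confirmed <- integer(length(grid))
  confirmed <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    p <- louvain_cluster(g, resolution = grid[i], seed = seed,
                         restarts = restarts)
    cs <- confirmed_repositionings(p, atc_old, atc_new, k = k)
    n_clusters[i] <- p$n_clusters
    n_confirmed[i] <- cs$n
    confirmed[[i]] <- cs
  }
  best_i <- max(which(n_confirmed == max(n_confirmed)))  # largest lambda wins ties
  structure(
    list(sweep = tibble::tibble(lambda = grid, n_clusters = n_clusters,
                                n_confirmed = n_confirmed),
         lambda_max = grid[best_i],
         best = confirmed[[best_i]],
         seed = seed, restarts = restarts),
    class = "ddsn_sweep"
  )
}

#' @export
print.ddsn_sweep <- function(x, ...) {
  cat(sprintf("<ddsn_sweep> %d resolutions | lambda_max = %s with %d confirmed\n",
              nrow(x$sweep), format(x$lambda_max), x$best$n))
  invisible(x)
}

#' Hints implied by an existing partition
#'
#' Every drug whose own level-1 letters (possibly none) do not include its
#' cluster's dominant letter yields one hint `(drug, predicted letter)`.
#' Drugs without any ATC code are eligible recipients and are flagged
#' `no_current_atc`. Clusters with no ATC-coded drugs produce no hints.
#'
#' @param partition A `ddsn_partition`.
#' @param atc `atc_table` used both for the histograms and the drugs' own
#'   letters.
#' @param k Dominant letters per cluster.
#' @return Tibble with columns `drug_id`, `cluster`, `current_level1`
#'   (comma-joined letters), `predicted_letter`, `no_current_atc`.
#' @export
hints_from_partition <- function(partition, atc, k = 1) {
  sets <- atc_level1_sets(atc)
  members <- cluster_members(partition)
  doms <- cluster_dominants(partition, atc, k)
  rows <- list()
  for (ci in names(doms)) {
    for (p in doms[[ci]]) {
      for (dj in members[[ci]]) {
        own <- sets[[dj]]
        if (!(p %in% own)) {
          rows[[length(rows) + 1L]] <- data.frame(
            drug_id = dj, cluster = as.integer(ci),
            current_level1 = paste(own, collapse = ","),
            predicted_letter = p,
            no_current_atc = length(own) == 0,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(drug_id = character(0), cluster = integer(0),
                          current_level1 = character(0),
                          predicted_letter = character(0),
                          no_current_atc = logical(0)))
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' Generate drug repositioning hints at a tuned resolution
#'
#' Clusters the DDSN at the given resolution and lists, for every cluster,
#' the member drugs that do not yet carry the cluster's dominant level-1 ATC
#' letter (see [hints_from_partition()]).
#'
#' @param g DDSN igraph.
#' @param resolution Tuned resolution (e.g. the `lambda_max` of a sweep).
#' @param atc `atc_table` of the release the DDSN was built from.
#' @param seed,restarts Passed to [louvain_cluster()].
#' @param k Dominant letters per cluster.
#' @return Tibble of hints; the partition used is attached as attribute
#'   `"partition"`.
#' @export
generate_hints <- function(g, resolution, atc, seed = 42L, restarts = 5L,
                           k = 1) {
  stopifnot(resolution > 0)
  p <- louvain_cluster(g, resolution = resolution, seed = seed,
                       restarts = restarts)
  hints <- hints_from_partition(p, atc, k = k)
  attr(hints, "partition") <- p
  hints
}

#' Rank repositioning hints by network centrality
#'
#' Within each cluster, hints are ordered by betweenness (descending), ties
#' by weighted degree (descending), then by drug id, and truncated to the
#' top `top_n` -- the drugs occupying topologically central positions are the
#' most interesting candidates.
#'
#' @param hints Tibble from [generate_hints()] / [hints_from_partition()].
#' @param report Centrality tibble from [centralities()], computed on the
#'   same graph.
#' @param top_n Hints kept per cluster (default 10); `Inf` keeps all.
#' @return The hints tibble with `betweenness`, `degree` and a per-cluster
#'   `rank` column, truncated and ordered.
#' @export
rank_candidates <- function(hints, report, top_n = 10) {
  missing <- setdiff(hints$drug_id, report$drug_id)
  if (length(missing) > 0) {
    stop(sprintf("no centrality available for: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  i <- match(hints$drug_id, report$drug_id)
  hints$betweenness <- report$betweenness[i]
  hints$degree <- report$degree[i]
  o <- order(hints$cluster, -hints$betweenness, -hints$degree, hints$drug_id)
  hints <- hints[o, ]
  rank <- stats::ave(seq_len(nrow(hints)), hints$cluster, FUN = seq_along)
  hints$rank <- as.integer(rank)
  hints[hints$rank <= top_n, ]
}
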