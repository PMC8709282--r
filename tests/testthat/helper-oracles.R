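# Independent oracles used across the suite. These deliberately take a
# different computational route than the package (dense double sums, brute
# enumeration) so agreement is meaningful.

# Direct dense evaluation of the modularity double sum:
# M = (1/2a) * sum_ij [res*w_ij - k_i k_j/(2a)] * [m_i == m_j]
brute_modularity <- function(g, memb, resolution = 1) {
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
  k <- rowSums(W)
  a <- sum(W) / 2
  m <- memb[rownames(W)]
  same <- outer(m, m, "==")
  sum((resolution * W - outer(k, k) / (2 * a)) * same) / (2 * a)
}

# Brute-force DDSN projection: triple loop over drug pairs x genes x types.
brute_project <- function(records) {
  drugs <- sort(unique(records$drug_id))
  genes <- unique(records$gene_symbol)
  types <- unique(records$interaction_type)
  has <- function(d, g, t) {
    any(records$drug_id == d & records$gene_symbol == g &
          records$interaction_type == t)
  }
  out <- list()
  if (length(drugs) >= 2) {
    for (i in seq_len(length(drugs) - 1)) {
      for (j in (i + 1):length(drugs)) {
        w <- 0
        for (g in genes) {
          shared <- FALSE
          for (t in types) {
            if (has(drugs[i], g, t) && has(drugs[j], g, t)) shared <- TRUE
          }
          if (shared) w <- w + 1
        }
        if (w > 0) {
          out[[length(out) + 1]] <- data.frame(
            d1 = drugs[i], d2 = drugs[j], w = w, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(d1 = character(0), d2 = character(0), w = numeric(0)))
  }
  do.call(rbind, out)
}

# All set partitions of n elements as 0-based restricted-growth strings.
enumerate_partitions <- function(n) {
  out <- vector("list", 0)
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in 0:(mx + 1)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), -1L)
  out
}

# Best modularity over every partition of g's nodes (exhaustive search).
exhaustive_best_modularity <- function(g, resolution = 1,
                                       parts = enumerate_partitions(igraph::vcount(g))) {
  vn <- igraph::V(g)$name
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
  k <- rowSums(W)
  a <- sum(W) / 2
  B <- resolution * W - outer(k, k) / (2 * a)
  best <- -Inf
  best_m <- NULL
  for (m in parts) {
    val <- sum(B[outer(m, m, "==")]) / (2 * a)
    if (val > best) {
      best <- val
      best_m <- m
    }
  }
  list(value = best, membership = stats::setNames(best_m, vn))
}

# Random connected-ish weighted graph with named nodes and integer weights.
random_weighted_graph <- function(n, p = 0.5, wmax = 4, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) >= 1) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  igraph::E(g)$weight <- sample.int(wmax, igraph::ecount(g), replace = TRUE)
  g
}

# Random interaction records over a small drug/gene/type universe.
random_records <- function(n_drugs, n_genes, n_types, n_rec, seed) {
  set.seed(seed)
  unique(data.frame(
    drug_id = sprintf("D%02d", sample.int(n_drugs, n_rec, replace = TRUE)),
    gene_symbol = sprintf("G%02d", sample.int(n_genes, n_rec, replace = TRUE)),
    interaction_type = c("inhibitor", "agonist", "antagonist",
                         "binder")[sample.int(n_types, n_rec, replace = TRUE)],
    stringsAsFactors = FALSE
  ))
}

records_to_ddsn <- function(records) {
  drugs <- data.frame(drug_id = unique(records$drug_id),
                      name = unique(records$drug_id),
                      stringsAsFactors = FALSE)
  project_ddsn(build_bipartite(interaction_table(records, drugs)))
}

# The 4-drug / 3-gene worked example: D1 and D3 interact with G1, G2, G3 in
# the same manner; the other drugs add a mix of matching and non-matching
# types.
worked_example_table <- function() {
  rec <- data.frame(
    drug_id = c("D1", "D1", "D1", "D3", "D3", "D3", "D2", "D2", "D4", "D4"),
    gene_symbol = c("G1", "G2", "G3", "G1", "G2", "G3", "G1", "G2", "G3", "G2"),
    interaction_type = c(rep("inhibitor", 6), "agonist", "inhibitor",
                         "antagonist", "inhibitor"),
    stringsAsFactors = FALSE
  )
  drugs <- data.frame(drug_id = paste0("D", 1:4), name = paste("Drug", 1:4),
                      stringsAsFactors = FALSE)
  interaction_table(rec, drugs)
}
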