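# Bipartite drug-gene graph and its one-mode projection onto drugs: the
# weighted drug-drug similarity network (DDSN). The weight of a drug pair is
# the number of DISTINCT genes with which both drugs interact in the same
# manner (same interaction type); a gene matched under two different shared
# types still counts once.

#' Build the bipartite drug-gene interaction graph
#'
#' One typed edge per unique interaction record. Drug and gene node names are
#' namespaced (`drug:`/`gene:` prefixes) so the two node sets are disjoint by
#' construction; the `kind` vertex attribute and igraph's `type` attribute
#' mark the two modes. Drugs without any interaction do not appear.
#'
#' @param table An `interaction_table`.
#' @return An undirected igraph with vertex attributes `kind`
#'   (`"drug"`/`"gene"`), `label` (the bare id), and edge attribute
#'   `interaction_type`. Parallel edges encode multiple interaction types for
#'   the same drug-gene pair.
#' @export
build_bipartite <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  rec <- table$records
  if (nrow(rec) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "kind", value = character(0))
    return(g)
  }
  dn <- paste0("drug:", sort(unique(rec$drug_id)))
  gn <- paste0("gene:", sort(unique(rec$gene_symbol)))
  g <- igraph::graph_from_edgelist(
    cbind(paste0("drug:", rec$drug_id), paste0("gene:", rec$gene_symbol)),
    directed = FALSE
  )
  g <- igraph::set_edge_attr(g, "interaction_type", value = rec$interaction_type)
  kind <- ifelse(igraph::V(g)$name %in% dn, "drug", "gene")
  g <- igraph::set_vertex_attr(g, "kind", value = kind)
  g <- igraph::set_vertex_attr(g, "type", value = kind == "gene")
  g <- igraph::set_vertex_attr(g, "label",
                               value = sub("^(drug|gene):", "", igraph::V(g)$name))
  g
}

#' Project the bipartite graph onto the weighted drug-drug similarity network
#'
#' For each unordered drug pair the edge weight counts the distinct genes g
#' for which some interaction type t is shared, i.e. both (Di, g, t) and
#' (Dj, g, t) are present. Pairs sharing a gene only under different types get
#' no edge. All drugs of the bipartite graph are kept as nodes, so a drug
#' whose interactions are unshared appears isolated.
#'
#' @param bipartite Graph from [build_bipartite()].
#' @return An undirected igraph over drug ids with integer edge attribute
#'   `weight`, no self-loops.
#' @export
project_ddsn <- function(bipartite) {
  vn <- igraph::V(bipartite)$name
  drug_ids <- sort(sub("^drug:", "", vn[igraph::V(bipartite)$kind == "drug"]))
  if (length(drug_ids) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  el <- igraph::as_edgelist(bipartite)
  # orient edges as (drug, gene)
  swap <- !startsWith(el[, 1], "drug:")
  tmp <- el[swap, 1]; el[swap, 1] <- el[swap, 2]; el[swap, 2] <- tmp
  rec <- data.frame(
    drug = sub("^drug:", "", el[, 1]),
    gene = sub("^gene:", "", el[, 2]),
    type = igraph::E(bipartite)$interaction_type,
    stringsAsFactors = FALSE
  )
  rec <- unique(rec)

  # within each (gene, type) group, every drug pair shares that gene in the
  # same manner; distinct-gene counting then dedups (pair, gene) before the
  # final tally so two shared types over one gene count once
  key <- paste(rec$gene, rec$type, sep = "\r")
  grp <- split(rec$drug, key)
  pair_gene <- lapply(names(grp), function(k) {
    ds <- sort(unique(grp[[k]]))
    if (length(ds) < 2) return(NULL)
    cmb <- utils::combn(ds, 2)
    data.frame(d1 = cmb[1, ], d2 = cmb[2, ],
               gene = sub("\r.*$", "", k), stringsAsFactors = FALSE)
  })
  pair_gene <- do.call(rbind, pair_gene)

  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(drug_ids), name = drug_ids)
  if (!is.null(pair_gene) && nrow(pair_gene) > 0) {
    pair_gene <- unique(pair_gene)
    pk <- paste(pair_gene$d1, pair_gene$d2, sep = "\r")
    w <- table(pk)
    ends <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(ends)), weight = as.integer(w))
  }
  g
}

#' Largest connected component of a weighted graph
#'
#' Induced subgraph on the largest component; when several components tie in
#' size, the one containing the lexicographically smallest node id wins. The
#' clustering operates on the full DDSN -- the component extraction is for
#' reporting and export.
#'
#' @param g An igraph.
#' @return The induced subgraph (empty graph for an empty input).
#' @export
largest_connected_component <- function(g) {
  if (igraph::vcount(g) == 0) return(g)
  comp <- igraph::components(g)
  mx <- max(comp$csize)
  cand <- which(comp$csize == mx)
  if (length(cand) > 1) {
    first_name <- vapply(cand, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    cand <- cand[order(first_name)][1]
  }
  igraph::induced_subgraph(g, which(comp$membership == cand[1]))
}

#' Betweenness and weighted degree of every DDSN node
#'
#' Betweenness uses unit edge lengths for shortest-path counting: the DDSN's
#' weights are similarity counts, not distances, so treating them as path
#' costs would invert their meaning. Degree is the weighted degree k_i (sum
#' of incident edge weights).
#'
#' @param g DDSN igraph with edge attribute `weight`.
#' @return Tibble with columns `drug_id`, `betweenness`, `degree`.
#' @export
centralities <- function(g) {
  if (igraph::vcount(g) == 0) {
    return(tibble::tibble(drug_id = character(0), betweenness = numeric(0),
                          degree = numeric(0)))
  }
  tibble::tibble(
    drug_id = igraph::V(g)$name,
    betweenness = unname(igraph::betweenness(g, weights = NA,
                                             normalized = FALSE)),
    degree = unname(igraph::strength(g, weights = edge_weights(g)))
  )
}

edge_weights <- function(g) {
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  w
}

#' Export a DDSN (optionally with its partition) to GraphML or GEXF
#'
#' Writes the `weight` edge attribute and, when a partition is given, a
#' `modularity_class` integer node attribute, the conventions network
#' visualization tools such as Gephi expect.
#'
#' @param g DDSN igraph.
#' @param path Output file path.
#' @param partition Optional `ddsn_partition` (or named membership vector)
#'   covering all nodes of `g`.
#' @param format `"graphml"` or `"gexf"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(g, path, partition = NULL,
                         format = c("graphml", "gexf")) {
  format <- match.arg(format)
  if (!is.null(partition)) {
    memb <- partition_membership(partition)
    missing <- setdiff(igraph::V(g)$name, names(memb))
    if (length(missing) > 0) {
      stop(sprintf("partition does not cover node(s): %s",
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
    g <- igraph::set_vertex_attr(g, "modularity_class",
                                 value = as.integer(memb[igraph::V(g)$name]))
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_gexf(g, path)
  }
  invisible(path)
}

# Minimal GEXF 1.2 writer (igraph has no GEXF backend).
write_gexf <- function(g, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  vn <- esc(igraph::V(g)$name)
  has_mc <- "modularity_class" %in% igraph::vertex_attr_names(g)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="undirected">'
  )
  if (has_mc) {
    lines <- c(lines,
      '    <attributes class="node">',
      '      <attribute id="0" title="modularity_class" type="integer"/>',
      '    </attributes>')
  }
  node_lines <- if (has_mc) {
    mc <- igraph::V(g)$modularity_class
    sprintf('      <node id="%s" label="%s"><attvalues><attvalue for="0" value="%d"/></attvalues></node>',
            vn, vn, mc)
  } else {
    sprintf('      <node id="%s" label="%s"/>', vn, vn)
  }
  el <- igraph::as_edgelist(g)
  w <- edge_weights(g)
  edge_lines <- if (nrow(el) > 0) {
    sprintf('      <edge id="%d" source="%s" target="%s" weight="%s"/>',
            seq_len(nrow(el)) - 1L, esc(el[, 1]), esc(el[, 2]),
            format(w, trim = TRUE))
  } else character(0)
  lines <- c(lines, "    <nodes>", node_lines, "    </nodes>",
             "    <edges>", edge_lines, "    </edges>",
             "  </graph>", "</gexf>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
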