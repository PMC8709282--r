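# Orchestration of the three-step pipeline (build -> tune -> hints) as
# subcommands with a reproducibility manifest. The CLI script in
# inst/cli/ddsn.R is a thin flag-parsing wrapper over run_pipeline().

#' Run one pipeline step and write its outputs plus a manifest
#'
#' Supported commands:
#' \describe{
#'   \item{parse}{DrugBank XML -> `interactions.tsv` (TSV interchange).}
#'   \item{build}{interactions TSV -> DDSN (`ddsn.graphml`).}
#'   \item{cluster}{interactions TSV or GraphML -> `partition.csv`
#'     (`drug_id,cluster`) at a fixed resolution.}
#'   \item{tune}{old interactions + old/new ATC TSVs -> `sweep.csv`
#'     (`lambda,n_clusters,n_confirmed`); the selected resolution is in the
#'     manifest.}
#'   \item{hints}{interactions + ATC TSV -> ranked `hints.csv`.}
#'   \item{simulate}{fixture spec -> synthetic TSV bundle.}
#' }
#' Every run writes `manifest.json` next to its outputs: command, package
#' version, seed and parameters, input checksums, and headline counts --
#' enough to re-run the step exactly. Manifests carry no timestamps, so
#' identical configs give byte-identical output trees.
#'
#' @param command One of `"parse"`, `"build"`, `"cluster"`, `"tune"`,
#'   `"hints"`, `"simulate"`.
#' @param config Named list of arguments for the command; see Details.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the manifest list.
#' @details Common config entries: `in` (input path), `seed` (default 42),
#'   `restarts` (default 5), `resolution` or `grid` (`c(from, to, by)` or a
#'   numeric vector), `atc`, `atc_old`, `atc_new` (ATC TSV paths), `top_k`
#'   (dominant letters, default 1), `top_n` (hints kept per cluster, default
#'   10), `categories`/`approved_only` (parse), `spec` (simulate; a
#'   [fixture_spec()] or list of its arguments).
#' @export
run_pipeline <- function(command, config = list(), out_dir = ".") {
  command <- match.arg(command,
                       c("parse", "build", "cluster", "tune", "hints", "simulate"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 42L)
  restarts <- as.integer(config$restarts %||% 5L)
  manifest <- list(command = command,
                   package = "ddsn",
                   package_version = as.character(utils::packageVersion("ddsn")),
                   seed = seed)
  inputs <- list()
  add_input <- function(path) {
    if (!file.exists(path)) {
      stop(sprintf("input file not found: %s", path), call. = FALSE)
    }
    inputs[[length(inputs) + 1L]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }

  outputs <- character(0)
  if (command == "parse") {
    add_input(config$`in`)
    tab <- parse_drugbank_xml(config$`in`,
                              categories = config$categories %||% "targets",
                              approved_only = config$approved_only %||% TRUE)
    out <- file.path(out_dir, "interactions.tsv")
    write_interaction_tsv(tab, out)
    outputs <- out
    manifest$counts <- list(drugs = nrow(tab$drugs),
                            genes = length(unique(tab$records$gene_symbol)),
                            interactions = nrow(tab$records))
  } else if (command == "build") {
    add_input(config$`in`)
    g <- project_ddsn(build_bipartite(read_interaction_tsv(config$`in`)))
    out <- file.path(out_dir, "ddsn.graphml")
    export_graph(g, out, format = "graphml")
    outputs <- out
    manifest$counts <- list(nodes = igraph::vcount(g), edges = igraph::ecount(g))
  } else if (command == "cluster") {
    add_input(config$`in`)
    g <- load_ddsn(config$`in`)
    resolution <- config$resolution %||% stop("cluster needs a resolution",
                                              call. = FALSE)
    p <- louvain_cluster(g, resolution = resolution, seed = seed,
                         restarts = restarts)
    out <- file.path(out_dir, "partition.csv")
    utils::write.csv(as.data.frame(p), out, row.names = FALSE, quote = FALSE)
    outputs <- out
    manifest$resolution <- resolution
    manifest$counts <- list(nodes = igraph::vcount(g),
                            clusters = p$n_clusters,
                            modularity = p$modularity)
  } else if (command == "tune") {
    add_input(config$`in`); add_input(config$atc_old); add_input(config$atc_new)
    check_drug_namespace(config)
    g <- load_ddsn(config$`in`)
    grid <- parse_grid(config$grid %||% c(0.1, 5.0, 0.1))
    sw <- tune_resolution(g, read_atc_table(config$atc_old),
                          read_atc_table(config$atc_new),
                          grid = grid, seed = seed, restarts = restarts,
                          k = config$top_k %||% 1)
    out <- file.path(out_dir, "sweep.csv")
    utils::write.csv(sw$sweep, out, row.names = FALSE, quote = FALSE)
    outputs <- out
    manifest$grid <- range(grid)
    manifest$lambda_max <- sw$lambda_max
    manifest$counts <- list(max_confirmed = sw$best$n)
  } else if (command == "hints") {
    add_input(config$`in`); add_input(config$atc)
    tab <- read_interaction_tsv(config$`in`)
    g <- project_ddsn(build_bipartite(tab))
    resolution <- config$resolution %||% stop("hints needs a resolution",
                                              call. = FALSE)
    hints <- generate_hints(g, resolution, read_atc_table(config$atc),
                            seed = seed, restarts = restarts,
                            k = config$top_k %||% 1)
    ranked <- rank_candidates(hints, centralities(g),
                              top_n = config$top_n %||% 10)
    name_of <- stats::setNames(tab$drugs$name, tab$drugs$drug_id)
    ranked$drug_name <- unname(name_of[ranked$drug_id])
    ranked <- ranked[, c("drug_id", "drug_name", "cluster", "current_level1",
                         "predicted_letter", "betweenness", "degree", "rank")]
    names(ranked)[names(ranked) == "predicted_letter"] <- "predicted_level1"
    out <- file.path(out_dir, "hints.csv")
    # current_level1 can hold comma-joined letters, so quoting stays on
    utils::write.csv(ranked, out, row.names = FALSE)
    outputs <- out
    manifest$resolution <- resolution
    manifest$counts <- list(hints = nrow(hints), ranked = nrow(ranked))
  } else if (command == "simulate") {
    spec <- config$spec %||% list()
    if (!inherits(spec, "fixture_spec")) spec <- do.call(fixture_spec, spec)
    bundle <- generate_fixture(spec)
    write_fixture(bundle, out_dir)
    outputs <- file.path(out_dir,
                         c("interactions.tsv", "atc_old.tsv", "atc_new.tsv",
                           "truth.json"))
    manifest$spec <- unclass(spec)
    manifest$counts <- list(interactions = nrow(bundle$interactions$records),
                            planted_hints = length(bundle$truth$hint_drugs),
                            planted_confirmable = length(bundle$truth$confirmable_drugs))
  }

  manifest$restarts <- restarts
  manifest$inputs <- inputs
  manifest$outputs <- basename(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_ddsn <- function(path) {
  if (grepl("\\.graphml$", path)) {
    igraph::read_graph(path, format = "graphml")
  } else {
    project_ddsn(build_bipartite(read_interaction_tsv(path)))
  }
}

parse_grid <- function(grid) {
  grid <- as.numeric(grid)
  if (length(grid) == 3 && grid[2] > grid[1]) {
    seq(grid[1], grid[2], by = grid[3])
  } else {
    grid
  }
}

# the tune inputs must share a drug_id namespace: at least one interaction
# drug must appear in each ATC table, otherwise the join is vacuous
check_drug_namespace <- function(config) {
  drugs <- unique(utils::read.delim(config$`in`, sep = "\t",
                                    colClasses = "character")$drug_id)
  for (side in c("atc_old", "atc_new")) {
    atc_drugs <- unique(utils::read.delim(config[[side]], sep = "\t",
                                          colClasses = "character")$drug_id)
    if (length(intersect(drugs, atc_drugs)) == 0) {
      stop(sprintf(
        "drug_id namespaces are disjoint between '%s' and '%s' (e.g. %s vs %s)",
        config$`in`, config[[side]],
        paste(utils::head(drugs, 3), collapse = ","),
        paste(utils::head(atc_drugs, 3), collapse = ",")), call. = FALSE)
    }
  }
  invisible(TRUE)
}
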