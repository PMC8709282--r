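# InteractionTable: the pipeline's universal input. A validated collection of
# typed drug-gene interaction records plus the drug metadata needed downstream
# (display name, approval groups, ATC codes).

#' Construct an interaction table
#'
#' A validated container of typed drug-gene interaction records. Interaction
#' types are normalized (lowercased, whitespace-trimmed), duplicate
#' (drug, gene, type) triples are collapsed, and every record's `drug_id`
#' must resolve to a row of `drugs`.
#'
#' @param records Data frame with columns `drug_id`, `gene_symbol`,
#'   `interaction_type`.
#' @param drugs Data frame with columns `drug_id`, `name`, and optionally
#'   list-columns `groups` (status strings such as `"approved"`) and
#'   `atc_codes`.
#' @param source Provenance label (e.g. `"drugbank_xml"`, `"tsv"`).
#' @param version Provenance version string.
#' @return An object of class `interaction_table` with elements `records`,
#'   `drugs` and `provenance`.
#' @export
interaction_table <- function(records, drugs, source = "unknown", version = "") {
  records <- tibble::as_tibble(records)
  drugs <- tibble::as_tibble(drugs)
  need <- c("drug_id", "gene_symbol", "interaction_type")
  if (!all(need %in% names(records))) {
    stop(sprintf("interaction records need columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (!all(c("drug_id", "name") %in% names(drugs))) {
    stop("drugs table needs columns 'drug_id' and 'name'", call. = FALSE)
  }
  records$drug_id <- as.character(records$drug_id)
  records$gene_symbol <- trimws(as.character(records$gene_symbol))
  records$interaction_type <- tolower(trimws(as.character(records$interaction_type)))
  if (any(!nzchar(records$gene_symbol))) {
    stop("empty gene_symbol in interaction records", call. = FALSE)
  }
  records <- unique(records[, need])

  drugs$drug_id <- as.character(drugs$drug_id)
  if (any(!nzchar(drugs$drug_id))) stop("empty drug_id", call. = FALSE)
  if (anyDuplicated(drugs$drug_id)) {
    stop("duplicate drug_id in drugs table", call. = FALSE)
  }
  if (!"groups" %in% names(drugs)) {
    drugs$groups <- rep(list(character(0)), nrow(drugs))
  }
  if (!"atc_codes" %in% names(drugs)) {
    drugs$atc_codes <- rep(list(character(0)), nrow(drugs))
  }
  orphan <- setdiff(records$drug_id, drugs$drug_id)
  if (length(orphan) > 0) {
    stop(sprintf("interaction records reference unknown drug_id(s): %s",
                 paste(utils::head(orphan, 5), collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(records = records,
         drugs = drugs[, c("drug_id", "name", "groups", "atc_codes")],
         provenance = list(source = source, version = version)),
    class = "interaction_table"
  )
}

#' Read an interaction table from the TSV interchange format
#'
#' The interchange format is a UTF-8 tab-separated file with header exactly
#' `drug_id  drug_name  gene_symbol  interaction_type`. Interaction types are
#' lowercased and whitespace-trimmed before the vocabulary check, and
#' duplicate triples are collapsed. The vocabulary check is advisory by
#' default (out-of-vocabulary types produce a warning and are kept) so newer
#' DrugBank action terms do not break parsing.
#'
#' @param path Path to the TSV file.
#' @param vocabulary Allowed interaction types; defaults to
#'   [default_interaction_types()].
#' @param strict If `TRUE`, out-of-vocabulary types are an error.
#' @return An `interaction_table`.
#' @export
read_interaction_tsv <- function(path, vocabulary = default_interaction_types(),
                                 strict = FALSE) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "")
  want <- c("drug_id", "drug_name", "gene_symbol", "interaction_type")
  if (!identical(names(df), want)) {
    stop(sprintf("expected TSV header '%s', found: %s",
                 paste(want, collapse = "\\t"),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  df$interaction_type <- tolower(trimws(df$interaction_type))
  check_vocabulary(df$interaction_type, vocabulary, strict = strict)
  drugs <- unique(df[, c("drug_id", "drug_name")])
  names(drugs) <- c("drug_id", "name")
  interaction_table(
    records = df[, c("drug_id", "gene_symbol", "interaction_type")],
    drugs = drugs,
    source = "tsv",
    version = basename(path)
  )
}

#' Write an interaction table to the TSV interchange format
#'
#' @param table An `interaction_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_interaction_tsv <- function(table, path) {
  stopifnot(inherits(table, "interaction_table"))
  name_of <- stats::setNames(table$drugs$name, table$drugs$drug_id)
  out <- data.frame(
    drug_id = table$records$drug_id,
    drug_name = unname(name_of[table$records$drug_id]),
    gene_symbol = table$records$gene_symbol,
    interaction_type = table$records$interaction_type,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$drug_id, out$gene_symbol, out$interaction_type), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' ATC table carried by an interaction table's drug metadata
#'
#' Convenience accessor: flattens the per-drug `atc_codes` list-column (as
#' filled by [parse_drugbank_xml()]) into an [atc_table()].
#'
#' @param table An `interaction_table`.
#' @param version Version label for the resulting table; defaults to the
#'   table's provenance version.
#' @return An `atc_table`.
#' @export
atc_table_from_interactions <- function(table, version = NULL) {
  stopifnot(inherits(table, "interaction_table"))
  if (is.null(version)) version <- table$provenance$version
  n <- lengths(table$drugs$atc_codes)
  atc_table(
    data.frame(drug_id = rep(table$drugs$drug_id, n),
               atc_code = unlist(table$drugs$atc_codes, use.names = FALSE),
               stringsAsFactors = FALSE),
    version = version
  )
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf(
    "<interaction_table> %d records | %d drugs | %d genes | source: %s %s\n",
    nrow(x$records), nrow(x$drugs), length(unique(x$records$gene_symbol)),
    x$provenance$source, x$provenance$version
  ))
  invisible(x)
}
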