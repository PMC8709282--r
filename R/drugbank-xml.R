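# DrugBank full-database XML ingestion. Works with any 5.x schema exposing
# drug -> {targets,enzymes,carriers,transporters} -> polypeptide -> gene-name
# and per-protein <actions>. Gene identity is the polypeptide gene-name string
# after trimming; no symbol aliasing is attempted.

.drugbank_categories <- c("targets", "enzymes", "carriers", "transporters")

#' Parse a DrugBank full-database XML export
#'
#' Extracts one typed drug-gene interaction record per (drug, gene, action)
#' triple found under the selected protein categories. Genes are identified by
#' the polypeptide `gene-name` field; proteins without a gene name are
#' skipped. A protein with no listed action contributes the action
#' `"other/unknown"`. Duplicate triples are collapsed. Drug approval groups
#' and ATC codes are retained on the drug table.
#'
#' @param path Path to a DrugBank full-database XML file.
#' @param categories Protein categories to harvest; subset of
#'   `c("targets", "enzymes", "carriers", "transporters")`. Defaults to
#'   targets only.
#' @param approved_only Drop drugs whose `groups` do not include
#'   `"approved"`.
#' @param vocabulary,strict Passed to the advisory vocabulary check; see
#'   [read_interaction_tsv()].
#' @return An `interaction_table`.
#' @export
parse_drugbank_xml <- function(path, categories = "targets",
                               approved_only = TRUE,
                               vocabulary = default_interaction_types(),
                               strict = FALSE) {
  unknown <- setdiff(categories, .drugbank_categories)
  if (length(unknown) > 0) {
    stop(sprintf("unknown protein category: %s (valid: %s)",
                 paste(unknown, collapse = ", "),
                 paste(.drugbank_categories, collapse = ", ")),
         call. = FALSE)
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("malformed DrugBank XML in '%s': %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  version <- xml2::xml_attr(xml2::xml_root(doc), "version")
  if (is.na(version)) version <- ""

  drug_nodes <- xml2::xml_find_all(doc, "./drug")
  singular <- sub("s$", "", categories)

  rec_drug <- character(0); rec_gene <- character(0); rec_type <- character(0)
  ids <- character(0); nm <- character(0)
  groups <- list(); atcs <- list()

  for (d in drug_nodes) {
    id <- xml2::xml_text(
      xml2::xml_find_first(d, "./drugbank-id[@primary='true']"))
    if (is.na(id) || !nzchar(id)) {
      id <- xml2::xml_text(xml2::xml_find_first(d, "./drugbank-id"))
    }
    grp <- xml2::xml_text(xml2::xml_find_all(d, "./groups/group"))
    if (approved_only && !"approved" %in% grp) next

    ids <- c(ids, id)
    nm <- c(nm, xml2::xml_text(xml2::xml_find_first(d, "./name")))
    groups <- c(groups, list(grp))
    atcs <- c(atcs, list(
      toupper(xml2::xml_attr(xml2::xml_find_all(d, "./atc-codes/atc-code"), "code"))))

    for (k in seq_along(categories)) {
      proteins <- xml2::xml_find_all(
        d, sprintf("./%s/%s", categories[k], singular[k]))
      for (p in proteins) {
        genes <- trimws(xml2::xml_text(
          xml2::xml_find_all(p, "./polypeptide/gene-name")))
        genes <- genes[nzchar(genes)]
        if (length(genes) == 0) next
        actions <- tolower(trimws(xml2::xml_text(
          xml2::xml_find_all(p, "./actions/action"))))
        actions <- actions[nzchar(actions)]
        if (length(actions) == 0) actions <- "other/unknown"
        combo <- expand.grid(gene = genes, type = actions,
                             stringsAsFactors = FALSE)
        rec_drug <- c(rec_drug, rep(id, nrow(combo)))
        rec_gene <- c(rec_gene, combo$gene)
        rec_type <- c(rec_type, combo$type)
      }
    }
  }

  check_vocabulary(rec_type, vocabulary, strict = strict)
  drugs <- tibble::tibble(drug_id = ids, name = nm,
                          groups = groups, atc_codes = atcs)
  interaction_table(
    records = data.frame(drug_id = rec_drug, gene_symbol = rec_gene,
                         interaction_type = rec_type,
                         stringsAsFactors = FALSE),
    drugs = drugs,
    source = "drugbank_xml",
    version = version
  )
}
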