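# Interaction-type vocabularies observed across DrugBank 5.x releases.
# The 5.0.9-era action set and the additions that appeared by 5.1.8 are kept
# separate so either era can be targeted; the default vocabulary is their union.

.types_509 <- c(
  "inhibitor", "agonist", "antagonist", "other/unknown", "ligand",
  "partial agonist", "inducer", "other", "suppressor", "binder", "antibody",
  "modulator", "allosteric modulator", "potentiator", "neutralizer",
  "stimulator", "activator", "component of", "substrate", "inactivator",
  "blocker", "antisense oligonucleotide"
)

.types_518_extra <- c(
  "cofactor", "degradation", "positive allosteric modulator",
  "incorporation into and destabilization", "binding", "inverse agonist",
  "chaperone", "inhibition of synthesis", "gene replacement", "regulator"
)

#' Default drug-gene interaction-type vocabulary
#'
#' The union of the action vocabularies of the two DrugBank releases the
#' pipeline is designed around (5.0.9 and 5.1.8). The vocabulary check in the
#' readers is advisory by default so that actions introduced by newer DrugBank
#' releases do not break parsing; pass `strict = TRUE` to a reader to reject
#' out-of-vocabulary types instead.
#'
#' @return Character vector of normalized (lowercase) interaction types.
#' @export
#' @examples
#' "inhibitor" %in% default_interaction_types()
default_interaction_types <- function() {
  sort(unique(c(.types_509, .types_518_extra)))
}

# The 14 anatomical main groups of the WHO ATC classification (level 1).
.atc_level1_letters <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N",
                         "P", "R", "S", "V")

#' Level-1 ATC letters
#'
#' The fourteen anatomical main-group letters of the WHO ATC classification.
#'
#' @return Character vector of 14 single letters.
#' @export
atc_level1_letters <- function() .atc_level1_letters

check_vocabulary <- function(types, vocabulary = default_interaction_types(),
                             strict = FALSE) {
  unknown <- setdiff(unique(types), vocabulary)
  if (length(unknown) > 0) {
    msg <- sprintf(
      "interaction types outside the configured vocabulary: %s",
      paste(utils::head(unknown, 10), collapse = ", ")
    )
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(unknown)
}
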