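# Seeded synthetic fixtures: a blocky bipartite drug-gene graph plus a pair
# of dated ATC tables with planted repositioning structure, so every pipeline
# stage is exercisable without a licensed DrugBank download.
#
# Interaction types are assigned per gene (one type per gene, shared by every
# drug touching it) so that block membership, not type diversity, drives
# DDSN similarity -- this isolates the "same manner" projection rule.

#' Specification of a synthetic fixture
#'
#' Describes a planted-block bipartite drug-gene graph and the paired ATC
#' tables derived from it. Each block owns `genes_per_block` genes; a drug
#' interacts with each gene of its own block with probability `p_in` and
#' with foreign genes with probability `p_out`, always using the gene's
#' fixed interaction type. Per block, a `hint_fraction` of drugs is given a
#' foreign level-1 letter instead of the block letter (planted hint
#' candidates); of those, a `confirm_fraction` gains the block letter in the
#' "newer" ATC table (planted confirmable repositionings).
#'
#' @param n_blocks,drugs_per_block,genes_per_block Block layout.
#' @param p_in,p_out Interaction probabilities, `0 <= p_out < p_in <= 1`.
#' @param n_types Number of interaction types used (drawn from the DrugBank
#'   vocabulary).
#' @param block_letters Level-1 letter per block; defaults to the first
#'   `n_blocks` of N, J, L, A, C, R, ... (distinct, from the 14 ATC letters).
#' @param hint_fraction,confirm_fraction Planted fractions in `[0, 1]`.
#' @param second_code_prob Probability that a drug carries a second ATC code
#'   (multi-valued labels, as in real tables).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_blocks = 4, drugs_per_block = 12,
                         genes_per_block = 8, p_in = 0.8, p_out = 0.03,
                         n_types = 3, block_letters = NULL,
                         hint_fraction = 0.25, confirm_fraction = 0.5,
                         second_code_prob = 0.3, seed = 7L) {
  if (is.null(block_letters)) {
    pref <- c("N", "J", "L", "A", "C", "R", "D", "G", "H", "M", "P", "S", "V", "B")
    block_letters <- pref[seq_len(n_blocks)]
  }
  spec <- list(n_blocks = as.integer(n_blocks),
               drugs_per_block = as.integer(drugs_per_block),
               genes_per_block = as.integer(genes_per_block),
               p_in = p_in, p_out = p_out, n_types = as.integer(n_types),
               block_letters = block_letters,
               hint_fraction = hint_fraction,
               confirm_fraction = confirm_fraction,
               second_code_prob = second_code_prob,
               seed = as.integer(seed))
  validate_fixture_spec(spec)
  structure(spec, class = "fixture_spec")
}

validate_fixture_spec <- function(spec) {
  with(spec, {
    if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
      stop("need 0 <= p_out < p_in <= 1", call. = FALSE)
    }
    frac <- c(hint_fraction, confirm_fraction, second_code_prob)
    if (any(frac < 0 | frac > 1)) {
      stop("fractions must lie in [0, 1]", call. = FALSE)
    }
    if (n_blocks < 1 || drugs_per_block < 1 || genes_per_block < 1) {
      stop("block layout must be positive", call. = FALSE)
    }
    if (length(block_letters) != n_blocks ||
        anyDuplicated(block_letters) ||
        !all(block_letters %in% atc_level1_letters())) {
      stop("block_letters must be distinct level-1 ATC letters, one per block",
           call. = FALSE)
    }
    if (n_types < 1) stop("need at least one interaction type", call. = FALSE)
  })
  invisible(spec)
}

#' Generate a synthetic fixture bundle
#'
#' Materializes a [fixture_spec()] into an interaction table, an "older" and
#' a "newer" ATC table, and the ground truth planted into them. The same
#' spec (same seed) always yields byte-identical tables.
#'
#' @param spec A `fixture_spec`.
#' @return A list of class `fixture_bundle`: `interactions`
#'   (`interaction_table`), `atc_old`, `atc_new` (`atc_table`s), and `truth`
#'   with `blocks` (drug -> block index), `block_letters`, `hint_drugs`
#'   (planted candidates lacking their block letter), `confirmable_drugs`
#'   (subset gaining it in the new table).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  validate_fixture_spec(spec)
  set.seed(spec$seed)

  n_drugs <- spec$n_blocks * spec$drugs_per_block
  drug_ids <- sprintf("SYND%04d", seq_len(n_drugs))
  drug_block <- rep(seq_len(spec$n_blocks), each = spec$drugs_per_block)
  names(drug_block) <- drug_ids
  gene_ids <- sprintf("GENB%d_%02d",
                      rep(seq_len(spec$n_blocks), each = spec$genes_per_block),
                      rep(seq_len(spec$genes_per_block), spec$n_blocks))
  gene_block <- rep(seq_len(spec$n_blocks), each = spec$genes_per_block)
  types <- default_interaction_types()[seq_len(spec$n_types)]
  gene_type <- sample(types, length(gene_ids), replace = TRUE)

  # interactions: Bernoulli per (drug, gene), probability by block match
  p <- ifelse(outer(drug_block, gene_block, "=="), spec$p_in, spec$p_out)
  hit <- matrix(stats::runif(length(p)) < p, nrow = n_drugs)
  idx <- which(hit, arr.ind = TRUE)
  records <- data.frame(
    drug_id = drug_ids[idx[, 1]],
    gene_symbol = gene_ids[idx[, 2]],
    interaction_type = gene_type[idx[, 2]],
    stringsAsFactors = FALSE
  )
  records <- records[order(records$drug_id, records$gene_symbol), ]

  # planted ATC structure
  hint_per_block <- round(spec$hint_fraction * spec$drugs_per_block)
  hint_drugs <- character(0)
  confirmable <- character(0)
  code_rows_old <- list()
  code_rows_new <- list()
  mk_code <- function(letter, i) sprintf("%s01AA%02d", letter, (i %% 99) + 1)

  for (b in seq_len(spec$n_blocks)) {
    ds <- drug_ids[drug_block == b]
    letter <- spec$block_letters[b]
    foreign <- setdiff(atc_level1_letters(), letter)
    hb <- sort(sample(ds, hint_per_block))
    hint_drugs <- c(hint_drugs, hb)
    cb <- sort(sample(hb, round(spec$confirm_fraction * length(hb))))
    confirmable <- c(confirmable, cb)
    for (i in seq_along(ds)) {
      d <- ds[i]
      own <- if (d %in% hb) sample(foreign, 1) else letter
      codes <- mk_code(own, i)
      if (stats::runif(1) < spec$second_code_prob) {
        extra_letter <- if (d %in% hb) sample(foreign, 1) else
          sample(atc_level1_letters(), 1)
        codes <- unique(c(codes, mk_code(extra_letter, i + 50)))
      }
      code_rows_old[[d]] <- codes
      code_rows_new[[d]] <- if (d %in% cb) c(codes, mk_code(letter, i)) else codes
    }
  }

  to_df <- function(rows) {
    data.frame(drug_id = rep(names(rows), lengths(rows)),
               atc_code = unlist(rows, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  drugs <- tibble::tibble(
    drug_id = drug_ids,
    name = sprintf("Synthetic drug %03d", seq_len(n_drugs)),
    groups = rep(list("approved"), n_drugs),
    atc_codes = unname(code_rows_old[drug_ids])
  )
  structure(list(
    interactions = interaction_table(records, drugs, source = "synthetic",
                                     version = sprintf("seed%d", spec$seed)),
    atc_old = atc_table(to_df(code_rows_old), version = "synthetic-old"),
    atc_new = atc_table(to_df(code_rows_new), version = "synthetic-new"),
    truth = list(blocks = drug_block,
                 block_letters = spec$block_letters,
                 hint_drugs = sort(hint_drugs),
                 confirmable_drugs = sort(confirmable)),
    spec = spec
  ), class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(
    "<fixture_bundle> %d blocks x %d drugs | %d interactions | %d planted hints (%d confirmable)\n",
    x$spec$n_blocks, x$spec$drugs_per_block, nrow(x$interactions$records),
    length(x$truth$hint_drugs), length(x$truth$confirmable_drugs)))
  invisible(x)
}

#' Write a fixture bundle to a directory
#'
#' Emits the TSV interchange files (`interactions.tsv`, `atc_old.tsv`,
#' `atc_new.tsv`) plus a `truth.json` with the planted ground truth.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interaction_tsv(bundle$interactions, file.path(dir, "interactions.tsv"))
  write_atc_table(bundle$atc_old, file.path(dir, "atc_old.tsv"))
  write_atc_table(bundle$atc_new, file.path(dir, "atc_new.tsv"))
  jsonlite::write_json(
    list(blocks = as.list(bundle$truth$blocks),
         block_letters = bundle$truth$block_letters,
         hint_drugs = bundle$truth$hint_drugs,
         confirmable_drugs = bundle$truth$confirmable_drugs),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
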