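# ATC tables: drug_id -> set of 7-character ATC codes, with level-1 extraction.

.atc_pattern <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

#' Construct an ATC table
#'
#' An ATC table maps drug identifiers to sets of 7-character ATC codes
#' (pattern letter, 2 digits, 2 letters, 2 digits, e.g. `N02BA01`). Looking up
#' a drug that is absent returns the empty set, so tables from different
#' database versions can be compared over a shared drug-id namespace.
#'
#' @param codes Data frame with columns `drug_id` and `atc_code`.
#' @param version Free-text version label (e.g. `"5.0.9"`).
#' @return An object of class `atc_table`.
#' @export
atc_table <- function(codes, version = "") {
  codes <- as.data.frame(codes, stringsAsFactors = FALSE)
  if (!all(c("drug_id", "atc_code") %in% names(codes))) {
    stop("ATC table needs columns 'drug_id' and 'atc_code'", call. = FALSE)
  }
  codes$drug_id <- as.character(codes$drug_id)
  codes$atc_code <- toupper(trimws(as.character(codes$atc_code)))
  bad <- codes$atc_code[!grepl(.atc_pattern, codes$atc_code)]
  if (length(bad) > 0) {
    stop(sprintf("malformed ATC code(s): %s",
                 paste(utils::head(unique(bad), 5), collapse = ", ")),
         call. = FALSE)
  }
  codes <- unique(codes[, c("drug_id", "atc_code")])
  structure(
    list(codes = tibble::as_tibble(codes), version = version),
    class = "atc_table"
  )
}

#' Read an ATC table from TSV
#'
#' Expects a UTF-8 tab-separated file with header `drug_id  atc_code`, one
#' code per row; rows are grouped by `drug_id` into code sets.
#'
#' @param path Path to the TSV file.
#' @param version Version label stored on the table.
#' @return An `atc_table`.
#' @export
read_atc_table <- function(path, version = "") {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "")
  if (!identical(names(df), c("drug_id", "atc_code"))) {
    stop(sprintf("expected ATC TSV header 'drug_id\\tatc_code', found: %s",
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  atc_table(df, version = version)
}

#' Write an ATC table to TSV
#'
#' @param x An `atc_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_atc_table <- function(x, path) {
  stopifnot(inherits(x, "atc_table"))
  utils::write.table(x$codes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' ATC codes of one drug
#'
#' @param x An `atc_table`.
#' @param drug_id Single drug identifier.
#' @return Character vector of codes; empty if the drug is absent.
#' @export
atc_codes_for <- function(x, drug_id) {
  stopifnot(inherits(x, "atc_table"))
  x$codes$atc_code[x$codes$drug_id == drug_id]
}

#' Extract the level-1 (anatomical group) letter of an ATC code
#'
#' Level 1 of the ATC hierarchy is the first character of the code. The
#' function accepts full 7-character codes or a bare level-1 letter (so it is
#' idempotent) and is case-insensitive on input.
#'
#' @param code Character vector of ATC codes (or single letters).
#' @return Uppercase single letters, same length as `code`.
#' @export
#' @examples
#' extract_atc_level1("L04AC06")  # "L"
#' extract_atc_level1("a11ha06")  # "A"
extract_atc_level1 <- function(code) {
  code <- trimws(as.character(code))
  if (length(code) == 0) return(character(0))
  if (any(is.na(code) | !nzchar(code))) {
    stop("empty ATC code", call. = FALSE)
  }
  ok <- grepl(.atc_pattern, toupper(code)) | grepl("^[A-Za-z]$", code)
  if (!all(ok)) {
    stop(sprintf("ATC code does not match the letter-2digit-2letter-2digit pattern: %s",
                 paste(utils::head(code[!ok], 5), collapse = ", ")),
         call. = FALSE)
  }
  toupper(substr(code, 1, 1))
}

# drug_id -> sorted unique level-1 letters; drugs without codes are absent.
atc_level1_sets <- function(x) {
  stopifnot(inherits(x, "atc_table"))
  if (nrow(x$codes) == 0) return(list())
  lapply(split(extract_atc_level1(x$codes$atc_code), x$codes$drug_id),
         function(l) sort(unique(l)))
}

#' @export
print.atc_table <- function(x, ...) {
  cat(sprintf("<atc_table> %d codes for %d drugs%s\n",
              nrow(x$codes), length(unique(x$codes$drug_id)),
              if (nzchar(x$version)) paste0(" (version ", x$version, ")") else ""))
  invisible(x)
}
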