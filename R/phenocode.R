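#' Phenocode hierarchy utilities
#'
#' Phenocodes group ICD billing codes into hierarchical phenotype codes.
#' A code is a string of 1--3 integer digits optionally followed by a dot
#' and one or two decimal digits, e.g. `"411"`, `"411.2"`, `"250.11"`.
#' The number of decimal digits is the code's *level* (0, 1 or 2); every
#' patient diagnosed with a level-2 code is by definition also diagnosed
#' with the level-1 and level-0 codes obtained by truncating one trailing
#' digit at a time. Codes are always handled as strings: `"250.10"` and
#' `"250.1"` are distinct codes and must never be collapsed by numeric
#' conversion.
#'
#' @name phenocode
NULL

.phenocode_rx <- "^[0-9]{1,3}(\\.[0-9]{1,2})?$"

#' Validate phenocode strings
#'
#' @param code character vector of candidate phenocodes.
#' @return `code`, invisibly, if all entries are well-formed; otherwise an
#'   error naming the first offending string.
#' @export
check_phenocode <- function(code) {
  bad <- code[!grepl(.phenocode_rx, code)]
  if (length(bad) > 0) {
    stop("malformed phenocode: '", bad[[1]], "'", call. = FALSE)
  }
  invisible(code)
}

#' Phenocode level
#'
#' @param code character vector of phenocodes.
#' @return integer vector: the number of digits after the decimal point
#'   (0 for root codes).
#' @examples
#' phenocode_level(c("411", "411.2", "250.11"))
#' @export
phenocode_level <- function(code) {
  check_phenocode(code)
  dec <- sub("^[0-9]+\\.?", "", code)
  nchar(dec)
}

#' Ancestors of a phenocode
#'
#' Returns the chain of broader codes obtained by removing one trailing
#' decimal digit at a time, nearest ancestor first. Level-0 codes have no
#' ancestors.
#'
#' @param code a single phenocode string.
#' @return character vector of 0, 1 or 2 ancestor codes, nearest first.
#' @examples
#' phenocode_ancestors("250.11") # "250.1" "250"
#' phenocode_ancestors("411")    # character(0)
#' @export
phenocode_ancestors <- function(code) {
  stopifnot(length(code) == 1L)
  check_phenocode(code)
  out <- character(0)
  while (grepl("\\.", code)) {
    code <- sub("\\.?[0-9]$", "", code)
    out <- c(out, code)
  }
  out
}

# level without grammar validation, for node annotation of identifiers
# that need not be phenocodes (e.g. toy disease labels)
.level_lenient <- function(code) {
  ifelse(grepl("\\.", code), nchar(sub(".*\\.", "", code)), 0L)
}

#' Test ancestor--descendant relationship between two phenocodes
#'
#' @param a,b phenocode strings (vectorised, recycled).
#' @return logical: `TRUE` where one code is a truncation-ancestor of the
#'   other (in either direction). Siblings and unrelated codes give `FALSE`.
#' @export
phenocode_related <- function(a, b) {
  check_phenocode(a)
  check_phenocode(b)
  mapply(function(x, y) {
    x %in% phenocode_ancestors(y) || y %in% phenocode_ancestors(x)
  }, a, b, USE.NAMES = FALSE)
}
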