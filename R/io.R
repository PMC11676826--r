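#' @importFrom rlang .data
#' @importFrom stats median pbinom phyper pnorm sd setNames rbinom rlnorm rnorm runif
#' @importFrom utils read.delim write.table head combn
NULL

.read_table_checked <- function(path, required, sep, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("schema error in ", what, " file '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

.as_numeric_checked <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "" & x != "NA")
  if (length(bad) > 0) {
    stop("parse error in '", path, "': non-numeric value '", x[bad[[1]]],
         "' in column '", col, "' at line ", bad[[1]] + 1L, call. = FALSE)
  }
  out
}

#' Read filtered PheWAS summary statistics
#'
#' Reads a tab-separated table of top-hit SNP--phenotype associations and
#' applies the association-strength filters: rows with `pval >=
#' p_threshold` or `maf < maf_cutoff` are dropped (the count of dropped
#' rows is reported as a message). One row per `(snp_id, phenocode)` is
#' required.
#'
#' @param path TSV file with header columns `snp_id`, `chrom`, `pos`,
#'   `phenocode`, `beta`, `pval`, `maf`.
#' @param p_threshold association p-value threshold; default `1e-6`.
#' @param maf_cutoff minor-allele-frequency cutoff; default `0.001` (0.1%).
#' @return tibble of associations with typed columns, one row per retained
#'   `(snp_id, phenocode)` pair.
#' @export
read_summary_stats <- function(path, p_threshold = 1e-6, maf_cutoff = 0.001) {
  req <- c("snp_id", "chrom", "pos", "phenocode", "beta", "pval", "maf")
  df <- .read_table_checked(path, req, sep = "\t", what = "summary statistics")
  if (nrow(df) == 0) {
    warning("summary statistics file '", path, "' contains no rows",
            call. = FALSE)
    return(tibble::tibble(
      snp_id = character(), chrom = character(), pos = integer(),
      phenocode = character(), beta = double(), pval = double(),
      maf = double()
    ))
  }
  out <- tibble::tibble(
    snp_id = df$snp_id,
    chrom = df$chrom,
    pos = as.integer(.as_numeric_checked(df$pos, "pos", path)),
    phenocode = df$phenocode,
    beta = .as_numeric_checked(df$beta, "beta", path),
    pval = .as_numeric_checked(df$pval, "pval", path),
    maf = .as_numeric_checked(df$maf, "maf", path)
  )
  check_phenocode(out$phenocode)
  dup <- duplicated(out[, c("snp_id", "phenocode")])
  if (any(dup)) {
    stop("duplicate (snp_id, phenocode) row(s): ",
         paste(utils::head(paste(out$snp_id[dup], out$phenocode[dup], sep = "/"), 3),
               collapse = ", "), call. = FALSE)
  }
  keep <- out$pval < p_threshold & out$maf >= maf_cutoff
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " association(s) dropped by p-value/MAF filter")
  }
  out[keep, ]
}

#' Read a long-format pairwise LD table
#'
#' @param path TSV file with header columns `snp1`, `snp2`, `r2`.
#' @return tibble with those columns; `r2` numeric in \[0, 1\]. Lookups on
#'   the table should be treated as symmetric in `(snp1, snp2)`; absent
#'   pairs mean r-squared 0.
#' @export
read_ld_table <- function(path) {
  df <- .read_table_checked(path, c("snp1", "snp2", "r2"), sep = "\t",
                            what = "LD")
  tibble::tibble(
    snp1 = df$snp1, snp2 = df$snp2,
    r2 = .as_numeric_checked(df$r2, "r2", path)
  )
}

#' Read phenocode metadata
#'
#' Each code carries its own category from this table; categories are not
#' inherited along the hierarchy.
#'
#' @param path TSV file with header columns `phenocode`, `description`,
#'   `category`.
#' @return tibble with `phenocode`, `description`, `category`, `level`.
#' @export
read_phenocode_meta <- function(path) {
  df <- .read_table_checked(path, c("phenocode", "description", "category"),
                            sep = "\t", what = "phenocode metadata")
  check_phenocode(df$phenocode)
  tibble::tibble(
    phenocode = df$phenocode,
    description = df$description,
    category = df$category,
    level = phenocode_level(df$phenocode)
  )
}

#' Read patient first-diagnosis events
#'
#' @param path CSV file with header columns `patient_id`, `phenocode`,
#'   `date` (ISO-8601 calendar dates).
#' @return tibble with `patient_id`, `phenocode`, `date` (`Date`).
#' @export
read_events <- function(path) {
  df <- .read_table_checked(path, c("patient_id", "phenocode", "date"),
                            sep = ",", what = "events")
  tibble::tibble(
    patient_id = df$patient_id,
    phenocode = df$phenocode,
    date = as.Date(df$date)
  )
}

#' Read the patient table
#'
#' @param path CSV file with header columns `patient_id`, `sex`,
#'   `birth_date`, `death_date`, `cod_phenocodes`. `sex` is a binary code
#'   (0/1); `death_date` may be empty for living patients;
#'   `cod_phenocodes` is a semicolon-separated list of cause-of-death
#'   phenocodes (possibly empty).
#' @return tibble with typed columns; `cod_phenocodes` is a list-column of
#'   character vectors.
#' @export
read_patients <- function(path) {
  df <- .read_table_checked(
    path, c("patient_id", "sex", "birth_date", "death_date", "cod_phenocodes"),
    sep = ",", what = "patients")
  tibble::tibble(
    patient_id = df$patient_id,
    sex = as.integer(.as_numeric_checked(df$sex, "sex", path)),
    birth_date = as.Date(df$birth_date),
    death_date = as.Date(ifelse(df$death_date == "", NA, df$death_date)),
    cod_phenocodes = lapply(strsplit(df$cod_phenocodes, ";", fixed = TRUE),
                            function(x) x[x != ""])
  )
}

# full-precision numeric formatting so write -> read round-trips bit-exactly
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

.edgelist_schemas <- list(
  phenet = c("From", "To", "N", "betaMerged", "FromCode", "ToCode", "SNPs"),
  sub_phenet = c("From", "To", "N", "betaMerged", "FromCode", "ToCode",
                 "SNPs", "C", "MCC", "fisherp"),
  trajectory_nodes = c("Phenocode", "Disease", "Prev", "Dprev", "Category",
                       "Sink", "Level"),
  trajectory_edges = c("First", "Second", "MedianTime", "Time")
)

#' Median-interval time bin
#'
#' Bins a median inter-diagnosis interval (in years) into the categorical
#' scale used by the directed-network edge list: 1 for under a year, 2 for
#' 1--3 years, 3 for 3--5, 4 for 5--10, 5 for over 10. Boundaries are
#' left-closed/right-open.
#'
#' @param median_years numeric vector of intervals in years.
#' @return integer vector of bins in 1..5.
#' @export
time_bin <- function(median_years) {
  as.integer(cut(median_years, breaks = c(0, 1, 3, 5, 10, Inf),
                 right = FALSE, labels = FALSE, include.lowest = TRUE))
}

#' Write a network table in one of the standard edge-list schemas
#'
#' @param x a tibble carrying the schema's fields (see Details), or a
#'   `phenet` / `sub_phenet` object whose `tidy()` form carries them.
#' @param schema one of `"phenet"`, `"sub_phenet"`, `"trajectory_nodes"`,
#'   `"trajectory_edges"`.
#' @param path output TSV path.
#' @details Column sets per schema: `phenet` writes `From, To, N,
#'   betaMerged, FromCode, ToCode, SNPs`; `sub_phenet` adds `C, MCC,
#'   fisherp`; `trajectory_nodes` writes `Phenocode, Disease, Prev, Dprev,
#'   Category, Sink, Level`; `trajectory_edges` writes `First, Second,
#'   MedianTime, Time` where `Time` is the categorical interval bin (see
#'   [time_bin()]) computed from `MedianTime` when absent.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(x, schema, path) {
  if (!schema %in% names(.edgelist_schemas)) {
    stop("unknown edge-list schema '", schema, "'; expected one of ",
         paste(names(.edgelist_schemas), collapse = ", "), call. = FALSE)
  }
  if (inherits(x, c("phenet", "sub_phenet", "directed_phenet"))) {
    x <- as_edgelist_table(x, schema)
  }
  cols <- .edgelist_schemas[[schema]]
  if (schema == "trajectory_edges" && !"Time" %in% names(x) &&
      "MedianTime" %in% names(x)) {
    x$Time <- time_bin(x$MedianTime)
  }
  gap <- setdiff(cols, names(x))
  if (length(gap) > 0) {
    stop("schema error: table for schema '", schema, "' lacks field(s) ",
         paste(gap, collapse = ", "), call. = FALSE)
  }
  out <- x[, cols, drop = FALSE]
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]])) {
      out[[cl]] <- .fmt_num(out[[cl]])
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list file written by [write_edgelist()]
#'
#' @inheritParams write_edgelist
#' @param path TSV path.
#' @return tibble with the schema's columns, numerics restored bit-exactly.
#' @export
read_edgelist <- function(path, schema) {
  if (!schema %in% names(.edgelist_schemas)) {
    stop("unknown edge-list schema '", schema, "'", call. = FALSE)
  }
  cols <- .edgelist_schemas[[schema]]
  df <- .read_table_checked(path, cols, sep = "\t", what = schema)
  num_cols <- list(
    phenet = c("N", "betaMerged"),
    sub_phenet = c("N", "betaMerged", "C", "MCC", "fisherp"),
    trajectory_nodes = c("Prev", "Dprev", "Sink", "Level"),
    trajectory_edges = c("MedianTime", "Time")
  )[[schema]]
  for (cl in num_cols) df[[cl]] <- .as_numeric_checked(df[[cl]], cl, path)
  df[, cols]
}

#' Export a network object as GraphML
#'
#' @param x a `phenet`, `sub_phenet` or `directed_phenet` object.
#' @param path output GraphML path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(x, path) {
  g <- as_igraph(x)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
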