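#' Expand diagnosis events along the phenocode hierarchy
#'
#' A diagnosis with a level-1 or level-2 phenocode implies a diagnosis with
#' every broader (ancestor) code at the same date. Expansion adds those
#' implied events, restricted to codes present in `universe`, and keeps the
#' minimum date per `(patient, code)` over explicit and implied events.
#'
#' @param events tibble with `patient_id`, `phenocode`, `date`.
#' @param universe character vector of phenocodes admitted to the analysis
#'   (typically the network's node set plus their ancestors). Events whose
#'   code is outside the universe are dropped with a warning.
#' @return tibble with `patient_id`, `phenocode`, `date`: at most one row
#'   per `(patient, phenocode)`, first-diagnosis dates.
#' @export
expand_hierarchy <- function(events, universe) {
  known <- events$phenocode %in% universe
  if (any(!known)) {
    warning(sum(!known), " event(s) with phenocodes outside the universe dropped",
            call. = FALSE)
    events <- events[known, ]
  }
  if (nrow(events) == 0) {
    return(tibble::tibble(patient_id = character(),
                          phenocode = character(), date = as.Date(integer(0))))
  }
  codes <- unique(events$phenocode)
  anc_map <- lapply(codes, function(cd) {
    c(cd, intersect(phenocode_ancestors(cd), universe))
  })
  names(anc_map) <- codes
  n_exp <- lengths(anc_map)[events$phenocode]
  expanded <- tibble::tibble(
    patient_id = rep(events$patient_id, n_exp),
    phenocode = unlist(anc_map[events$phenocode], use.names = FALSE),
    date = rep(events$date, n_exp)
  )
  expanded |>
    dplyr::group_by(.data$patient_id, .data$phenocode) |>
    dplyr::summarise(date = min(.data$date), .groups = "drop")
}

#' Count disease-pair co-occurrences across patients
#'
#' In unordered mode every 2-subset of a patient's disease set contributes
#' one count to its pair. In ordered mode the patient's events are sorted
#' by first-diagnosis date and only *consecutive* pairs of the sorted
#' sequence are counted, so a patient with history A, B, C, D contributes
#' A-B, B-C and C-D only. Within ordered mode, same-date diagnoses carry no
#' temporal information: tied codes produce no ordered pair between
#' themselves and are ordered lexicographically for adjacency to their
#' neighbours.
#'
#' @param events hierarchy-expanded event tibble (`patient_id`,
#'   `phenocode`, `date`), at most one row per patient and code.
#' @param mode `"unordered"` or `"ordered"`.
#' @return list with `counts` (tibble `code_a`, `code_b`, `C`; in ordered
#'   mode `code_a` precedes `code_b`) and `prevalence` (tibble `phenocode`,
#'   `P`: number of patients per disease).
#' @export
pair_counts <- function(events, mode = c("unordered", "ordered")) {
  mode <- match.arg(mode)
  prevalence <- events |>
    dplyr::count(.data$phenocode, name = "P") |>
    dplyr::arrange(.data$phenocode)

  if (mode == "unordered") {
    counts <- events |>
      dplyr::inner_join(events, by = "patient_id", suffix = c("_a", "_b"),
                        relationship = "many-to-many") |>
      dplyr::filter(.data$phenocode_a < .data$phenocode_b) |>
      dplyr::count(code_a = .data$phenocode_a, code_b = .data$phenocode_b,
                   name = "C")
  } else {
    seqs <- events |>
      dplyr::arrange(.data$patient_id, .data$date, .data$phenocode) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(
        nxt = dplyr::lead(.data$phenocode),
        nxt_date = dplyr::lead(.data$date)) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$nxt), .data$nxt_date > .data$date)
    counts <- seqs |>
      dplyr::count(code_a = .data$phenocode, code_b = .data$nxt, name = "C")
  }
  list(counts = dplyr::arrange(counts, .data$code_a, .data$code_b),
       prevalence = prevalence)
}

#' Matthews correlation coefficient for a disease pair
#'
#' Comorbidity-strength measure: the Pearson correlation of the two binary
#' disease-indicator vectors over the cohort,
#' `(C*N - Pi*Pj) / sqrt(Pi*Pj*(N-Pi)*(N-Pj))`.
#'
#' @param C number of patients with both diseases.
#' @param P_i,P_j numbers of patients with each disease.
#' @param N cohort size.
#' @return numeric in \[-1, 1\]; `NA` (undefined) when either prevalence is
#'   0 or N. Vectorised.
#' @export
mcc <- function(C, P_i, P_j, N) {
  C <- as.numeric(C); P_i <- as.numeric(P_i); P_j <- as.numeric(P_j)
  N <- as.numeric(N)
  denom2 <- P_i * P_j * (N - P_i) * (N - P_j)
  out <- ifelse(denom2 > 0, (C * N - P_i * P_j) / sqrt(denom2), NA_real_)
  out
}

#' One-sided Fisher exact test for co-occurrence enrichment
#'
#' Upper-tail probability of observing `C` or more patients with both
#' diseases in the 2x2 contingency table with fixed margins `P_i`, `P_j`,
#' `N`: a hypergeometric tail probability `P(X >= C)`.
#'
#' @inheritParams mcc
#' @return p-value in (0, 1\]. Vectorised.
#' @export
fisher_one_sided <- function(C, P_i, P_j, N) {
  bad <- C < 0 | P_i - C < 0 | P_j - C < 0 | N - P_i - P_j + C < 0
  if (any(bad)) {
    i <- which(bad)[[1]]
    stop("negative contingency cell for C=", C[i], ", P_i=", P_i[i],
         ", P_j=", P_j[i], ", N=", N[i], call. = FALSE)
  }
  phyper(C - 1, P_i, N - P_i, P_j, lower.tail = FALSE)
}

#' Per-pair comorbidity statistics
#'
#' Computes `C`, `P_i`, `P_j`, MCC and the one-sided Fisher p-value for
#' disease pairs observed in the cohort. Pairs whose MCC is undefined
#' (either disease has zero or full prevalence) are excluded from testing
#' and reported with `tested = FALSE`.
#'
#' @param events hierarchy-expanded event tibble.
#' @param n_patients total cohort size `N` (includes patients without any
#'   network-mapped event).
#' @param mode `"unordered"` or `"ordered"` (see [pair_counts()]).
#' @return tibble `code_a`, `code_b`, `C`, `P_i`, `P_j`, `N`, `mcc`,
#'   `fisher_p`, `tested`, of class `comorbidity_stats` with the mode
#'   stored as an attribute.
#' @export
comorbidity_stats <- function(events, n_patients,
                              mode = c("unordered", "ordered")) {
  mode <- match.arg(mode)
  pc <- pair_counts(events, mode)
  prev <- setNames(pc$prevalence$P, pc$prevalence$phenocode)
  out <- pc$counts |>
    dplyr::mutate(
      P_i = unname(prev[.data$code_a]),
      P_j = unname(prev[.data$code_b]),
      N = n_patients,
      mcc = mcc(.data$C, .data$P_i, .data$P_j, .data$N),
      tested = !is.na(.data$mcc),
      fisher_p = ifelse(.data$tested,
                        fisher_one_sided(.data$C, .data$P_i, .data$P_j,
                                         .data$N),
                        NA_real_)
    ) |>
    dplyr::select("code_a", "code_b", "C", "P_i", "P_j", "N", "mcc",
                  "fisher_p", "tested")
  structure(out, mode = mode, class = c("comorbidity_stats", class(out)))
}

# look up stats rows for given unordered pairs; missing pairs -> C = 0 rows
.stats_for_pairs <- function(stats, code_a, code_b) {
  key <- paste(pmin(code_a, code_b), pmax(code_a, code_b))
  idx <- match(key, paste(stats$code_a, stats$code_b))
  tibble::tibble(code_a = pmin(code_a, code_b),
                 code_b = pmax(code_a, code_b),
                 C = ifelse(is.na(idx), 0L, stats$C[idx]),
                 mcc = stats$mcc[idx],
                 fisher_p = stats$fisher_p[idx],
                 tested = !is.na(idx) & stats$tested[idx])
}

#' Extract the co-occurrence-validated sub-network
#'
#' Keeps exactly the network links whose disease pair shows
#' Bonferroni-significant co-occurrence: one-sided Fisher p below
#' `alpha / m`, with `m` the number of network links actually tested
#' (links with undefined MCC count as not significant and are excluded
#' from `m`). Nodes left without links are removed; the link-weight
#' measure switches to the MCC.
#'
#' @param phenet a `phenet` object.
#' @param stats unordered-mode [comorbidity_stats()] table.
#' @param alpha family-wise error level; default 0.05.
#' @return a `sub_phenet` object (same shape as `phenet`, links carrying
#'   `C`, `mcc`, `fisher_p`, weight measure `"mcc"`), with attributes
#'   `n_tested` (the Bonferroni denominator `m`), `n_links_total` and
#'   `threshold`.
#' @export
extract_sub_phenet <- function(phenet, stats, alpha = 0.05) {
  st <- .stats_for_pairs(stats, phenet$links$code_a, phenet$links$code_b)
  m <- sum(st$tested)
  if (m < nrow(phenet$links)) {
    message(nrow(phenet$links) - m,
            " link(s) untested (undefined MCC or no cohort record); ",
            "Bonferroni denominator m = ", m)
  }
  thr <- if (m > 0) alpha / m else 0
  keep <- st$tested & !is.na(st$fisher_p) & st$fisher_p < thr
  links <- phenet$links[keep, ]
  links$C <- st$C[keep]
  links$mcc <- st$mcc[keep]
  links$fisher_p <- st$fisher_p[keep]
  nodes <- phenet$nodes[
    phenet$nodes$phenocode %in% c(links$code_a, links$code_b), ]
  structure(list(nodes = nodes, links = links),
            weight_measure = "mcc", n_tested = m,
            n_links_total = nrow(phenet$links), threshold = thr,
            class = c("sub_phenet", "phenet"))
}

#' @export
print.sub_phenet <- function(x, ...) {
  cat("<sub_phenet> ", nrow(x$nodes), " diseases, ", nrow(x$links),
      " co-occurrence-validated links (m = ", attr(x, "n_tested"),
      " tested, threshold ", format(attr(x, "threshold"), digits = 3),
      ")\n", sep = "")
  invisible(x)
}
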