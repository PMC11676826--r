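#' Shuffle node labels of a network
#'
#' Draws a uniform random permutation of the disease labels over the node
#' positions, leaving topology and link weights untouched: the degree
#' sequence of the relabeled network equals the original's. Uses the
#' current R random-number stream.
#'
#' @param x a `phenet` or `sub_phenet` object.
#' @return a network object of the same class with links rewritten to the
#'   permuted labels.
#' @export
shuffle_node_labels <- function(x) {
  codes <- x$nodes$phenocode
  relabel <- setNames(sample(codes), codes)
  links <- x$links
  a <- unname(relabel[links$code_a])
  b <- unname(relabel[links$code_b])
  links$code_a <- pmin(a, b)
  links$code_b <- pmax(a, b)
  x$links <- dplyr::arrange(links, .data$code_a, .data$code_b)
  x
}

#' Null distribution of significant co-occurring link counts
#'
#' For each replicate, node labels are shuffled and the number of links
#' whose (pre-computed) comorbidity is Bonferroni-significant is counted.
#' Significance is fixed before shuffling: a pair is significant when its
#' one-sided Fisher p-value falls below `alpha / m` (unordered mode) or
#' `alpha / (2 m)` (ordered mode, where each undirected link yields two
#' directed tests and either direction may qualify), with `m` the number
#' of network links tested in the observed analysis. Relabeled links
#' touching a disease pair with no cohort record count as not significant.
#'
#' Replicates are driven by per-replicate substreams spawned from the
#' master `seed`, so the distribution is reproducible and independent of
#' execution order.
#'
#' @param x a `phenet` object.
#' @param stats full-cohort [comorbidity_stats()] table in the matching
#'   mode (all observed pairs, not just network pairs).
#' @param n_reps number of replicates; default 1000.
#' @param mode `"unordered"` or `"ordered"`.
#' @param seed master integer seed.
#' @param alpha family-wise level used for the Bonferroni threshold.
#' @return a `null_distribution` object: list with `statistic`, `values`
#'   (length `n_reps`), `n_reps`, `seed`, `observed` (the count on the
#'   unshuffled network) and `threshold`.
#' @export
overlap_null_distribution <- function(x, stats, n_reps = 1000,
                                      mode = c("unordered", "ordered"),
                                      seed = 1L, alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(identical(attr(stats, "mode"), mode))
  links <- x$links
  obs_st <- .stats_for_pairs(
    structure(.undirect_stats(stats), mode = "unordered"),
    links$code_a, links$code_b)
  m <- sum(obs_st$tested)
  n_tests <- if (mode == "ordered") 2 * m else m
  thr <- if (n_tests > 0) alpha / n_tests else 0

  sig_keys <- .significant_pair_keys(stats, thr, mode)
  count_sig <- function(a, b) {
    sum(paste(pmin(a, b), pmax(a, b)) %in% sig_keys)
  }

  observed <- count_sig(links$code_a, links$code_b)
  codes <- x$nodes$phenocode
  rep_seeds <- local({
    set.seed(seed)
    sample.int(.Machine$integer.max, n_reps)
  })
  values <- vapply(rep_seeds, function(s) {
    set.seed(s)
    relabel <- setNames(sample(codes), codes)
    count_sig(unname(relabel[links$code_a]), unname(relabel[links$code_b]))
  }, numeric(1))

  structure(list(statistic = paste0("significant_", mode, "_pairs"),
                 values = values, n_reps = n_reps, seed = seed,
                 observed = observed, threshold = thr),
            class = "null_distribution")
}

# collapse a (possibly directed) stats table to one row per unordered pair,
# keeping whether either direction was tested
.undirect_stats <- function(stats) {
  tibble::as_tibble(stats) |>
    dplyr::mutate(ka = pmin(.data$code_a, .data$code_b),
                  kb = pmax(.data$code_a, .data$code_b)) |>
    dplyr::group_by(code_a = .data$ka, code_b = .data$kb) |>
    dplyr::summarise(C = max(c(.data$C, -Inf)),
                     mcc = suppressWarnings(max(.data$mcc, na.rm = TRUE)),
                     fisher_p = suppressWarnings(min(.data$fisher_p, na.rm = TRUE)),
                     tested = any(.data$tested), .groups = "drop") |>
    dplyr::mutate(mcc = ifelse(is.finite(.data$mcc), .data$mcc, NA_real_),
                  fisher_p = ifelse(is.finite(.data$fisher_p), .data$fisher_p,
                                    NA_real_))
}

# unordered keys of pairs significant at threshold thr; in ordered mode a
# pair qualifies when either direction's test passes
.significant_pair_keys <- function(stats, thr, mode) {
  sig <- stats$tested & !is.na(stats$fisher_p) & stats$fisher_p < thr
  a <- stats$code_a[sig]
  b <- stats$code_b[sig]
  unique(paste(pmin(a, b), pmax(a, b)))
}

#' Empirical p-value against a null distribution
#'
#' The upper-tail p-value is the fraction of null values strictly larger
#' than the observed statistic (ties therefore favour significance). When
#' no null value exceeds the observation the p-value is 0 and the display
#' string reports the resolution bound, e.g. `"< 1e-04"` at 10^4
#' replicates.
#'
#' @param observed observed statistic (scalar).
#' @param null_values numeric vector of null replicates (nonempty).
#' @param tail `"upper"` (default) or `"lower"`.
#' @return list with `p` (numeric in \[0, 1\]) and `display` (string).
#' @export
empirical_p <- function(observed, null_values, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (length(null_values) == 0) {
    stop("empirical_p needs a nonempty null distribution", call. = FALSE)
  }
  n <- length(null_values)
  p <- if (tail == "upper") mean(null_values > observed)
       else mean(null_values < observed)
  display <- if (p == 0) paste0("< ", format(1 / n)) else format(p)
  list(p = p, display = display)
}

#' @export
print.null_distribution <- function(x, ...) {
  ep <- empirical_p(x$observed, x$values)
  cat("<null_distribution> ", x$statistic, ": observed ", x$observed,
      ", null mean ", format(mean(x$values), digits = 4),
      " (", x$n_reps, " reps, seed ", x$seed, "), empirical p ",
      ep$display, "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.phenet
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, value = x$values)
}

#' Write a null distribution as a single-column TSV
#'
#' The header comment line records the statistic name, replicate count and
#' seed.
#'
#' @param x a `null_distribution` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_null_distribution <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# statistic=%s n_reps=%d seed=%d", x$statistic,
                     x$n_reps, x$seed), con)
  writeLines("value", con)
  writeLines(format(x$values, trim = TRUE), con)
  invisible(path)
}
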