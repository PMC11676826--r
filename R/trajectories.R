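#' Disease pairs eligible for direction testing
#'
#' Ancestor--descendant pairs of the same phenocode family carry no
#' temporal information (a lower-level diagnosis implies the higher levels
#' at the same event), so only pairs where neither code is a
#' truncation-ancestor of the other are tested. Siblings under a common
#' parent are retained.
#'
#' @param x a `sub_phenet` (or `phenet`) object.
#' @return tibble (`code_a`, `code_b`) of eligible unordered pairs.
#' @export
eligible_pairs <- function(x) {
  links <- x$links[, c("code_a", "code_b")]
  keep <- !phenocode_related(links$code_a, links$code_b)
  links[keep, ]
}

#' Per-event regression table for a directed disease pair
#'
#' One row per (patient, event) over the patient's date-sorted sequence of
#' first diagnoses, truncated at the patient's first `B` event
#' (inclusive); patients never diagnosed with `B` contribute all their
#' events. `outcome` indicates whether the event is `B`; `prior_A`
#' whether `A` was diagnosed strictly before the event's date (same-date
#' `A` does not count); `age` is years from birth at the event.
#'
#' @param events hierarchy-expanded event tibble (`patient_id`,
#'   `phenocode`, `date`), the full event universe of network-mapped
#'   phenocodes.
#' @param patients patient tibble (`patient_id`, `sex`, `birth_date`).
#' @param code_a,code_b the A and B phenocodes of the A-before-B
#'   hypothesis.
#' @return tibble (`patient_id`, `j`, `outcome`, `prior_A`, `age`, `sex`).
#' @export
build_event_table <- function(events, patients, code_a, code_b) {
  ev <- events |>
    dplyr::arrange(.data$patient_id, .data$date, .data$phenocode) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      j = dplyr::row_number(),
      a_date = .data$date[match(code_a, .data$phenocode)],
      b_j = .data$j[match(code_b, .data$phenocode)]
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(is.na(.data$b_j) | .data$j <= .data$b_j)
  ev |>
    dplyr::inner_join(patients[, c("patient_id", "sex", "birth_date")],
                      by = "patient_id") |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      j = .data$j,
      outcome = as.integer(.data$phenocode == code_b),
      prior_A = as.integer(!is.na(.data$a_date) &
                             .data$a_date < .data$date),
      age = as.numeric(.data$date - .data$birth_date) / 365.25,
      sex = .data$sex
    )
}

#' Logistic direction model for a disease pair
#'
#' Fits `outcome ~ prior_A + age + sex` by maximum-likelihood logistic
#' regression and returns the `prior_A` coefficient with its p-value
#' (Wald by default, likelihood-ratio on request). A positive significant
#' coefficient is evidence that having already contracted A raises the
#' probability that the next diagnosis is B, independent of age and sex.
#' Single-class outcomes, constant predictors, separation and
#' non-convergence are flagged inestimable rather than raised.
#'
#' @param event_table output of [build_event_table()].
#' @param test `"wald"` (default) or `"lrt"`.
#' @return tibble (`beta1`, `beta1_p`, `estimable`, `reason`).
#' @export
fit_direction <- function(event_table, test = c("wald", "lrt")) {
  test <- match.arg(test)
  fail <- function(reason) {
    tibble::tibble(beta1 = NA_real_, beta1_p = NA_real_,
                   estimable = FALSE, reason = reason)
  }
  if (nrow(event_table) == 0) return(fail("no events"))
  if (length(unique(event_table$outcome)) < 2) {
    return(fail("single-class outcome"))
  }
  if (length(unique(event_table$prior_A)) < 2) {
    return(fail("constant prior_A"))
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    tryCatch(
      stats::glm(outcome ~ prior_A + age + sex, family = stats::binomial(),
                 data = event_table),
      error = function(e) NULL),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (is.null(fit)) return(fail("fit error"))
  if (!fit$converged) return(fail("non-convergence"))
  if (separation) return(fail("separation"))
  beta1 <- stats::coef(fit)[["prior_A"]]
  if (is.na(beta1)) return(fail("prior_A aliased"))
  p <- if (test == "wald") {
    summary(fit)$coefficients["prior_A", "Pr(>|z|)"]
  } else {
    fit0 <- stats::update(fit, . ~ . - prior_A)
    stats::anova(fit0, fit, test = "Chisq")[2, "Pr(>Chi)"]
  }
  tibble::tibble(beta1 = beta1, beta1_p = p, estimable = TRUE,
                 reason = NA_character_)
}

#' Binomial majority-ordering test
#'
#' Among `n` patients diagnosed with both diseases (same-date pairs
#' excluded from both counts), `x` is the number with A strictly before
#' B. The one-sided upper-tail p-value `P(X >= x)` under
#' `Binomial(n, p0)` tests the null that either ordering is equally
#' likely.
#'
#' @param x count of A-before-B patients.
#' @param n count of dual-diagnosed patients with distinct dates (>= 1).
#' @param p0 null ordering probability; default 0.5.
#' @return p-value. Vectorised.
#' @export
binomial_ordering_test <- function(x, n, p0 = 0.5) {
  if (any(n < 1)) stop("binomial ordering test needs n >= 1", call. = FALSE)
  stopifnot(all(x >= 0), all(x <= n))
  pbinom(x - 1, n, p0, lower.tail = FALSE)
}

# per-patient first-diagnosis dates of two codes, dropping ties
.dual_dates <- function(events, code_a, code_b) {
  da <- events[events$phenocode == code_a, c("patient_id", "date")]
  db <- events[events$phenocode == code_b, c("patient_id", "date")]
  dd <- dplyr::inner_join(da, db, by = "patient_id",
                          suffix = c("_a", "_b"))
  dd[dd$date_a != dd$date_b, ]
}

#' Build the directed disease-trajectory network
#'
#' Two-step procedure over the eligible pairs of the co-occurrence
#' validated sub-network. Step 1 fits the logistic direction model for
#' both directions of every pair and keeps directions with a positive
#' `prior_A` coefficient significant at `alpha1 / n_fitted` (Bonferroni
#' over the number of models actually fitted). Step 2 applies the
#' binomial majority-ordering test at `alpha2 / n_step1` (Bonferroni over
#' step-1 survivors) and keeps only the majority direction (`x/n > 0.5`),
#' so the kept arc set contains no 2-cycles. Median inter-event times are
#' computed over patients with the kept ordering and follow-up longer
#' than `min_followup_years`. Node annotations: prevalence, mortality
#' rate (cause-of-death count over prevalence; deaths without any
#' clinical record of the disease still count, so rates above 1 are
#' possible and logged), sink flag (no outgoing arc) and weak-component
#' membership.
#'
#' @param sub_phenet a `sub_phenet` object.
#' @param events hierarchy-expanded event tibble restricted to the
#'   network universe.
#' @param patients patient tibble from [read_patients()] or
#'   [simulate_cohort()].
#' @param alpha1,alpha2 family-wise levels of the two steps; default 0.05.
#' @param min_followup_years follow-up (last minus first event date)
#'   required for the interval computation; default 2.
#' @param followup_filter when `TRUE` (default) the whole stage is
#'   restricted to patients whose follow-up exceeds
#'   `min_followup_years`; when `FALSE` only the interval computation is.
#' @param test p-value type for the logistic fits (see
#'   [fit_direction()]).
#' @return a `directed_phenet` object: list with `nodes`, `arcs` and the
#'   full per-direction `pair_stats` table (both steps, drop reasons);
#'   attributes `n_fitted` and `n_step1`.
#' @export
build_directed_network <- function(sub_phenet, events, patients,
                                   alpha1 = 0.05, alpha2 = 0.05,
                                   min_followup_years = 2,
                                   followup_filter = TRUE,
                                   test = "wald") {
  followup <- events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      fu_years = as.numeric(max(.data$date) - min(.data$date)) / 365.25,
      .groups = "drop")
  if (followup_filter) {
    keep_pat <- followup$patient_id[followup$fu_years > min_followup_years]
    events <- events[events$patient_id %in% keep_pat, ]
    patients <- patients[patients$patient_id %in% keep_pat, ]
  }

  pairs <- eligible_pairs(sub_phenet)
  directed <- dplyr::bind_rows(
    tibble::tibble(A = pairs$code_a, B = pairs$code_b),
    tibble::tibble(A = pairs$code_b, B = pairs$code_a))

  fits <- purrr::pmap_dfr(directed, function(A, B) {
    et <- build_event_table(events, patients, A, B)
    cbind(tibble::tibble(A = A, B = B), fit_direction(et, test = test))
  })
  n_fitted <- sum(fits$estimable)
  thr1 <- if (n_fitted > 0) alpha1 / n_fitted else 0
  fits$step1 <- fits$estimable & !is.na(fits$beta1) & fits$beta1 > 0 &
    fits$beta1_p < thr1

  surv <- fits[fits$step1, ]
  n_step1 <- nrow(surv)
  thr2 <- if (n_step1 > 0) alpha2 / n_step1 else 0
  if (n_step1 > 0) {
    ord <- purrr::pmap_dfr(surv[, c("A", "B")], function(A, B) {
      dd <- .dual_dates(events, A, B)
      n <- nrow(dd)
      x <- sum(dd$date_a < dd$date_b)
      tibble::tibble(A = A, B = B, x = x, n = n,
                     binom_p = if (n >= 1) {
                       binomial_ordering_test(x, n)
                     } else {
                       NA_real_
                     })
    })
    surv <- dplyr::left_join(surv, ord, by = c("A", "B"))
    surv$kept <- !is.na(surv$binom_p) & surv$binom_p < thr2 &
      surv$x / surv$n > 0.5
  } else {
    surv$x <- integer(0); surv$n <- integer(0)
    surv$binom_p <- numeric(0); surv$kept <- logical(0)
  }

  fu_map <- setNames(followup$fu_years, followup$patient_id)
  arcs <- surv[surv$kept, , drop = FALSE]
  if (nrow(arcs) > 0) {
    arcs$median_interval <- purrr::pmap_dbl(
      arcs[, c("A", "B")], function(A, B) {
        dd <- .dual_dates(events, A, B)
        dd <- dd[dd$date_a < dd$date_b, ]
        dd <- dd[fu_map[dd$patient_id] > min_followup_years, ]
        if (nrow(dd) == 0) return(NA_real_)
        median(as.numeric(dd$date_b - dd$date_a)) / 365.25
      })
    arcs$time_bin <- time_bin(arcs$median_interval)
  } else {
    arcs$median_interval <- numeric(0)
    arcs$time_bin <- integer(0)
  }
  arc_tbl <- tibble::tibble(
    first = arcs$A, second = arcs$B, beta1 = arcs$beta1,
    beta1_p = arcs$beta1_p, x = arcs$x, n = arcs$n,
    binom_p = arcs$binom_p, median_interval = arcs$median_interval,
    time_bin = arcs$time_bin)

  node_codes <- sort(unique(c(arc_tbl$first, arc_tbl$second)))
  n_cohort <- nrow(patients)
  prev_count <- events |>
    dplyr::filter(.data$phenocode %in% node_codes) |>
    dplyr::count(.data$phenocode, name = "P")
  # a death attributes to D when D or any descendant of D is a recorded cause
  cod_expanded <- lapply(patients$cod_phenocodes, function(cds) {
    unique(unlist(lapply(cds, function(cd) c(cd, phenocode_ancestors(cd)))))
  })
  deaths <- vapply(node_codes, function(cd) {
    sum(vapply(cod_expanded, function(s) cd %in% s, logical(1)))
  }, numeric(1))

  meta_cols <- sub_phenet$nodes[match(node_codes,
                                      sub_phenet$nodes$phenocode), ]
  nodes <- tibble::tibble(
    phenocode = node_codes,
    description = meta_cols$description,
    category = meta_cols$category,
    level = .level_lenient(node_codes),
    prevalence_n = prev_count$P[match(node_codes, prev_count$phenocode)],
    prevalence = prev_count$P[match(node_codes, prev_count$phenocode)] /
      n_cohort,
    mortality = deaths /
      prev_count$P[match(node_codes, prev_count$phenocode)],
    sink = !(node_codes %in% arc_tbl$first)
  )
  if (any(nodes$mortality > 1, na.rm = TRUE)) {
    message(sum(nodes$mortality > 1, na.rm = TRUE),
            " disease(s) with mortality rate > 1 ",
            "(deaths recorded without prior clinical record)")
  }
  if (nrow(nodes) > 0) {
    g <- igraph::graph_from_data_frame(
      arc_tbl[, c("first", "second")], directed = TRUE,
      vertices = nodes$phenocode)
    comp <- igraph::components(g, mode = "weak")
    nodes$component <- unname(comp$membership[nodes$phenocode])
    giant <- which.max(comp$csize)
    nodes$in_giant <- nodes$component == giant
  } else {
    nodes$component <- integer(0)
    nodes$in_giant <- logical(0)
  }

  structure(list(nodes = nodes, arcs = arc_tbl, pair_stats = surv,
                 fits = fits),
            n_fitted = n_fitted, n_step1 = n_step1,
            n_cohort = n_cohort, class = "directed_phenet")
}

#' @export
print.directed_phenet <- function(x, ...) {
  cat("<directed_phenet> ", nrow(x$nodes), " diseases, ", nrow(x$arcs),
      " directed pairs (", attr(x, "n_fitted"), " models fitted, ",
      attr(x, "n_step1"), " step-1 survivors)\n", sep = "")
  invisible(x)
}

#' @export
as_igraph.directed_phenet <- function(x) {
  igraph::graph_from_data_frame(
    data.frame(from = x$arcs$first, to = x$arcs$second,
               weight = x$arcs$median_interval),
    directed = TRUE,
    vertices = as.data.frame(x$nodes[, c("phenocode", "category", "level",
                                         "prevalence", "mortality",
                                         "sink")]))
}

#' @export
as_edgelist_table.directed_phenet <- function(x, schema) {
  if (schema == "trajectory_nodes") {
    tibble::tibble(
      Phenocode = x$nodes$phenocode,
      Disease = x$nodes$description,
      Prev = x$nodes$prevalence,
      Dprev = x$nodes$mortality,
      Category = x$nodes$category,
      Sink = as.integer(x$nodes$sink),
      Level = as.integer(x$nodes$level))
  } else {
    tibble::tibble(
      First = x$arcs$first,
      Second = x$arcs$second,
      MedianTime = x$arcs$median_interval,
      Time = as.integer(x$arcs$time_bin))
  }
}

#' @rdname tidy.phenet
#' @export
tidy.directed_phenet <- function(x, ...) x$arcs

#' @rdname tidy.phenet
#' @export
glance.directed_phenet <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_arcs = nrow(x$arcs),
    n_fitted = attr(x, "n_fitted"),
    n_step1 = attr(x, "n_step1"),
    n_sinks = sum(x$nodes$sink),
    giant_size = if (nrow(x$nodes) > 0) sum(x$nodes$in_giant) else 0L
  )
}
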