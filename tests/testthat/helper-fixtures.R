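# fixture builders shared across test files; everything is generated in code

# a phenet-like object from an edge list and node categories
toy_network <- function(edges, categories, weights = NULL) {
  codes <- names(categories)
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  links <- tibble::tibble(
    code_a = pmin(edges[[1]], edges[[2]]),
    code_b = pmax(edges[[1]], edges[[2]]),
    n_shared = 1L,
    beta_weight = weights,
    shared_units = replicate(nrow(edges), "u", simplify = FALSE)
  )
  nodes <- tibble::tibble(
    phenocode = codes,
    description = paste("Disease", codes),
    category = unname(categories),
    level = ifelse(grepl("\\.", codes),
                   nchar(sub(".*\\.", "", codes)), 0L),
    n_units = 1L
  )
  structure(list(nodes = nodes, links = links),
            weight_measure = "beta", class = "phenet")
}

# association tibble from compact row specs
toy_associations <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(snp_id = r[[1]], chrom = as.character(r[[2]]),
                   pos = as.integer(r[[3]]), phenocode = r[[4]],
                   beta = as.numeric(r[[5]]),
                   pval = 1e-8, maf = 0.1)
  }))
}

toy_ld <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(snp1 = r[[1]], snp2 = r[[2]], r2 = as.numeric(r[[3]]))
  }))
}

# brute-force single-linkage grouping of SNPs: start from qualifying pairs
# and iterate merges until a fixed point (independent of the igraph path)
brute_force_blocks <- function(snps, ld, r2_min = 0.8, max_dist = 500000) {
  qualifying <- list()
  for (i in seq_len(nrow(ld))) {
    s1 <- ld$snp1[i]; s2 <- ld$snp2[i]
    r1 <- snps[snps$snp_id == s1, ]; r2row <- snps[snps$snp_id == s2, ]
    if (nrow(r1) == 0 || nrow(r2row) == 0) next
    if (ld$r2[i] >= r2_min && r1$chrom == r2row$chrom &&
        abs(r1$pos - r2row$pos) <= max_dist) {
      qualifying[[length(qualifying) + 1]] <- c(s1, s2)
    }
  }
  groups <- lapply(snps$snp_id, function(s) s)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (pr in qualifying) {
      gi <- which(vapply(groups, function(g) pr[1] %in% g, logical(1)))
      gj <- which(vapply(groups, function(g) pr[2] %in% g, logical(1)))
      if (gi != gj) {
        groups[[gi]] <- sort(union(groups[[gi]], groups[[gj]]))
        groups[[gj]] <- NULL
        changed <- TRUE
      }
    }
  }
  lapply(groups, sort)
}

# direct double-sum evaluation of weighted modularity
brute_force_modularity <- function(adj, membership) {
  n <- nrow(adj)
  two_m <- sum(adj)
  k <- rowSums(adj)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + adj[i, j] - k[i] * k[j] / two_m
      }
    }
  }
  unname(q / two_m)
}

# explicit hypergeometric upper-tail enumeration via log-binomials
enumerate_fisher_tail <- function(C, P_i, P_j, N) {
  ks <- C:min(P_i, P_j)
  sum(exp(lchoose(P_i, ks) + lchoose(N - P_i, P_j - ks) - lchoose(N, P_j)))
}

# exact binomial upper tail by term-wise enumeration
enumerate_binom_tail <- function(x, n, p = 0.5) {
  ks <- x:n
  sum(choose(n, ks) * p^ks * (1 - p)^(n - ks))
}

# the standard recovery fixture: flat hierarchy so orderings are not
# diluted by ancestor-date expansion; planted genetic links, comorbidity
# and temporal orderings on overlapping pairs
recovery_config <- function(seed, n_patients = 5000) {
  sim_config(
    n_diseases = 10, hierarchy_depth = 0, n_snps = 120,
    n_patients = n_patients,
    baseline_prevalences = 0.08,
    planted_ld_blocks = list(
      list(n_snps = 3, max_span = 4e5, r2_range = c(0.85, 0.95))),
    planted_shared_pairs = list(
      list(a = "101", b = "102", n_shared = 3, beta_range = c(0.2, 0.6)),
      list(a = "103", b = "104", n_shared = 1, beta_range = c(0.2, 0.6)),
      list(a = "105", b = "106", n_shared = 2, beta_range = c(0.2, 0.6))),
    planted_comorbidity = list(
      list(a = "101", b = "102", rr = 4),
      list(a = "103", b = "104", rr = 4),
      list(a = "105", b = "106", rr = 3)),
    planted_orderings = list(
      list(a = "101", b = "102", p_first = 0.95, median_years = 2,
           sdlog = 0.5),
      list(a = "103", b = "104", p_first = 0.95, median_years = 4,
           sdlog = 0.5)),
    seed = seed)
}

# run the full pipeline on a simulated study; returns all intermediates
run_pipeline <- function(study, n_reps = 0, seed = 1L) {
  units <- build_ld_blocks(study$associations, study$ld)$units
  net <- build_phenet(study$associations, units, study$meta)
  universe <- unique(c(study$meta$phenocode,
                       unlist(lapply(study$meta$phenocode,
                                     phenocode_ancestors))))
  events <- expand_hierarchy(study$events, universe)
  stats <- comorbidity_stats(events, nrow(study$patients))
  sub <- extract_sub_phenet(net, stats)
  list(net = net, events = events, stats = stats, sub = sub)
}

# age-confound fixture: disease B's per-event hazard rises log-linearly
# with age and is independent of A given age; A simply has a young onset.
# Non-carriers receive a placebo early diagnosis with the same onset
# distribution so carrier and non-carrier event streams are identically
# distributed: the age-adjusted linear-logit model is then exactly null in
# the prior-A term, while omitting age leaves prior_A to soak up the
# shared age trend.
confounded_cohort <- function(n_patients, seed) {
  set.seed(seed)
  rows <- list()
  pts <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%05d", i)
    birth <- as.Date("1987-08-01") - round(runif(1, 28, 35) * 365.25)
    pts[[i]] <- tibble::tibble(patient_id = pid, sex = rbinom(1, 1, 0.5),
                               birth_date = birth,
                               death_date = as.Date(NA),
                               cod_phenocodes = list(character(0)))
    has_a <- runif(1) < 0.6
    a_age <- rnorm(1, 40, 5)
    ev_ages <- sort(c(a_age, seq(36, 64, by = 4) + runif(8, -1, 1)))
    # every event, including the onset slot, is an honest hazard trial for
    # B; the first non-B label at the onset age is A (or the placebo)
    b_hit <- runif(length(ev_ages)) < stats::plogis(-7 + 0.1 * ev_ages)
    codes <- sprintf("X%d", seq_along(ev_ages))
    codes[ev_ages == a_age] <- if (has_a) "A" else "X0"
    codes[b_hit] <- "B"
    first_b <- which(b_hit)[1]
    if (!is.na(first_b)) {
      ev_ages <- ev_ages[seq_len(first_b)]
      codes <- codes[seq_len(first_b)]
    }
    keep <- !duplicated(codes)
    rows[[i]] <- tibble::tibble(
      patient_id = pid, phenocode = codes[keep],
      date = birth + round(ev_ages[keep] * 365.25))
  }
  list(events = dplyr::bind_rows(rows), patients = dplyr::bind_rows(pts))
}

expect_pair_set_equal <- function(got_a, got_b, want_a, want_b) {
  got <- sort(paste(pmin(got_a, got_b), pmax(got_a, got_b)))
  want <- sort(paste(pmin(want_a, want_b), pmax(want_a, want_b)))
  expect_identical(got, want)
}
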