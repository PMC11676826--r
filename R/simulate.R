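#' Simulation configuration
#'
#' Defines the study conditions for the synthetic generators: a hierarchy
#' of phenocodes with categories, a SNP panel with optional planted LD
#' blocks, planted shared-locus disease pairs (the genetic ground truth),
#' and a cohort with planted comorbidity relative risks, planted temporal
#' orderings, age/sex structure and deaths. All generators are pure
#' functions of the configuration (including its `seed`).
#'
#' @param n_diseases number of phenocodes to simulate.
#' @param n_categories number of disease categories (default 17, the full
#'   phenocode category system).
#' @param hierarchy_depth 0, 1 or 2: phenocode levels generated. Codes are
#'   built in families (root, root.1, root.11) so ancestor relations are
#'   realistic.
#' @param n_snps size of the SNP panel.
#' @param planted_shared_pairs list of `list(a=, b=, n_shared=,
#'   beta_range=c(lo, hi))`: disease pairs that must share `n_shared`
#'   SNP/LD-block units with association effect sizes drawn from
#'   `beta_range` (random sign).
#' @param planted_ld_blocks list of `list(n_snps=, max_span=,
#'   r2_range=c(lo, hi))` with `r2_range` within \[0.8, 1\] and `max_span`
#'   in base pairs; blocks are consumed as shared units before bare SNPs.
#' @param decoy_shared_pairs list of `c(a, b)` pairs given one shared SNP
#'   *not* recorded in the truth (off by default; without decoys,
#'   non-planted pairs share no SNP).
#' @param n_private_snps private (unshared) significant SNPs per disease.
#' @param n_patients cohort size.
#' @param baseline_prevalences named numeric vector of per-disease
#'   prevalence targets; unnamed scalar recycles to all diseases
#'   (default 0.08).
#' @param planted_comorbidity list of `list(a=, b=, rr=)`: relative risk
#'   of disease `b` given `a` (conditional Bernoulli,
#'   `P(b|a) = min(1, rr * P(b))`, `P(b|not a) = P(b)`); `rr >= 1`, and
#'   each disease may appear as `b` in at most one pair.
#' @param planted_orderings list of `list(a=, b=, p_first=,
#'   median_years=, sdlog=)`: among dual-diagnosed patients, `a` precedes
#'   `b` with probability `p_first` and the inter-event gap is log-normal
#'   with the given median (years) and spread; gaps are strictly positive
#'   so ties cannot occur in planted pairs.
#' @param window_start,window_end observation window (ISO dates); defaults
#'   1987-08-01 to 2017-06-30.
#' @param age_range_at_start range of patient ages (years) at the start of
#'   the observation window; births are uniform over it. Default
#'   `c(25, 75)`, an adult population.
#' @param death_rates named numeric vector: probability that a diagnosed
#'   patient's death is attributed to the disease.
#' @param death_without_record named numeric vector: probability that an
#'   *undiagnosed* patient dies with the disease as recorded cause (lets
#'   mortality rates exceed 1, as death may precede any clinical record).
#' @param age_effects named list `code -> c(mean, sd)` of age-of-onset
#'   (years); when set, that disease's event dates are drawn from the
#'   patient's birth date plus a normal onset age instead of uniformly
#'   over the window. Off by default.
#' @param sex_effects named numeric vector: prevalence multiplier applied
#'   for patients with `sex == 1`. Off by default.
#' @param seed integer master seed.
#' @return a validated `sim_config` object (a list).
#' @export
sim_config <- function(n_diseases = 12, n_categories = 17,
                       hierarchy_depth = 2, n_snps = 200,
                       planted_shared_pairs = list(),
                       planted_ld_blocks = list(),
                       decoy_shared_pairs = list(),
                       n_private_snps = 2,
                       n_patients = 2000,
                       baseline_prevalences = 0.08,
                       planted_comorbidity = list(),
                       planted_orderings = list(),
                       window_start = "1987-08-01",
                       window_end = "2017-06-30",
                       age_range_at_start = c(25, 75),
                       death_rates = numeric(0),
                       death_without_record = numeric(0),
                       age_effects = list(),
                       sex_effects = numeric(0),
                       seed = 1L) {
  stopifnot(n_diseases >= 1, n_categories >= 2,
            hierarchy_depth %in% 0:2, n_snps >= 1, n_patients >= 1)
  cfg <- list(
    n_diseases = as.integer(n_diseases),
    n_categories = as.integer(n_categories),
    hierarchy_depth = as.integer(hierarchy_depth),
    n_snps = as.integer(n_snps),
    planted_shared_pairs = planted_shared_pairs,
    planted_ld_blocks = planted_ld_blocks,
    decoy_shared_pairs = decoy_shared_pairs,
    n_private_snps = as.integer(n_private_snps),
    n_patients = as.integer(n_patients),
    baseline_prevalences = baseline_prevalences,
    planted_comorbidity = planted_comorbidity,
    planted_orderings = planted_orderings,
    window_start = as.Date(window_start),
    window_end = as.Date(window_end),
    age_range_at_start = age_range_at_start,
    death_rates = death_rates,
    death_without_record = death_without_record,
    age_effects = age_effects,
    sex_effects = sex_effects,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  .validate_sim_config(cfg)
  cfg
}

.validate_sim_config <- function(cfg) {
  codes <- .sim_disease_codes(cfg)
  prev <- .sim_prevalences(cfg, codes)
  if (any(prev < 0 | prev > 1)) {
    stop("config error: baseline prevalences must be in [0, 1]",
         call. = FALSE)
  }
  for (b in cfg$planted_ld_blocks) {
    stopifnot(b$n_snps >= 2, b$max_span > 0)
    if (b$r2_range[1] < 0.8 || b$r2_range[2] > 1) {
      stop("config error: planted LD-block r2 range must lie in [0.8, 1]",
           call. = FALSE)
    }
  }
  n_block_units <- length(cfg$planted_ld_blocks)
  n_block_snps <- sum(vapply(cfg$planted_ld_blocks, function(b) b$n_snps,
                             numeric(1)))
  n_shared <- sum(vapply(cfg$planted_shared_pairs,
                         function(p) p$n_shared, numeric(1)))
  need_singletons <- max(0, n_shared - n_block_units) +
    length(cfg$decoy_shared_pairs) + cfg$n_diseases * cfg$n_private_snps
  if (n_block_snps + need_singletons > cfg$n_snps) {
    stop("config error: requested shared/private loci exceed n_snps",
         call. = FALSE)
  }
  for (p in cfg$planted_shared_pairs) {
    stopifnot(all(c(p$a, p$b) %in% codes), p$n_shared >= 1)
  }
  b_codes <- character(0)
  for (p in cfg$planted_comorbidity) {
    stopifnot(all(c(p$a, p$b) %in% codes))
    if (p$rr < 1) {
      stop("config error: planted relative risks must be >= 1",
           call. = FALSE)
    }
    if (p$rr * prev[[p$b]] > 1) {
      stop("config error: infeasible prevalence, RR pushes P(", p$b,
           " | ", p$a, ") above 1", call. = FALSE)
    }
    if (p$b %in% b_codes) {
      stop("config error: disease ", p$b,
           " conditioned on in more than one comorbidity pair",
           call. = FALSE)
    }
    b_codes <- c(b_codes, p$b)
  }
  ord_codes <- character(0)
  for (p in cfg$planted_orderings) {
    stopifnot(all(c(p$a, p$b) %in% codes),
              p$p_first >= 0, p$p_first <= 1, p$median_years > 0,
              p$sdlog >= 0)
    if (any(c(p$a, p$b) %in% ord_codes)) {
      stop("config error: disease in more than one planted ordering",
           call. = FALSE)
    }
    ord_codes <- c(ord_codes, p$a, p$b)
  }
  invisible(cfg)
}

# the 17 phenocode disease categories
.phenocode_categories <- c(
  "circulatory system", "congenital anomalies", "dermatologic",
  "digestive", "endocrine/metabolic", "genitourinary", "hematopoietic",
  "infectious diseases", "injuries & poisonings", "mental disorders",
  "musculoskeletal", "neoplasms", "neurological", "pregnancy complications",
  "respiratory", "sense organs", "symptoms")

# deterministic code layout: families (root, root.1, root.11) truncated to
# hierarchy_depth, concatenated until n_diseases codes exist
.sim_disease_codes <- function(cfg) {
  fam_size <- cfg$hierarchy_depth + 1L
  n_fam <- ceiling(cfg$n_diseases / fam_size)
  codes <- unlist(lapply(seq_len(n_fam), function(k) {
    root <- as.character(100 + k)
    c(root, paste0(root, ".1"), paste0(root, ".11"))[seq_len(fam_size)]
  }))
  codes[seq_len(cfg$n_diseases)]
}

.sim_prevalences <- function(cfg, codes) {
  bp <- cfg$baseline_prevalences
  if (is.null(names(bp)) && length(bp) == 1) {
    bp <- setNames(rep(bp, length(codes)), codes)
  }
  if (!all(codes %in% names(bp))) {
    bp <- setNames(rep(unname(bp)[1], length(codes)), codes)
  }
  bp[codes]
}

#' Phenocode metadata for a simulation
#'
#' Categories cycle over the category system by code family, so codes and
#' their ancestors share a category (each code still carries its own row).
#'
#' @param config a [sim_config()] object.
#' @return metadata tibble (`phenocode`, `description`, `category`,
#'   `level`).
#' @export
simulate_phenocode_meta <- function(config) {
  codes <- .sim_disease_codes(config)
  roots <- vapply(codes, function(cd) {
    anc <- phenocode_ancestors(cd)
    if (length(anc) > 0) anc[[length(anc)]] else cd
  }, character(1))
  cats <- .phenocode_categories[seq_len(config$n_categories)]
  root_ids <- match(roots, unique(roots))
  tibble::tibble(
    phenocode = codes,
    description = paste("Disease", codes),
    category = cats[(root_ids - 1L) %% length(cats) + 1L],
    level = phenocode_level(codes)
  )
}

# SNP panel layout: planted blocks first (each on its own well-separated
# region), then isolated singletons >= 1 Mb apart; deterministic given seed
.sim_genome <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- as.character(1:22)
  blocks <- list()
  snp_rows <- list()
  idx <- 0L
  for (k in seq_along(cfg$planted_ld_blocks)) {
    b <- cfg$planted_ld_blocks[[k]]
    chrom <- chroms[(k - 1L) %% 22L + 1L]
    base <- 1e6 + (ceiling(k / 22) - 1) * 2e7 + 5e6
    nb <- b$n_snps
    span <- min(b$max_span, 4e5 * (nb - 1))
    pos <- round(base + seq(0, span, length.out = nb))
    ids <- sprintf("rs%04d", idx + seq_len(nb))
    idx <- idx + nb
    snp_rows[[length(snp_rows) + 1L]] <-
      tibble::tibble(snp_id = ids, chrom = chrom, pos = as.integer(pos))
    blocks[[k]] <- list(snp_ids = ids, chrom = chrom,
                        r2_range = b$r2_range)
  }
  n_left <- cfg$n_snps - idx
  if (n_left > 0) {
    ids <- sprintf("rs%04d", idx + seq_len(n_left))
    chrom <- chroms[seq_len(n_left) %% 22L + 1L]
    pos <- as.integer(1e8 + (seq_len(n_left)) * 2e6)
    snp_rows[[length(snp_rows) + 1L]] <-
      tibble::tibble(snp_id = ids, chrom = chrom, pos = pos)
  }
  list(snps = dplyr::bind_rows(snp_rows), blocks = blocks)
}

#' Simulate PheWAS summary statistics with planted shared loci
#'
#' Every planted shared pair receives exactly the requested number of
#' shared units (planted LD blocks are consumed first, then bare SNPs);
#' each disease additionally receives private significant SNPs. All rows
#' satisfy `pval < 1e-6` and `maf >= 0.001`. Deterministic given the
#' configuration.
#'
#' @param config a [sim_config()] object.
#' @return list with `associations` (tibble in [read_summary_stats()]
#'   layout), `meta` (phenocode metadata) and `truth`: `shared_pairs`
#'   (tibble `code_a`, `code_b`, `n_shared`, `units` list-column),
#'   `disease_units` (tibble `phenocode`, `unit_id`) and `blocks`.
#' @export
simulate_summary_stats <- function(config) {
  genome <- .sim_genome(config)
  set.seed(config$seed + 1L)
  meta <- simulate_phenocode_meta(config)
  codes <- meta$phenocode

  free_blocks <- seq_along(genome$blocks)
  block_snps <- unlist(lapply(genome$blocks, function(b) b$snp_ids))
  free_snps <- setdiff(genome$snps$snp_id, block_snps)

  rows <- list()
  truth_pairs <- list()
  truth_units <- list()
  add_assoc <- function(snp, code, beta_range) {
    beta <- runif(1, beta_range[1], beta_range[2]) * sample(c(-1, 1), 1)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      snp_id = snp, phenocode = code, beta = beta,
      pval = 10^-runif(1, 7, 15), maf = runif(1, 0.05, 0.5))
  }

  for (p in config$planted_shared_pairs) {
    units <- character(0)
    for (i in seq_len(p$n_shared)) {
      if (length(free_blocks) > 0) {
        bi <- free_blocks[[1]]
        free_blocks <- free_blocks[-1]
        blk <- genome$blocks[[bi]]
        unit_name <- paste0("planted_block_", bi)
        # disease a hits up to two members, disease b hits the last member
        n_a <- min(2L, length(blk$snp_ids))
        for (s in blk$snp_ids[seq_len(n_a)]) add_assoc(s, p$a, p$beta_range)
        add_assoc(blk$snp_ids[[length(blk$snp_ids)]], p$b, p$beta_range)
        units <- c(units, unit_name)
      } else {
        snp <- free_snps[[1]]
        free_snps <- free_snps[-1]
        add_assoc(snp, p$a, p$beta_range)
        add_assoc(snp, p$b, p$beta_range)
        units <- c(units, snp)
      }
    }
    key <- sort(c(p$a, p$b))
    truth_pairs[[length(truth_pairs) + 1L]] <- tibble::tibble(
      code_a = key[1], code_b = key[2], n_shared = p$n_shared,
      units = list(sort(units)))
    truth_units[[length(truth_units) + 1L]] <- tibble::tibble(
      phenocode = rep(c(p$a, p$b), each = length(units)),
      unit_id = rep(units, 2))
  }

  for (d in config$decoy_shared_pairs) {
    snp <- free_snps[[1]]
    free_snps <- free_snps[-1]
    add_assoc(snp, d[[1]], c(0.05, 0.3))
    add_assoc(snp, d[[2]], c(0.05, 0.3))
  }

  for (code in codes) {
    for (i in seq_len(config$n_private_snps)) {
      if (length(free_snps) == 0) break
      snp <- free_snps[[1]]
      free_snps <- free_snps[-1]
      add_assoc(snp, code, c(0.05, 0.5))
    }
  }

  assoc <- dplyr::bind_rows(rows) |>
    dplyr::inner_join(genome$snps, by = "snp_id") |>
    dplyr::select("snp_id", "chrom", "pos", "phenocode", "beta", "pval",
                  "maf") |>
    dplyr::arrange(.data$snp_id, .data$phenocode)

  truth <- list(
    shared_pairs = if (length(truth_pairs) > 0) {
      dplyr::bind_rows(truth_pairs) |>
        dplyr::arrange(.data$code_a, .data$code_b)
    } else {
      tibble::tibble(code_a = character(), code_b = character(),
                     n_shared = integer(), units = list())
    },
    disease_units = if (length(truth_units) > 0) {
      dplyr::bind_rows(truth_units) |> dplyr::distinct()
    } else {
      tibble::tibble(phenocode = character(), unit_id = character())
    },
    blocks = genome$blocks
  )
  list(associations = assoc, meta = meta, truth = truth)
}

#' Simulate a long-format pairwise LD table
#'
#' Emits one row per SNP pair inside each planted LD block, with r-squared
#' drawn from the block's configured range; no cross-block or singleton
#' rows are produced (absent pairs mean r-squared 0). Consecutive members
#' of a block are at most 500 kb apart by construction.
#'
#' @param config a [sim_config()] object.
#' @return tibble with `snp1`, `snp2`, `r2` (each unordered pair emitted
#'   once; lookups should be symmetric).
#' @export
simulate_ld_r2 <- function(config) {
  genome <- .sim_genome(config)
  set.seed(config$seed + 2L)
  rows <- lapply(genome$blocks, function(blk) {
    prs <- utils::combn(sort(blk$snp_ids), 2)
    tibble::tibble(snp1 = prs[1, ], snp2 = prs[2, ],
                   r2 = runif(ncol(prs), blk$r2_range[1], blk$r2_range[2]))
  })
  if (length(rows) == 0) {
    return(tibble::tibble(snp1 = character(), snp2 = character(),
                          r2 = double()))
  }
  dplyr::bind_rows(rows)
}

#' Simulate a patient cohort with planted comorbidity and orderings
#'
#' Disease status is drawn per patient: baseline Bernoulli prevalence,
#' overridden for planted comorbid pairs by the conditional rule
#' `P(b | a) = min(1, rr * P(b))`. First-diagnosis dates are uniform over
#' the observation window (or normal age-of-onset when `age_effects` is
#' set); for dual-diagnosed patients of a planted ordering the order is a
#' Bernoulli draw and the inter-event gap log-normal and strictly
#' positive. Deaths are attributed per `death_rates` (and
#' `death_without_record` for deaths preceding any clinical record).
#'
#' @param config a [sim_config()] object.
#' @return list with `patients` (tibble `patient_id`, `sex`, `birth_date`,
#'   `death_date`, `cod_phenocodes` list-column), `events` (tibble
#'   `patient_id`, `phenocode`, `date`) and `truth` (`comorbidity` and
#'   `orderings` tibbles plus target `prevalence`).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed + 3L)
  meta <- simulate_phenocode_meta(config)
  codes <- meta$phenocode
  n <- config$n_patients
  prev <- .sim_prevalences(config, codes)
  window_days <- as.numeric(config$window_end - config$window_start)

  patients <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    sex = rbinom(n, 1, 0.5),
    birth_date = config$window_start -
      round(runif(n, config$age_range_at_start[1],
                  config$age_range_at_start[2]) * 365.25)
  )

  # disease indicator matrix: baseline, then conditional-Bernoulli planting
  has <- matrix(FALSE, nrow = n, ncol = length(codes),
                dimnames = list(NULL, codes))
  cond_on <- vapply(config$planted_comorbidity, function(p) p$b,
                    character(1))
  for (cd in codes) {
    p_cd <- rep(prev[[cd]], n)
    if (cd %in% names(config$sex_effects)) {
      p_cd <- pmin(1, p_cd * ifelse(patients$sex == 1,
                                    config$sex_effects[[cd]], 1))
    }
    if (!cd %in% cond_on) has[, cd] <- runif(n) < p_cd
  }
  for (p in config$planted_comorbidity) {
    p_b <- rep(prev[[p$b]], n)
    if (p$b %in% names(config$sex_effects)) {
      p_b <- pmin(1, p_b * ifelse(patients$sex == 1,
                                  config$sex_effects[[p$b]], 1))
    }
    p_draw <- ifelse(has[, p$a], pmin(1, p$rr * p_b), p_b)
    has[, p$b] <- runif(n) < p_draw
  }

  # first-diagnosis dates
  date_mat <- matrix(NA_real_, nrow = n, ncol = length(codes),
                     dimnames = list(NULL, codes))
  for (cd in codes) {
    idx <- which(has[, cd])
    if (length(idx) == 0) next
    if (cd %in% names(config$age_effects)) {
      ae <- config$age_effects[[cd]]
      age_days <- rnorm(length(idx), ae[1], ae[2]) * 365.25
      d <- as.numeric(patients$birth_date[idx] - config$window_start) +
        age_days
      d <- pmin(pmax(d, 0), window_days)
    } else {
      d <- runif(length(idx), 0, window_days)
    }
    date_mat[idx, cd] <- d
  }

  # planted orderings override dates of dual-diagnosed patients
  for (p in config$planted_orderings) {
    dual <- which(has[, p$a] & has[, p$b])
    if (length(dual) == 0) next
    a_first <- runif(length(dual)) < p$p_first
    gap <- rlnorm(length(dual), log(p$median_years), p$sdlog) * 365.25
    gap <- pmin(pmax(gap, 1), 0.95 * window_days)
    start <- runif(length(dual), 0, window_days - gap)
    first_cd <- ifelse(a_first, p$a, p$b)
    second_cd <- ifelse(a_first, p$b, p$a)
    for (i in seq_along(dual)) {
      date_mat[dual[i], first_cd[i]] <- start[i]
      date_mat[dual[i], second_cd[i]] <- start[i] + gap[i]
    }
  }

  ev_idx <- which(!is.na(date_mat), arr.ind = TRUE)
  events <- tibble::tibble(
    patient_id = patients$patient_id[ev_idx[, 1]],
    phenocode = codes[ev_idx[, 2]],
    date = config$window_start + round(date_mat[ev_idx])
  ) |>
    dplyr::arrange(.data$patient_id, .data$date, .data$phenocode)

  # deaths attributed to diagnosed diseases
  death_date <- rep(as.Date(NA), n)
  cod <- vector("list", n)
  for (i in seq_len(n)) cod[[i]] <- character(0)
  for (cd in names(config$death_rates)) {
    idx <- which(has[, cd])
    hit <- idx[runif(length(idx)) < config$death_rates[[cd]]]
    for (i in hit) cod[[i]] <- c(cod[[i]], cd)
  }
  for (cd in names(config$death_without_record)) {
    idx <- which(!has[, cd])
    hit <- idx[runif(length(idx)) < config$death_without_record[[cd]]]
    for (i in hit) cod[[i]] <- c(cod[[i]], cd)
  }
  died <- which(lengths(cod) > 0)
  if (length(died) > 0) {
    last_ev <- vapply(died, function(i) {
      d <- date_mat[i, ]
      if (all(is.na(d))) window_days / 2 else max(d, na.rm = TRUE)
    }, numeric(1))
    death_date[died] <- config$window_start +
      round(last_ev + stats::rexp(length(died), 1 / 730))
  }
  patients$death_date <- death_date
  patients$cod_phenocodes <- cod

  truth <- list(
    comorbidity = dplyr::bind_rows(lapply(config$planted_comorbidity,
      function(p) tibble::tibble(code_a = p$a, code_b = p$b, rr = p$rr))),
    orderings = dplyr::bind_rows(lapply(config$planted_orderings,
      function(p) tibble::tibble(first = p$a, second = p$b,
                                 p_first = p$p_first,
                                 median_years = p$median_years,
                                 sdlog = p$sdlog))),
    prevalence = tibble::tibble(phenocode = codes, target = unname(prev))
  )
  list(patients = patients, events = events, truth = truth)
}

#' Run every generator of a configuration
#'
#' @param config a [sim_config()] object.
#' @return list with `associations`, `ld`, `meta`, `patients`, `events`
#'   and a merged `truth` record sufficient to score recovery of every
#'   planted edge and ordering.
#' @export
simulate_study <- function(config) {
  ss <- simulate_summary_stats(config)
  ld <- simulate_ld_r2(config)
  ch <- simulate_cohort(config)
  list(associations = ss$associations, ld = ld, meta = ss$meta,
       patients = ch$patients, events = ch$events,
       truth = c(ss$truth, ch$truth))
}

#' Write a truth record as YAML
#'
#' @param truth truth record from a generator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  ser <- lapply(truth, function(x) {
    if (inherits(x, "data.frame")) {
      lapply(seq_len(nrow(x)), function(i) {
        row <- as.list(x[i, ])
        lapply(row, function(v) if (is.list(v)) v[[1]] else v)
      })
    } else {
      x
    }
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Write simulated tables in the formats the readers consume
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    summary_stats = file.path(dir, "summary_stats.tsv"),
    ld = file.path(dir, "ld_r2.tsv"),
    meta = file.path(dir, "phenocode_meta.tsv"),
    events = file.path(dir, "events.csv"),
    patients = file.path(dir, "patients.csv"),
    truth = file.path(dir, "truth.yaml")
  )
  write.table(study$associations, paths[["summary_stats"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(study$ld, paths[["ld"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(study$meta[, c("phenocode", "description", "category")],
              paths[["meta"]], sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- study$events
  ev$date <- format(ev$date)
  write.table(ev, paths[["events"]], sep = ",", quote = FALSE,
              row.names = FALSE)
  pt <- study$patients
  pt$birth_date <- format(pt$birth_date)
  pt$death_date <- ifelse(is.na(pt$death_date), "",
                          format(pt$death_date))
  pt$cod_phenocodes <- vapply(pt$cod_phenocodes, paste, character(1),
                              collapse = ";")
  write.table(pt, paths[["patients"]], sep = ",", quote = FALSE,
              row.names = FALSE)
  write_truth_yaml(study$truth, paths[["truth"]])
  invisible(paths)
}
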