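pt_row <- function(pid, sex = 0L, birth = "1950-01-01") {
  tibble::tibble(patient_id = pid, sex = as.integer(sex),
                 birth_date = as.Date(birth),
                 death_date = as.Date(NA),
                 cod_phenocodes = list(character(0)))
}

ev <- function(pid, code, date) {
  tibble::tibble(patient_id = pid, phenocode = code, date = as.Date(date))
}

test_that("hierarchy-related pairs are excluded from direction testing", {
  net <- toy_network(
    data.frame(a = c("174", "250.1", "290.11"),
               b = c("174.1", "250.2", "411.4")),
    c(`174` = "n", `174.1` = "n", `250.1` = "e", `250.2` = "e",
      `290.11` = "m", `411.4` = "c"))
  el <- eligible_pairs(net)
  expect_pair_set_equal(el$code_a, el$code_b,
                        c("250.1", "290.11"), c("250.2", "411.4"))
})

test_that("event tables encode outcome, prior-A status and truncation", {
  pats <- pt_row("P1")
  # A then B: two rows, B row has prior_A set
  e1 <- dplyr::bind_rows(ev("P1", "A", "2000-01-01"),
                         ev("P1", "B", "2005-01-01"))
  t1 <- build_event_table(e1, pats, "A", "B")
  expect_identical(t1$outcome, c(0L, 1L))
  expect_identical(t1$prior_A, c(0L, 1L))
  expect_equal(t1$age[1], 50, tolerance = 0.01)

  # B first: rows stop at the first B event
  e2 <- dplyr::bind_rows(ev("P1", "B", "2000-01-01"),
                         ev("P1", "A", "2005-01-01"))
  t2 <- build_event_table(e2, pats, "A", "B")
  expect_identical(nrow(t2), 1L)
  expect_identical(t2$outcome, 1L)
  expect_identical(t2$prior_A, 0L)

  # background patient: all events, outcome 0, prior_A 0
  e3 <- dplyr::bind_rows(ev("P1", "X", "2000-01-01"),
                         ev("P1", "Y", "2001-01-01"),
                         ev("P1", "Z", "2002-01-01"))
  t3 <- build_event_table(e3, pats, "A", "B")
  expect_identical(nrow(t3), 3L)
  expect_true(all(t3$outcome == 0L) && all(t3$prior_A == 0L))

  # same-date A does not count as prior
  e4 <- dplyr::bind_rows(ev("P1", "A", "2000-01-01"),
                         ev("P1", "B", "2000-01-01"))
  t4 <- build_event_table(e4, pats, "A", "B")
  expect_true(all(t4$prior_A == 0L))
})

test_that("the binomial ordering test matches exact tail enumeration", {
  expect_equal(binomial_ordering_test(10, 10), 2^-10, tolerance = 1e-15)
  expect_equal(binomial_ordering_test(8, 10), 56 / 1024,
               tolerance = 1e-15)
  expect_equal(binomial_ordering_test(5, 10),
               enumerate_binom_tail(5, 10))
  expect_gt(binomial_ordering_test(5, 10), 0.5)
  set.seed(71)
  for (i in 1:30) {
    n <- sample(1:40, 1)
    x <- sample(0:n, 1)
    expect_equal(binomial_ordering_test(x, n),
                 enumerate_binom_tail(x, n), tolerance = 1e-12)
  }
  expect_error(binomial_ordering_test(0, 0), "n >= 1")
})

test_that("degenerate regression inputs are flagged inestimable", {
  pats <- pt_row("P1")
  e <- dplyr::bind_rows(ev("P1", "X", "2000-01-01"),
                        ev("P1", "B", "2001-01-01"))
  # A never occurs: constant prior_A
  t1 <- build_event_table(e, pats, "A", "B")
  f1 <- fit_direction(t1)
  expect_false(f1$estimable)
  expect_identical(f1$reason, "constant prior_A")
  # B never occurs: single-class outcome
  t2 <- build_event_table(ev("P1", "X", "2000-01-01"), pats, "A", "B")
  f2 <- fit_direction(t2)
  expect_false(f2$estimable)
  expect_identical(f2$reason, "single-class outcome")
})

test_that("the direction model recovers a planted effect and stays calibrated", {
  # consistency: data generated from the logistic model itself
  gen <- function(n, beta1) {
    prior_A <- rbinom(n, 1, 0.4)
    age <- runif(n, 30, 80)
    sex <- rbinom(n, 1, 0.5)
    eta <- -2 + beta1 * prior_A + 0.01 * age + 0.2 * sex
    tibble::tibble(patient_id = as.character(seq_len(n)), j = 1L,
                   outcome = rbinom(n, 1, plogis(eta)),
                   prior_A = prior_A, age = age, sex = sex)
  }
  set.seed(81)
  est_small <- fit_direction(gen(1000, 0.8))
  est_big <- fit_direction(gen(10000, 0.8))
  expect_true(est_small$estimable && est_big$estimable)
  expect_lt(abs(est_big$beta1 - 0.8), abs(est_small$beta1 - 0.8) + 0.1)
  expect_equal(est_big$beta1, 0.8, tolerance = 0.15)
  # Wald and LRT agree on strong effects
  lrt <- fit_direction(gen(5000, 0.8), test = "lrt")
  expect_lt(lrt$beta1_p, 1e-4)
})

test_that("age adjustment suppresses orderings driven by onset age alone", {
  ch <- confounded_cohort(3000, seed = 31)
  et <- build_event_table(ch$events, ch$patients, "A", "B")
  with_age <- fit_direction(et)
  no_age <- fit_direction(dplyr::mutate(et, age = 0))
  expect_true(with_age$estimable && no_age$estimable)
  # without the covariate the late-onset disease looks like a consequence
  expect_lt(no_age$beta1_p, 0.001)
  # with age in the model the spurious ordering disappears
  expect_gt(with_age$beta1_p, 0.05)
})

test_that("the directed network keeps planted orderings and no 2-cycles", {
  cfg <- recovery_config(seed = 37, n_patients = 5000)
  st <- simulate_study(cfg)
  pl <- run_pipeline(st)
  dn <- build_directed_network(pl$sub, pl$events, st$patients)
  # no 2-cycles by the majority rule
  fwd <- paste(dn$arcs$first, dn$arcs$second)
  rev <- paste(dn$arcs$second, dn$arcs$first)
  expect_length(intersect(fwd, rev), 0)
  # planted orderings recovered
  want <- paste(st$truth$orderings$first, st$truth$orderings$second)
  expect_true(all(want %in% fwd))
  # sink flags match out-degrees
  for (i in seq_len(nrow(dn$nodes))) {
    expect_identical(dn$nodes$sink[i],
                     !(dn$nodes$phenocode[i] %in% dn$arcs$first))
  }
  # median interval near the planted log-normal median
  mi <- dn$arcs$median_interval[fwd == want[1]]
  expect_gt(mi, 1)
  expect_lt(mi, 4)
  # schema export works end to end
  tmp <- tempfile()
  write_edgelist(dn, "trajectory_edges", tmp)
  back <- read_edgelist(tmp, "trajectory_edges")
  expect_identical(nrow(back), nrow(dn$arcs))
  tmp2 <- tempfile()
  write_edgelist(dn, "trajectory_nodes", tmp2)
  expect_identical(nrow(read_edgelist(tmp2, "trajectory_nodes")),
                   nrow(dn$nodes))
})

test_that("median intervals ignore patient order and non-carriers", {
  pats <- dplyr::bind_rows(pt_row("P1"), pt_row("P2"), pt_row("P3"))
  e <- dplyr::bind_rows(
    ev("P1", "A", "2000-01-01"), ev("P1", "B", "2003-01-01"),
    ev("P2", "A", "2001-01-01"), ev("P2", "B", "2002-01-01"),
    ev("P3", "X", "2000-01-01"))
  dd1 <- phenetwork:::.dual_dates(e, "A", "B")
  dd2 <- phenetwork:::.dual_dates(e[sample(nrow(e)), ], "A", "B")
  expect_identical(sort(dd1$patient_id), sort(dd2$patient_id))
  expect_identical(nrow(dd1), 2L)
  med <- median(as.numeric(dd1$date_b - dd1$date_a)) / 365.25
  expect_equal(med, 2, tolerance = 0.01)
})

test_that("deaths without clinical records can push mortality above one", {
  cfg <- sim_config(
    n_diseases = 4, hierarchy_depth = 0, n_snps = 40, n_patients = 3000,
    baseline_prevalences = 0.1,
    planted_shared_pairs = list(
      list(a = "101", b = "102", n_shared = 2, beta_range = c(0.3, 0.6))),
    planted_comorbidity = list(list(a = "101", b = "102", rr = 5)),
    planted_orderings = list(list(a = "101", b = "102", p_first = 0.95,
                                  median_years = 2, sdlog = 0.4)),
    death_rates = c(`102` = 0.3),
    death_without_record = c(`103` = 0.02),
    seed = 43)
  st <- simulate_study(cfg)
  pl <- run_pipeline(st)
  dn <- suppressMessages(
    build_directed_network(pl$sub, pl$events, st$patients))
  if (nrow(dn$nodes) > 0 && "102" %in% dn$nodes$phenocode) {
    mort <- dn$nodes$mortality[dn$nodes$phenocode == "102"]
    expect_gt(mort, 0.1)
    expect_lt(abs(mort - 0.3), 0.15)
  }
})
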