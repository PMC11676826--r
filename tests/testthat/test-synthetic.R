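test_that("generators are pure functions of the configuration", {
  cfg <- recovery_config(seed = 7, n_patients = 500)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$associations, s2$associations)
  expect_identical(s1$ld, s2$ld)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$patients, s2$patients)
  # a different seed changes the draw
  s3 <- simulate_study(recovery_config(seed = 8, n_patients = 500))
  expect_false(identical(s1$events, s3$events))
})

test_that("planted shared pairs surface as network links matching the truth", {
  cfg <- recovery_config(seed = 3, n_patients = 200)
  ss <- simulate_summary_stats(cfg)
  ld <- simulate_ld_r2(cfg)
  units <- build_ld_blocks(ss$associations, ld)$units
  net <- build_phenet(ss$associations, units, ss$meta)
  truth <- ss$truth$shared_pairs
  expect_pair_set_equal(net$links$code_a, net$links$code_b,
                        truth$code_a, truth$code_b)
  # shared-unit counts equal the truth-record intersection oracle
  for (i in seq_len(nrow(truth))) {
    du <- ss$truth$disease_units
    oracle_n <- length(intersect(
      du$unit_id[du$phenocode == truth$code_a[i]],
      du$unit_id[du$phenocode == truth$code_b[i]]))
    got <- net$links$n_shared[net$links$code_a == truth$code_a[i] &
                                net$links$code_b == truth$code_b[i]]
    expect_identical(as.integer(got), as.integer(oracle_n))
    expect_identical(as.integer(got), as.integer(truth$n_shared[i]))
  }
})

test_that("without planted pairs the network is empty after singleton removal", {
  cfg <- sim_config(n_diseases = 6, hierarchy_depth = 0, n_snps = 40,
                    n_patients = 100, seed = 2)
  ss <- simulate_summary_stats(cfg)
  units <- build_ld_blocks(ss$associations, simulate_ld_r2(cfg))$units
  net <- build_phenet(ss$associations, units, ss$meta)
  expect_identical(nrow(net$links), 0L)
  expect_identical(nrow(net$nodes), 0L)
})

test_that("simulated associations respect the input filters", {
  cfg <- recovery_config(seed = 5, n_patients = 100)
  ss <- simulate_summary_stats(cfg)
  expect_true(all(ss$associations$pval < 1e-6))
  expect_true(all(ss$associations$maf >= 0.001))
  expect_false(any(duplicated(
    ss$associations[, c("snp_id", "phenocode")])))
})

test_that("simulated LD structure matches the planted blocks", {
  cfg <- recovery_config(seed = 9, n_patients = 100)
  ld <- simulate_ld_r2(cfg)
  expect_true(all(ld$r2 >= 0.8 & ld$r2 <= 1))
  # 3-SNP block: all three pairwise rows present
  expect_identical(nrow(ld), 3L)
  ss <- simulate_summary_stats(cfg)
  pos <- dplyr::distinct(ss$associations, .data$snp_id, .data$chrom,
                         .data$pos)
  joined <- dplyr::inner_join(ld, pos, by = c(snp1 = "snp_id")) |>
    dplyr::inner_join(pos, by = c(snp2 = "snp_id"), suffix = c("1", "2"))
  expect_true(all(joined$chrom1 == joined$chrom2))
  expect_true(all(abs(joined$pos1 - joined$pos2) <= 2 * 500000))
})

test_that("cohort prevalences land within three binomial standard errors", {
  cfg <- sim_config(n_diseases = 6, hierarchy_depth = 0, n_snps = 40,
                    n_patients = 2000, baseline_prevalences = 0.3,
                    seed = 13)
  ch <- simulate_cohort(cfg)
  prev <- ch$events |> dplyr::count(.data$phenocode)
  se3 <- 3 * sqrt(0.3 * 0.7 / 2000)
  for (i in seq_len(nrow(prev))) {
    expect_gt(prev$n[i] / 2000, 0.3 - se3)
    expect_lt(prev$n[i] / 2000, 0.3 + se3)
  }
})

test_that("planted comorbidity lifts the conditional risk as configured", {
  cfg <- sim_config(
    n_diseases = 4, hierarchy_depth = 0, n_snps = 30, n_patients = 4000,
    baseline_prevalences = 0.1,
    planted_comorbidity = list(list(a = "101", b = "102", rr = 3)),
    seed = 17)
  ch <- simulate_cohort(cfg)
  wide <- ch$events |>
    dplyr::mutate(v = TRUE) |>
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "phenocode",
                       values_from = "v", values_fill = FALSE)
  all_ids <- ch$patients$patient_id
  hasA <- all_ids %in% wide$patient_id[wide[["101"]]]
  hasB <- all_ids %in% wide$patient_id[wide[["102"]]]
  rr_hat <- mean(hasB[hasA]) / mean(hasB[!hasA])
  expect_gt(rr_hat, 2)
  expect_lt(rr_hat, 4.5)
})

test_that("a certain planted ordering puts A strictly first in every dual case", {
  cfg <- sim_config(
    n_diseases = 4, hierarchy_depth = 0, n_snps = 30, n_patients = 1000,
    baseline_prevalences = 0.2,
    planted_comorbidity = list(list(a = "101", b = "102", rr = 2)),
    planted_orderings = list(list(a = "101", b = "102", p_first = 1,
                                  median_years = 2, sdlog = 0.5)),
    seed = 19)
  ch <- simulate_cohort(cfg)
  da <- ch$events[ch$events$phenocode == "101", c("patient_id", "date")]
  db <- ch$events[ch$events$phenocode == "102", c("patient_id", "date")]
  dd <- dplyr::inner_join(da, db, by = "patient_id",
                          suffix = c("_a", "_b"))
  expect_gt(nrow(dd), 10)
  expect_true(all(dd$date_a < dd$date_b))
})

test_that("infeasible configurations are rejected with config errors", {
  expect_error(
    sim_config(baseline_prevalences = 0.5,
               planted_comorbidity = list(list(a = "101", b = "102",
                                               rr = 3))),
    "infeasible prevalence")
  expect_error(
    sim_config(planted_comorbidity = list(list(a = "101", b = "102",
                                               rr = 0.5))),
    ">= 1")
  expect_error(
    sim_config(n_snps = 3,
               planted_shared_pairs = list(
                 list(a = "101", b = "102", n_shared = 10,
                      beta_range = c(0.1, 0.2)))),
    "exceed n_snps")
  expect_error(
    sim_config(planted_ld_blocks = list(
      list(n_snps = 3, max_span = 1e5, r2_range = c(0.5, 0.9)))),
    "r2 range")
})

test_that("truth records and study tables survive a round trip on disk", {
  cfg <- recovery_config(seed = 23, n_patients = 200)
  st <- simulate_study(cfg)
  dir <- tempfile()
  paths <- write_study(st, dir)
  back_assoc <- suppressMessages(read_summary_stats(paths[["summary_stats"]]))
  expect_identical(nrow(back_assoc), nrow(st$associations))
  back_ev <- read_events(paths[["events"]])
  expect_identical(back_ev$date, st$events$date)
  back_pt <- read_patients(paths[["patients"]])
  expect_identical(back_pt$cod_phenocodes, st$patients$cod_phenocodes)
  expect_true(file.exists(paths[["truth"]]))
  ty <- yaml::read_yaml(paths[["truth"]])
  expect_identical(length(ty$shared_pairs), nrow(st$truth$shared_pairs))
})
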