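test_that("modularity reproduces the closed-form small cases", {
  # whole graph in one module: the two terms cancel
  net <- toy_network(data.frame(a = c("A", "B"), b = c("B", "C")),
                     c(A = "x", B = "x", C = "x"))
  memb <- setNames(rep(1, 3), c("A", "B", "C"))
  expect_equal(graph_modularity(net, memb), 0)

  # two disjoint unit edges, partition by component
  net2 <- toy_network(data.frame(a = c("A", "C"), b = c("B", "D")),
                      c(A = "x", B = "x", C = "y", D = "y"))
  memb2 <- setNames(c(1, 1, 2, 2), c("A", "B", "C", "D"))
  expect_equal(graph_modularity(net2, memb2), 0.5)

  # single edge with each node its own module
  net3 <- toy_network(data.frame(a = "A", b = "B"), c(A = "x", B = "y"))
  expect_equal(graph_modularity(net3, c(A = 1, B = 2)), -0.5)

  bad <- toy_network(data.frame(a = "A", b = "B"), c(A = "x", B = "y"),
                     weights = -1)
  expect_error(graph_modularity(bad, c(A = 1, B = 1)), "negative")
})

test_that("modularity matches the brute-force double sum on random graphs", {
  set.seed(51)
  for (rep in 1:15) {
    n <- sample(5:20, 1)
    codes <- sprintf("%d", 100 + seq_len(n))
    prs <- t(combn(codes, 2))
    pick <- sample(nrow(prs), min(nrow(prs), n * 2))
    w <- runif(length(pick), 0.1, 2)
    net <- toy_network(data.frame(a = prs[pick, 1], b = prs[pick, 2]),
                       setNames(rep("x", n), codes), weights = w)
    memb <- setNames(sample(1:3, n, replace = TRUE), codes)
    adj <- matrix(0, n, n, dimnames = list(codes, codes))
    for (i in seq_along(pick)) {
      adj[prs[pick[i], 1], prs[pick[i], 2]] <- w[i]
      adj[prs[pick[i], 2], prs[pick[i], 1]] <- w[i]
    }
    expect_equal(graph_modularity(net, memb),
                 brute_force_modularity(adj, memb[codes]),
                 tolerance = 1e-12)
  }
})

test_that("Louvain separates weakly joined cliques and is deterministic", {
  clique <- function(codes) t(combn(codes, 2))
  e <- rbind(clique(c("A", "B", "C", "D")), clique(c("E", "F", "G", "H")),
             c("D", "E"))
  w <- c(rep(1, 12), 0.05)
  net <- toy_network(data.frame(a = e[, 1], b = e[, 2]),
                     setNames(rep("x", 8), LETTERS[1:8]), weights = w)
  p1 <- louvain_partition(net, seed = 3)
  p2 <- louvain_partition(net, seed = 3)
  expect_identical(p1$module, p2$module)
  m <- setNames(p1$module, p1$phenocode)
  expect_identical(length(unique(m[c("A", "B", "C", "D")])), 1L)
  expect_identical(length(unique(m[c("E", "F", "G", "H")])), 1L)
  expect_false(m[["A"]] == m[["E"]])

  # exhaustive search over all 2-block partitions confirms optimality
  best <- -Inf
  for (mask in 0:(2^8 - 1)) {
    mm <- setNames(as.integer(intToBits(mask))[1:8] + 1L, LETTERS[1:8])
    best <- max(best, graph_modularity(net, mm))
  }
  expect_gte(attr(p1, "modularity") + 1e-12, best)

  # single edge: one module, Q = 0
  net1 <- toy_network(data.frame(a = "A", b = "B"), c(A = "x", B = "y"))
  ps <- louvain_partition(net1, seed = 1)
  expect_identical(length(unique(ps$module)), 1L)
  expect_equal(attr(ps, "modularity"), 0)
})

test_that("the scaled H-score reproduces the worked examples", {
  expect_equal(round(h_score(c(12, 1), 17)$h_scaled, 2), 0.85)
  expect_equal(round(h_score(c(4, 2, 1, 1, 1, 1, 1), 17)$h_scaled, 2),
               0.13)
  expect_equal(h_score(c(9), 17)$h_scaled, 1)
  expect_equal(h_score(c(1), 17)$h_scaled, 1)  # degree-1 convention
  expect_error(h_score(c(0, 0), 17), "at least 1")
})

test_that("the scaling pins the attainable range to [0, 1] at every degree", {
  cc <- 17
  for (k in c(2, 5, 13, 17, 23, 40)) {
    # fully homogeneous neighbourhood scores exactly 1
    expect_equal(h_score(k, cc)$h_scaled, 1)
    # most even attainable split scores exactly 0
    q <- k %/% cc; r <- k %% cc
    most_even <- c(rep(q + 1, r), rep(q, cc - r))
    most_even <- most_even[most_even > 0]
    expect_equal(h_score(most_even, cc)$h_scaled, 0)
  }
  # raw score depends only on the shares; the scaled score narrows the
  # degree effect relative to the raw minimum drift
  h4 <- h_score(c(3, 1), cc)
  h8 <- h_score(c(6, 2), cc)
  expect_equal(h4$h_raw, h8$h_raw, tolerance = 1e-12)
  expect_lt(abs(h4$h_scaled - h8$h_scaled),
            abs(h4$h_min - h8$h_min) + 0.05)
})

test_that("per-node H-scores agree with direct per-node computation", {
  net <- toy_network(
    data.frame(a = c("A", "A", "A", "B"), b = c("B", "C", "D", "C")),
    c(A = "x", B = "x", C = "y", D = "z"))
  hs <- node_h_scores(net)
  # A has neighbours B(x), C(y), D(z): counts 1,1,1 at degree 3
  expect_equal(hs$h_scaled[hs$phenocode == "A"],
               h_score(c(1, 1, 1), 3)$h_scaled)
  # D has one neighbour: naturally homogeneous
  expect_equal(hs$h_scaled[hs$phenocode == "D"], 1)
  expect_identical(hs$degree, c(3L, 2L, 2L, 1L))
})

test_that("category-assortative networks beat the category-shuffle null", {
  set.seed(61)
  codes <- sprintf("%d", 101:112)
  cats <- setNames(rep(c("x", "y", "z"), each = 4), codes)
  within_edges <- do.call(rbind, lapply(split(codes, cats), function(g) {
    t(combn(g, 2))
  }))
  net <- toy_network(data.frame(a = within_edges[, 1],
                                b = within_edges[, 2]), cats)
  res <- mean_h_tests(net, "all", n_reps = 500, seed = 7)
  expect_lt(res$p_adj, 0.05)
  expect_gt(res$mean_h, res$null_mean)

  # anti-homogeneous ring cycling through the categories: every node's
  # two neighbours belong to two different other categories
  ring <- codes[as.vector(t(cbind(1:4, 5:8, 9:12)))]
  net2 <- toy_network(
    data.frame(a = ring, b = ring[c(2:12, 1)]), cats)
  res2 <- mean_h_tests(net2, "all", n_reps = 200, seed = 7)
  expect_gt(res2$p, 0.5)
})

test_that("grouped H tests cover modules and categories with Bonferroni", {
  codes <- sprintf("%d", 101:109)
  cats <- setNames(rep(c("x", "y", "z"), each = 3), codes)
  e <- rbind(t(combn(codes[1:3], 2)), t(combn(codes[4:6], 2)),
             t(combn(codes[7:9], 2)), c("103", "104"))
  net <- toy_network(data.frame(a = e[, 1], b = e[, 2]), cats)
  part <- louvain_partition(net, seed = 2)
  by_mod <- mean_h_tests(net, "module", partition = part, n_reps = 100,
                         seed = 3)
  expect_identical(nrow(by_mod), length(unique(part$module)))
  expect_true(all(by_mod$p_adj >= by_mod$p - 1e-15))
  expect_true(all(by_mod$p_adj <= 1))
  by_cat <- mean_h_tests(net, "category", n_reps = 100, seed = 3)
  expect_identical(sort(by_cat$group), c("x", "y", "z"))
})

test_that("category Z-scores conserve links and match exact enumeration", {
  codes <- c("A", "B", "C", "D", "E", "F")
  cats <- setNames(c("x", "x", "x", "y", "y", "y"), codes)
  e <- rbind(t(combn(c("A", "B", "C"), 2)), t(combn(c("D", "E", "F"), 2)))
  net <- toy_network(data.frame(a = e[, 1], b = e[, 2]), cats)
  z <- category_z_scores(net, n_reps = 2000, seed = 9)
  expect_equal(sum(z$x), nrow(net$links))
  # all links within category: positive z for self-pairs, negative across
  expect_gt(z$z[z$cat_i == "x" & z$cat_j == "x"], 0)
  expect_lt(z$z[z$cat_i == "x" & z$cat_j == "y"], 0)

  # exact enumeration over all 6! label permutations gives mu and sigma
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  xs <- vapply(all_perms(1:6), function(pm) {
    cc <- unname(cats)[pm]
    sum(cc[match(net$links$code_a, codes)] == "x" &
          cc[match(net$links$code_b, codes)] == "x")
  }, numeric(1))
  expect_equal(z$mu[z$cat_i == "x" & z$cat_j == "x"], mean(xs),
               tolerance = 0.1)
  expect_equal(z$sigma[z$cat_i == "x" & z$cat_j == "x"], sd(xs),
               tolerance = 0.1)

  # x count equal to the null mean gives z = 0 and no significance
  fake <- z
  expect_false(any(abs(fake$x - fake$mu) > 0 &
                     !is.na(fake$z) &
                     fake$z == 0))
})

test_that("H-score and Z-score nulls share the replicate stream per seed", {
  codes <- sprintf("%d", 101:108)
  cats <- setNames(rep(c("x", "y"), each = 4), codes)
  e <- t(combn(codes, 2))[sample(28, 10), ]
  net <- toy_network(data.frame(a = e[, 1], b = e[, 2]), cats)
  z1 <- category_z_scores(net, n_reps = 50, seed = 4)
  z2 <- category_z_scores(net, n_reps = 50, seed = 4)
  expect_identical(z1$mu, z2$mu)
  expect_identical(z1$sigma, z2$sigma)
})
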