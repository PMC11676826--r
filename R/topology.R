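# run code under a temporary RNG state, restoring the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.weight_column <- function(x) {
  if (identical(attr(x, "weight_measure"), "mcc")) "mcc" else "beta_weight"
}

#' Weighted Newman modularity of a partition
#'
#' Modularity compares the weight of links inside modules with the
#' expectation under the configuration model:
#' `Q = 1/(2m) * sum_ij (A_ij - k_i k_j / (2m)) * delta(c_i, c_j)`, with
#' `A` the symmetric weight matrix, `k_i` the weighted degree and
#' `m` half the total weight. `Q` lies in \[-1, 1\].
#'
#' @param x a `phenet`-like object (positive link weights required).
#' @param membership named vector mapping every node phenocode to a module
#'   id.
#' @return scalar modularity `Q`.
#' @export
graph_modularity <- function(x, membership) {
  wcol <- .weight_column(x)
  w <- x$links[[wcol]]
  if (any(w < 0)) stop("negative link weight", call. = FALSE)
  codes <- x$nodes$phenocode
  if (!all(codes %in% names(membership))) {
    stop("membership must cover every network node", call. = FALSE)
  }
  a <- x$links$code_a
  b <- x$links$code_b
  two_m <- 2 * sum(w)
  if (two_m == 0) return(0)
  deg <- setNames(numeric(length(codes)), codes)
  for (i in seq_along(w)) {
    deg[a[i]] <- deg[a[i]] + w[i]
    deg[b[i]] <- deg[b[i]] + w[i]
  }
  mods <- membership[codes]
  # within-module link weight (each undirected link counted twice in the
  # double sum) minus the expected weight over all within-module pairs
  within <- sum(w[membership[a] == membership[b]])
  expected <- sum(vapply(split(deg, mods), function(d) sum(d)^2, numeric(1)))
  (2 * within) / two_m - expected / two_m^2
}

#' Louvain module detection
#'
#' Greedy modularity optimisation (Louvain) over the weighted network;
#' deterministic given `seed`. The reported `Q` is recomputed with
#' [graph_modularity()] on the returned partition, and module ids are
#' renumbered by decreasing module size.
#'
#' @param x a `phenet`-like object with positive link weights.
#' @param seed integer seed.
#' @return a `phenet_partition` object: tibble (`phenocode`, `module`)
#'   with attribute `modularity`.
#' @export
louvain_partition <- function(x, seed = 1L) {
  g <- as_igraph(x)
  comm <- .with_seed(seed, igraph::cluster_louvain(g))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  renum <- setNames(seq_along(sizes), names(sizes))
  out <- tibble::tibble(
    phenocode = names(memb),
    module = unname(renum[as.character(memb)])
  ) |> dplyr::arrange(.data$phenocode)
  q <- graph_modularity(x, setNames(out$module, out$phenocode))
  structure(out, modularity = q,
            class = c("phenet_partition", class(out)))
}

# minimal attainable raw homogeneity for degree k over c categories:
# the most even integer split of k neighbours among the categories
.h_min <- function(k, c) {
  if (k <= c) return(1 / k)
  q <- k %/% c
  r <- k %% c
  (r * (q + 1)^2 + (c - r) * q^2) / k^2
}

#' Neighbourhood homogeneity H-score
#'
#' The raw score is the sum of squared neighbour-category shares,
#' `H* = sum_j (k_ij / k)^2`, which attains 1 when all `k` neighbours
#' share one category but whose minimum depends on the degree. The scaled
#' score removes that degree dependence by min-max scaling against the
#' most even attainable split: `H = (H* - H*_min) / (1 - H*_min)`, with
#' `H*_min = 1/k` for `k <= c` and the most even integer composition of
#' `k` among the `c` categories otherwise. Nodes of degree 1 are
#' naturally homogeneous and score 1 by convention.
#'
#' @param counts neighbour counts per represented category (positive
#'   integers summing to the degree `k`).
#' @param n_categories number of possible categories `c` (>= 2).
#' @return list with `k`, `h_raw`, `h_min`, `h_scaled`.
#' @export
h_score <- function(counts, n_categories) {
  counts <- counts[counts > 0]
  k <- sum(counts)
  if (k < 1) stop("neighbour counts must sum to at least 1", call. = FALSE)
  stopifnot(n_categories >= 2)
  h_raw <- sum((counts / k)^2)
  h_min <- .h_min(k, n_categories)
  h_scaled <- if (h_min >= 1) 1 else (h_raw - h_min) / (1 - h_min)
  list(k = k, h_raw = h_raw, h_min = h_min, h_scaled = h_scaled)
}

# integer category codes, neighbour index lists, and a scaled-H evaluator
.h_engine <- function(x, n_categories = NULL) {
  codes <- x$nodes$phenocode
  cats <- x$nodes$category
  if (anyNA(cats)) stop("node categories required", call. = FALSE)
  lev <- sort(unique(cats))
  c_eff <- if (is.null(n_categories)) length(lev) else n_categories
  cat_int <- match(cats, lev)
  ai <- match(x$links$code_a, codes)
  bi <- match(x$links$code_b, codes)
  nbrs <- vector("list", length(codes))
  for (i in seq_along(ai)) {
    nbrs[[ai[i]]] <- c(nbrs[[ai[i]]], bi[i])
    nbrs[[bi[i]]] <- c(nbrs[[bi[i]]], ai[i])
  }
  h_fun <- function(perm_cat) {
    vapply(seq_along(codes), function(i) {
      nb <- nbrs[[i]]
      if (length(nb) == 0) return(NA_real_)
      cnt <- tabulate(perm_cat[nb], nbins = length(lev))
      h_score(cnt, c_eff)$h_scaled
    }, numeric(1))
  }
  list(codes = codes, cat_int = cat_int, levels = lev, c_eff = c_eff,
       h_fun = h_fun, nbrs = nbrs)
}

#' Per-node scaled H-scores of a network
#'
#' @param x a `phenet`-like object with node categories.
#' @param n_categories number of possible categories; defaults to the
#'   number of categories present among the network's nodes.
#' @return tibble (`phenocode`, `category`, `degree`, `h_raw`,
#'   `h_scaled`).
#' @export
node_h_scores <- function(x, n_categories = NULL) {
  eng <- .h_engine(x, n_categories)
  h <- eng$h_fun(eng$cat_int)
  raw <- vapply(seq_along(eng$codes), function(i) {
    nb <- eng$nbrs[[i]]
    if (length(nb) == 0) return(NA_real_)
    h_score(tabulate(eng$cat_int[nb], nbins = length(eng$levels)),
            eng$c_eff)$h_raw
  }, numeric(1))
  tibble::tibble(
    phenocode = eng$codes,
    category = x$nodes$category,
    degree = lengths(eng$nbrs),
    h_raw = raw,
    h_scaled = h
  )
}

# shared category-shuffle replicate stream: permutations of the node
# category assignment, fixed topology; same seed -> same permutations for
# the H-score and Z-score analyses
.category_shuffle_perms <- function(n_nodes, n_reps, seed) {
  .with_seed(seed, {
    matrix(replicate(n_reps, sample.int(n_nodes)), ncol = n_reps)
  })
}

#' Mean H-score tests against category-shuffle nulls
#'
#' Compares observed group-mean scaled H-scores with nulls in which only
#' the node categories are shuffled without replacement (topology fixed).
#' The empirical p-value is the fraction of null means strictly larger
#' than the observed mean, Bonferroni-multiplied by the number of groups
#' (capped at 1).
#'
#' @param x a `phenet`-like object with node categories.
#' @param grouping `"all"` (one overall mean), `"module"` (needs
#'   `partition`) or `"category"` (a node's own category).
#' @param partition a [louvain_partition()] result, required for
#'   `grouping = "module"`.
#' @param n_reps number of shuffle replicates; default 1000.
#' @param seed integer seed (shared with [category_z_scores()]: the same
#'   seed draws the same replicate stream).
#' @param n_categories see [node_h_scores()].
#' @return tibble (`group`, `n_nodes`, `mean_h`, `null_mean`, `p`,
#'   `p_adj`).
#' @export
mean_h_tests <- function(x, grouping = c("all", "module", "category"),
                         partition = NULL, n_reps = 1000, seed = 1L,
                         n_categories = NULL) {
  grouping <- match.arg(grouping)
  eng <- .h_engine(x, n_categories)
  group <- switch(grouping,
    all = rep("all", length(eng$codes)),
    category = x$nodes$category,
    module = {
      if (is.null(partition)) {
        stop("grouping = 'module' needs a partition", call. = FALSE)
      }
      as.character(partition$module[match(eng$codes,
                                          partition$phenocode)])
    })
  obs_h <- eng$h_fun(eng$cat_int)
  groups <- sort(unique(group))
  group_mean <- function(h) {
    vapply(groups, function(g) mean(h[group == g], na.rm = TRUE),
           numeric(1))
  }
  obs_means <- group_mean(obs_h)

  perms <- .category_shuffle_perms(length(eng$codes), n_reps, seed)
  null_means <- matrix(NA_real_, nrow = length(groups), ncol = n_reps)
  for (r in seq_len(n_reps)) {
    null_means[, r] <- group_mean(eng$h_fun(eng$cat_int[perms[, r]]))
  }

  p_raw <- vapply(seq_along(groups), function(i) {
    empirical_p(obs_means[[i]], null_means[i, ])$p
  }, numeric(1))
  tibble::tibble(
    group = groups,
    n_nodes = vapply(groups, function(g) sum(group == g), integer(1)),
    mean_h = unname(obs_means),
    null_mean = rowMeans(null_means),
    p = p_raw,
    p_adj = pmin(1, p_raw * length(groups))
  )
}

# counts of links by unordered endpoint-category pair, as a vector over
# all c*(c+1)/2 pairs (self-pairs included)
.category_link_counts <- function(cat_int, ai, bi, n_lev) {
  ci <- pmin(cat_int[ai], cat_int[bi])
  cj <- pmax(cat_int[ai], cat_int[bi])
  # row-major upper-triangular (incl. diagonal) linear index of (ci, cj)
  idx <- (ci - 1L) * (n_lev + 1L) - (ci * (ci - 1L)) %/% 2L + (cj - ci + 1L)
  tabulate(idx, nbins = n_lev * (n_lev + 1L) / 2L)
}

#' Category-interaction Z-scores
#'
#' Counts the links whose endpoint categories form each unordered
#' category pair (self-pairs included) and standardises each count
#' against the mean and standard deviation of the same count in
#' category-shuffle replicates: `z = (x - mu) / sigma`. A two-sided
#' normal test flags pairs with `p < alpha / n_pairs` (Bonferroni over
#' all `c (c + 1) / 2` pairs); pairs with `sigma = 0` are reported
#' unscored.
#'
#' @param x a `phenet`-like object with node categories.
#' @param n_reps number of shuffle replicates; default 1000.
#' @param seed integer seed (shared stream with [mean_h_tests()]).
#' @param alpha two-sided family-wise level; default 0.05.
#' @return tibble (`cat_i`, `cat_j`, `x`, `mu`, `sigma`, `z`, `p`,
#'   `significant`) with `cat_i <= cat_j`, plus attribute `n_pairs`.
#' @export
category_z_scores <- function(x, n_reps = 1000, seed = 1L, alpha = 0.05) {
  eng <- .h_engine(x)
  codes <- eng$codes
  ai <- match(x$links$code_a, codes)
  bi <- match(x$links$code_b, codes)
  n_lev <- length(eng$levels)
  obs <- .category_link_counts(eng$cat_int, ai, bi, n_lev)

  perms <- .category_shuffle_perms(length(codes), n_reps, seed)
  null_mat <- matrix(NA_real_, nrow = length(obs), ncol = n_reps)
  for (r in seq_len(n_reps)) {
    null_mat[, r] <- .category_link_counts(eng$cat_int[perms[, r]], ai, bi,
                                           n_lev)
  }
  mu <- rowMeans(null_mat)
  sigma <- apply(null_mat, 1, sd)

  pair_idx <- which(upper.tri(matrix(0, n_lev, n_lev), diag = TRUE),
                    arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, "row"], pair_idx[, "col"]), ,
                       drop = FALSE]
  n_pairs <- nrow(pair_idx)
  z <- ifelse(sigma > 0, (obs - mu) / sigma, NA_real_)
  p <- 2 * pnorm(-abs(z))
  out <- tibble::tibble(
    cat_i = eng$levels[pair_idx[, "row"]],
    cat_j = eng$levels[pair_idx[, "col"]],
    x = obs, mu = mu, sigma = sigma, z = z, p = p,
    significant = !is.na(p) & p < alpha / n_pairs
  )
  attr(out, "n_pairs") <- n_pairs
  out
}
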