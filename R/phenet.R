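#' Group top-hit SNPs into LD blocks
#'
#' Different diseases can carry different top-hit SNPs that tag the same
#' associated locus. To merge such hits, SNPs are grouped into blocks:
#' two SNPs are mergeable when their pairwise linkage disequilibrium
#' satisfies `r2 >= r2_min`, they lie on the same chromosome, and their
#' positions differ by at most `max_dist` base pairs. Blocks are the
#' connected components of the graph of mergeable pairs (single linkage,
#' so a chain of pairwise-close SNPs may span more than `max_dist`
#' overall). Components of size one remain bare SNPs; the resulting units
#' partition the SNP set.
#'
#' @param associations tibble of associations as returned by
#'   [read_summary_stats()] (needs `snp_id`, `chrom`, `pos`).
#' @param r2_table tibble with `snp1`, `snp2`, `r2`; treated as symmetric.
#' @param r2_min minimum r-squared for merging; default 0.8.
#' @param max_dist maximum pairwise distance in base pairs; default 500000.
#' @return list with `blocks` (tibble: `block_id`, `members` list-column,
#'   `chrom`) and `units` (tibble: `snp_id`, `unit_id` mapping every SNP in
#'   `associations` to its unit; singletons map to their own `snp_id`).
#' @export
build_ld_blocks <- function(associations, r2_table, r2_min = 0.8,
                            max_dist = 500000) {
  snps <- dplyr::distinct(associations, .data$snp_id, .data$chrom, .data$pos)
  unknown <- setdiff(unique(c(r2_table$snp1, r2_table$snp2)), snps$snp_id)
  if (length(unknown) > 0) {
    warning(length(unknown),
            " SNP(s) in the LD table have no association row; ignored",
            call. = FALSE)
  }
  edges <- r2_table |>
    dplyr::filter(.data$r2 >= r2_min) |>
    dplyr::inner_join(snps, by = c(snp1 = "snp_id")) |>
    dplyr::inner_join(snps, by = c(snp2 = "snp_id"),
                      suffix = c("1", "2")) |>
    dplyr::filter(.data$chrom1 == .data$chrom2,
                  abs(.data$pos1 - .data$pos2) <= max_dist)

  g <- igraph::graph_from_data_frame(
    edges[, c("snp1", "snp2")], directed = FALSE,
    vertices = snps$snp_id)
  comp <- igraph::components(g)
  membership <- comp$membership[snps$snp_id]

  units <- tibble::tibble(snp_id = snps$snp_id, chrom = snps$chrom,
                          pos = snps$pos, comp = unname(membership)) |>
    dplyr::group_by(.data$comp) |>
    dplyr::mutate(.size = dplyr::n(), .minpos = min(.data$pos)) |>
    dplyr::ungroup()

  block_ids <- units |>
    dplyr::filter(.data$.size >= 2) |>
    dplyr::distinct(.data$comp, .data$chrom, .data$.minpos) |>
    dplyr::arrange(.data$chrom, .data$.minpos) |>
    dplyr::mutate(block_id = sprintf("block_%s_%d", .data$chrom,
                                     seq_len(dplyr::n())))

  units <- units |>
    dplyr::left_join(block_ids[, c("comp", "block_id")], by = "comp") |>
    dplyr::mutate(unit_id = dplyr::coalesce(.data$block_id, .data$snp_id))

  blocks <- units |>
    dplyr::filter(!is.na(.data$block_id)) |>
    dplyr::group_by(block_id = .data$block_id, chrom = .data$chrom) |>
    dplyr::summarise(members = list(sort(.data$snp_id)), .groups = "drop") |>
    dplyr::select("block_id", "members", "chrom")

  list(blocks = blocks,
       units = units |> dplyr::select("snp_id", "unit_id") |>
         dplyr::arrange(.data$snp_id))
}

#' Per-disease effect size of a SNP or LD-block unit
#'
#' For a bare SNP the unit effect size is the absolute effect size |beta|
#' of the disease's association with that SNP. For an LD block it is the
#' sum of |beta| over the block's member SNPs that are associated with the
#' disease.
#'
#' @param associations association tibble (`snp_id`, `phenocode`, `beta`).
#' @param units SNP-to-unit mapping from [build_ld_blocks()].
#' @param disease phenocode string.
#' @param unit unit id (a `snp_id` or a block id).
#' @return nonnegative scalar effect size.
#' @export
block_effect_size <- function(associations, units, disease, unit) {
  betas <- associations |>
    dplyr::inner_join(units, by = "snp_id") |>
    dplyr::filter(.data$phenocode == disease, .data$unit_id == unit)
  if (nrow(betas) == 0) {
    stop("disease ", disease, " has no association in unit ", unit,
         call. = FALSE)
  }
  sum(abs(betas$beta))
}

#' Link weight between two diseases from shared units
#'
#' Each shared SNP/LD-block unit i contributes the geometric mean
#' sqrt(b1_i * b2_i) of the two per-disease absolute effect sizes; the link
#' weight is the sum of these contributions over all shared units, so
#' diseases sharing more loci accrue larger weights at equal effect sizes.
#'
#' @param beta_a,beta_b nonnegative per-unit effect sizes for the two
#'   diseases, aligned by shared unit.
#' @return positive scalar link weight; symmetric in the two arguments.
#' @export
link_weight <- function(beta_a, beta_b) {
  if (length(beta_a) == 0 || length(beta_a) != length(beta_b)) {
    stop("link_weight needs one or more aligned per-unit effect-size pairs",
         call. = FALSE)
  }
  sum(sqrt(beta_a * beta_b))
}

#' Build the phenome-wide disease network (PheNet)
#'
#' Two diseases are linked when they are associated with at least one
#' common unit (SNP or LD block). A block counts as one shared unit even
#' when several of its member SNPs hit both diseases; multiplicity enters
#' only through the summed per-disease effect sizes. Diseases without any
#' link are excluded.
#'
#' @param associations association tibble from [read_summary_stats()].
#' @param units SNP-to-unit mapping from [build_ld_blocks()].
#' @param meta phenocode metadata tibble from [read_phenocode_meta()]
#'   (optional; adds descriptions and categories to nodes).
#' @return a `phenet` object: list with `nodes` (tibble `phenocode`,
#'   `description`, `category`, `level`, `n_units`) and `links` (tibble
#'   `code_a`, `code_b`, `n_shared`, `beta_weight`, `shared_units`
#'   list-column), plus a `weight_measure` attribute naming the link-weight
#'   scale.
#' @export
build_phenet <- function(associations, units, meta = NULL) {
  per_unit <- associations |>
    dplyr::inner_join(units, by = "snp_id") |>
    dplyr::group_by(phenocode = .data$phenocode, unit_id = .data$unit_id) |>
    dplyr::summarise(beta_tilde = sum(abs(.data$beta)), .groups = "drop")

  shared <- per_unit |>
    dplyr::inner_join(per_unit, by = "unit_id",
                      suffix = c("_a", "_b"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$phenocode_a < .data$phenocode_b)
  if (nrow(shared) > 0) {
    links <- shared |>
      dplyr::group_by(code_a = .data$phenocode_a,
                      code_b = .data$phenocode_b) |>
      dplyr::summarise(
        n_shared = dplyr::n(),
        beta_weight = link_weight(.data$beta_tilde_a, .data$beta_tilde_b),
        shared_units = list(sort(.data$unit_id)),
        .groups = "drop") |>
      dplyr::arrange(.data$code_a, .data$code_b)
  } else {
    links <- tibble::tibble(code_a = character(), code_b = character(),
                            n_shared = integer(), beta_weight = double(),
                            shared_units = list())
  }

  n_units <- per_unit |>
    dplyr::count(.data$phenocode, name = "n_units")

  node_codes <- sort(unique(c(links$code_a, links$code_b)))
  nodes <- tibble::tibble(phenocode = node_codes) |>
    dplyr::left_join(n_units, by = "phenocode") |>
    dplyr::mutate(level = .level_lenient(.data$phenocode))
  if (!is.null(meta)) {
    nodes <- nodes |>
      dplyr::left_join(meta[, c("phenocode", "description", "category")],
                       by = "phenocode")
  } else {
    nodes$description <- nodes$phenocode
    nodes$category <- NA_character_
  }
  nodes <- nodes[, c("phenocode", "description", "category", "level",
                     "n_units")]

  structure(list(nodes = nodes, links = links),
            weight_measure = "beta", class = "phenet")
}

#' @export
print.phenet <- function(x, ...) {
  cat("<phenet> ", nrow(x$nodes), " diseases, ", nrow(x$links),
      " links (weight: ", attr(x, "weight_measure"), ")\n", sep = "")
  invisible(x)
}

#' Convert a network object to igraph
#'
#' @param x a `phenet`, `sub_phenet` or `directed_phenet` object.
#' @return an igraph graph with node attributes and a `weight` edge
#'   attribute.
#' @export
as_igraph <- function(x) UseMethod("as_igraph")

#' @export
as_igraph.phenet <- function(x) {
  weight_col <- if (identical(attr(x, "weight_measure"), "mcc")) "mcc" else "beta_weight"
  edges <- data.frame(from = x$links$code_a, to = x$links$code_b,
                      weight = x$links[[weight_col]],
                      n_shared = x$links$n_shared)
  vertices <- as.data.frame(x$nodes[, c("phenocode", "description",
                                        "category", "level", "n_units")])
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}

#' @export
as_igraph.sub_phenet <- function(x) as_igraph.phenet(x)

#' Flatten a network object to a schema table
#'
#' @param x network object.
#' @param schema edge-list schema name (see [write_edgelist()]).
#' @return tibble in the requested schema.
#' @export
as_edgelist_table <- function(x, schema) {
  UseMethod("as_edgelist_table")
}

#' @export
as_edgelist_table.phenet <- function(x, schema = "phenet") {
  desc <- setNames(x$nodes$description, x$nodes$phenocode)
  out <- tibble::tibble(
    From = unname(desc[x$links$code_a]),
    To = unname(desc[x$links$code_b]),
    N = as.integer(x$links$n_shared),
    betaMerged = x$links$beta_weight,
    FromCode = x$links$code_a,
    ToCode = x$links$code_b,
    SNPs = vapply(x$links$shared_units, paste, character(1), collapse = ";")
  )
  if (schema == "sub_phenet") {
    out$C <- as.integer(x$links$C)
    out$MCC <- x$links$mcc
    out$fisherp <- x$links$fisher_p
  }
  out
}

#' @export
as_edgelist_table.sub_phenet <- function(x, schema = "sub_phenet") {
  as_edgelist_table.phenet(x, schema)
}

#' @rdname tidy.phenet
#' @export
glance.phenet <- function(x, ...) {
  g <- as_igraph(x)
  comp <- igraph::components(g)
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_links = nrow(x$links),
    n_components = comp$no,
    giant_size = if (comp$no > 0) max(comp$csize) else 0L,
    mean_degree = if (nrow(x$nodes) > 0) 2 * nrow(x$links) / nrow(x$nodes) else NA_real_
  )
}

#' Tidy and summarise network objects
#'
#' `tidy()` returns one row per link with endpoint codes, shared-unit count
#' and weight; `glance()` returns one-row network-level summaries.
#'
#' @param x a `phenet` or `sub_phenet` object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.phenet <- function(x, ...) {
  out <- x$links
  out$shared_units <- vapply(out$shared_units, paste, character(1),
                             collapse = ";")
  out
}

#' @rdname tidy.phenet
#' @export
tidy.sub_phenet <- function(x, ...) tidy.phenet(x, ...)

#' @rdname tidy.phenet
#' @export
glance.sub_phenet <- function(x, ...) glance.phenet(x, ...)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
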