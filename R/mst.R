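#' Minimum-cost spanning tree by Prim's algorithm
#'
#' Grows the tree from the lexicographically smallest species ID, adding at
#' each step the frontier edge of minimal weight. Ties break by (smaller
#' weight, lexicographically smaller in-tree endpoint, lexicographically
#' smaller new endpoint), so the tree is deterministic even when the distance
#' matrix has repeated values; total weight always equals the global minimum.
#'
#' @param matrix A `domtax_dist` object from [distance_matrix()], or a
#'   symmetric non-negative numeric matrix with species IDs as dimnames.
#' @return A `domtax_mst` object: `species_ids`, `edges` (tibble `from`,
#'   `to`, `weight`, in insertion order, with `from` the in-tree endpoint),
#'   `total_weight`, and the model labels when built from a `domtax_dist`.
#' @export
build_mst_prim <- function(matrix) {
  stat_model <- if (inherits(matrix, "domtax_dist")) matrix$statistical_model else NA_character_
  dist_model <- if (inherits(matrix, "domtax_dist")) matrix$distance_model else NA_character_
  m <- as.matrix(matrix)
  ids <- rownames(m)
  if (is.null(ids)) stop("matrix needs species IDs as dimnames", call. = FALSE)
  if (!isSymmetric(unname(m)) || any(m < 0)) {
    stop("distance matrix must be symmetric and non-negative", call. = FALSE)
  }
  n <- length(ids)
  if (n == 1L) {
    return(new_mst(ids, tibble::tibble(
      from = character(), to = character(), weight = double()
    ), stat_model, dist_model))
  }

  ord <- order(ids) # lexicographic processing order
  in_tree <- rep(FALSE, n)
  key <- rep(Inf, n) # best frontier weight per out-of-tree vertex
  parent <- rep(NA_integer_, n)
  start <- ord[1]
  key[start] <- 0

  from <- to <- character(n - 1L)
  weight <- double(n - 1L)
  for (step in seq_len(n)) {
    # pick the frontier edge minimal by (weight, in-tree endpoint, new endpoint)
    cand <- which(!in_tree)
    k <- key[cand]
    pid <- ifelse(is.na(parent[cand]), "", ids[parent[cand]])
    sel <- cand[order(k, pid, ids[cand])[1]]
    if (!is.finite(key[sel])) {
      stop("distance matrix is not connected (non-finite entries)", call. = FALSE)
    }
    in_tree[sel] <- TRUE
    if (step > 1L) {
      from[step - 1L] <- ids[parent[sel]]
      to[step - 1L] <- ids[sel]
      weight[step - 1L] <- m[parent[sel], sel]
    }
    w <- m[sel, ]
    for (v in which(!in_tree)) {
      if (w[v] < key[v] ||
          (w[v] == key[v] && !is.na(parent[v]) && ids[sel] < ids[parent[v]])) {
        key[v] <- w[v]
        parent[v] <- sel
      }
    }
  }
  new_mst(
    ids,
    tibble::tibble(from = from, to = to, weight = weight),
    stat_model, dist_model
  )
}

new_mst <- function(species_ids, edges, statistical_model = NA_character_,
                    distance_model = NA_character_) {
  structure(
    list(
      species_ids = species_ids,
      edges = edges,
      total_weight = sum(edges$weight),
      statistical_model = statistical_model,
      distance_model = distance_model
    ),
    class = "domtax_mst"
  )
}

#' @export
print.domtax_mst <- function(x, ...) {
  cat(
    "<domtax_mst> ", length(x$species_ids), " species, ",
    nrow(x$edges), " edges, total weight ",
    format(x$total_weight, digits = 6), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname tidy.domtax_dist
#' @method tidy domtax_mst
#' @export
tidy.domtax_mst <- function(x, ...) x$edges

#' One-row summary of a spanning tree
#'
#' @param x A `domtax_mst` object.
#' @param ... Unused.
#' @return Tibble with `n_species`, `n_edges`, `total_weight`,
#'   `statistical_model`, `distance_model`.
#' @method glance domtax_mst
#' @export
glance.domtax_mst <- function(x, ...) {
  tibble::tibble(
    n_species = length(x$species_ids),
    n_edges = nrow(x$edges),
    total_weight = x$total_weight,
    statistical_model = x$statistical_model,
    distance_model = x$distance_model
  )
}

rank_labels <- function(tree, taxonomy, rank) {
  if (!rank %in% taxonomy_ranks()) {
    stop(
      "rank must be one of ", paste(taxonomy_ranks(), collapse = ", "),
      call. = FALSE
    )
  }
  ids <- tree$species_ids
  lab <- taxonomy[[rank]][match(ids, taxonomy$species_id)]
  missing <- is.na(lab)
  # species lacking the rank keep a unique singleton label so the partition
  # still covers every node
  lab[missing] <- paste0("unassigned:", ids[missing])
  stats::setNames(lab, ids)
}

#' Cluster a spanning tree against a reference taxonomy
#'
#' Tags every node with its taxon at the requested rank, drops every edge
#' whose endpoints disagree, and takes connected components of what remains.
#' Same-taxon species linked only through a different-taxon node therefore
#' land in different groups — exactly the signal the agreement metrics
#' measure. The partition is independent of any seed-node choice. Species
#' missing the rank (or missing from the taxonomy) get a unique singleton
#' label rather than being dropped.
#'
#' @param tree A `domtax_mst` from [build_mst_prim()].
#' @param taxonomy Taxonomy tibble ([read_taxonomy()]).
#' @param rank Rank to cluster at; the framework's reference analyses use
#'   `"phylum"`.
#' @return Tibble with one row per species: `species_id`, `taxon`, `group`
#'   (a global integer group ID; groups are numbered by their
#'   lexicographically smallest member).
#' @export
cluster_by_taxon <- function(tree, taxonomy, rank = "phylum") {
  lab <- rank_labels(tree, taxonomy, rank)
  ids <- tree$species_ids
  idx <- stats::setNames(seq_along(ids), ids)

  # union-find over same-taxon edges
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  e <- tree$edges
  for (k in seq_len(nrow(e))) {
    u <- idx[[e$from[k]]]
    v <- idx[[e$to[k]]]
    if (lab[[u]] == lab[[v]]) {
      ru <- find(u)
      rv <- find(v)
      if (ru != rv) parent[rv] <- ru
    }
  }
  root <- vapply(seq_along(ids), find, integer(1))
  # stable group numbering: by lexicographically smallest member
  smallest <- vapply(split(ids, root), min, character(1))
  group_of_root <- stats::setNames(
    rank(smallest, ties.method = "first"),
    names(smallest)
  )
  tibble::tibble(
    species_id = ids,
    taxon = unname(lab),
    group = as.integer(group_of_root[as.character(root)])
  ) |>
    dplyr::arrange(.data$group, .data$species_id)
}

#' Per-taxon isolation counts
#'
#' For each taxon: `T` is its total species count and `S` the number of
#' species isolated from the taxon's main part, the largest same-taxon group
#' on the tree (`S = T - max(group size)`). When two groups tie for largest,
#' the first under descending size then lexicographic smallest member is the
#' main part; `S` is unaffected by that choice.
#'
#' @param groups Group table from [cluster_by_taxon()].
#' @return Tibble with one row per taxon: `taxon`, `n_groups`, `T`, `S`,
#'   `group_sizes` (list column, descending).
#' @export
isolation_counts <- function(groups) {
  groups |>
    dplyr::group_by(.data$taxon, .data$group) |>
    dplyr::summarise(
      size = dplyr::n(),
      first_member = min(.data$species_id),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$taxon, dplyr::desc(.data$size), .data$first_member) |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      n_groups = dplyr::n(),
      T = sum(.data$size),
      S = .data$T - .data$size[1],
      group_sizes = list(.data$size),
      .groups = "drop"
    )
}

#' Taxonomy agreement metrics
#'
#' The three comparison standards for how well a spanning tree matches a
#' reference taxonomy:
#' \describe{
#'   \item{arithmetic_percentage}{total isolated species over total species,
#'     `sum(S_i) / sum(T_i)`}
#'   \item{weighted_percentage}{mean per-taxon isolation fraction,
#'     `mean(S_i / T_i)` over the taxa observed}
#'   \item{split_taxon_count}{number of taxa divided into more than one
#'     group}
#' }
#' Both percentages are 0 exactly when no taxon is split.
#'
#' @param counts Per-taxon counts from [isolation_counts()].
#' @return One-row tibble with the three standards and `n_taxa`.
#' @export
agreement_metrics <- function(counts) {
  if (nrow(counts) == 0L) stop("need at least one taxon", call. = FALSE)
  if (any(counts$T <= 0)) stop("every taxon must have T > 0", call. = FALSE)
  tibble::tibble(
    arithmetic_percentage = sum(counts$S) / sum(counts$T),
    weighted_percentage = mean(counts$S / counts$T),
    split_taxon_count = sum(counts$n_groups >= 2L),
    n_taxa = nrow(counts)
  )
}

#' Full taxonomy-concordance report for a spanning tree
#'
#' Convenience wrapper running [cluster_by_taxon()], [isolation_counts()] and
#' [agreement_metrics()] in one step.
#'
#' @inheritParams cluster_by_taxon
#' @return A `taxon_cluster_report`: list with `groups`, `counts`, `metrics`,
#'   `rank`. `tidy()` returns the per-taxon counts, `glance()` the metric row.
#' @export
taxon_cluster_report <- function(tree, taxonomy, rank = "phylum") {
  groups <- cluster_by_taxon(tree, taxonomy, rank)
  counts <- isolation_counts(groups)
  structure(
    list(
      groups = groups,
      counts = counts,
      metrics = agreement_metrics(counts),
      rank = rank,
      statistical_model = tree$statistical_model,
      distance_model = tree$distance_model
    ),
    class = "taxon_cluster_report"
  )
}

#' @export
print.taxon_cluster_report <- function(x, ...) {
  cat(
    "<taxon_cluster_report> rank ", x$rank, ": ", nrow(x$counts), " taxa, ",
    nrow(x$groups), " species\n",
    sep = ""
  )
  print(x$metrics)
  invisible(x)
}

#' @rdname tidy.domtax_dist
#' @method tidy taxon_cluster_report
#' @export
tidy.taxon_cluster_report <- function(x, ...) x$counts

#' @rdname glance.domtax_mst
#' @method glance taxon_cluster_report
#' @export
glance.taxon_cluster_report <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble::tibble(
      rank = x$rank,
      statistical_model = x$statistical_model,
      distance_model = x$distance_model
    )
  )
}
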