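#' Run the full three-step classification pipeline
#'
#' For each requested statistical x distance model combination: build species
#' profiles from the domain-hit files, compute the pairwise distance matrix,
#' construct the minimum spanning tree, cluster it against the taxonomy at
#' the requested rank, and score the three agreement standards. Optionally
#' applies the assembly quality filter first. When `output_dir` is given,
#' every stage is written to disk: per-combination distance matrix (TSV),
#' Cytoscape JSON edge list, cluster report (TSV), plus a combined
#' `metrics.tsv` ranking table and a `run_summary.json` with stage counts.
#'
#' @param input Directory of hit files (species ID = file basename without
#'   extension), or a named character vector of file paths (names are species
#'   IDs).
#' @param taxonomy Taxonomy tibble or path to a taxonomy TSV.
#' @param quality Optional quality tibble or path to a quality TSV; species
#'   whose quality score falls under `threshold` are removed before
#'   profiling.
#' @param threshold Quality threshold (percent), default 95.
#' @param statistical_models,distance_models Character vectors selecting the
#'   combinations to run; defaults run all 12.
#' @param rank Taxonomic rank for clustering, default `"phylum"`.
#' @param dialect Hit-file dialect, see [read_domain_hits()].
#' @param output_dir Optional directory for the output files.
#' @param verbose Log stage counts to stderr.
#' @return A list with `metrics` (tibble of one row per combination, the
#'   three standards plus tree weight), `reports` (named list of
#'   `taxon_cluster_report`s), `trees`, `matrices`, and `summary` (stage
#'   counts).
#' @export
run_pipeline <- function(input, taxonomy, quality = NULL, threshold = 95,
                         statistical_models = NULL, distance_models = NULL,
                         rank = "phylum", dialect = "pfam_scan",
                         output_dir = NULL, verbose = TRUE) {
  log_msg <- function(...) if (verbose) message("[domtax] ", ...)

  if (is.character(taxonomy) && length(taxonomy) == 1L) {
    taxonomy <- read_taxonomy(taxonomy)
  }
  if (is.character(quality) && length(quality) == 1L) {
    quality <- read_quality(quality)
  }

  files <- if (length(input) == 1L && dir.exists(input)) {
    paths <- sort(list.files(input, pattern = "\\.(pfamscan|txt|tsv)$",
                             full.names = TRUE))
    paths <- paths[!basename(paths) %in% c("taxonomy.tsv", "quality.tsv")]
    stats::setNames(paths, sub("\\.[^.]*$", "", basename(paths)))
  } else {
    stopifnot(!is.null(names(input)))
    input
  }
  log_msg("species read: ", length(files))

  n_removed <- 0L
  if (!is.null(quality)) {
    decisions <- filter_by_quality(quality, threshold)
    removed <- decisions$species_id[!decisions$kept]
    n_removed <- sum(names(files) %in% removed)
    files <- files[!names(files) %in% removed]
    log_msg("species removed by quality filter: ", n_removed)
  }
  if (length(files) == 0L) {
    stop("no species left after quality filtering", call. = FALSE)
  }

  arch <- purrr::imap(files, function(path, id) {
    hits <- read_domain_hits(path, dialect = dialect)
    dplyr::mutate(build_architectures(hits), species_id = id)
  }) |>
    dplyr::bind_rows()
  log_msg(
    "proteins with architectures: ", nrow(arch),
    " across ", length(files), " species"
  )

  combos <- model_combinations()
  if (!is.null(statistical_models)) {
    combos <- combos[combos$statistical_model %in% statistical_models, ]
  }
  if (!is.null(distance_models)) {
    combos <- combos[combos$distance_model %in% distance_models, ]
  }
  if (nrow(combos) == 0L) stop("no model combination selected", call. = FALSE)

  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }

  matrices <- trees <- reports <- vector("list", nrow(combos))
  names(matrices) <- names(trees) <- names(reports) <- combos$label
  profiles_cache <- list()
  for (k in seq_len(nrow(combos))) {
    sm <- combos$statistical_model[k]
    dm <- combos$distance_model[k]
    label <- combos$label[k]
    if (is.null(profiles_cache[[sm]])) {
      profiles_cache[[sm]] <- build_profiles(
        arch, sm, species_ids = sort(names(files))
      )
    }
    mat <- distance_matrix(profiles_cache[[sm]], dm)
    tree <- build_mst_prim(mat)
    report <- taxon_cluster_report(tree, taxonomy, rank)
    matrices[[label]] <- mat
    trees[[label]] <- tree
    reports[[label]] <- report
    log_msg(
      label, ": profile sizes ",
      paste(range(vapply(profiles_cache[[sm]], nrow, integer(1))),
        collapse = "-"
      ),
      ", tree weight ", format(tree$total_weight, digits = 4)
    )
    if (!is.null(output_dir)) {
      write_distance_matrix(
        mat, file.path(output_dir, paste0(label, "_distances.tsv")),
        format = "square_tsv"
      )
      write_edge_list_json(
        tree, taxonomy, file.path(output_dir, paste0(label, "_mst.json"))
      )
      write_cluster_report(
        report, file.path(output_dir, paste0(label, "_clusters.tsv"))
      )
    }
  }

  metrics <- purrr::imap(reports, function(r, label) {
    dplyr::bind_cols(tibble::tibble(label = label), glance(r))
  }) |>
    dplyr::bind_rows()

  summary <- list(
    n_species_read = length(files) + n_removed,
    n_species_removed = n_removed,
    n_species_used = length(files),
    n_proteins = nrow(arch),
    rank = rank,
    combinations = combos$label
  )
  if (!is.null(output_dir)) {
    readr::write_tsv(
      dplyr::select(metrics, !"n_taxa"),
      file.path(output_dir, "metrics.tsv"),
      progress = FALSE
    )
    jsonlite::write_json(
      summary, file.path(output_dir, "run_summary.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  list(
    metrics = metrics, reports = reports, trees = trees,
    matrices = matrices, summary = summary
  )
}

#' Rank model combinations by the three agreement standards
#'
#' Produces, for each standard (arithmetic percentage, weighted percentage,
#' split taxon count; smaller is better for all three), a ranking of the
#' combinations with the best and second-best flagged. Ties share a rank.
#'
#' @param metrics Metrics tibble from [run_pipeline()] (columns `label` and
#'   the three standards).
#' @return Long tibble: `standard`, `label`, `value`, `rank`, `flag`
#'   (`"best"`, `"second"` or `NA`).
#' @export
compare_combinations <- function(metrics) {
  long <- tidyr::pivot_longer(
    metrics[, c(
      "label", "arithmetic_percentage", "weighted_percentage",
      "split_taxon_count"
    )],
    cols = !"label", names_to = "standard", values_to = "value"
  )
  long |>
    dplyr::group_by(.data$standard) |>
    dplyr::mutate(
      rank = dplyr::min_rank(.data$value),
      flag = dplyr::case_when(
        .data$rank == 1L ~ "best",
        .data$rank == sum(.data$rank == 1L) + 1L ~ "second",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$standard, .data$rank, .data$label)
}
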