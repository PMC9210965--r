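#' Read a domain-hit table
#'
#' Parses per-protein Pfam domain hits from either the 15-column output of
#' `pfam_scan.pl` (whitespace- or comma-delimited, `#`-comment header) or a
#' simplified 5-column TSV with a header row. Pfam accession version suffixes
#' are stripped (`"PF00005.27"` becomes `"PF00005"`) so that profile identity
#' does not depend on Pfam release minor versions.
#'
#' @param path Path to the hit file.
#' @param dialect `"pfam_scan"` (default) for pfam_scan.pl output, `"tsv"` for
#'   a tab-separated file with columns `protein_id`, `domain_acc`, `ali_start`,
#'   `ali_end`, `bit_score` (an `e_value` column is kept if present).
#' @return A tibble with one row per hit, in file order, with columns
#'   `protein_id`, `domain_acc`, `domain_name`, `ali_start`, `ali_end`,
#'   `bit_score`, `e_value`. Alignment coordinates are 1-based inclusive.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c(
#'   "# pfam_scan.pl output",
#'   "p1  10  60  8 62 PF00005.27 ABC_tran Domain 1 55 55 70.2 1e-12 1 CL0023"
#' ), f)
#' read_domain_hits(f)
#' @export
read_domain_hits <- function(path, dialect = c("pfam_scan", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  is_data <- !grepl("^\\s*(#|$)", lines)
  data_idx <- which(is_data)

  if (length(data_idx) == 0L) {
    warning("no data rows in ", path, call. = FALSE)
    return(empty_hits())
  }

  if (dialect == "pfam_scan") {
    parse_pfam_scan_lines(lines[data_idx], data_idx, path)
  } else {
    parse_hits_tsv_lines(lines[data_idx], data_idx, path)
  }
}

empty_hits <- function() {
  tibble::tibble(
    protein_id = character(), domain_acc = character(),
    domain_name = character(), ali_start = integer(), ali_end = integer(),
    bit_score = double(), e_value = double()
  )
}

#' @noRd
strip_acc_version <- function(acc) sub("\\..*$", "", acc)

# pfam_scan.pl columns: seq id, ali start, ali end, env start, env end,
# hmm acc, hmm name, type, hmm start, hmm end, hmm length, bit score,
# E-value, significance, clan
parse_pfam_scan_lines <- function(rows, line_numbers, path) {
  # sniff delimiter on the first data line: pfam_scan.pl proper is
  # whitespace-delimited; a "csv-format" export uses commas
  sep_comma <- grepl(",", rows[1], fixed = TRUE)
  fields <- if (sep_comma) {
    strsplit(trimws(rows), "\\s*,\\s*")
  } else {
    strsplit(trimws(rows), "\\s+")
  }

  n_fields <- lengths(fields)
  bad <- which(n_fields != 15L)
  if (length(bad) > 0L) {
    stop(
      "malformed row at line ", line_numbers[bad[1]], " of ", path,
      ": expected 15 fields, found ", n_fields[bad[1]],
      call. = FALSE
    )
  }
  m <- do.call(rbind, fields)
  build_hits(
    protein_id = m[, 1], ali_start = m[, 2], ali_end = m[, 3],
    domain_acc = m[, 6], domain_name = m[, 7], bit_score = m[, 12],
    e_value = m[, 13], line_numbers = line_numbers, path = path
  )
}

parse_hits_tsv_lines <- function(rows, line_numbers, path) {
  header <- strsplit(rows[1], "\t", fixed = TRUE)[[1]]
  required <- c("protein_id", "domain_acc", "ali_start", "ali_end", "bit_score")
  if (!all(required %in% header)) {
    stop(
      "tsv dialect requires header columns ",
      paste(required, collapse = ", "), " in ", path,
      call. = FALSE
    )
  }
  body <- rows[-1]
  body_lines <- line_numbers[-1]
  if (length(body) == 0L) {
    warning("no data rows in ", path, call. = FALSE)
    return(empty_hits())
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields != length(header))
  if (length(bad) > 0L) {
    stop(
      "malformed row at line ", body_lines[bad[1]], " of ", path,
      ": expected ", length(header), " fields, found ", n_fields[bad[1]],
      call. = FALSE
    )
  }
  m <- do.call(rbind, fields)
  colnames(m) <- header
  ev <- if ("e_value" %in% header) m[, "e_value"] else rep(NA_character_, nrow(m))
  nm <- if ("domain_name" %in% header) m[, "domain_name"] else m[, "domain_acc"]
  build_hits(
    protein_id = m[, "protein_id"], ali_start = m[, "ali_start"],
    ali_end = m[, "ali_end"], domain_acc = m[, "domain_acc"],
    domain_name = nm, bit_score = m[, "bit_score"], e_value = ev,
    line_numbers = body_lines, path = path
  )
}

build_hits <- function(protein_id, ali_start, ali_end, domain_acc, domain_name,
                       bit_score, e_value, line_numbers, path) {
  check_numeric_field <- function(x, what, integer = FALSE) {
    v <- suppressWarnings(if (integer) as.integer(x) else as.numeric(x))
    bad <- which(is.na(v) & !(is.na(x) | x == "NA"))
    if (length(bad) > 0L) {
      stop(
        "malformed row at line ", line_numbers[bad[1]], " of ", path,
        ": non-numeric ", what, " (", x[bad[1]], ")",
        call. = FALSE
      )
    }
    v
  }
  start <- check_numeric_field(ali_start, "ali_start", integer = TRUE)
  end <- check_numeric_field(ali_end, "ali_end", integer = TRUE)
  score <- check_numeric_field(bit_score, "bit_score")
  evalue <- suppressWarnings(as.numeric(e_value))

  bad <- which(start < 1L | end < start | !is.finite(score))
  if (length(bad) > 0L) {
    stop(
      "invalid hit at line ", line_numbers[bad[1]], " of ", path,
      ": requires ali_start >= 1, ali_end >= ali_start, finite bit_score",
      call. = FALSE
    )
  }
  tibble::tibble(
    protein_id = as.character(protein_id),
    domain_acc = strip_acc_version(as.character(domain_acc)),
    domain_name = as.character(domain_name),
    ali_start = start, ali_end = end,
    bit_score = score, e_value = evalue
  )
}

taxonomy_ranks <- function() {
  c("phylum", "class", "order", "family", "genus", "species")
}

#' Read a taxonomy table
#'
#' Reads a tab-separated taxonomy with header
#' `species_id, phylum, class, order, family, genus, species`. Ranks other
#' than phylum may be empty; empty cells become `NA`.
#'
#' @param path Path to the taxonomy TSV.
#' @return A tibble with one row per species, columns `species_id` plus the
#'   six ranks.
#' @export
read_taxonomy <- function(path) {
  stopifnot(file.exists(path))
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!all(c("species_id", "phylum") %in% names(tab))) {
    stop("taxonomy table must contain species_id and phylum columns", call. = FALSE)
  }
  dup <- tab$species_id[duplicated(tab$species_id)]
  if (length(dup) > 0L) {
    stop("duplicate species_id in taxonomy: ", dup[1], call. = FALSE)
  }
  if (any(is.na(tab$species_id) | tab$species_id == "")) {
    stop("empty species_id in taxonomy", call. = FALSE)
  }
  for (r in setdiff(taxonomy_ranks(), names(tab))) tab[[r]] <- NA_character_
  tab[tab == ""] <- NA
  dplyr::select(tab, "species_id", dplyr::all_of(taxonomy_ranks()))
}

#' Read a CheckM-style assembly quality summary
#'
#' @param path TSV with header columns `species_id`, `completeness`,
#'   `contamination` (percent scales).
#' @return A tibble with those three columns, numeric percentages validated
#'   (`completeness` in \[0, 100\], `contamination` non-negative).
#' @export
read_quality <- function(path) {
  stopifnot(file.exists(path))
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      species_id = readr::col_character(),
      completeness = readr::col_double(),
      contamination = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (!all(c("species_id", "completeness", "contamination") %in% names(tab))) {
    stop("quality table needs species_id, completeness, contamination", call. = FALSE)
  }
  if (any(tab$completeness < 0 | tab$completeness > 100, na.rm = TRUE)) {
    stop("completeness must lie in [0, 100]", call. = FALSE)
  }
  if (any(tab$contamination < 0, na.rm = TRUE)) {
    stop("contamination must be non-negative", call. = FALSE)
  }
  tab[, c("species_id", "completeness", "contamination")]
}

#' Write a distance matrix
#'
#' Serializes a symmetric species distance matrix either as a square TSV
#' (header row and column of species IDs, six decimal places) or in square
#' PHYLIP format. Values survive a round trip to within 1e-6.
#'
#' @param matrix A [distance_matrix()] result (or symmetric numeric matrix
#'   with species IDs as dimnames).
#' @param path Output path.
#' @param format `"square_tsv"` or `"phylip_square"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(matrix, path,
                                  format = c("square_tsv", "phylip_square")) {
  format <- match.arg(format)
  m <- as.matrix(matrix)
  ids <- rownames(m)
  stopifnot(isSymmetric(unname(m)), all(abs(diag(m)) < 1e-12))

  fmt <- function(x) sprintf("%.6f", x)
  if (format == "square_tsv") {
    header <- paste(c("species_id", ids), collapse = "\t")
    rows <- vapply(seq_along(ids), function(i) {
      paste(c(ids[i], fmt(m[i, ])), collapse = "\t")
    }, character(1))
    writeLines(c(header, rows), path)
  } else {
    rows <- vapply(seq_along(ids), function(i) {
      paste(c(formatC(ids[i], width = 10, flag = "-"), fmt(m[i, ])),
        collapse = "  "
      )
    }, character(1))
    writeLines(c(sprintf("%5d", length(ids)), rows), path)
  }
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @inheritParams write_distance_matrix
#' @return A `domtax_dist` distance matrix (model labels unknown).
#' @export
read_distance_matrix <- function(path, format = c("square_tsv", "phylip_square")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "square_tsv") {
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    ids <- header[-1]
    body <- strsplit(lines[-1], "\t", fixed = TRUE)
  } else {
    n <- as.integer(trimws(lines[1]))
    body <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
    ids <- vapply(body, `[`, character(1), 1)
  }
  m <- do.call(rbind, lapply(body, function(f) as.numeric(f[-1])))
  dimnames(m) <- list(ids, ids)
  new_dist_matrix(m, statistical_model = NA_character_,
                  distance_model = NA_character_)
}

#' Export a spanning tree as a Cytoscape-importable JSON edge list
#'
#' Writes `nodes` (species ID plus lineage attributes, so a network viewer can
#' color by rank) and `edges` (source, target, numeric weight). Nodes missing
#' from the taxonomy are emitted with an empty lineage, with a warning.
#'
#' @param tree An `domtax_mst` tree from [build_mst_prim()].
#' @param taxonomy Taxonomy tibble from [read_taxonomy()] (or `NULL`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list_json <- function(tree, taxonomy = NULL, path) {
  stopifnot(inherits(tree, "domtax_mst"))
  ranks <- taxonomy_ranks()
  lineage_for <- function(id) {
    if (!is.null(taxonomy) && id %in% taxonomy$species_id) {
      row <- taxonomy[taxonomy$species_id == id, ranks]
      as.list(row[, !vapply(row, is.na, logical(1)), drop = FALSE])
    } else {
      stats::setNames(list(), character())
    }
  }
  if (!is.null(taxonomy)) {
    missing <- setdiff(tree$species_ids, taxonomy$species_id)
    if (length(missing) > 0L) {
      warning(
        "species without taxonomy record emitted with empty lineage: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
  }
  nodes <- lapply(tree$species_ids, function(id) {
    c(list(id = id), lineage_for(id))
  })
  edges <- purrr::pmap(tree$edges, function(from, to, weight) {
    list(source = from, target = to, weight = weight)
  })
  doc <- list(nodes = nodes, edges = edges)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an edge-list JSON written by [write_edge_list_json()]
#'
#' @param path Path to the JSON document.
#' @return A list with `nodes` (tibble of `id` and lineage columns) and
#'   `edges` (tibble `from`, `to`, `weight`).
#' @export
read_edge_list_json <- function(path) {
  doc <- jsonlite::read_json(path)
  nodes <- dplyr::bind_rows(lapply(doc$nodes, tibble::as_tibble))
  edges <- dplyr::bind_rows(lapply(doc$edges, function(e) {
    tibble::tibble(from = e$source, to = e$target, weight = as.numeric(e$weight))
  }))
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(from = character(), to = character(), weight = double())
  }
  list(nodes = nodes, edges = edges)
}

#' Write a per-taxon cluster report as TSV
#'
#' Fixed column order: `taxon`, `T` (species in the taxon), `n_groups`,
#' `S` (species isolated from the largest same-taxon group), `group_sizes`
#' (descending, comma-separated).
#'
#' @param report A `taxon_cluster_report` from [taxon_cluster_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(report, path) {
  counts <- tidy(report)
  out <- tibble::tibble(
    taxon = counts$taxon,
    T = counts$T,
    n_groups = counts$n_groups,
    S = counts$S,
    group_sizes = vapply(counts$group_sizes, paste, character(1), collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
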