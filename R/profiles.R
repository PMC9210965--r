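statistical_models <- function() {
  c("content", "organization", "f_content", "f_organization")
}

#' Resolve overlapping domain hits on one protein
#'
#' Pfam matches on a protein frequently overlap; the profile models require a
#' non-overlapping tiling. Hits are polished greedily by descending bit score:
#' a hit is kept iff its alignment interval shares no residue with any
#' already-kept hit. Ties in bit score break by lexicographically smaller
#' accession, then smaller `ali_start`, making the result deterministic and
#' independent of input row order.
#'
#' @param hits Tibble of hits (as from [read_domain_hits()]) all sharing one
#'   `protein_id`.
#' @return The kept hits, sorted by `ali_start`.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$protein_id)) != 1L) {
    stop("resolve_overlaps expects hits from a single protein", call. = FALSE)
  }
  ord <- order(-hits$bit_score, hits$domain_acc, hits$ali_start)
  h <- hits[ord, ]
  kept <- logical(nrow(h))
  # intervals are short (protein scale); quadratic scan is fine
  for (i in seq_len(nrow(h))) {
    ok <- TRUE
    for (j in which(kept)) {
      if (h$ali_start[i] <= h$ali_end[j] && h$ali_end[i] >= h$ali_start[j]) {
        ok <- FALSE
        break
      }
    }
    kept[i] <- ok
  }
  out <- h[kept, ]
  out[order(out$ali_start), ]
}

#' Assemble per-protein domain architectures
#'
#' Groups hits by protein, resolves overlaps within each protein
#' ([resolve_overlaps()]), and orders the surviving domains N-to-C by
#' alignment start. The architecture key joins accessions with `"|"`;
#' within-protein repeats are preserved (`"D1|D1|D2"` differs from
#' `"D1|D2"`), because domain order and multiplicity both carry signal under
#' the organization models.
#'
#' @param hits Tibble of hits, possibly spanning many proteins.
#' @return Tibble with one row per protein that retains at least one hit:
#'   `protein_id`, `architecture` (the `|`-joined key), `n_domains`.
#' @export
build_architectures <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble::tibble(
      protein_id = character(), architecture = character(),
      n_domains = integer()
    ))
  }
  hits |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(~ resolve_overlaps(dplyr::mutate(.x, protein_id = .y$protein_id))[
      , c("domain_acc", "ali_start")
    ]) |>
    dplyr::summarise(
      architecture = paste(.data$domain_acc, collapse = "|"),
      n_domains = dplyr::n(),
      .groups = "drop"
    )
}

#' Build a species profile under one statistical model
#'
#' The four models record a species' domainome at different resolutions:
#' \describe{
#'   \item{content}{the set of distinct domain accessions present anywhere}
#'   \item{organization}{the set of distinct protein architectures}
#'   \item{f_content}{accession -> number of occurrences across all proteins
#'     (within-protein repeats each count)}
#'   \item{f_organization}{architecture -> number of proteins bearing it}
#' }
#'
#' @param architectures Tibble from [build_architectures()] for one species.
#' @param model One of `"content"`, `"organization"`, `"f_content"`,
#'   `"f_organization"`.
#' @return A tibble of profile items: column `key`, plus `count` for the
#'   frequency models. Attribute `"model"` records the model. A species with
#'   no architectures yields an empty (zero-row) profile.
#' @examples
#' arch <- tibble::tibble(
#'   protein_id = c("p1", "p2", "p3"),
#'   architecture = c("D1|D2", "D1", "D1|D2"),
#'   n_domains = c(2L, 1L, 2L)
#' )
#' build_profile(arch, "f_content")
#' @export
build_profile <- function(architectures, model) {
  if (!is.character(model) || length(model) != 1L ||
      !model %in% statistical_models()) {
    stop(
      "unknown model; valid models: ",
      paste(statistical_models(), collapse = ", "),
      call. = FALSE
    )
  }
  keys <- switch(model,
    content = ,
    f_content = unlist(strsplit(architectures$architecture, "|", fixed = TRUE)),
    organization = ,
    f_organization = architectures$architecture
  )
  keys <- as.character(keys %||% character())
  prof <- if (model %in% c("content", "organization")) {
    tibble::tibble(key = sort(unique(keys)))
  } else {
    tab <- table(keys)
    tibble::tibble(
      key = names(tab) %||% character(),
      count = as.integer(tab)
    )[order(names(tab) %||% character()), ]
  }
  attr(prof, "model") <- model
  prof
}

#' Build profiles for many species at once
#'
#' @param architectures Tibble with columns `species_id`, `protein_id`,
#'   `architecture` (as produced per species by [build_architectures()], or by
#'   [simulate_domainomes()]).
#' @param model Statistical model name (see [build_profile()]).
#' @param species_ids Optional character vector fixing the species universe;
#'   species with no architectures get empty profiles (they are retained, not
#'   dropped, so downstream distances can apply the empty-profile rule).
#' @return A named list of per-species profile tibbles, with attribute
#'   `"model"`.
#' @export
build_profiles <- function(architectures, model,
                           species_ids = unique(architectures$species_id)) {
  split_arch <- split(architectures, architectures$species_id)
  profs <- lapply(species_ids, function(id) {
    a <- split_arch[[id]]
    if (is.null(a)) {
      a <- tibble::tibble(
        protein_id = character(), architecture = character(),
        n_domains = integer()
      )
    }
    build_profile(a, model)
  })
  names(profs) <- species_ids
  attr(profs, "model") <- model
  profs
}

#' Assembly quality score
#'
#' CheckM-style genome quality, `completeness - 5 * contamination`, on the
#' percent scale. The factor 5 penalizes contamination heavily relative to
#' missing marker genes; the score may be negative.
#'
#' @param completeness Percent in \[0, 100\].
#' @param contamination Percent, non-negative.
#' @return Numeric quality score (vectorized).
#' @examples
#' quality_score(100, 1) # 95
#' @export
quality_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100, na.rm = TRUE)) {
    stop("completeness must lie in [0, 100]", call. = FALSE)
  }
  if (any(contamination < 0, na.rm = TRUE)) {
    stop("contamination must be non-negative", call. = FALSE)
  }
  completeness - 5 * contamination
}

#' Filter assemblies by quality score
#'
#' Assemblies whose quality falls strictly under the threshold are flagged for
#' removal; a quality exactly at the threshold is kept.
#'
#' @param records Tibble with columns `species_id`, `completeness`,
#'   `contamination` (see [read_quality()]).
#' @param threshold Percent threshold, default 95.
#' @return The input tibble with added columns `quality` and `kept`, input
#'   order preserved.
#' @export
filter_by_quality <- function(records, threshold = 95) {
  q <- quality_score(records$completeness, records$contamination)
  dplyr::mutate(records, quality = q, kept = q >= threshold)
}
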