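#' Configuration for the domainome simulator
#'
#' Bundles and validates the generator's parameters. Defaults describe a
#' small but structured study: 4 taxa of 5 species, a root proteome of 120
#' domain-bearing proteins with architectures of mean length 2, and event
#' rates giving clear between-clade divergence (branch to a clade ancestor
#' 20 times the within-clade branch).
#'
#' @param n_taxa Number of clades (taxa) in the two-level tree.
#' @param species_per_taxon Leaves per clade.
#' @param root_n_proteins Proteins in the root domainome.
#' @param root_arch_length_mean Mean architecture length at the root
#'   (lengths are `1 + Poisson(mean - 1)`).
#' @param domain_alphabet_size Number of distinct synthetic domain
#'   accessions available.
#' @param gain_rate,loss_rate,duplication_rate,shuffle_rate Per-protein,
#'   per-unit-branch event probabilities in \[0, 1\]: gain adds a new random
#'   architecture, loss removes a protein, duplication copies one, shuffle
#'   permutes a protein's domain order (or swaps its single domain),
#'   perturbing organization profiles while leaving content largely intact.
#' @param between_taxon_branch Branch length root -> clade ancestor.
#' @param within_taxon_branch Branch length clade ancestor -> species; must
#'   not exceed `between_taxon_branch`.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_taxa = 4, species_per_taxon = 5,
                              root_n_proteins = 120,
                              root_arch_length_mean = 2,
                              domain_alphabet_size = 400,
                              gain_rate = 0.02, loss_rate = 0.02,
                              duplication_rate = 0.01, shuffle_rate = 0.02,
                              between_taxon_branch = 10,
                              within_taxon_branch = 0.5,
                              seed = 1L) {
  cfg <- list(
    n_taxa = as.integer(n_taxa),
    species_per_taxon = as.integer(species_per_taxon),
    root_n_proteins = as.integer(root_n_proteins),
    root_arch_length_mean = root_arch_length_mean,
    domain_alphabet_size = as.integer(domain_alphabet_size),
    gain_rate = gain_rate, loss_rate = loss_rate,
    duplication_rate = duplication_rate, shuffle_rate = shuffle_rate,
    between_taxon_branch = between_taxon_branch,
    within_taxon_branch = within_taxon_branch,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_taxa >= 1L, cfg$species_per_taxon >= 1L,
    cfg$root_n_proteins >= 1L, cfg$root_arch_length_mean >= 1,
    cfg$domain_alphabet_size >= 1L,
    cfg$between_taxon_branch >= cfg$within_taxon_branch,
    cfg$within_taxon_branch >= 0
  )
  rates <- c(cfg$gain_rate, cfg$loss_rate, cfg$duplication_rate, cfg$shuffle_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("event rates must lie in [0, 1]", call. = FALSE)
  }
  if (event_prob(cfg$loss_rate, cfg$between_taxon_branch) >= 1 &&
      cfg$gain_rate == 0) {
    stop("impossible config: certain loss with no gains empties every species",
      call. = FALSE
    )
  }
  structure(cfg, class = "simulation_config")
}

# per-protein event probability on a branch of length t
event_prob <- function(rate, t) min(1, rate * t)

random_architecture <- function(mean_len, alphabet) {
  len <- 1L + stats::rpois(1, mean_len - 1)
  paste(sample(alphabet, len, replace = TRUE), collapse = "|")
}

evolve_branch <- function(proteome, t, cfg, alphabet) {
  p_loss <- event_prob(cfg$loss_rate, t)
  p_dup <- event_prob(cfg$duplication_rate, t)
  p_shuf <- event_prob(cfg$shuffle_rate, t)
  p_gain <- event_prob(cfg$gain_rate, t)
  events <- c(loss = 0L, duplication = 0L, shuffle = 0L, gain = 0L)

  out <- character(0)
  for (arch in proteome) {
    if (stats::runif(1) < p_loss) {
      events["loss"] <- events["loss"] + 1L
      next
    }
    if (stats::runif(1) < p_shuf) {
      events["shuffle"] <- events["shuffle"] + 1L
      doms <- strsplit(arch, "|", fixed = TRUE)[[1]]
      if (length(doms) > 1L) {
        arch <- paste(sample(doms), collapse = "|")
      } else {
        arch <- sample(alphabet, 1) # single-domain protein: swap the domain
      }
    }
    out <- c(out, arch)
    if (stats::runif(1) < p_dup) {
      events["duplication"] <- events["duplication"] + 1L
      out <- c(out, arch)
    }
  }
  n_gain <- stats::rbinom(1, length(proteome), p_gain)
  if (n_gain > 0) {
    events["gain"] <- n_gain
    out <- c(out, replicate(
      n_gain,
      random_architecture(cfg$root_arch_length_mean, alphabet)
    ))
  }
  list(proteome = out, events = events)
}

#' Simulate species domainomes with known clade structure
#'
#' Generates a two-level tree (taxa as clades, species as leaves), draws a
#' root domainome, and evolves it along each branch with per-protein loss,
#' duplication, gain and domain-order shuffle events whose probabilities
#' scale with branch length. Because shuffles change a protein's domain order
#' but not its domain content, the four statistical models receive genuinely
#' different signals. The true clade labels are returned as ground truth, so
#' the whole pipeline can be validated end to end.
#'
#' @param config A [simulation_config()] (or arguments passed to it via
#'   `...`).
#' @param ... Used to build a config when `config` is missing.
#' @return A list with:
#'   \item{architectures}{tibble `species_id`, `protein_id`, `architecture`}
#'   \item{taxonomy}{tibble mapping `species_id` to its true taxon (column
#'     `phylum`; `species` holds the species ID)}
#'   \item{events}{tibble of per-branch event counts}
#'   \item{config}{the configuration used}
#' @export
simulate_domainomes <- function(config = simulation_config(...), ...) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  alphabet <- sprintf("SD%05d", seq_len(config$domain_alphabet_size))

  root <- replicate(
    config$root_n_proteins,
    random_architecture(config$root_arch_length_mean, alphabet)
  )

  taxa <- sprintf("taxon_%02d", seq_len(config$n_taxa))
  arch_rows <- list()
  event_rows <- list()
  taxonomy <- list()
  for (ti in seq_len(config$n_taxa)) {
    anc <- evolve_branch(root, config$between_taxon_branch, config, alphabet)
    event_rows[[length(event_rows) + 1L]] <- tibble::tibble(
      branch = paste0("root->", taxa[ti]),
      event = names(anc$events), count = unname(anc$events)
    )
    for (si in seq_len(config$species_per_taxon)) {
      sp_id <- sprintf("%s_sp%02d", taxa[ti], si)
      leaf <- evolve_branch(
        anc$proteome, config$within_taxon_branch, config, alphabet
      )
      event_rows[[length(event_rows) + 1L]] <- tibble::tibble(
        branch = paste0(taxa[ti], "->", sp_id),
        event = names(leaf$events), count = unname(leaf$events)
      )
      if (length(leaf$proteome) > 0L) {
        arch_rows[[length(arch_rows) + 1L]] <- tibble::tibble(
          species_id = sp_id,
          protein_id = sprintf("%s_p%04d", sp_id, seq_along(leaf$proteome)),
          architecture = leaf$proteome
        )
      }
      taxonomy[[length(taxonomy) + 1L]] <- tibble::tibble(
        species_id = sp_id, phylum = taxa[ti]
      )
    }
  }
  taxonomy <- dplyr::bind_rows(taxonomy)
  for (r in setdiff(taxonomy_ranks(), names(taxonomy))) {
    taxonomy[[r]] <- NA_character_
  }
  taxonomy$species <- taxonomy$species_id
  list(
    architectures = dplyr::bind_rows(arch_rows),
    taxonomy = taxonomy[, c("species_id", taxonomy_ranks())],
    events = dplyr::bind_rows(event_rows),
    config = config
  )
}

# deterministic synthetic bit score from a domain accession
synthetic_bit_score <- function(acc) {
  30 + (as.integer(sub("^SD", "", acc)) %% 970) / 10
}

#' Write a simulated domainome as an on-disk fixture
#'
#' Materializes a [simulate_domainomes()] result the way a real study's
#' inputs would arrive: one pfam_scan-style hit file per species (synthetic
#' coordinates laid left to right, non-overlapping unless decoys are
#' requested), a taxonomy TSV, and a CheckM-style quality TSV whose records
#' deliberately straddle the 95% quality threshold (at least one below, one
#' exactly at it) so the filter path is exercised.
#'
#' @param sim Result of [simulate_domainomes()].
#' @param dir Output directory (created if needed).
#' @param overlap_decoys If `TRUE`, each species' first multi-domain protein
#'   gets an extra lower-scoring decoy hit overlapping its first domain, so
#'   overlap resolution has real work to do; the decoy never survives, so
#'   round-tripping still reproduces the simulated architectures.
#' @return Invisibly, a list with `hit_files` (named by species), plus
#'   `taxonomy` and `quality` file paths.
#' @export
write_fixture <- function(sim, dir, overlap_decoys = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dom_len <- 100L
  gap <- 10L

  hit_files <- character(0)
  for (sp in unique(sim$architectures$species_id)) {
    rows <- sim$architectures[sim$architectures$species_id == sp, ]
    lines <- c(
      "# synthetic pfam_scan-style hits",
      "# <seq id> <ali start> <ali end> <env start> <env end> <hmm acc> <hmm name> <type> <hmm start> <hmm end> <hmm length> <bit score> <E-value> <significance> <clan>"
    )
    decoy_done <- FALSE
    for (k in seq_len(nrow(rows))) {
      doms <- strsplit(rows$architecture[k], "|", fixed = TRUE)[[1]]
      starts <- (seq_along(doms) - 1L) * (dom_len + gap) + 1L
      ends <- starts + dom_len - 1L
      scores <- synthetic_bit_score(doms)
      lines <- c(lines, sprintf(
        "%s %d %d %d %d %s.1 %s Domain 1 %d %d %.1f 1.0e-10 1 No_clan",
        rows$protein_id[k], starts, ends, starts, ends, doms, doms,
        dom_len, dom_len, scores
      ))
      if (overlap_decoys && !decoy_done && length(doms) > 1L) {
        # decoy overlapping the first domain, strictly lower score
        lines <- c(lines, sprintf(
          "%s %d %d %d %d %s.1 %s Domain 1 %d %d %.1f 1.0e-3 1 No_clan",
          rows$protein_id[k], starts[1] + 5L, ends[1] + 5L,
          starts[1] + 5L, ends[1] + 5L, "SD99999", "SD99999",
          dom_len, dom_len, scores[1] - 5
        ))
        decoy_done <- TRUE
      }
    }
    path <- file.path(dir, paste0(sp, ".pfamscan"))
    writeLines(lines, path)
    hit_files[sp] <- path
  }

  tax_path <- file.path(dir, "taxonomy.tsv")
  tax <- sim$taxonomy
  tax[is.na(tax)] <- ""
  readr::write_tsv(tax, tax_path, progress = FALSE)

  # quality table straddling the threshold: first species exactly at 95,
  # second clearly below, the rest comfortably above
  ids <- sim$taxonomy$species_id
  completeness <- rep(99.5, length(ids))
  contamination <- rep(0.5, length(ids))
  completeness[1] <- 95
  contamination[1] <- 0
  if (length(ids) >= 2L) {
    completeness[2] <- 90
    contamination[2] <- 2
  }
  qual_path <- file.path(dir, "quality.tsv")
  readr::write_tsv(
    tibble::tibble(
      species_id = ids,
      completeness = completeness,
      contamination = contamination
    ),
    qual_path,
    progress = FALSE
  )
  invisible(list(hit_files = hit_files, taxonomy = tax_path, quality = qual_path))
}
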