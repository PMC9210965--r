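# shared fixture builders; everything is generated in code

make_hits <- function(protein_id, ali_start, ali_end, domain_acc,
                      bit_score = 50, domain_name = domain_acc,
                      e_value = 1e-10) {
  tibble::tibble(
    protein_id = protein_id,
    domain_acc = domain_acc,
    domain_name = domain_name,
    ali_start = as.integer(ali_start),
    ali_end = as.integer(ali_end),
    bit_score = as.numeric(bit_score),
    e_value = e_value
  )
}

make_arch <- function(architectures,
                      protein_id = sprintf("p%03d", seq_along(architectures))) {
  tibble::tibble(
    protein_id = protein_id,
    architecture = architectures,
    n_domains = lengths(strsplit(architectures, "|", fixed = TRUE))
  )
}

pfam_scan_line <- function(protein, start, end, acc, name = acc, score = 50,
                           evalue = "1e-10", sep = " ") {
  paste(protein, start, end, start, end, acc, name, "Domain",
    1, end - start + 1, end - start + 1, score, evalue, 1, "No_clan",
    sep = sep
  )
}

write_pfam_scan_file <- function(lines, comments = "# header") {
  path <- withr::local_tempfile(
    fileext = ".txt",
    .local_envir = parent.frame()
  )
  writeLines(c(comments, lines), path)
  path
}

write_taxonomy_file <- function(tab) {
  path <- withr::local_tempfile(
    fileext = ".tsv",
    .local_envir = parent.frame()
  )
  tab[is.na(tab)] <- ""
  readr::write_tsv(tab, path, progress = FALSE)
  path
}

# random architecture table for one species
random_architectures <- function(n_proteins, alphabet = sprintf("D%02d", 1:10),
                                 max_len = 3) {
  archs <- vapply(seq_len(n_proteins), function(i) {
    paste(sample(alphabet, sample.int(max_len, 1), replace = TRUE),
      collapse = "|"
    )
  }, character(1))
  make_arch(archs)
}

# independent Jaccard oracle working on the raw key multisets, never on the
# (a, b, c) formula under test
jaccard_oracle <- function(keys_p, keys_q) {
  all_keys <- union(keys_p, keys_q)
  np <- table(factor(keys_p, levels = all_keys))
  nq <- table(factor(keys_q, levels = all_keys))
  inter <- sum(pmin(np, nq))
  uni <- sum(pmax(np, nq))
  if (uni == 0) 0 else 1 - inter / uni
}

# random symmetric distance matrix with zero diagonal
random_dist_matrix <- function(n, repeats = FALSE) {
  vals <- if (repeats) {
    sample(seq(0.1, 0.9, by = 0.1), n * (n - 1) / 2, replace = TRUE)
  } else {
    stats::runif(n * (n - 1) / 2)
  }
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  dimnames(m) <- list(sprintf("sp%02d", 1:n), sprintf("sp%02d", 1:n))
  m
}

kruskal_total_weight <- function(m) {
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  sum(igraph::E(igraph::mst(g))$weight)
}
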