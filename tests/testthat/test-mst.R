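triangle_matrix <- function(ab, ac, bc, ids = c("A", "B", "C")) {
  m <- matrix(c(0, ab, ac, ab, 0, bc, ac, bc, 0), 3,
    dimnames = list(ids, ids)
  )
  m
}

test_that("Prim recovers the unique minimum tree on a worked triangle", {
  # spanning trees: {AB,AC}=0.3, {AB,BC}=0.4, {AC,BC}=0.5
  tree <- build_mst_prim(triangle_matrix(0.1, 0.2, 0.3))
  expect_equal(tree$total_weight, 0.3)
  edges <- paste(tree$edges$from, tree$edges$to, sep = "-")
  expect_setequal(edges, c("A-B", "A-C"))

  two <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- build_mst_prim(two)
  expect_equal(nrow(t2$edges), 1)
  expect_equal(t2$edges$weight, 0.4)

  one <- matrix(0, 1, 1, dimnames = list("solo", "solo"))
  expect_equal(nrow(build_mst_prim(one)$edges), 0)

  asym <- triangle_matrix(0.1, 0.2, 0.3)
  asym[1, 2] <- 0.15
  expect_error(build_mst_prim(asym), "symmetric")
})

test_that("Prim total weight equals an independent Kruskal-style oracle", {
  skip_if_not_installed("igraph")
  withr::local_seed(33)
  for (rep in 1:40) {
    n <- sample(2:50, 1)
    m <- random_dist_matrix(n, repeats = rep %% 2 == 0)
    tree <- build_mst_prim(m)
    expect_equal(nrow(tree$edges), n - 1)
    expect_equal(tree$total_weight, kruskal_total_weight(m), tolerance = 1e-10)
  }
})

test_that("Prim tie-breaking is deterministic under row/column permutation", {
  withr::local_seed(34)
  m <- random_dist_matrix(12, repeats = TRUE)
  tree <- build_mst_prim(m)
  perm <- sample(nrow(m))
  tree2 <- build_mst_prim(m[perm, perm])
  e1 <- tree$edges[order(tree$edges$from, tree$edges$to), ]
  e2 <- tree2$edges[order(tree2$edges$from, tree2$edges$to), ]
  expect_equal(e1, e2)
})

path_tree <- function(ids, weights = rep(0.1, length(ids) - 1)) {
  domtax:::new_mst(
    sort(ids),
    tibble::tibble(
      from = ids[-length(ids)], to = ids[-1], weight = weights
    )
  )
}

simple_taxonomy <- function(ids, phyla) {
  tibble::tibble(
    species_id = ids, phylum = phyla, class = NA_character_,
    order = NA_character_, family = NA_character_, genus = NA_character_,
    species = ids
  )
}

test_that("clustering splits same-taxon species linked through another taxon", {
  # path A1 - A2 - B1 - A3: phylum A splits into {A1, A2} and {A3}
  tree <- path_tree(c("A1", "A2", "B1", "A3"))
  tax <- simple_taxonomy(c("A1", "A2", "B1", "A3"), c("A", "A", "B", "A"))
  groups <- cluster_by_taxon(tree, tax, "phylum")
  expect_equal(dplyr::n_distinct(groups$group), 3)
  ga <- groups$group[groups$species_id %in% c("A1", "A2")]
  expect_equal(ga[1], ga[2])
  expect_false(groups$group[groups$species_id == "A3"] %in% ga)

  counts <- isolation_counts(groups)
  expect_equal(counts$S[counts$taxon == "A"], 1)
  expect_equal(counts$T[counts$taxon == "A"], 3)
  expect_equal(counts$n_groups[counts$taxon == "A"], 2)
})

test_that("single-taxon trees form one group; hub-and-leaf taxa split", {
  tree <- path_tree(c("s1", "s2", "s3"))
  tax <- simple_taxonomy(c("s1", "s2", "s3"), rep("P", 3))
  groups <- cluster_by_taxon(tree, tax)
  expect_equal(dplyr::n_distinct(groups$group), 1)

  # star: center phylum A, two leaves phylum B -> 3 groups
  star <- domtax:::new_mst(
    c("a0", "b1", "b2"),
    tibble::tibble(from = c("a0", "a0"), to = c("b1", "b2"), weight = c(.1, .1))
  )
  tax <- simple_taxonomy(c("a0", "b1", "b2"), c("A", "B", "B"))
  groups <- cluster_by_taxon(star, tax)
  expect_equal(dplyr::n_distinct(groups$group), 3)
  counts <- isolation_counts(groups)
  expect_equal(counts$S[counts$taxon == "B"], 1)
})

test_that("clustering is invariant to node and edge ordering", {
  withr::local_seed(35)
  ids <- sprintf("n%02d", 1:10)
  tree <- path_tree(ids)
  tax <- simple_taxonomy(ids, sample(c("A", "B"), 10, replace = TRUE))
  base <- cluster_by_taxon(tree, tax)
  for (rep in 1:5) {
    shuf <- domtax:::new_mst(
      sample(tree$species_ids),
      tree$edges[sample(nrow(tree$edges)), ]
    )
    got <- cluster_by_taxon(shuf, tax)
    expect_equal(
      got[order(got$species_id), c("species_id", "group")],
      base[order(base$species_id), c("species_id", "group")]
    )
  }
})

test_that("species lacking the rank become singletons; bad ranks error", {
  tree <- path_tree(c("x1", "x2"))
  tax <- simple_taxonomy(c("x1", "x2"), c("A", NA))
  groups <- cluster_by_taxon(tree, tax, "phylum")
  expect_equal(dplyr::n_distinct(groups$group), 2)
  expect_match(groups$taxon[groups$species_id == "x2"], "unassigned")

  expect_error(cluster_by_taxon(tree, tax, "kingdom"), "rank must be one of")
})

test_that("isolation counts and metrics reproduce hand-computed values", {
  # taxon A groups [4, 1], taxon B intact [3]
  groups <- tibble::tibble(
    species_id = sprintf("s%d", 1:8),
    taxon = c(rep("A", 5), rep("B", 3)),
    group = c(1, 1, 1, 1, 2, 3, 3, 3)
  )
  counts <- isolation_counts(groups)
  expect_equal(counts$S, c(1, 0))
  expect_equal(counts$T, c(5, 3))
  expect_equal(counts$group_sizes[[1]], c(4, 1))

  metrics <- agreement_metrics(counts)
  expect_equal(metrics$arithmetic_percentage, 1 / 8)
  expect_equal(metrics$weighted_percentage, (0.2 + 0) / 2)
  expect_equal(metrics$split_taxon_count, 1)

  # tie case: groups [2, 2] -> S = 2 whichever is "main"
  tie <- tibble::tibble(
    species_id = sprintf("t%d", 1:4), taxon = "A", group = c(1, 1, 2, 2)
  )
  expect_equal(isolation_counts(tie)$S, 2)

  # fully split singleton taxon: arithmetic = weighted = (k-1)/k
  k <- 6
  split <- tibble::tibble(
    species_id = sprintf("u%d", 1:k), taxon = "Z", group = 1:k
  )
  m <- agreement_metrics(isolation_counts(split))
  expect_equal(m$arithmetic_percentage, (k - 1) / k)
  expect_equal(m$weighted_percentage, (k - 1) / k)
  expect_equal(m$split_taxon_count, 1)

  perfect <- agreement_metrics(
    isolation_counts(tibble::tibble(
      species_id = c("a", "b"), taxon = c("A", "B"), group = c(1, 2)
    ))
  )
  expect_equal(perfect$arithmetic_percentage, 0)
  expect_equal(perfect$weighted_percentage, 0)
  expect_equal(perfect$split_taxon_count, 0)
})

test_that("metric identities hold on randomized partitions", {
  withr::local_seed(36)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    groups <- tibble::tibble(
      species_id = sprintf("r%03d", 1:n),
      taxon = sample(LETTERS[1:4], n, replace = TRUE),
      group = sample(1:6, n, replace = TRUE)
    )
    # make group ids taxon-specific so groups never span taxa
    groups$group <- as.integer(factor(paste(groups$taxon, groups$group)))
    counts <- isolation_counts(groups)
    expect_equal(sum(counts$T), n)
    expect_equal(sum(unlist(counts$group_sizes)), n)
    expect_true(all(
      vapply(counts$group_sizes, function(s) s[1], double(1)) ==
        counts$T - counts$S
    ))
    m <- agreement_metrics(counts)
    expect_equal(m$arithmetic_percentage, sum(counts$S) / sum(counts$T))
    expect_equal(m$weighted_percentage, mean(counts$S / counts$T))
    expect_true(m$arithmetic_percentage >= 0 && m$arithmetic_percentage <= 1)
    expect_true(m$weighted_percentage >= 0 && m$weighted_percentage <= 1)
    expect_equal(
      m$split_taxon_count == 0,
      m$arithmetic_percentage == 0 && m$weighted_percentage == 0
    )
  }
})

test_that("model combinations enumerate the full 4 x 3 cross product", {
  combos <- model_combinations()
  expect_equal(nrow(combos), 12)
  expect_equal(anyDuplicated(combos$label), 0)
  expect_true("org_ja" %in% combos$label)
  expect_setequal(unique(combos$statistical_model),
                  c("content", "organization", "f_content", "f_organization"))
  expect_setequal(unique(combos$distance_model),
                  c("jaccard", "poisson", "loss_corrected"))
})

test_that("tidy and glance expose edges, counts and the metric row", {
  tree <- build_mst_prim(triangle_matrix(0.1, 0.2, 0.3))
  expect_equal(nrow(tidy(tree)), 2)
  g <- glance(tree)
  expect_equal(g$n_species, 3)
  expect_equal(g$total_weight, 0.3)

  tax <- simple_taxonomy(c("A", "B", "C"), c("P", "P", "Q"))
  report <- taxon_cluster_report(tree, tax, "phylum")
  expect_equal(nrow(tidy(report)), 2)
  expect_equal(glance(report)$split_taxon_count, 0)
  expect_equal(glance(report)$rank, "phylum")
})
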