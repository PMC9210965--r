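test_that("overlap resolution keeps the maximal-score non-overlapping tiling", {
  # B outscores the overlapping A
  h <- make_hits(
    "p1", c(1, 50), c(100, 150), c("PFA", "PFB"), bit_score = c(50, 80)
  )
  kept <- resolve_overlaps(h)
  expect_equal(kept$domain_acc, "PFB")

  # disjoint intervals both survive, sorted by start
  h <- make_hits("p1", c(60, 1), c(100, 50), c("PFB", "PFA"), bit_score = c(10, 5))
  expect_equal(resolve_overlaps(h)$domain_acc, c("PFA", "PFB"))

  # score tie broken by lexicographically smaller accession
  h <- make_hits(
    "p1", c(1, 40), c(50, 90), c("PF00002", "PF00001"), bit_score = c(10, 10)
  )
  expect_equal(resolve_overlaps(h)$domain_acc, "PF00001")

  expect_error(
    resolve_overlaps(make_hits(c("p1", "p2"), c(1, 1), c(5, 5), "PFA")),
    "single protein"
  )
})

test_that("resolved hits never share a residue and match an independent greedy", {
  greedy_oracle <- function(h) {
    h <- h[order(-h$bit_score, h$domain_acc, h$ali_start), ]
    kept <- h[0, ]
    for (i in seq_len(nrow(h))) {
      overlaps <- any(
        h$ali_start[i] <= kept$ali_end & h$ali_end[i] >= kept$ali_start
      )
      if (!isTRUE(overlaps)) kept <- rbind(kept, h[i, ])
    }
    kept[order(kept$ali_start), ]
  }
  withr::local_seed(101)
  for (rep in 1:30) {
    n <- sample(1:6, 1)
    start <- sample(1:200, n)
    h <- make_hits(
      "p1", start, start + sample(10:120, n, replace = TRUE),
      sprintf("PF%05d", sample(1:20, n, replace = TRUE)),
      bit_score = sample(seq(10, 60, 5), n, replace = TRUE)
    )
    kept <- resolve_overlaps(h)
    # no shared residues, exhaustively
    if (nrow(kept) > 1) {
      for (i in 1:(nrow(kept) - 1)) {
        expect_lt(kept$ali_end[i], kept$ali_start[i + 1])
      }
    }
    expect_equal(kept$domain_acc, greedy_oracle(h)$domain_acc)
    expect_equal(kept$ali_start, greedy_oracle(h)$ali_start)
    # input order never matters
    shuffled <- h[sample(nrow(h)), ]
    expect_equal(resolve_overlaps(shuffled), kept)
  }
})

test_that("greedy resolution is valid, maximal, and bounded by the exhaustive optimum", {
  best_subset_score <- function(h) {
    n <- nrow(h)
    best <- 0
    for (mask in 0:(2^n - 1)) {
      sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      if (length(sel) > 1) {
        ok <- TRUE
        for (i in seq_along(sel)[-1]) {
          for (j in seq_len(i - 1)) {
            if (h$ali_start[sel[i]] <= h$ali_end[sel[j]] &&
                h$ali_end[sel[i]] >= h$ali_start[sel[j]]) {
              ok <- FALSE
            }
          }
        }
        if (!ok) next
      }
      best <- max(best, sum(h$bit_score[sel]))
    }
    best
  }
  withr::local_seed(103)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    start <- sample(1:150, n)
    h <- make_hits(
      "p1", start, start + sample(20:100, n, replace = TRUE),
      sprintf("PF%05d", seq_len(n)),
      bit_score = round(stats::runif(n, 10, 80), 1)
    )
    kept <- resolve_overlaps(h)
    expect_lte(sum(kept$bit_score), best_subset_score(h) + 1e-9)
    # maximality: no discarded hit fits into the kept tiling
    for (i in setdiff(seq_len(n), match(kept$domain_acc, h$domain_acc))) {
      expect_true(any(
        h$ali_start[i] <= kept$ali_end & h$ali_end[i] >= kept$ali_start
      ))
    }
  }
})

test_that("architectures order domains N-to-C and group by protein", {
  h <- dplyr::bind_rows(
    make_hits("p1", c(80, 10), c(120, 60), c("D2", "D1"), bit_score = c(30, 40)),
    make_hits("p2", 5, 45, "D1"),
    make_hits("p3", 5, 45, "D1")
  )
  arch <- build_architectures(h)
  expect_equal(arch$architecture[arch$protein_id == "p1"], "D1|D2")
  expect_equal(sum(arch$architecture == "D1"), 2)

  empty <- build_architectures(make_hits(character(), integer(), integer(), character()))
  expect_equal(nrow(empty), 0)
})

test_that("the four statistical models record the expected profile items", {
  arch <- make_arch(c("D1|D2", "D1", "D1|D2"))

  content <- build_profile(arch, "content")
  expect_equal(content$key, c("D1", "D2"))
  expect_false("count" %in% names(content))

  organization <- build_profile(arch, "organization")
  expect_equal(organization$key, c("D1", "D1|D2"))

  f_content <- build_profile(arch, "f_content")
  expect_equal(
    tibble::deframe(f_content), c(D1 = 3L, D2 = 2L)
  )

  f_organization <- build_profile(arch, "f_organization")
  expect_equal(
    tibble::deframe(f_organization), c(D1 = 1L, `D1|D2` = 2L)
  )

  expect_error(build_profile(arch, "both"), "valid models")
})

test_that("within-protein repeats count in f_content and keep distinct keys", {
  arch <- make_arch(c("D1|D1|D2", "D1|D2"))
  f_content <- build_profile(arch, "f_content")
  expect_equal(tibble::deframe(f_content), c(D1 = 3L, D2 = 2L))
  organization <- build_profile(arch, "organization")
  expect_equal(organization$key, c("D1|D1|D2", "D1|D2"))
})

test_that("profile size identities hold on random species", {
  withr::local_seed(7)
  for (rep in 1:10) {
    arch <- random_architectures(n_proteins = sample(5:30, 1))
    content <- build_profile(arch, "content")
    f_content <- build_profile(arch, "f_content")
    organization <- build_profile(arch, "organization")
    f_organization <- build_profile(arch, "f_organization")

    expect_lte(nrow(content), sum(f_content$count))
    expect_lte(nrow(organization), nrow(arch))
    expect_equal(sum(f_organization$count), nrow(arch))
    expect_setequal(
      content$key,
      unique(unlist(strsplit(arch$architecture, "|", fixed = TRUE)))
    )
  }
})

test_that("species with zero hits get an empty, retained profile", {
  empty_arch <- make_arch(character(0), protein_id = character(0))
  prof <- build_profile(empty_arch, "f_organization")
  expect_equal(nrow(prof), 0)
  expect_equal(attr(prof, "model"), "f_organization")

  profs <- build_profiles(
    tibble::tibble(
      species_id = "sp1", protein_id = "p1", architecture = "D1"
    ),
    "content",
    species_ids = c("sp1", "sp2")
  )
  expect_equal(nrow(profs$sp2), 0)
  expect_named(profs, c("sp1", "sp2"))
})

test_that("quality score and threshold filter follow the CheckM rule", {
  expect_equal(quality_score(100, 1), 95)
  expect_equal(quality_score(96, 0), 96)
  expect_equal(quality_score(99, 1), 94)
  expect_error(quality_score(101, 0), "completeness")
  expect_error(quality_score(90, -1), "contamination")

  records <- tibble::tibble(
    species_id = c("a", "b", "c", "d"),
    completeness = c(100, 99, 96, 95),
    contamination = c(1, 1, 0, 0)
  )
  decisions <- filter_by_quality(records)
  expect_equal(decisions$kept, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(decisions$quality, c(95, 94, 96, 95))
  expect_equal(decisions$species_id, records$species_id) # order preserved

  none <- filter_by_quality(records[0, ])
  expect_equal(nrow(none), 0)
})
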