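distance_models <- function() {
  c("jaccard", "poisson", "loss_corrected")
}

#' Overlap triple for a pair of species profiles
#'
#' Computes the `(a, b, c)` triple that feeds every distance model: `a` and
#' `b` are the profile sizes of the two species and `c` the shared part. For
#' the set models (content, organization) these are set cardinalities; for
#' the frequency models they are multiset totals with elementwise-minimum
#' sharing, the canonical multiset generalization of the set semantics.
#'
#' @param p,q Profile tibbles from [build_profile()], built under the same
#'   statistical model.
#' @return One-row tibble with columns `a`, `b`, `c`, `model`.
#' @examples
#' arch <- function(ids, keys) tibble::tibble(
#'   protein_id = ids, architecture = keys, n_domains = 1L
#' )
#' p <- build_profile(arch(c("p1", "p2"), c("x", "y")), "content")
#' q <- build_profile(arch(c("p1", "p2"), c("y", "z")), "content")
#' profile_overlap(p, q) # a = 2, b = 2, c = 1
#' @export
profile_overlap <- function(p, q) {
  mp <- attr(p, "model")
  mq <- attr(q, "model")
  if (is.null(mp) || is.null(mq) || mp != mq) {
    stop("profiles must be built under the same statistical model", call. = FALSE)
  }
  if (mp %in% c("content", "organization")) {
    a <- nrow(p)
    b <- nrow(q)
    c_ <- length(intersect(p$key, q$key))
  } else {
    a <- sum(p$count)
    b <- sum(q$count)
    shared <- dplyr::inner_join(p, q, by = "key", suffix = c("_p", "_q"))
    c_ <- sum(pmin(shared$count_p, shared$count_q))
  }
  tibble::tibble(a = as.integer(a), b = as.integer(b), c = as.integer(c_),
                 model = mp)
}

# accept either an overlap tibble/data.frame or bare numeric vectors
overlap_abc <- function(a, b, c) {
  if (is.data.frame(a)) {
    list(a = a$a, b = a$b, c = a$c)
  } else {
    list(a = a, b = b, c = c)
  }
}

check_abc <- function(a, b, c) {
  if (any(a < 0 | b < 0 | c < 0) || any(c > pmin(a, b))) {
    stop("overlap triple requires 0 <= c <= min(a, b)", call. = FALSE)
  }
}

#' Jaccard distance from an overlap triple
#'
#' `1 - c / (a + b - c)`, the fraction of the profile union not shared.
#' Assumes domain changes (mutation, loss, recombination) strike randomly and
#' independently. Two empty profiles are defined as identical (distance 0,
#' with a warning).
#'
#' @param a Overlap tibble from [profile_overlap()], or the size of profile A.
#' @param b,c Sizes of profile B and of the shared part (ignored when `a` is
#'   an overlap tibble). Vectorized.
#' @return Distance(s) in \[0, 1\].
#' @export
jaccard_distance <- function(a, b = NULL, c = NULL) {
  o <- overlap_abc(a, b, c)
  check_abc(o$a, o$b, o$c)
  denom <- o$a + o$b - o$c
  if (any(denom == 0)) {
    warning("two empty profiles: Jaccard distance defined as 0", call. = FALSE)
  }
  ifelse(denom == 0, 0, (o$a + o$b - 2 * o$c) / denom)
}

#' Poisson distance from an overlap triple
#'
#' Models domain change as a Poisson process: `-ln(c/a)` and `-ln(c/b)` are
#' the distances of the two species to their common ancestor and the species
#' distance is their geometric mean, `sqrt(ln(a/c) * ln(b/c))`. The raw
#' expression is unbounded as `c -> 0`; to keep the documented \[0, 1\] range
#' the value is clamped at 1 and `c = 0` maps to 1. Empty profiles follow the
#' empty-profile rule: distance 1 against a non-empty profile, 0 against
#' another empty one (with a warning).
#'
#' @inheritParams jaccard_distance
#' @return Distance(s) in \[0, 1\].
#' @export
poisson_distance <- function(a, b = NULL, c = NULL) {
  o <- overlap_abc(a, b, c)
  check_abc(o$a, o$b, o$c)
  empty <- o$a == 0 | o$b == 0
  if (any(empty)) {
    warning("empty profile in Poisson distance: applying empty-profile rule",
      call. = FALSE
    )
  }
  raw <- ifelse(
    o$c == 0,
    1,
    pmin(1, sqrt(log(o$a / o$c) * log(o$b / o$c)))
  )
  ifelse(empty, ifelse(o$a == 0 & o$b == 0, 0, 1), raw)
}

#' Loss-corrected distance from an overlap triple
#'
#' `1 - c / min(a, b)`: the smaller profile is the comparison standard, so a
#' lineage that lost much of its domainome is not pushed away from its
#' relatives by the loss alone. Empty profiles follow the empty-profile rule
#' (see [poisson_distance()]).
#'
#' @inheritParams jaccard_distance
#' @return Distance(s) in \[0, 1\].
#' @export
loss_corrected_distance <- function(a, b = NULL, c = NULL) {
  o <- overlap_abc(a, b, c)
  check_abc(o$a, o$b, o$c)
  m <- pmin(o$a, o$b)
  if (any(m == 0)) {
    warning(
      "empty profile in loss-corrected distance: applying empty-profile rule",
      call. = FALSE
    )
  }
  ifelse(m == 0, ifelse(o$a == 0 & o$b == 0, 0, 1), 1 - o$c / m)
}

distance_fun <- function(distance_model) {
  switch(match.arg(distance_model, distance_models()),
    jaccard = jaccard_distance,
    poisson = poisson_distance,
    loss_corrected = loss_corrected_distance
  )
}

new_dist_matrix <- function(values, statistical_model, distance_model) {
  structure(
    list(
      species_ids = rownames(values),
      values = values,
      statistical_model = statistical_model,
      distance_model = distance_model
    ),
    class = "domtax_dist"
  )
}

#' Pairwise species distance matrix
#'
#' Evaluates one distance model over every pair of species profiles,
#' producing a symmetric matrix with zero diagonal and values in \[0, 1\].
#'
#' @param profiles Named list of per-species profiles from
#'   [build_profiles()] (names are species IDs).
#' @param distance_model `"jaccard"`, `"poisson"` or `"loss_corrected"`.
#' @return A `domtax_dist` object; use `as.matrix()` for the raw matrix and
#'   [tidy()][generics::tidy] for a long pair table.
#' @export
distance_matrix <- function(profiles, distance_model) {
  distance_model <- match.arg(distance_model, distance_models())
  ids <- names(profiles)
  if (is.null(ids) || length(ids) < 2L) {
    stop("need a named list of at least 2 species profiles", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate species_id among profiles: ",
      ids[duplicated(ids)][1],
      call. = FALSE
    )
  }
  fun <- distance_fun(distance_model)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      o <- profile_overlap(profiles[[i]], profiles[[j]])
      d <- suppressWarnings(fun(o))
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  new_dist_matrix(m, attr(profiles, "model"), distance_model)
}

#' @export
as.matrix.domtax_dist <- function(x, ...) x$values

#' @export
print.domtax_dist <- function(x, ...) {
  cat(
    "<domtax_dist> ", length(x$species_ids), " species, ",
    x$statistical_model, " x ", x$distance_model, "\n",
    sep = ""
  )
  print(utils::head(round(x$values, 4), 6))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a distance matrix into a long pair table
#'
#' @param x A `domtax_dist` object.
#' @param ... Unused.
#' @return Tibble with one row per unordered species pair: `from`, `to`,
#'   `distance`, `statistical_model`, `distance_model`.
#' @method tidy domtax_dist
#' @export
tidy.domtax_dist <- function(x, ...) {
  ids <- x$species_ids
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    from = ids[idx[, 1]],
    to = ids[idx[, 2]],
    distance = x$values[idx],
    statistical_model = x$statistical_model,
    distance_model = x$distance_model
  )
}

#' Enumerate all statistical x distance model combinations
#'
#' The four statistical models crossed with the three distance models give
#' twelve candidate pipelines. Labels follow the con/org/f_con/f_org x
#' ja/po/lo scheme (e.g. `"org_ja"` for organization + Jaccard).
#'
#' @return Tibble with columns `statistical_model`, `distance_model`, `label`
#'   (12 rows, deterministic order).
#' @export
model_combinations <- function() {
  short_stat <- c(
    content = "con", organization = "org",
    f_content = "f_con", f_organization = "f_org"
  )
  short_dist <- c(jaccard = "ja", poisson = "po", loss_corrected = "lo")
  grid <- tidyr::expand_grid(
    statistical_model = statistical_models(),
    distance_model = distance_models()
  )
  dplyr::mutate(
    grid,
    label = paste(
      short_stat[.data$statistical_model],
      short_dist[.data$distance_model],
      sep = "_"
    )
  )
}
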