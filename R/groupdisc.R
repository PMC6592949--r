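#' Cliff's Delta effect size between two samples
#'
#' Exact pair-count semantics: \deqn{\delta = (\#\{x > y\} - \#\{x < y\}) /
#' (n_a n_b)} over all cross pairs \eqn{(x, y)} with \eqn{x} from `a` and
#' \eqn{y} from `b`; ties contribute 0. \eqn{\delta \in [-1, 1]}, is
#' antisymmetric in its arguments, and depends only on ranks (it is invariant
#' under any strictly increasing transform applied to both samples).
#'
#' Computed via sorted-sample counting (O((n+m) log(n+m))), equivalent to
#' brute-force enumeration over all pairs.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A single number in \[-1, 1\].
#' @examples
#' cliffs_delta(c(1, 2, 3), c(2, 3, 4)) # -5/9
#' @export
cliffs_delta <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    abort_data("Cliff's Delta requires two non-empty samples.")
  }
  check_finite_values(a, "sample")
  check_finite_values(b, "sample")
  sb <- sort(b)
  n_le <- findInterval(a, sb)                    # b values <= x
  n_lt <- findInterval(a, sb, left.open = TRUE)  # b values <  x
  n_gt <- length(b) - n_le
  (sum(n_lt) - sum(n_gt)) / (length(a) * length(b))
}

#' Pairwise Cliff's Delta matrix for a cohort of interval samples
#'
#' Builds the signed Cliff's Delta matrix between all pairs of animals and the
#' derived distance matrix `|delta|` used for clustering. The signed value is
#' antisymmetric with a zero diagonal; its magnitude is the between-animal
#' distance (high similarity = low distance).
#'
#' @param ici Long data frame with columns `animal` and `interval` (and
#'   optionally `group`), e.g. rows from [breath_ici()] across animals.
#' @return An object of class `delta_matrix`: list with `animals` (ids, in
#'   first-appearance order), `groups` (or NULL), `delta` (signed n x n
#'   matrix) and `distance` (`abs(delta)`). Has [tidy()] and
#'   [ggplot2::autoplot()] methods.
#' @export
delta_matrix <- function(ici) {
  if (!is.data.frame(ici) || !all(c("animal", "interval") %in% names(ici))) {
    abort_data("`ici` must be a data frame with `animal` and `interval` columns.")
  }
  ids <- unique(ici$animal)
  if (length(ids) < 2L) abort_data("Need at least 2 animals.")
  samples <- lapply(ids, function(id) ici$interval[ici$animal == id])
  names(samples) <- as.character(ids)
  empty <- ids[vapply(samples, length, integer(1)) == 0L]
  if (length(empty) > 0L) {
    abort_data(sprintf("Animal `%s` has an empty interval sample.", empty[1L]))
  }
  n <- length(ids)
  delta <- matrix(0, n, n, dimnames = list(as.character(ids), as.character(ids)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- cliffs_delta(samples[[i]], samples[[j]])
      delta[i, j] <- d
      delta[j, i] <- -d
    }
  }
  groups <- NULL
  if ("group" %in% names(ici)) {
    groups <- unname(vapply(ids, function(id) as.character(ici$group[ici$animal == id][1L]),
                            character(1)))
  }
  structure(
    list(animals = ids, groups = groups, delta = delta, distance = abs(delta)),
    class = "delta_matrix"
  )
}

#' @export
print.delta_matrix <- function(x, ...) {
  cat(sprintf("<delta_matrix> %d animals; mean |delta| = %.3f\n",
              length(x$animals), mean(x$distance[upper.tri(x$distance)])))
  invisible(x)
}

#' @rdname delta_matrix
#' @param x A `delta_matrix`.
#' @param ... Unused.
#' @method tidy delta_matrix
#' @export
tidy.delta_matrix <- function(x, ...) {
  expand <- expand.grid(animal_a = x$animals, animal_b = x$animals,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble(
    animal_a = expand$animal_a,
    animal_b = expand$animal_b,
    delta = as.vector(x$delta),
    distance = as.vector(x$distance)
  )
}

# Cosine distance between the rows of a non-negative matrix.
cosine_distance_rows <- function(m) {
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) {
    abort_data(paste0(
      "Degenerate input: at least one animal has an all-zero distance profile, ",
      "so the cosine distance is undefined."
    ))
  }
  sim <- (m %*% t(m)) / outer(norms, norms)
  d <- 1 - sim
  d[d < 0] <- 0 # clip floating-point residue
  diag(d) <- 0
  d
}

#' Hierarchically cluster animals on their Cliff's Delta profiles
#'
#' Each animal is represented by its row of the `|delta|` distance matrix (its
#' distance profile to every animal, diagonal included); animals are
#' agglomeratively clustered on the cosine distance between these profiles and
#' the tree is cut at `k` clusters. The default `k = 3` matches a design with
#' three nominal experimental groups.
#'
#' @param dm A [delta_matrix()].
#' @param k Number of clusters to cut the tree into (2 <= k <= n).
#' @param linkage Agglomeration rule: `"average"` (default), `"complete"`,
#'   `"single"`, or `"ward"` (Ward.D2 on a classical MDS embedding of the
#'   cosine distances, since Ward assumes Euclidean geometry).
#' @return An object of class `cluster_result`: list with `labels` (tibble:
#'   `animal`, `cluster`), `k`, `hclust` (the tree, for merge heights),
#'   `cosine` (the pairwise cosine-distance matrix) and `groups` (true group
#'   per animal if known). Deterministic given its input.
#' @export
cluster_animals <- function(dm, k = 3L, linkage = c("average", "complete", "single", "ward")) {
  if (!inherits(dm, "delta_matrix")) abort_param("`dm` must be a `delta_matrix`.")
  linkage <- match.arg(linkage)
  n <- length(dm$animals)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) abort_param("`k` must be an integer >= 2.")
  if (k > n) abort_param(sprintf("`k` = %d exceeds the number of animals (%d).", k, n))
  cd <- cosine_distance_rows(dm$distance)
  if (linkage == "ward") {
    emb <- cmdscale(as.dist(cd), k = max(1L, n - 2L))
    tree <- hclust(dist(emb), method = "ward.D2")
  } else {
    tree <- hclust(as.dist(cd), method = linkage)
  }
  labels <- cutree(tree, k = k)
  structure(
    list(
      labels = tibble(animal = dm$animals, cluster = unname(labels)),
      k = k,
      hclust = tree,
      cosine = cd,
      groups = dm$groups
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  sizes <- table(x$labels$cluster)
  cat(sprintf("<cluster_result> k = %d; cluster sizes: %s\n",
              x$k, paste(sizes, collapse = ", ")))
  invisible(x)
}

#' @rdname cluster_animals
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  out <- x$labels
  if (!is.null(x$groups)) out$group <- x$groups
  out
}

#' @rdname cluster_animals
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(
    k = x$k,
    n_animals = nrow(x$labels),
    n_populated = length(unique(x$labels$cluster)),
    max_merge_height = max(x$hclust$height)
  )
}

#' Exact binomial significance of cluster composition
#'
#' Tests, for each true experimental group, whether the number of its animals
#' landing in a single cluster exceeds what random classification would give.
#' Under random assignment with `n_choices` equally likely clusters, the count
#' `c` of a group's `n` animals in any designated cluster is Binomial(n,
#' 1/n_choices); the reported p-value is the exact upper tail `P(X >= c)` for
#' the group's majority cluster (the cluster holding most of its animals; count
#' ties give identical tails).
#'
#' The success probability defaults to 1/3 — a design with three possible
#' choices — independent of the `k` actually used; set
#' `p_success = 1/result$k` to tie it to the cut.
#'
#' @param result A `cluster_result` from [cluster_animals()].
#' @param groups True group label per animal: either a vector aligned with the
#'   clustering's animal order, or NULL to use the groups recorded in `result`.
#' @param n_choices Number of equally likely choices under random
#'   classification (default 3).
#' @return A tibble with one row per group: `group`, `n`, `majority_cluster`,
#'   `n_majority`, `p_value`.
#' @export
cluster_significance <- function(result, groups = NULL, n_choices = 3) {
  if (!inherits(result, "cluster_result")) abort_param("`result` must be a `cluster_result`.")
  if (is.null(groups)) groups <- result$groups
  if (is.null(groups)) abort_data("No true group labels available.")
  labels <- result$labels$cluster
  if (length(groups) != length(labels)) {
    abort_data("`groups` must have one label per clustered animal.")
  }
  check_scalar_num(n_choices, "n_choices", positive = TRUE)
  p <- 1 / n_choices
  purrr::map_dfr(unique(groups), function(g) {
    in_g <- groups == g
    n <- sum(in_g)
    if (n == 0L) abort_data(sprintf("Group `%s` is empty.", g))
    counts <- table(labels[in_g])
    c_max <- max(counts)
    maj <- as.integer(names(counts)[which.max(counts)])
    tibble(
      group = g,
      n = n,
      majority_cluster = maj,
      n_majority = as.integer(c_max),
      p_value = pbinom(c_max - 1, size = n, prob = p, lower.tail = FALSE)
    )
  })
}
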