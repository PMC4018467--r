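# Grouping construction and concordance: hierarchical clustering of
# compression distances, distance-based (neighbour-joining) trees with
# bootstrap support for the alignable sectors, and comparison of the
# groupings the different gene sectors induce.

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with single or complete linkage (the two
#' methods used for the published STR trees). A thin validation wrapper
#' over [stats::hclust()].
#'
#' @param d A `dist` object or symmetric numeric matrix with zero
#'   diagonal.
#' @param linkage `"complete"` (default, as in the published STR figure)
#'   or `"single"`.
#' @return An `hclust` object.
#' @export
str_hclust <- function(d, linkage = c("complete", "single")) {
  linkage <- match.arg(linkage)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)) || any(diag(d) != 0)) {
      stop("distance matrix must be symmetric with zero diagonal",
           call. = FALSE)
    }
    d <- as.dist(d)
  }
  stopifnot(inherits(d, "dist"), attr(d, "Size") >= 2L)
  hclust(d, method = linkage)
}

#' Uncorrected p-distance of an alignment
#'
#' Proportion of differing comparable columns per pair, with pairwise
#' deletion of gap/N columns; computed via [ape::dist.dna()] with
#' `model = "raw"`.
#'
#' @param alignment Character matrix, named character vector or `DNAbin`.
#' @return A `dist` object.
#' @export
p_distance <- function(alignment) {
  m <- as_alignment_matrix(alignment)
  ape::dist.dna(ape::as.DNAbin(tolower(m)), model = "raw",
                pairwise.deletion = TRUE)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Canonical neighbour joining via [ape::nj()]. On an additive distance
#' matrix the generating topology and branch lengths are recovered
#' exactly.
#'
#' @param d A `dist` object or symmetric numeric matrix (>= 3 labels; >= 4
#'   for an informative unrooted tree).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (is.matrix(d)) d <- as.dist(d)
  stopifnot(inherits(d, "dist"))
  if (attr(d, "Size") < 3L) {
    stop("neighbour joining needs at least 3 labels", call. = FALSE)
  }
  ape::nj(d)
}

#' Bootstrap support for a distance-based tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree with
#' `tree_builder` on each replicate, and reports for each internal edge of
#' the original tree the percentage of replicates containing the same
#' bipartition (counted with [ape::prop.clades()] on unrooted
#' bipartitions). Replicates on which the builder fails are skipped with
#' a warning and the denominator adjusted.
#'
#' @param alignment Character matrix (or coercible) with >= 4 rows.
#' @param tree_builder Function from alignment matrix to `phylo`
#'   (default: neighbour joining on p-distance).
#' @param n Number of replicates (default 1000).
#' @param seed Integer seed for reproducible resampling.
#' @param support_threshold Support level (percent) regarded as a
#'   supported group (default 70).
#' @return An object of class `support_tree`: list with `tree` (`phylo`),
#'   `support` (percent per internal node, in `tree$node.label`),
#'   `n_replicates`, `support_threshold`.
#' @export
bootstrap_support <- function(alignment,
                              tree_builder = function(a) nj_tree(p_distance(a)),
                              n = 1000L, seed = 1L,
                              support_threshold = 70) {
  m <- as_alignment_matrix(alignment)
  stopifnot(nrow(m) >= 4L, n >= 1L)
  # zero-length internal edges carry no signal: collapse them so that
  # unresolved structure is never assigned support
  tree <- ape::di2multi(tree_builder(m), tol = 1e-10)
  with_seed(seed, {
    reps <- vector("list", n)
    failed <- 0L
    for (b in seq_len(n)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      reps[[b]] <- tryCatch(tree_builder(m[, cols, drop = FALSE]),
                            error = function(e) NULL)
      if (is.null(reps[[b]])) failed <- failed + 1L
    }
    if (failed > 0L) {
      warning(sprintf("%d bootstrap replicate(s) failed and were skipped",
                      failed))
      reps <- reps[!vapply(reps, is.null, logical(1))]
    }
    counts <- ape::prop.clades(tree, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    support <- 100 * counts / length(reps)
    support[1] <- NA_real_   # the root "clade" (all tips) is no bipartition
    tree$node.label <- c("", formatC(support[-1], format = "f", digits = 1))
    structure(
      list(tree = tree, support = support, n_replicates = length(reps),
           support_threshold = support_threshold),
      class = "support_tree"
    )
  })
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf(
    "support_tree: %d tips, %d replicates, %d/%d internal nodes >= %g%%\n",
    length(x$tree$tip.label), x$n_replicates,
    sum(x$support >= x$support_threshold, na.rm = TRUE),
    length(x$support), x$support_threshold))
  invisible(x)
}

# ---- groupings ------------------------------------------------------------

# k-group cut of an hclust, phylo or support_tree, as a named factor
cut_groups <- function(x, k) {
  if (inherits(x, "support_tree")) x <- x$tree
  if (inherits(x, "hclust")) {
    return(cutree(x, k = k))
  }
  if (inherits(x, "phylo")) {
    # cluster tips by cophenetic (path-length) distance on the tree
    d <- as.dist(cophenetic(x))
    return(cutree(hclust(d, method = "average"), k = k))
  }
  stop("cannot cut groups from an object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

# internal unrooted bipartitions as canonical strings (smaller side,
# sorted labels), optionally only those meeting the support threshold
bipartition_set <- function(x, support_filter = TRUE) {
  support <- NULL
  if (inherits(x, "support_tree")) {
    support <- x$support
    threshold <- x$support_threshold
    x <- x$tree
  }
  if (inherits(x, "hclust")) x <- ape::as.phylo(x)
  stopifnot(inherits(x, "phylo"))
  x <- ape::unroot(x)
  tips <- sort(x$tip.label)
  parts <- ape::prop.part(x)
  keys <- character(0)
  for (i in seq_along(parts)) {
    side <- sort(attr(parts, "labels")[parts[[i]]])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    other <- setdiff(tips, side)
    smaller <- if (length(side) < length(other) ||
                   (length(side) == length(other) &&
                      paste(side, collapse = ",") <=
                      paste(other, collapse = ","))) side else other
    keep <- TRUE
    if (!is.null(support) && support_filter) {
      keep <- !is.na(support[i]) && support[i] >= threshold
    }
    if (keep) keys <- c(keys, paste(smaller, collapse = ","))
  }
  unique(keys)
}

#' Adjusted Rand index between two labelled partitions
#'
#' Chance-corrected agreement via [mclust::adjustedRandIndex()]; the two
#' vectors are matched by name when named.
#'
#' @param a,b Cluster label vectors over the same items.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    stopifnot(setequal(names(a), names(b)))
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Compare the groupings induced by two trees or dendrograms
#'
#' Reports the internal bipartitions shared by the two trees (restricted
#' to supported bipartitions where bootstrap supports are available), the
#' adjusted Rand index between their k-group cuts, and — when truth
#' lineage labels are given — which lineages are merged with others or
#' split across groups in each cut.
#'
#' @param a,b `hclust`, `phylo` or `support_tree` objects over the same
#'   leaf set.
#' @param truth Optional named vector of lineage labels per leaf; sets
#'   `k` to the number of distinct lineages.
#' @param k Number of groups for the ARI cut (required without `truth`).
#' @return An object of class `grouping_comparison`.
#' @export
compare_groupings <- function(a, b, truth = NULL, k = NULL) {
  leaf_set <- function(x) {
    if (inherits(x, "support_tree")) x <- x$tree
    if (inherits(x, "hclust")) x$labels else x$tip.label
  }
  la <- leaf_set(a)
  lb <- leaf_set(b)
  if (!setequal(la, lb)) {
    stop("leaf sets differ between the two groupings", call. = FALSE)
  }
  if (is.null(k)) {
    if (is.null(truth)) {
      stop("k is required when no truth labels are given", call. = FALSE)
    }
    k <- length(unique(truth))
  }
  ga <- cut_groups(a, k)
  gb <- cut_groups(b, k)
  gb <- gb[names(ga)]
  pa <- bipartition_set(a)
  pb <- bipartition_set(b)
  shared <- intersect(pa, pb)

  lineage_fate <- function(groups) {
    if (is.null(truth)) return(NULL)
    tr <- truth[names(groups)]
    split_l <- sort(unique(tr[ave(as.integer(factor(groups)), tr,
                                  FUN = function(g) length(unique(g))) > 1L]))
    merged <- sort(unique(unlist(lapply(split(tr, groups), function(ls) {
      if (length(unique(ls)) > 1L) unique(ls)
    }))))
    list(split = split_l, merged = merged)
  }

  structure(
    list(ari = adjusted_rand(ga, gb), k = k,
         shared_bipartitions = length(shared),
         n_bipartitions = c(a = length(pa), b = length(pb)),
         shared = shared,
         groups = list(a = ga, b = gb),
         ari_truth = if (!is.null(truth)) {
           c(a = adjusted_rand(ga, truth[names(ga)]),
             b = adjusted_rand(gb, truth[names(gb)]))
         },
         fate = list(a = lineage_fate(ga), b = lineage_fate(gb))),
    class = "grouping_comparison"
  )
}

#' @export
print.grouping_comparison <- function(x, ...) {
  cat(sprintf(
    "grouping comparison (k = %d): ARI %.3f, %d shared bipartitions (of %d / %d)\n",
    x$k, x$ari, x$shared_bipartitions, x$n_bipartitions["a"],
    x$n_bipartitions["b"]))
  if (!is.null(x$ari_truth)) {
    cat(sprintf("  ARI against truth lineages: a %.3f, b %.3f\n",
                x$ari_truth["a"], x$ari_truth["b"]))
  }
  invisible(x)
}

#' Newick serialisation
#'
#' `to_newick()` serialises a `phylo`, `support_tree` (supports as
#' internal node labels) or `hclust` object (exported as an
#' ultrametric-style rooted tree: each merge height is split evenly
#' around the midpoint, so a two-leaf dendrogram of height 5 becomes
#' `(A:2.5,B:2.5);`). `from_newick()` parses Newick text into a `phylo`.
#'
#' @param x Tree-like object.
#' @param path Optional path; when given the text is also written there.
#' @return `to_newick()`: Newick string. `from_newick()`: a `phylo`.
#' @export
to_newick <- function(x, path = NULL) {
  if (inherits(x, "support_tree")) x <- x$tree
  if (inherits(x, "hclust")) x <- ape::as.phylo(x)
  stopifnot(inherits(x, "phylo"))
  txt <- ape::write.tree(x)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' @rdname to_newick
#' @param text Newick string (used when `path` is `NULL`).
#' @export
from_newick <- function(text = NULL, path = NULL) {
  tr <- if (!is.null(path)) {
    ape::read.tree(path)
  } else {
    ape::read.tree(text = text)
  }
  if (is.null(tr)) stop("malformed Newick text", call. = FALSE)
  tr
}
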