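test_that("hierarchical clustering reproduces hand-enumerated merge sequences", {
  d2 <- as.dist(matrix(c(0, 5, 5, 0), 2, dimnames = list(c("A", "B"))))
  for (link in c("single", "complete")) {
    hc <- str_hclust(d2, link)
    expect_equal(hc$height, 5)
  }
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(str_hclust(m, "single")$height, c(1, 2))
  expect_equal(str_hclust(m, "complete")$height, c(1, 3))
})

test_that("merge heights are monotone for single and complete linkage", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    pts <- matrix(rnorm(2 * n), ncol = 2)
    d <- dist(pts)
    for (link in c("single", "complete")) {
      expect_true(all(diff(str_hclust(d, link)$height) >= 0))
    }
  }
})

test_that("asymmetric matrices are rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(str_hclust(m), "symmetric")
})

test_that("neighbour joining recovers additive trees exactly", {
  # hand-built 4-taxon additive matrix from ((A:1,B:2):1,(C:3,D:1))
  dm <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  dm["A", "B"] <- dm["B", "A"] <- 3      # 1 + 2
  dm["A", "C"] <- dm["C", "A"] <- 5      # 1 + 1 + 3
  dm["A", "D"] <- dm["D", "A"] <- 3      # 1 + 1 + 1
  dm["B", "C"] <- dm["C", "B"] <- 6
  dm["B", "D"] <- dm["D", "B"] <- 4
  dm["C", "D"] <- dm["D", "C"] <- 4
  tr <- nj_tree(dm)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  # recovered path lengths equal the generating distances
  expect_equal(as.matrix(cophenetic(tr))[rownames(dm), colnames(dm)], dm)
  # AB | CD is the single internal bipartition
  pp <- ape::prop.part(ape::unroot(tr))
  labs <- attr(pp, "labels")
  sides <- lapply(pp, function(x) sort(labs[x]))
  expect_true(any(vapply(sides, function(s) {
    identical(s, c("A", "B")) || identical(s, c("C", "D"))
  }, logical(1))))

  # property: random additive trees, 7-12 taxa
  set.seed(17)
  skip_if_not_installed("phangorn")
  for (rep in 1:10) {
    n <- sample(7:12, 1)
    true_tree <- ape::rtree(n, rooted = FALSE,
                            br = function(k) runif(k, 0.2, 1.5))
    d_add <- cophenetic(true_tree)
    rec <- nj_tree(d_add)
    expect_equal(phangorn::RF.dist(ape::unroot(true_tree), rec), 0)
    expect_equal(as.matrix(cophenetic(rec))[rownames(d_add), colnames(d_add)],
                 d_add, tolerance = 1e-8)
  }
})

test_that("a star matrix yields zero-length internal branches and label order is immaterial", {
  m <- matrix(2, 5, 5, dimnames = list(paste0("t", 1:5), paste0("t", 1:5)))
  diag(m) <- 0
  tr <- nj_tree(m)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(abs(tr$edge.length[internal]) < 1e-12))

  p <- generate_panel(separated_config(3L))
  prof <- profile_panel(p, 10)
  d <- as.matrix(distance_matrix(prof))
  t1 <- nj_tree(d)
  perm <- sample(nrow(d))
  t2 <- nj_tree(d[perm, perm])
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(t1, t2), 0)

  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b")))),
               "3 labels")
})

test_that("bootstrap supports separate clans and are seed-reproducible", {
  # two 4-taxon clans separated by 30 fixed differences
  set.seed(4)
  block_a <- random_dna(30)
  block_b <- paste(rev(strsplit(random_dna(30), "")[[1]]), collapse = "")
  shared <- random_dna(40)
  mk <- function(block) {
    s <- paste0(block, shared)
    mutate <- sample(nchar(s), 2)
    chars <- strsplit(s, "")[[1]]
    chars[mutate] <- sample(c("A", "C", "G", "T"), 2, TRUE)
    paste(chars, collapse = "")
  }
  aln <- c(a1 = mk(block_a), a2 = mk(block_a), a3 = mk(block_a),
           a4 = mk(block_a), b1 = mk(block_b), b2 = mk(block_b),
           b3 = mk(block_b), b4 = mk(block_b))
  bt <- bootstrap_support(aln, n = 100, seed = 9L)
  idx <- match_bipartition(bt, c("a1", "a2", "a3", "a4"))
  expect_false(is.na(idx))
  expect_gte(bt$support[idx], 95)

  bt2 <- bootstrap_support(aln, n = 100, seed = 9L)
  expect_identical(bt$support, bt2$support)
})

test_that("identical sequences give no supported internal structure", {
  aln <- setNames(rep(strrep("ACGT", 25), 5), paste0("s", 1:5))
  bt <- suppressWarnings(bootstrap_support(aln, n = 50, seed = 2L))
  expect_true(all(is.na(bt$support) | bt$support < bt$support_threshold |
                    length(bt$support) == 0))
})

test_that("grouping comparison: self-comparison is perfect, caterpillar conflict shares nothing", {
  p <- generate_panel(separated_config(5L))
  prof <- profile_panel(p, 10)
  hc <- str_hclust(distance_matrix(prof))
  truth <- setNames(p$truth$lineage, p$truth$id)
  cmp <- compare_groupings(hc, hc, truth = truth)
  expect_equal(cmp$ari, 1)
  expect_equal(cmp$shared_bipartitions,
               unname(cmp$n_bipartitions["a"]))

  t1 <- from_newick("((((((A,B),C),D),E),F));")
  t2 <- from_newick("((((((F,E),D),C),B),A));")
  t1$edge.length <- rep(1, nrow(t1$edge))
  t2$edge.length <- rep(1, nrow(t2$edge))
  cmp2 <- compare_groupings(t1, t2, k = 2)
  expect_equal(cmp2$shared_bipartitions, 0)

  t3 <- from_newick("((A,B),(C,X));")
  expect_error(compare_groupings(t1, t3, k = 2), "leaf sets")
})

test_that("ARI is 1 against itself and ~0 against label permutations", {
  truth <- rep(paste0("L", 1:5), each = 4)
  expect_equal(adjusted_rand(truth, truth), 1)
  set.seed(12)
  aris <- replicate(100, adjusted_rand(truth, sample(truth)))
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("newick round-trips preserve topology, lengths and supports", {
  set.seed(23)
  skip_if_not_installed("phangorn")
  for (rep in 1:20) {
    tr <- ape::rtree(sample(4:12, 1))
    back <- from_newick(to_newick(tr))
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(back)), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-8)
  }
  # two-leaf dendrogram of height 5 exports under the midpoint convention
  d2 <- as.dist(matrix(c(0, 5, 5, 0), 2, dimnames = list(c("A", "B"))))
  expect_identical(to_newick(str_hclust(d2)), "(A:2.5,B:2.5);")
  # supports serialised as node labels survive the round trip
  aln <- c(a1 = strrep("AC", 30), a2 = strrep("AC", 30),
           b1 = strrep("GT", 30), b2 = strrep("GT", 30),
           c1 = paste0(strrep("AC", 15), strrep("GT", 15)),
           c2 = paste0(strrep("AC", 15), strrep("GT", 15)))
  bt <- suppressWarnings(bootstrap_support(aln, n = 20, seed = 1L))
  back <- from_newick(to_newick(bt))
  expect_identical(back$node.label[-1], bt$tree$node.label[-1])
  f <- tempfile(fileext = ".nwk")
  to_newick(bt, f)
  expect_identical(to_newick(from_newick(path = f)), to_newick(bt$tree))
  expect_error(from_newick("((A,B);"))
})
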