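test_that("distance measures satisfy their definitions", {
  eu <- distance_measure("euclidean")
  expect_equal(profile_distance(c(0, 0), c(3, 4), eu), 5)
  expect_equal(profile_distance(c(1, 2), c(4, 6),
                                distance_measure("minkowski", p = 1)), 7)
  expect_equal(profile_distance(c(1, 2), c(4, 6),
                                distance_measure("manhattan")), 7)
  expect_equal(profile_distance(c(0, 0), c(3, 4),
                                distance_measure("minkowski", p = 2)), 5)
  x <- c(1, 3, 2, 5)
  pe <- distance_measure("pearson")
  expect_equal(profile_distance(x, x, pe), 0)
  expect_equal(profile_distance(x, -x, pe), 2)
  expect_error(profile_distance(c(1, 1), c(1, 2), pe), "constant")
  expect_error(profile_distance(1:3, 1:4), "length")
  expect_error(distance_measure("minkowski", p = 0), "p")

  set.seed(3)
  m <- matrix(rnorm(30), 6, 5, dimnames = list(paste0("i", 1:6), NULL))
  dm <- distance_matrix(m, eu)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), setNames(rep(0, 6), rownames(m)))
  expect_equal(dm["i1", "i2"], profile_distance(m[1, ], m[2, ], eu))
})

test_that("k-means: degenerate cases and exact recovery of separated blobs", {
  set.seed(42)
  blobs <- planted_blobs(sd = 0.05)
  p1 <- kmeans_cluster(blobs$mat, k = 1, seed = 1)
  expect_equal(n_clusters(p1), 1L)

  pts <- matrix(c(0, 0, 1, 1, 2, 2), 3, 2, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
  pn <- kmeans_cluster(pts, k = 3, seed = 1)
  expect_equal(n_clusters(pn), 3L)

  p <- kmeans_cluster(blobs$mat, k = 3, seed = 7)
  expect_equal(compare_partitions(p, blobs$truth), 1)
  # deterministic given seed
  expect_identical(kmeans_cluster(blobs$mat, k = 3, seed = 7)$labels, p$labels)
  expect_error(kmeans_cluster(blobs$mat, k = 0, seed = 1), "k")
  expect_error(kmeans_cluster(blobs$mat, k = 99, seed = 1), "k")
})

test_that("QT clustering respects the diameter bound and recovers planted groups", {
  set.seed(55)
  blobs <- planted_blobs(sd = 0.02)
  p <- qt_cluster(blobs$mat, diameter = 0.4)
  expect_equal(compare_partitions(p, blobs$truth), 1)
  expect_equal(length(p$unassigned), 0)

  # brute-force diameter verification on random instances
  for (rep in 1:20) {
    mat <- matrix(runif(40), 20, 2,
                  dimnames = list(paste0("x", 1:20), NULL))
    dm <- distance_matrix(mat)
    part <- qt_cluster(dm, diameter = 0.3, is_distance = TRUE)
    for (cl in cluster_members(part)) {
      expect_lte(max(dm[cl, cl]), 0.3)
    }
    sizes <- lengths(cluster_members(part))
    expect_true(all(diff(as.numeric(sizes)) <= 0))  # non-increasing
  }

  # all identical items -> one cluster
  same <- matrix(1, 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  pall <- qt_cluster(same, diameter = 0.1)
  expect_equal(n_clusters(pall), 1L)
  expect_equal(length(pall$labels), 5)

  # threshold below min pairwise distance -> everything unassigned
  spread <- matrix(c(0, 0, 5, 5, 10, 10), 3, 2, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), NULL))
  pnone <- qt_cluster(spread, diameter = 0.5)
  expect_equal(length(pnone$labels), 0)
  expect_setequal(pnone$unassigned, c("a", "b", "c"))
  expect_error(qt_cluster(spread, diameter = -1), "positive")
})

test_that("UPGMA/WPGMA match hclust cophenetics and are exact on ultrametric input", {
  # two items at distance 2 -> root height 1
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- agglomerate(d2, "upgma")
  expect_equal(write_newick(t2), "(A:1,B:1);")

  # ultrametric input: cophenetic == input exactly
  ultra <- ape::read.tree(text = "((A:1,B:1):2,(C:2,D:2):1);")
  D <- stats::cophenetic(ultra)
  tu <- agglomerate(D, "upgma")
  expect_equal(stats::cophenetic(tu)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)

  # random matrices: agreement with the reference average/mcquitty linkage
  set.seed(66)
  for (rep in 1:10) {
    m <- rand_dist(8)
    for (link in c("upgma", "wpgma")) {
      tree <- agglomerate(m, link)
      hc <- stats::hclust(stats::as.dist(m),
                          method = if (link == "upgma") "average" else "mcquitty")
      expect_equal(
        stats::cophenetic(tree)[rownames(m), colnames(m)],
        as.matrix(stats::cophenetic(hc))[rownames(m), colnames(m)],
        tolerance = 1e-9)
    }
  }
  asym <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(agglomerate(asym), "symmetric")
})

test_that("neighbor joining recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  D <- stats::cophenetic(tr)
  for (alg in c("naive", "rapid")) {
    out <- neighbor_joining(D, alg)
    expect_equal(stats::cophenetic(out)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
    # split AB|CD present
    expect_equal(as.numeric(ape::dist.topo(out, tr)), 0)
  }
  # n = 3 closed form
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(d3, "naive")
  expect_equal(stats::cophenetic(t3)[rownames(d3), colnames(d3)], d3,
               tolerance = 1e-9)
  expect_error(neighbor_joining(d3[1:2, 1:2]), "n >= 3")
})

test_that("rapid NJ equals naive NJ and the ape reference on random metrics", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(4:15, 1)
    m <- rand_dist(n)
    t_naive <- suppressWarnings(neighbor_joining(m, "naive"))
    t_rapid <- suppressWarnings(neighbor_joining(m, "rapid"))
    expect_equal(as.numeric(ape::dist.topo(t_naive, t_rapid)), 0)
  }
  # independent oracle: ape's NJ implementation
  for (rep in 1:10) {
    m <- rand_dist(10)
    t_mine <- suppressWarnings(neighbor_joining(m, "rapid"))
    t_ape <- ape::nj(m)
    expect_equal(as.numeric(ape::dist.topo(t_mine, t_ape)), 0)
  }
})

test_that("silhouette matches the reference implementation and conventions", {
  set.seed(88)
  # random partitions vs cluster::silhouette
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    mat <- matrix(rnorm(2 * n), n, 2, dimnames = list(paste0("x", 1:n), NULL))
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    p <- partition(setNames(lab, rownames(mat)))
    dm <- distance_matrix(mat)
    mine <- silhouette_widths(p, dm)
    ref <- cluster::silhouette(as.integer(p$labels), stats::dist(mat))
    expect_equal(unname(mine$widths), unname(ref[, 3]), tolerance = 1e-9)
    expect_true(all(mine$widths >= -1 & mine$widths <= 1))
  }
  # two tight, far-apart clusters -> mean s > 0.9
  blobs <- planted_blobs(sd = 0.01)
  p <- partition(blobs$truth$labels)
  s <- silhouette_widths(p, distance_matrix(blobs$mat))
  expect_gt(s$mean, 0.9)
  # singleton convention: s = 0
  p1 <- partition(setNames(c(1, 1, 2), c("g1", "g2", "g3")))
  s1 <- silhouette_widths(p1, distance_matrix(blobs$mat[1:3, ]))
  expect_equal(unname(s1$widths["g3"]), 0)
  expect_error(silhouette_widths(partition(setNames(c(1, 1), c("g1", "g2"))),
                                 distance_matrix(blobs$mat[1:2, ])),
               "2 clusters")
})

test_that("adjusted Rand index: identity, relabeling, chance level", {
  lab <- setNames(sample(1:3, 40, replace = TRUE), paste0("i", 1:40))
  p <- partition(lab)
  relab <- partition(setNames(c(3, 1, 2)[lab], names(lab)))
  expect_equal(compare_partitions(p, relab), 1)

  # one cluster vs singletons on n = 4: ARI 0
  one <- partition(setNames(rep(1, 4), letters[1:4]))
  singles <- partition(setNames(1:4, letters[1:4]))
  expect_equal(compare_partitions(one, singles), 0)

  # agreement with the mclust reference on random pairs
  set.seed(99)
  for (rep in 1:10) {
    a <- partition(setNames(sample(1:4, 30, TRUE), paste0("i", 1:30)))
    b <- partition(setNames(sample(1:4, 30, TRUE), paste0("i", 1:30)))
    expect_equal(compare_partitions(a, b),
                 mclust::adjustedRandIndex(a$labels, b$labels[names(a$labels)]),
                 tolerance = 1e-12)
  }
  # random labelings are at chance: mean ARI ~ 0
  aris <- replicate(300, {
    a <- partition(setNames(sample(1:3, 25, TRUE), paste0("i", 1:25)))
    b <- partition(setNames(sample(1:3, 25, TRUE), paste0("i", 1:25)))
    compare_partitions(a, b)
  })
  expect_lt(abs(mean(aris)), 0.05)

  expect_error(compare_partitions(one,
    partition(setNames(1:3, letters[2:4]))), "different item sets")
})
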