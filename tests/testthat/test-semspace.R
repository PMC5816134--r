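test_that("label profiles are per-stimulus choice proportions", {
  labs <- c("laugh", "moan", "groan")
  tr <- make_trials(
    stimulus = c(rep("s1", 10), rep("s2", 4)),
    sound = c(rep("laugh", 10), "moan", "moan", "moan", "groan")
  )
  prof <- name_profile_matrix(tr, labs, "sound")
  expect_equal(unname(prof["s1", ]), c(1, 0, 0))
  expect_equal(unname(prof["s2", ]), c(0, 0.75, 0.25))
  expect_equal(rowSums(prof), c(s1 = 1, s2 = 1))

  # multi-label trials contribute one count per chosen label
  tr2 <- make_trials("s1", "laugh;moan")
  prof2 <- name_profile_matrix(tr2, labs, "sound")
  expect_equal(unname(prof2["s1", ]), c(0.5, 0.5, 0))

  expect_error(name_profile_matrix(make_trials("s1", "howl"), labs, "sound"),
               "outside")
  expect_error(name_profile_matrix(make_trials("s1", ""), labs, "sound"),
               "zero label choices")
})

test_that("co-occurrence distances match hand-computed Euclidean values", {
  prof <- structure(rbind(s1 = c(1, 0), s2 = c(0, 1), s3 = c(0.5, 0.5),
                          s4 = c(1, 0)),
                    class = c("label_profile", "matrix"))
  d <- cooccurrence_distances(prof)
  expect_distance_matrix(d)
  expect_equal(d["s1", "s2"], sqrt(2), tolerance = 1e-12)
  expect_equal(d["s1", "s3"], sqrt(0.5), tolerance = 1e-12)
  expect_equal(d["s1", "s4"], 0)
})

test_that("co-occurrence distances are invariant to duplicating every trial", {
  tr <- fixture_naming()
  labs <- fixture_lexicon()$sound_labels
  d1 <- cooccurrence_distances(name_profile_matrix(tr, labs, "sound"))
  d2 <- cooccurrence_distances(
    name_profile_matrix(dplyr::bind_rows(tr, tr), labs, "sound"))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("distance-matrix averaging is the element-wise mean", {
  d <- as.matrix(dist(matrix(rnorm(20), 10)))
  dimnames(d) <- list(letters[1:10], letters[1:10])
  expect_equal(average_distance_matrices(list(d, d)), d)
  expect_equal(average_distance_matrices(list(d, 3 * d)), 2 * d)
  expect_equal(average_distance_matrices(list(d)), d)
  d_bad <- d[c(2:10, 1), c(2:10, 1)]
  expect_error(average_distance_matrices(list(d, d_bad)), "ordering")
})

test_that("classical MDS reproduces Euclidean configurations exactly", {
  # collinear points: one dimension carries all the variance
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  emb <- embed_space(d3, k = 1)
  expect_equal(emb$explained_variance[1], 1, tolerance = 1e-10)

  # exact distance recovery from known 3-D coordinates
  set.seed(42)
  X <- matrix(rnorm(60), 20, 3)
  dX <- as.matrix(dist(X))
  dimnames(dX) <- list(sprintf("s%02d", 1:20), sprintf("s%02d", 1:20))
  emb3 <- embed_space(dX, k = 3)
  expect_equal(as.matrix(dist(emb3$coords)), dX, tolerance = 1e-8)
  expect_true(all(diff(emb3$explained_variance) <= 1e-12))

  # unit square: two equal leading shares of 0.5
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  dsq <- as.matrix(dist(sq))
  emb_sq <- embed_space(dsq, k = 2)
  expect_equal(emb_sq$explained_variance, c(0.5, 0.5), tolerance = 1e-10)

  # oracle: eigenvalue shares agree with stats::cmdscale
  cm <- cmdscale(as.dist(dX), k = 3, eig = TRUE)
  expect_equal(as.vector(abs(emb3$coords)), as.vector(abs(cm$points)),
               tolerance = 1e-6)
  expect_error(embed_space(dX, k = 20), "at most")
  expect_warning(embed_space(dsq, k = 3), "truncating")
})

test_that("modal clusters pick the argmax label with documented tie-break", {
  labs <- c("laugh", "giggle")
  tr <- make_trials(
    stimulus = c(rep("s1", 4), rep("s2", 2), "s3"),
    sound = c("laugh", "laugh", "laugh", "giggle", "laugh", "giggle", "giggle")
  )
  m <- modal_clusters(tr, labs, "sound")
  expect_equal(m$modal_label, c("laugh", "laugh", "giggle"))
  expect_equal(m$modal_proportion, c(0.75, 0.5, 1))
  expect_equal(m$tie, c(FALSE, TRUE, FALSE))
})

test_that("weighted centroids are prototype-weighted means", {
  coords <- rbind(s1 = c(0, 0), s2 = c(3, 0), s3 = c(5, 5))
  assign <- c(s1 = "A", s2 = "A", s3 = "B")
  cert <- c(s1 = 2, s2 = 1, s3 = 3)
  modal <- c(s1 = 1, s2 = 1, s3 = 0.5)
  cent <- weighted_centroids(coords, assign, cert, modal)
  expect_equal(cent$V1[cent$cluster == "A"], 1)   # (2*0 + 1*3) / 3
  expect_equal(unlist(cent[cent$cluster == "B", c("V1", "V2")]),
               c(V1 = 5, V2 = 5))                 # singleton
  # equal weights reduce to the arithmetic mean
  cent_eq <- weighted_centroids(coords, assign, cert * 0 + 1, modal * 0 + 1)
  expect_equal(cent_eq$V1[cent_eq$cluster == "A"], 1.5)
  expect_error(weighted_centroids(coords, assign, cert * 0, modal),
               "all-zero")
})

test_that("affinity propagation separates two tight pairs and handles n = 1", {
  d1 <- matrix(0, 1, 1, dimnames = list("a", "a"))
  sol1 <- affinity_propagation(d1)
  expect_equal(sol1$n_clusters, 1)
  expect_equal(unname(sol1$assignment), "a")

  pts <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  sol <- affinity_propagation(d, q = 0.5)
  expect_true(sol$converged)
  expect_equal(sol$n_clusters, 2)
  expect_equal(sol$assignment[["a"]], sol$assignment[["b"]])
  expect_equal(sol$assignment[["c"]], sol$assignment[["d"]])
  # matches the brute-force optimum for the same preference
  expect_equal(sol$net_similarity, bf_best_net_similarity(d, 0.5)$net,
               tolerance = 1e-9)
})

test_that("higher preference never yields fewer optimal exemplars", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:8, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    expect_gte(bf_best_net_similarity(d, 1)$n_exemplars,
               bf_best_net_similarity(d, 0)$n_exemplars)
    sol_hi <- affinity_propagation(d, q = 1)
    sol_lo <- affinity_propagation(d, q = 0)
    if (sol_hi$converged && sol_lo$converged) {
      expect_gte(sol_hi$n_clusters, sol_lo$n_clusters)
    }
  }
})

test_that("silhouette matches hand computation and degenerate conventions", {
  pts <- c(0, 0.1, 10, 10.1)
  d <- as.matrix(dist(pts))
  cl <- c(1, 1, 2, 2)
  # hand: a = 0.1; b = mean(9.9+...) etc
  expected <- silhouette_oracle(d, cl)
  expect_equal(silhouette_index(d, cl), expected, tolerance = 1e-12)
  expect_gt(expected, 0.98)

  # identical points, arbitrary split: a = b = 0 convention gives 0
  dz <- matrix(0, 4, 4)
  expect_equal(silhouette_index(dz, c(1, 2, 1, 2)), 0)
  expect_error(silhouette_index(d, c(1, 1, 1, 1)), "at least 2")

  # cross-check against cluster::silhouette on a random instance
  set.seed(7)
  X <- matrix(rnorm(40), 20)
  dd <- as.matrix(dist(X))
  cl2 <- sample(1:3, 20, replace = TRUE)
  sil_pkg <- mean(cluster::silhouette(cl2, dist(X))[, 3])
  expect_equal(silhouette_index(dd, cl2), sil_pkg, tolerance = 1e-10)
})

test_that("adjusted Rand index matches hand values and is label-invariant", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  set.seed(3)
  a <- sample(letters[1:4], 30, replace = TRUE)
  b <- sample(letters[1:3], 30, replace = TRUE)
  expect_equal(adjusted_rand(a, b), adjusted_rand(b, a))
  expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})

test_that("ARI of random relabelings is centred on zero", {
  set.seed(11)
  a <- rep(1:4, each = 25)
  vals <- vapply(1:1000, function(i) adjusted_rand(a, sample(a)), double(1))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("q_sweep deduplicates the grid and reports per-q quality", {
  tr <- fixture_naming()
  labs <- fixture_lexicon()$sound_labels
  d <- cooccurrence_distances(name_profile_matrix(tr, labs, "sound"))
  truth <- setNames(fixture_world()$stimuli$true_type,
                    fixture_world()$stimuli$stimulus)
  res <- q_sweep(d, truth, q_grid = c(0.3, 0.45, 0.5, 0.5))
  expect_equal(res$q, c(0.3, 0.45, 0.5))
  expect_true(all(c("n_clusters", "silhouette", "ari", "converged") %in%
                    names(res)))
  expect_error(q_sweep(d, truth, q_grid = numeric(0)), "nonempty")
})

test_that("cladograms merge closest items first and export as Newick", {
  d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- hierarchical_cladogram(d)
  expect_equal(tree$hclust$height[1], 1)
  expect_equal(sort(tree$hclust$merge[1, ]), c(-2, -1))

  # two items: single merge at their distance
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- hierarchical_cladogram(d2)
  expect_equal(t2$hclust$height, 4)

  # ultrametric distances are reproduced exactly as merge heights
  du <- matrix(c(0, 2, 6, 6, 2, 0, 6, 6, 6, 6, 0, 4, 6, 6, 4, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tu <- hierarchical_cladogram(du)
  expect_equal(sort(tu$hclust$height), c(2, 4, 6))

  nwk <- write_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
  expect_error(hierarchical_cladogram(d2[1, 1, drop = FALSE]), "at least 2")
})
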