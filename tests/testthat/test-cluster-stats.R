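test_that("channel t-tests match the closed form", {
  set.seed(1)
  n <- 25
  m <- matrix(rnorm(n * 8, mean = 0.1, sd = 0.25), n,
              dimnames = list(NULL, paste0("ch", 1:8)))
  stat <- channel_ttest(m)
  hand <- apply(m, 2, function(x) mean(x) / (sd(x) / sqrt(n)))
  expect_equal(stat$t, unname(hand), tolerance = 1e-12)
  expect_true(all(stat$df == n - 1))

  # per-subject constant maps: every channel shares the same t
  cm <- matrix(rep(rnorm(6), 4), 6, 4)
  colnames(cm) <- paste0("c", 1:4)
  st <- channel_ttest(cm)
  expect_equal(diff(range(st$t)), 0, tolerance = 1e-12)

  expect_error(channel_ttest(matrix(0, 5, 3)), "zero-variance")
  expect_error(channel_ttest(m[1:2, ]), "3 subjects")
})

test_that("adjacency respects the distance threshold and unit sphere", {
  mont <- fixture_montage()
  expect_true(all(!build_adjacency(mont, threshold = 1e-9)))
  full <- build_adjacency(mont, threshold = 3)
  expect_true(all(full[upper.tri(full)]))
  adj <- build_adjacency(mont, 0.4)
  expect_true(isSymmetric(adj))
  expect_true(all(!diag(adj)))
  # neighbours exist but the graph is sparse
  expect_gt(sum(adj), 0)
  expect_lt(mean(adj), 0.4)

  bad <- mont
  bad$x <- bad$x * 3
  expect_error(build_adjacency(bad), "normalized")
})

test_that("a toy square connects its sides but not its diagonals", {
  # 4 channels on a planar square of side 0.3 (diagonal ~ 0.424)
  sq <- tibble::tibble(
    label = c("a", "b", "c", "d"),
    x = c(0, 0.3, 0, 0.3), y = c(0, 0, 0.3, 0.3), z = sqrt(1 - c(
      0, 0.09, 0.09, 0.18))
  )
  adj <- build_adjacency(sq, 0.4)
  # 3D chord distances shrink slightly relative to the planar layout, so
  # recompute the oracle directly from the geometry
  d <- as.matrix(dist(sq[, c("x", "y", "z")]))
  expect_identical(unname(adj), unname(d < 0.4 & row(d) != col(d)))
  expect_true(adj["a", "b"] && adj["a", "c"])
  expect_false(adj["a", "d"])  # diagonal pair
  expect_false(adj["b", "c"])
})

test_that("cluster formation matches hand-enumerated components", {
  # 5-channel chain: adjacency i ~ i+1
  adj <- matrix(FALSE, 5, 5, dimnames = rep(list(paste0("e", 1:5)), 2))
  for (i in 1:4) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  t_vals <- c(e1 = 3, e2 = 3, e3 = -3, e4 = 3, e5 = 3)
  cl <- form_clusters(t_vals, adj, t_crit = 2)
  expect_equal(nrow(cl), 3)
  has_set <- function(s) any(vapply(cl$channels, setequal, NA, s))
  expect_true(has_set(c("e1", "e2")))
  expect_true(has_set("e3"))
  expect_true(has_set(c("e4", "e5")))

  # mass and peak of a homogeneous negative cluster
  t2 <- c(e1 = -3, e2 = -4, e3 = -5, e4 = 0, e5 = 0)
  cl2 <- form_clusters(t2, adj, t_crit = 2)
  expect_equal(cl2$mass, -12)
  expect_equal(cl2$peak_t, -5)
  expect_gte(abs(cl2$mass), abs(cl2$peak_t))

  expect_equal(nrow(form_clusters(c(e1 = 1, e2 = -1, e3 = 0, e4 = 0, e5 = 0),
                                  adj, 2)), 0)
})

test_that("components agree with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(2)
  mont <- fixture_montage()
  adj <- build_adjacency(mont, 0.4)
  t_vals <- setNames(rnorm(nrow(mont), sd = 3), mont$label)
  cl <- form_clusters(t_vals, adj, t_crit = 2)
  # oracle: igraph components on each sign's supra-threshold subgraph
  n_oracle <- 0
  for (sgn in c(-1, 1)) {
    keep <- which(sign(t_vals) == sgn & abs(t_vals) > 2)
    if (!length(keep)) next
    g <- igraph::graph_from_adjacency_matrix(adj[keep, keep, drop = FALSE],
                                             mode = "undirected")
    comps <- igraph::components(g)
    n_oracle <- n_oracle + comps$no
    oracle_sets <- split(mont$label[keep], comps$membership)
    for (s in oracle_sets) {
      expect_true(any(vapply(cl$channels, setequal, NA, s)))
    }
  }
  expect_equal(nrow(cl), n_oracle)
})

test_that("cluster formation reduces to per-channel t under empty adjacency", {
  adj <- matrix(FALSE, 4, 4, dimnames = rep(list(paste0("e", 1:4)), 2))
  t_vals <- c(e1 = 3, e2 = -3, e3 = 2.5, e4 = 0)
  cl <- form_clusters(t_vals, adj, t_crit = 2)
  expect_equal(nrow(cl), 3)  # each supra channel is its own cluster
  expect_true(all(cl$n_channels == 1))
  expect_equal(sort(abs(cl$peak_t)), c(2.5, 3, 3))
})

test_that("an injected posterior effect is recovered as significant", {
  mont <- fixture_montage()
  adj <- build_adjacency(mont, 0.4)
  post <- region_sets(mont)$posterior
  set.seed(3)
  n <- 25
  m <- matrix(rnorm(n * nrow(mont), 0, 0.1), n,
              dimnames = list(NULL, mont$label))
  m[, post] <- m[, post] - 0.15
  res <- signflip_permutation(m, adj, n_perm = 1000, seed = 4)
  sig_neg <- res$clusters[res$clusters$significant & res$clusters$sign < 0, ]
  expect_gte(nrow(sig_neg), 1)
  expect_gt(length(intersect(unlist(sig_neg$channels), post)), 5)
  expect_equal(sig_neg$d, sig_neg$peak_t / sqrt(n))
  expect_gte(min(res$clusters$p_corrected), 1 / 1001)
})

test_that("the sampled sign-flip null matches exhaustive enumeration (n = 8)", {
  set.seed(5)
  mont <- fixture_montage()
  adj <- build_adjacency(mont, 0.4)
  n <- 8
  m <- matrix(rnorm(n * nrow(mont)), n, dimnames = list(NULL, mont$label))
  res <- signflip_permutation(m, adj, n_perm = 2000, seed = 6)
  # exhaustive 2^8 oracle using independent code paths where possible
  flips_all <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t_crit <- res$t_crit
  exact <- apply(flips_all, 1, function(s) {
    ms <- m * s
    tv <- apply(ms, 2, function(x) mean(x) / (sd(x) / sqrt(n)))
    cl <- form_clusters(setNames(tv, colnames(m)), adj, t_crit)
    if (nrow(cl)) max(abs(cl$mass)) else 0
  })
  se <- sd(exact) / sqrt(2000)
  expect_lt(abs(mean(res$null_max) - mean(exact)), 4 * se)
  expect_lt(abs(sd(res$null_max) - sd(exact)), 6 * se)
})

test_that("permutation p is invariant to consistent channel relabeling", {
  mont <- fixture_montage()
  adj <- build_adjacency(mont, 0.4)
  set.seed(7)
  n <- 12
  m <- matrix(rnorm(n * nrow(mont), -0.05, 0.12), n,
              dimnames = list(NULL, mont$label))
  res1 <- signflip_permutation(m, adj, n_perm = 500, seed = 8)
  perm <- sample(ncol(m))
  res2 <- signflip_permutation(m[, perm], adj[perm, perm], n_perm = 500,
                               seed = 8)
  o1 <- res1$clusters[order(res1$clusters$mass), ]
  o2 <- res2$clusters[order(res2$clusters$mass), ]
  expect_equal(o1$mass, o2$mass, tolerance = 1e-12)
  expect_equal(o1$p_corrected, o2$p_corrected, tolerance = 1e-12)
})

test_that("Cohen's d reproduces the printed sensor-table effect sizes", {
  expect_equal(round(cohens_d_from_t(-4.47, 25), 2), -0.89)
  expect_equal(round(cohens_d_from_t(2.24, 25), 2), 0.45)
  expect_equal(cohens_d_from_t(0, 25), 0)
  # linearity in t
  expect_equal(cohens_d_from_t(3, 25) * 2, cohens_d_from_t(6, 25))
  expect_error(cohens_d_from_t(1, 0), "positive")
})

test_that("BH-FDR matches hand computation and is monotone", {
  res <- fdr_correct(c(0.01, 0.02, 0.03, 0.9), q = 0.05)
  # hand BH: 0.03 <= (3/4) * 0.05, so the first three are rejected
  expect_identical(res$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$p_adjusted, c(0.04, 0.04, 0.04, 0.9), tolerance = 1e-12)

  expect_true(all(fdr_correct(rep(0.001, 68))$rejected))
  expect_equal(fdr_correct(0.04)$p_adjusted, 0.04)

  set.seed(9)
  p <- runif(50)
  adj <- fdr_correct(p)$p_adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(fdr_correct(c(0.1, 1.2)), "\\[0, 1\\]")
})
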