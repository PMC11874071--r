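test_that("curve distances are Euclidean row distances", {
  m <- rbind(a = c(0, 0, 0), b = c(3, 4, 0), c = c(0, 0, 0))
  d <- as.matrix(curve_distances(m))
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 0)

  set.seed(31)
  x <- matrix(rnorm(80), 10, 8,
              dimnames = list(sprintf("r%d", 1:10), sprintf("window_%d", 1:8)))
  got <- as.matrix(curve_distances(x))
  want <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    want[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  }
  expect_equal(unname(got), want, tolerance = 1e-12)
  expect_true(isSymmetric(got))

  x[3, 2] <- NA
  expect_warning(d2 <- curve_distances(x), "excluded")
  expect_equal(attr(d2, "excluded"), "r3")
  expect_equal(attr(d2, "Size"), 9L)
})

test_that("complete linkage merges by maximum pairwise distance", {
  dm <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3)
  hc <- complete_linkage(dm)
  expect_equal(hc$height, c(1, 10))
  expect_equal(sort(cut_tree(hc, 2)), c(1, 1, 2))

  # two items: a single merge at their distance
  d2 <- dist(c(0, 7))
  expect_equal(complete_linkage(d2)$height, 7)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(complete_linkage(bad), class = "entrajectory_parameter_error")
})

test_that("complete linkage reproduces the brute-force agglomeration oracle", {
  set.seed(32)
  for (rep in 1:20) {
    pts <- matrix(rnorm(6 * 4), 6, 4)
    d <- dist(pts)
    hc <- complete_linkage(d)
    orc <- complete_linkage_oracle(d)
    expect_equal(hc$height, orc$heights, tolerance = 1e-12)
    # the partition after every merge agrees (labels are arbitrary)
    for (step in seq_len(5)) {
      expect_identical(partition_signature(cutree(hc, k = 6 - step)),
                       partition_signature(orc$partitions[[step]]))
    }
    # merge heights are monotone non-decreasing
    expect_true(all(diff(hc$height) >= 0))
  }
})

test_that("tree cutting spans the trivial and planted cases", {
  set.seed(33)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  hc <- complete_linkage(dist(pts))
  expect_equal(length(unique(cut_tree(hc, 8))), 8)
  expect_equal(length(unique(cut_tree(hc, 1))), 1)
  expect_error(cut_tree(hc, 0), class = "entrajectory_parameter_error")
  expect_error(cut_tree(hc, 9), class = "entrajectory_parameter_error")

  # planted blobs far apart are recovered exactly
  blob <- rbind(matrix(rnorm(40, 0, 0.1), 10, 4),
                matrix(rnorm(40, 10, 0.1), 10, 4))
  lab <- cut_tree(complete_linkage(dist(blob)), 2)
  expect_equal(ari(lab, rep(1:2, each = 10)), 1)
})

test_that("Calinski-Harabasz matches manual arithmetic and prefers the true k", {
  # 4 points on a line, 2 planted pairs: B = 100, W = 1, CH = 200
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(calinski_harabasz(x, c(1, 1, 2, 2)), 200)

  set.seed(34)
  blob <- rbind(matrix(rnorm(60, 0, 0.5), 15, 4),
                matrix(rnorm(60, 8, 0.5), 15, 4))
  hc <- complete_linkage(dist(blob))
  ch <- sapply(2:4, function(k) calinski_harabasz(blob, cut_tree(hc, k)))
  expect_gt(ch[1], ch[2])
  expect_gt(ch[1], ch[3])

  # random labels on homogeneous data: CH near 1 on average
  ch_null <- replicate(200, {
    z <- matrix(rnorm(40 * 3), 40, 3)
    calinski_harabasz(z, sample(1:2, 40, replace = TRUE))
  })
  expect_gt(mean(ch_null), 0.8)
  expect_lt(mean(ch_null), 1.25)

  # zero within-cluster dispersion is flagged as infinite
  dup <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  expect_warning(val <- calinski_harabasz(dup, c(1, 2)), "infinite")
  expect_identical(val, Inf)

  expect_error(calinski_harabasz(x, rep(1, 4)),
               class = "entrajectory_parameter_error")
})

test_that("CH model selection finds the planted cluster count", {
  set.seed(35)
  hits <- 0
  for (rep in 1:50) {
    k_true <- sample(2:3, 1)
    centers <- matrix(rnorm(k_true * 6, 0, 5), k_true, 6)
    m <- centers[rep(seq_len(k_true), each = 8), ] + matrix(rnorm(8 * k_true * 6, 0, 0.3),
                                                            8 * k_true, 6)
    hc <- complete_linkage(dist(m))
    ch <- sapply(2:6, function(k) calinski_harabasz(m, cut_tree(hc, k)))
    hits <- hits + ((2:6)[which.max(ch)] == k_true)
  }
  expect_gte(hits / 50, 0.95)
})

test_that("leaf order is a deterministic permutation that respects structure", {
  d2 <- dist(c(0, 5))
  expect_equal(leaf_ordering(complete_linkage(d2)), c(1, 2))

  # an increasing-gap chain: leaf order is a permutation in which every
  # merged subchain stays contiguous ({1,2} first, then {3,4,5})
  chain <- c(0, 1, 2.2, 3.6, 5.2)
  hc <- complete_linkage(dist(chain))
  ord <- leaf_ordering(hc)
  expect_setequal(ord, 1:5)
  pos <- match(1:5, ord)
  expect_equal(abs(pos[1] - pos[2]), 1)                # {1,2} adjacent
  expect_equal(diff(range(pos[3:5])), 2)               # {3,4,5} contiguous
  expect_identical(ord, leaf_ordering(complete_linkage(dist(chain))))

  # permuting input rows permutes the clustering but not its structure
  set.seed(36)
  m <- rbind(matrix(rnorm(12, 0, 0.2), 4, 3), matrix(rnorm(12, 6, 0.2), 4, 3))
  rownames(m) <- sprintf("r%d", 1:8)
  perm <- sample(8)
  lab1 <- cut_tree(complete_linkage(dist(m)), 2)
  lab2 <- cut_tree(complete_linkage(dist(m[perm, ])), 2)
  expect_equal(ari(lab1[perm], lab2), 1)
})

test_that("window-profile correlations behave like Pearson r", {
  m <- rbind(w1 = c(1, 2, 3, 4), w2 = c(1, 2, 3, 4), w3 = -c(1, 2, 3, 4))
  r <- age_group_correlations(m)
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)

  set.seed(37)
  x <- matrix(rnorm(100), 5, 20)
  got <- age_group_correlations(x)
  for (i in 1:5) for (j in 1:5) {
    xi <- x[i, ]; xj <- x[j, ]
    want <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(got[i, j], want, tolerance = 1e-12)
  }

  x[2, ] <- 3
  expect_warning(r2 <- age_group_correlations(x), "Zero-variance")
  expect_true(all(is.na(r2[2, -2])))
})

test_that("cluster mean curves recover templates and flag extremes", {
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(NULL, sprintf("window_%d", 1:10)))
  mc1 <- cluster_mean_curves(m, rep(1, 4))
  expect_equal(mc1$means$mean_diff, unname(colMeans(m)))

  set.seed(38)
  t1 <- dnorm(1:10, mean = 4, sd = 1.5) * 0.2   # unique interior peak
  t2 <- -t1
  m2 <- rbind(t(replicate(6, t1 + rnorm(10, 0, 0.002))),
              t(replicate(6, t2 + rnorm(10, 0, 0.002))))
  colnames(m2) <- sprintf("window_%d", 1:10)
  mc2 <- cluster_mean_curves(m2, rep(1:2, each = 6))
  expect_lt(max(abs(mc2$means$mean_diff[mc2$means$cluster == 1] - t1)), 0.005)
  expect_equal(mc2$extremes$peak_window[1], which.max(t1))

  zeros <- matrix(0, 3, 5, dimnames = list(NULL, sprintf("window_%d", 1:5)))
  mcz <- cluster_mean_curves(zeros, c(1, 1, 2))
  expect_true(all(mcz$extremes$flat))

  expect_error(cluster_mean_curves(m, rep(1, 3)),
               class = "entrajectory_parameter_error")
})

test_that("planted two-cluster curve sets are recovered exactly across seeds", {
  noise_sd <- 0.004
  t1 <- cos(seq(0, 2 * pi, length.out = 21)) * 0.02
  t2 <- t1 + 0.04 * sin(seq(0, pi, length.out = 21))
  sep <- sqrt(sum((t1 - t2)^2))
  expect_gte(sep, 10 * noise_sd)
  for (s in 1:50) {
    set.seed(400 + s)
    m <- rbind(t(replicate(7, t1 + rnorm(21, 0, noise_sd))),
               t(replicate(13, t2 + rnorm(21, 0, noise_sd))))
    colnames(m) <- sprintf("window_%d", 1:21)
    res <- cluster_curves(m, k_range = 2:6, k = 2)
    expect_equal(ari(res$labels, rep(1:2, c(7, 13))), 1)
  }
})

test_that("cluster trendline comparison offers paired and unpaired tests", {
  set.seed(39)
  means <- tibble::tibble(
    cluster = rep(1:2, each = 21),
    window_index = rep(1:21, 2),
    mean_diff = c(rnorm(21, 0, 0.01), rnorm(21, 0.005, 0.01))
  )
  paired <- compare_cluster_trendlines(means, paired = TRUE)
  unpaired <- compare_cluster_trendlines(means, paired = FALSE)
  expect_equal(paired$method, "paired-by-window")
  expect_equal(paired$df, 20)
  expect_equal(unpaired$df, 40)
  expect_true(paired$p_value >= 0 && paired$p_value <= 1)
})
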