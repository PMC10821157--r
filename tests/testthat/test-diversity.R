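test_that("alpha indices match hand-computed values", {
  m <- rbind(s1 = c(25, 25, 25, 25), s2 = c(10, 1, 1, 0))
  colnames(m) <- paste0("t", 1:4)
  at <- alpha_diversity(community_from_matrix(m))
  expect_equal(at$shannon[1], log(4))
  expect_equal(at$simpson[1], 0.75)
  expect_equal(at$pielou[1], 1)
  expect_equal(at$richness, c(4L, 3L))

  # Chao1: S_obs = 10, F1 = 4, F2 = 2 -> 10 + 16/4 = 14
  x <- c(rep(1, 4), rep(2, 2), rep(7, 4))
  m2 <- rbind(s1 = x); colnames(m2) <- paste0("t", 1:10)
  expect_equal(alpha_diversity(community_from_matrix(m2))$chao1, 14)
  # bias-corrected branch when F2 = 0: 10 + 4*3/2 = 16
  x[x == 2] <- 3
  m3 <- rbind(s1 = x); colnames(m3) <- paste0("t", 1:10)
  expect_equal(alpha_diversity(community_from_matrix(m3))$chao1, 16)
})

test_that("Faith's PD on a star tree is the taxon count; Pielou NA for singletons", {
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:9, ":1", collapse = ","), ");"))
  m <- rbind(s1 = c(rep(1, 7), 0, 0), s2 = c(1, rep(0, 8)))
  colnames(m) <- paste0("t", 1:9)
  at <- alpha_diversity(community_from_matrix(m), tree = star)
  expect_equal(at$faith_pd[1], 7)
  expect_true(is.na(at$pielou[2]))
})

test_that("Shannon is maximal exactly at equal abundances", {
  set.seed(5)
  for (i in 1:20) {
    S <- sample(3:12, 1)
    uneven <- rmultinom(1, 200, runif(S))[, 1] + 1
    even <- rep(10, S)
    m <- rbind(u = uneven, e = even)
    colnames(m) <- paste0("t", seq_len(S))
    at <- alpha_diversity(community_from_matrix(m))
    if (length(unique(uneven)) > 1) expect_lt(at$shannon[1], at$shannon[2])
  }
})

test_that("Bray-Curtis matches the definition and is bounded", {
  m <- rbind(x = c(6, 0, 2), y = c(2, 2, 0))
  colnames(m) <- c("A", "B", "C")
  expect_equal(as.matrix(bray_curtis(community_from_matrix(m)))["x", "y"], 8 / 12)
  m2 <- rbind(a = c(1, 2, 0, 0), b = c(0, 0, 3, 4), c = c(1, 2, 0, 0))
  colnames(m2) <- paste0("t", 1:4)
  bc <- as.matrix(bray_curtis(community_from_matrix(m2)))
  expect_equal(bc["a", "b"], 1)   # disjoint
  expect_equal(bc["a", "c"], 0)   # identical
  set.seed(6)
  for (i in 1:50) {
    mm <- matrix(rpois(5 * 8, 2), 5, 8); mm[rowSums(mm) == 0, 1] <- 1
    colnames(mm) <- paste0("t", 1:8); rownames(mm) <- paste0("s", 1:5)
    b <- as.matrix(bray_curtis(community_from_matrix(mm)))
    expect_true(all(b >= 0 & b <= 1))
    expect_equal(b, t(b))
    expect_true(all(diag(b) == 0))
  }
})

test_that("PCoA recovers Euclidean configurations and scales equivariantly", {
  set.seed(7)
  pts <- matrix(rnorm(16), 8, 2)
  ord <- pcoa_ord(dist(pts), k = 2)
  pro <- vegan::procrustes(pts, as.matrix(ord$points[, c("Axis1", "Axis2")]),
                           symmetric = FALSE)
  expect_lt(pro$ss, 1e-16)
  ord2 <- pcoa_ord(dist(pts) * 2, k = 2)
  expect_equal(abs(as.matrix(ord2$points[-1])), 2 * abs(as.matrix(ord$points[-1])),
               tolerance = 1e-8)
  expect_equal(ord2$proportion, ord$proportion, tolerance = 1e-12)
  # two samples: one axis, all variance
  o2 <- pcoa_ord(dist(c(0, 3)))
  expect_equal(ncol(o2$points) - 1, 1)
  expect_equal(o2$proportion[1], 1)
  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("ANOSIM separates block structure and is reproducible", {
  m <- rbind(a1 = c(10, 10, 0, 0), a2 = c(9, 11, 0, 0),
             b1 = c(0, 0, 10, 10), b2 = c(0, 0, 11, 9))
  colnames(m) <- paste0("t", 1:4)
  d <- bray_curtis(community_from_matrix(m))
  res <- anosim_test(d, c("a", "a", "b", "b"), n_perm = 199, seed = 3)
  expect_equal(res$statistic, 1)
  res2 <- anosim_test(d, c("a", "a", "b", "b"), n_perm = 199, seed = 3)
  expect_identical(res, res2)
  expect_error(anosim_test(d, c("a", "a", "b", "c")), "singleton")
})

test_that("ANOSIM R is centred near zero under random labels", {
  set.seed(10)
  rs <- replicate(200, {
    mm <- matrix(rpois(20 * 15, 4), 20, 15); mm[rowSums(mm) == 0, 1] <- 1
    colnames(mm) <- paste0("t", 1:15); rownames(mm) <- paste0("s", 1:20)
    d <- bray_curtis(community_from_matrix(mm))
    g <- sample(rep(c("a", "b"), each = 10))
    fit <- vegan::anosim(d, g, permutations = 0)
    unname(fit$statistic)
  })
  expect_lt(mean(abs(rs)), 0.15)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("group tests match known small-sample answers", {
  d <- data.frame(v = c(5, 5, 5, 5, 5, 5), g = rep(c("a", "b", "c"), 2))
  expect_equal(group_tests(d, "v", "g")$statistic, 0)
  d2 <- data.frame(v = c(1, 2, 3, 10, 11, 12), g = rep(c("a", "b"), each = 3))
  gt <- group_tests(d2, "v", "g", pairwise = TRUE)
  mw <- gt[gt$test == "mann_whitney_u", ]
  expect_equal(mw$statistic, 0)
  expect_lt(mw$p_value, 0.1)
  expect_error(group_tests(data.frame(v = 1:3, g = "a"), "v", "g"), "2 groups")
})

test_that("Spearman screen honours monotone invariance and flags significance", {
  set.seed(8)
  x <- tibble::tibble(sample = paste0("s", 1:12), idx = rnorm(12))
  y <- tibble::tibble(sample = x$sample, up = exp(x$idx), down = -x$idx,
                      flat = rep(1, 12))
  sc <- spearman_screen(x, y)
  expect_equal(sc$rho[sc$var_y == "up"], 1)
  expect_equal(sc$rho[sc$var_y == "down"], -1)
  expect_true(is.na(sc$rho[sc$var_y == "flat"]))
  # t-approximation agrees with cor.test's non-exact path
  xv <- rnorm(15); yv <- rnorm(15)
  ct <- suppressWarnings(cor.test(xv, yv, method = "spearman", exact = FALSE))
  x2 <- tibble::tibble(sample = paste0("s", 1:15), a = xv)
  y2 <- tibble::tibble(sample = x2$sample, b = yv)
  sc2 <- spearman_screen(x2, y2)
  expect_equal(sc2$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(sc2$p_value, ct$p.value, tolerance = 1e-6)
})
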