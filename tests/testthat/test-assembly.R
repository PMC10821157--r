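test_that("betaMNTD equals hand-derived values on a 3-tip tree", {
  tree <- ape::read.tree(text = "(A:1,(B:1,C:1):1);")
  m <- rbind(s1 = c(1, 0, 0), s2 = c(0, 1, 0), s3 = c(1, 0, 0))
  colnames(m) <- c("A", "B", "C")
  b <- as.matrix(beta_mntd(community_from_matrix(m), tree))
  expect_equal(b["s1", "s2"], 3)   # patristic A-B
  expect_equal(b["s1", "s3"], 0)   # identical samples
})

test_that("betaMNTD agrees with the naive double-loop oracle", {
  set.seed(20)
  for (i in 1:10) {
    tree <- simulate_tree(20, seed = i)
    m <- matrix(rpois(6 * 20, 2), 6, 20,
                dimnames = list(paste0("s", 1:6), tree$tip.label))
    m[cbind(which(rowSums(m) == 0), 1)] <- 1
    keep <- colSums(m) > 0
    m <- m[, keep, drop = FALSE]
    D <- ape::cophenetic.phylo(tree)[colnames(m), colnames(m)]
    comm <- community_from_matrix(m)
    for (w in c(TRUE, FALSE)) {
      got <- as.matrix(beta_mntd(comm, tree, abundance_weighted = w))
      want <- bmntd_oracle(m, D, weighted = w)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("weighted betaMNTD agrees with picante", {
  tree <- simulate_tree(25, seed = 31)
  set.seed(31)
  m <- matrix(rpois(8 * 25, 2), 8, 25,
              dimnames = list(paste0("s", 1:8), tree$tip.label))
  m[cbind(which(rowSums(m) == 0), 1)] <- 1
  m <- m[, colSums(m) > 0]
  got <- as.matrix(beta_mntd(community_from_matrix(m), tree))
  ref <- as.matrix(picante::comdistnt(m, ape::cophenetic.phylo(tree),
                                      abundance.weighted = TRUE))
  expect_equal(got, ref[rownames(got), colnames(got)], tolerance = 1e-10)
})

test_that("betaNTI handles degenerate star-tree nulls and is label-invariant", {
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:10, ":1", collapse = ","), ");"))
  set.seed(4)
  m <- matrix(rpois(4 * 10, 2), 4, 10,
              dimnames = list(paste0("s", 1:4), star$tip.label))
  m[, colSums(m) == 0] <- 1; m[rowSums(m) == 0, 1] <- 1
  expect_warning(bn <- beta_nti(community_from_matrix(m), star, n_null = 49, seed = 1),
                 "zero null variance")
  expect_true(all(is.na(bn[upper.tri(bn)])))

  # joint relabeling of OTUs in matrix and tree leaves betaNTI unchanged
  tree <- simulate_tree(15, seed = 7)
  set.seed(7)
  m2 <- matrix(rpois(5 * 15, 3), 5, 15,
               dimnames = list(paste0("s", 1:5), tree$tip.label))
  m2[rowSums(m2) == 0, 1] <- 1; m2 <- m2[, colSums(m2) > 0]
  b1 <- beta_nti(community_from_matrix(m2), tree, n_null = 99, seed = 5)
  relab <- setNames(paste0("X", seq_len(ncol(m2))), colnames(m2))
  m3 <- m2; colnames(m3) <- unname(relab[colnames(m2)])
  tree3 <- tree; tree3$tip.label <- unname(relab[tree$tip.label])
  b2 <- beta_nti(community_from_matrix(m3), tree3, n_null = 99, seed = 5)
  expect_equal(unname(b1), unname(b2), tolerance = 1e-12)

  b3 <- beta_nti(community_from_matrix(m2), tree, n_null = 99, seed = 5)
  expect_identical(b1, b3)  # bit-reproducible under the same seed
})

test_that("RCbray hits its limits: identical pairs -1, disjoint pairs near +1", {
  set.seed(9)
  pool <- rpois(40, 5) + 1
  m <- rbind(s1 = pool, s2 = pool,
             s3 = c(pool[1:20], rep(0, 20)), s4 = c(rep(0, 20), pool[21:40]))
  colnames(m) <- paste0("t", 1:40)
  rc <- raup_crick(community_from_matrix(m), n_null = 199, seed = 2)
  expect_equal(rc["s1", "s2"], -1)
  expect_gt(rc["s3", "s4"], 0.9)
  expect_true(all(rc[upper.tri(rc)] >= -1 & rc[upper.tri(rc)] <= 1))
  rc2 <- raup_crick(community_from_matrix(m), n_null = 199, seed = 2)
  expect_identical(rc, rc2)
})

test_that("RCbray matches an independent R implementation of the null", {
  set.seed(14)
  m <- matrix(rpois(6 * 25, 3), 6, 25,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:25)))
  m[rowSums(m) == 0, 1] <- 1
  comm <- community_from_matrix(m)
  got <- raup_crick(comm, n_null = 999, seed = 3)
  occ <- colMeans(m > 0); ab <- colSums(m) / sum(m)
  oracle_pair <- function(a, b, n_null = 999) {
    obs <- sum(abs(m[a, ] - m[b, ])) / sum(m[a, ] + m[b, ])
    nullbc <- replicate(n_null, {
      mk <- function(k) {
        r <- sum(m[k, ] > 0)
        ch <- sample(ncol(m), r, prob = occ)
        v <- numeric(ncol(m)); v[ch] <- 1
        if (sum(m[k, ]) > r) v[ch] <- v[ch] + drop(rmultinom(1, sum(m[k, ]) - r, ab[ch]))
        v
      }
      x <- mk(a); y <- mk(b)
      sum(abs(x - y)) / sum(x + y)
    })
    2 * ((sum(nullbc < obs) + 0.5 * sum(nullbc == obs)) / n_null) - 1
  }
  set.seed(99)
  for (pr in list(c(1, 2), c(3, 5))) {
    expect_equal(got[pr[1], pr[2]], oracle_pair(pr[1], pr[2]), tolerance = 0.08)
  }
})

test_that("process classification follows the strict threshold cascade", {
  grid <- expand.grid(bnti = c(-3, -2, 0, 2, 2.5),
                      rc = c(-0.99, -0.95, 0, 0.95, 0.99))
  got <- lakeassembly:::classify_pair(grid$bnti, grid$rc)
  want <- with(grid, ifelse(bnti < -2, "homogeneous_selection",
               ifelse(bnti > 2, "heterogeneous_selection",
               ifelse(rc > 0.95, "dispersal_limitation",
               ifelse(rc < -0.95, "homogeneous_dispersal", "undominated")))))
  expect_equal(got, want)
  # spot checks from the decision rule
  expect_equal(lakeassembly:::classify_pair(-3, 0.99), "homogeneous_selection")
  expect_equal(lakeassembly:::classify_pair(1.0, 0.99), "dispersal_limitation")
  expect_equal(lakeassembly:::classify_pair(2.0, 0.0), "undominated")
})

test_that("classified fractions sum to 100 and NA pairs are excluded", {
  ids <- paste0("s", 1:6)
  set.seed(3)
  bn <- matrix(rnorm(36, 0, 2), 6, 6, dimnames = list(ids, ids))
  bn[lower.tri(bn)] <- t(bn)[lower.tri(bn)]; diag(bn) <- 0
  rc <- matrix(runif(36, -1, 1), 6, 6, dimnames = list(ids, ids))
  rc[lower.tri(rc)] <- t(rc)[lower.tri(rc)]; diag(rc) <- NA
  bn[1, 2] <- bn[2, 1] <- NA
  res <- classify_processes(bn, rc)
  expect_equal(sum(res$fractions$percent), 100, tolerance = 0.01)
  expect_equal(res$n_excluded, 1)
  expect_equal(nrow(tidy(res)), 15)
  g <- glance(res)
  expect_equal(g$n_pairs, 15)
  # within-group restriction
  grp <- setNames(rep(c("A", "B"), each = 3), ids)
  resw <- classify_processes(bn, rc, groups = grp, within_group = TRUE)
  expect_equal(nrow(tidy(resw)), 6)
})

test_that("betaNTI-environment correlation finds monotone structure", {
  ids <- paste0("s", 1:10)
  set.seed(21)
  v <- sort(runif(10, 0, 5))
  dv <- abs(outer(v, v, "-"))
  bn <- 2 * dv - 3 + 0  # strictly monotone in delta-v
  dimnames(bn) <- list(ids, ids)
  env <- tibble::tibble(sample = ids, driver = v, noise = rnorm(10))
  res <- bnti_env_correlation(bn, env, n_perm = 199, seed = 5)
  expect_equal(res$rho[res$variable == "driver"], 1)
  expect_lt(res$p_value[res$variable == "driver"], 0.05)
  expect_gt(res$p_value[res$variable == "noise"], 0.05)
  # agrees with a naive all-pairs Spearman
  ut <- upper.tri(bn)
  expect_equal(res$rho[res$variable == "noise"],
               cor(bn[ut], abs(outer(env$noise, env$noise, "-"))[ut],
                   method = "spearman"))
})

test_that("Mantel permutation p is roughly uniform for independent matrices", {
  set.seed(30)
  ps <- replicate(100, {
    ids <- paste0("s", 1:8)
    bn <- matrix(rnorm(64), 8, 8, dimnames = list(ids, ids))
    bn[lower.tri(bn)] <- t(bn)[lower.tri(bn)]; diag(bn) <- 0
    env <- tibble::tibble(sample = ids, x = rnorm(8))
    bnti_env_correlation(bn, env, n_perm = 49, seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(ps <= 0.1), 0.03)
  expect_lt(mean(ps <= 0.1), 0.2)
})
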