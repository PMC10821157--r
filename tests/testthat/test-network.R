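test_that("perfectly correlated OTUs form an edge; sub-threshold pairs never do", {
  set.seed(1)
  a <- round(abs(rnorm(10)) * 10) + 1
  m <- cbind(a = a, b = 2 * a,                  # rho = 1
             c = rpois(10, 5) + 1, d = rpois(10, 5) + 1)
  rownames(m) <- paste0("s", 1:10)
  net <- build_network(community_from_matrix(m), prevalence_min = 0)
  expect_true(any(net$edges$otu_1 == "a" & net$edges$otu_2 == "b" |
                  net$edges$otu_1 == "b" & net$edges$otu_2 == "a"))
  expect_equal(net$edges$rho[1], 1)

  # |rho| = 0.79 is excluded by the strict 0.8 threshold no matter the p
  x <- 1:10
  y <- c(3, 1, 5, 2, 7, 4, 9, 6, 10, 8)   # rho = 0.794
  stopifnot(abs(cor(x, y, method = "spearman")) < 0.8)
  m2 <- cbind(a = x, b = y, c = rev(x) + c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1))
  rownames(m2) <- paste0("s", 1:10)
  net2 <- suppressWarnings(build_network(community_from_matrix(m2), prevalence_min = 0))
  expect_false(any((net2$edges$otu_1 == "a" & net2$edges$otu_2 == "b") |
                   (net2$edges$otu_1 == "b" & net2$edges$otu_2 == "a")))
})

test_that("BH adjustment over tested pairs matches the hand computation", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"), rep(0.03, 3))
})

test_that("with thresholds disabled the complete correlation graph appears", {
  comm <- toy_community(10, 12, seed = 3, lambda = 6)
  net <- build_network(comm, r_threshold = 0, p_threshold = 1.01,
                       prevalence_min = 0)
  S <- length(setdiff(names(comm), "sample"))
  expect_equal(nrow(net$edges), net$n_tested)
  expect_equal(net$n_tested, S * (S - 1) / 2)
})

test_that("edge set is invariant to sample and OTU order", {
  comm <- toy_community(12, 15, seed = 8, lambda = 5)
  canon <- function(net) {
    e <- net$edges
    key <- ifelse(e$otu_1 < e$otu_2, paste(e$otu_1, e$otu_2), paste(e$otu_2, e$otu_1))
    sort(paste(key, round(e$rho, 12)))
  }
  n1 <- build_network(comm, r_threshold = 0.5, p_threshold = 0.2, prevalence_min = 0)
  comm2 <- comm[sample(nrow(comm)), c("sample", sample(setdiff(names(comm), "sample")))]
  n2 <- build_network(comm2, r_threshold = 0.5, p_threshold = 0.2, prevalence_min = 0)
  expect_identical(canon(n1), canon(n2))
})

test_that("topology identities hold on canonical graphs", {
  tri <- igraph::make_full_graph(3)
  t1 <- net_topology(tri)
  expect_equal(t1$avg_degree, 2)
  expect_equal(t1$density, 1)
  expect_equal(t1$avg_clustering, 1)
  expect_equal(t1$avg_path_length, 1)
  expect_equal(t1$modularity, 0, tolerance = 1e-12)

  two_tri <- igraph::disjoint_union(igraph::make_full_graph(3),
                                    igraph::make_full_graph(3))
  expect_equal(net_topology(two_tri)$modularity, 0.5)   # Newman sum(e_ii - a_i^2)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_true(is.na(net_topology(empty)$avg_degree))
})

test_that("ER ensemble honours the fixed-edge identities", {
  ens <- er_ensemble(60, 120, n_rand = 40, seed = 2)
  expect_true(all(ens$replicates$avg_degree == 2 * 120 / 60))
  expect_true(all(ens$replicates$density == 2 * 120 / (60 * 59)))
  expect_error(er_ensemble(5, 11), "infeasible")
  # reproducibility
  ens2 <- er_ensemble(60, 120, n_rand = 40, seed = 2)
  expect_identical(ens$summary, ens2$summary)
})

test_that("ER clustering approximates density at moderate size", {
  ens <- er_ensemble(300, 1700, n_rand = 60, seed = 4)
  cc <- ens$summary[ens$summary$property == "avg_clustering", ]
  dens <- 2 * 1700 / (300 * 299)
  expect_lt(abs(cc$mean - dens), 3 * cc$sd / sqrt(60) + 3 * cc$sd)
})

test_that("modularity of block-structured communities exceeds the ER ensemble", {
  hits <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_groups = 3, samples_per_group = 5, n_taxa = 120,
                      regime = "dispersal_limitation", spatial_decay_rate = 5,
                      m = 0.3, library_size = 2000, seed = seed)
    sim <- simulate_metacommunity(cfg)
    net <- suppressWarnings(build_network(sim$community, r_threshold = 0.7,
                                          p_threshold = 0.05))
    if (igraph::ecount(net$graph) < 10) return(NA)
    emp <- net_topology(net)$modularity
    ens <- er_ensemble(igraph::vcount(net$graph), igraph::ecount(net$graph),
                       n_rand = 30, seed = seed)
    emp > ens$summary$mean[ens$summary$property == "modularity"]
  }, logical(1))
  expect_gte(sum(hits, na.rm = TRUE), 8)
})

test_that("per-sample subnetworks reduce to the full network when saturated", {
  comm <- toy_community(10, 10, seed = 5, lambda = 8)
  net <- suppressWarnings(build_network(comm, r_threshold = 0.3,
                                        p_threshold = 0.9, prevalence_min = 0))
  skip_if(igraph::ecount(net$graph) == 0)
  m <- as.matrix(comm[-1])
  full_sample <- comm$sample[which.max(rowSums(m > 0))]
  # force one sample to contain every node
  comm2 <- comm
  comm2[comm2$sample == full_sample, -1] <-
    as.list(pmax(unlist(comm2[comm2$sample == full_sample, -1]), 1))
  net2 <- suppressWarnings(build_network(comm2, r_threshold = 0.3,
                                         p_threshold = 0.9, prevalence_min = 0))
  props <- sample_subnetwork_properties(net2, comm2)
  full_row <- props[props$sample == full_sample, ]
  expect_equal(full_row$nodes, igraph::vcount(net2$graph))
  expect_equal(full_row$edges, igraph::ecount(net2$graph))
  expect_equal(full_row$modularity, net_topology(net2)$modularity)
})
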