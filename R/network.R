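#' Build a thresholded Spearman co-occurrence network
#'
#' Computes all pairwise Spearman correlations between OTUs (after a
#' prevalence prefilter), adjusts the two-sided p-values with
#' Benjamini-Hochberg over every tested pair, and keeps edges with
#' `|rho| > r_threshold` and adjusted p below `p_threshold`. Isolated nodes
#' are dropped.
#'
#' @param comm community tibble (>= 8 samples for meaningful p-values)
#' @param r_threshold absolute-correlation cutoff, strict (default 0.8)
#' @param p_threshold BH-adjusted p cutoff, strict (default 0.01)
#' @param prevalence_min keep OTUs present in at least this fraction of
#'   samples (default 1/3); heavy prefiltering is what takes thousands of
#'   OTUs down to a few hundred network nodes
#' @return a `cooccur_network`: list with `graph` (signed [igraph] graph with
#'   edge attributes `rho`, `p_adj`, `sign`) and `edges` (tibble)
#' @export
build_network <- function(comm, r_threshold = 0.8, p_threshold = 0.01,
                          prevalence_min = 1 / 3) {
  validate_community(comm)
  m <- as_count_matrix(comm)
  if (nrow(m) < 8) warning("fewer than 8 samples: correlation p-values are weak",
                           call. = FALSE)
  keep <- colMeans(m > 0) >= prevalence_min
  m <- m[, keep, drop = FALSE]
  S <- ncol(m)
  if (S < 2) stop("fewer than 2 OTUs pass the prevalence filter", call. = FALSE)
  n <- nrow(m)
  rho <- cor(m, method = "spearman")
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[ut]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  pval <- 2 * pt(-abs(tstat), df = n - 2)
  pval[abs(r) >= 1] <- 0
  padj <- p.adjust(pval, method = "BH")
  sel <- abs(r) > r_threshold & padj < p_threshold & !is.na(r)
  edges <- new_tbl(otu_1 = colnames(m)[ut[sel, 1]],
                   otu_2 = colnames(m)[ut[sel, 2]],
                   rho = r[sel], p_adj = padj[sel],
                   sign = ifelse(r[sel] > 0, "positive", "negative"))
  if (nrow(edges) == 0) {
    warning("no edges survive the thresholds; empty network", call. = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  structure(list(graph = g, edges = edges,
                 n_tested = length(r), n_otus_screened = S),
            class = "cooccur_network")
}

#' @export
print.cooccur_network <- function(x, ...) {
  cat("Co-occurrence network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

#' @export
tidy.cooccur_network <- function(x, ...) x$edges

#' @export
glance.cooccur_network <- function(x, ...) net_topology(x)

#' Topological properties of a network
#'
#' Average degree `2E/N`, graph density `2E/(N(N-1))`, mean local clustering
#' (nodes of degree < 2 contribute 0), modularity of a greedy community
#' partition of the unsigned graph, average shortest-path length on the
#' largest connected component, harmonic geodesic distance (harmonic mean of
#' finite geodesics), geodesic efficiency (mean of 1/geodesic over all node
#' pairs, disconnected pairs contributing 0), and the positive/negative edge
#' percentages when edge signs are present.
#'
#' @param net a `cooccur_network` or an [igraph] graph
#' @return one-row tibble of properties (`NA`s for an empty graph);
#'   community detection uses deterministic greedy modularity maximization,
#'   so no seed is involved
#' @export
net_topology <- function(net) {
  g <- if (inherits(net, "cooccur_network")) net$graph else net
  N <- igraph::vcount(g); E <- igraph::ecount(g)
  if (N == 0 || E == 0) {
    return(new_tbl(nodes = N, edges = E, avg_degree = NA_real_,
                   density = NA_real_, avg_clustering = NA_real_,
                   modularity = NA_real_, avg_path_length = NA_real_,
                   harmonic_distance = NA_real_, efficiency = NA_real_,
                   pct_positive = NA_real_, pct_negative = NA_real_))
  }
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  lc[is.na(lc)] <- 0
  cm <- igraph::cluster_fast_greedy(igraph::simplify(g))
  geo <- igraph::distances(igraph::induced_subgraph(
    g, which(igraph::components(g)$membership ==
               which.max(igraph::components(g)$csize))))
  apl <- mean(geo[upper.tri(geo)])
  geo_all <- igraph::distances(g)
  inv <- 1 / geo_all[upper.tri(geo_all)]  # 1/Inf = 0 for disconnected pairs
  finite <- is.finite(geo_all[upper.tri(geo_all)]) & geo_all[upper.tri(geo_all)] > 0
  hd <- 1 / mean(inv[finite])
  eff <- mean(inv)
  sgn <- igraph::edge_attr(g, "sign")
  pct_pos <- if (is.null(sgn)) NA_real_ else 100 * mean(sgn == "positive")
  new_tbl(nodes = N, edges = E,
          avg_degree = 2 * E / N,
          density = 2 * E / (N * (N - 1)),
          avg_clustering = mean(lc),
          modularity = igraph::modularity(cm),
          avg_path_length = apl,
          harmonic_distance = hd,
          efficiency = eff,
          pct_positive = pct_pos,
          pct_negative = if (is.null(sgn)) NA_real_ else 100 - pct_pos)
}

#' Erdos-Renyi random-network ensemble
#'
#' Generates `n_rand` G(n, M) random graphs with the same node and edge
#' counts as an empirical network and summarizes their topology. Because the
#' edge count is fixed, every replicate's average degree is exactly `2M/N`
#' and its density exactly `2M/(N(N-1))`.
#'
#' @param n_nodes,n_edges node and edge counts to match
#' @param n_rand ensemble size (default 1000)
#' @param seed integer seed
#' @return list with `summary` (tibble: property, mean, sd) and `replicates`
#'   (tibble of per-replicate properties)
#' @export
er_ensemble <- function(n_nodes, n_edges, n_rand = 1000, seed = 1L) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop("infeasible edge count for ", n_nodes, " nodes", call. = FALSE)
  }
  set.seed(seed)
  reps <- purrr::map_dfr(seq_len(n_rand), function(i) {
    g <- igraph::sample_gnm(n_nodes, n_edges, directed = FALSE)
    net_topology(g)
  })
  num <- reps[vapply(reps, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("pct_positive", "pct_negative"))]
  summ <- new_tbl(property = names(num),
                  mean = vapply(num, mean, numeric(1)),
                  sd = vapply(num, sd, numeric(1)))
  list(summary = summ, replicates = reps)
}

#' Per-sample subnetwork properties joined with environment
#'
#' For every sample, induces the subgraph of the pooled co-occurrence
#' network on the OTUs that sample contains, computes its topology, and
#' (optionally) screens the properties against environmental factors with
#' [spearman_screen()]. Samples inducing an empty subgraph yield `NA` rows.
#'
#' @param net a `cooccur_network` built on the pooled samples
#' @param comm the community tibble the network was built from
#' @param env optional environmental tibble; when given, the returned list
#'   gains a `screen` element
#' @return tibble of per-sample properties, or list(`properties`, `screen`)
#' @export
sample_subnetwork_properties <- function(net, comm, env = NULL) {
  stopifnot(inherits(net, "cooccur_network"))
  m <- as_count_matrix(comm)
  nodes <- igraph::V(net$graph)$name
  props <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    present <- colnames(m)[m[i, ] > 0]
    sub <- igraph::induced_subgraph(net$graph, intersect(nodes, present))
    dplyr::bind_cols(new_tbl(sample = rownames(m)[i]), net_topology(sub))
  })
  if (is.null(env)) return(props)
  keep <- c("sample", "avg_degree", "density", "avg_clustering", "modularity",
            "avg_path_length", "harmonic_distance", "efficiency")
  list(properties = props,
       screen = spearman_screen(props[keep], env))
}
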