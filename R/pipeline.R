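# Fixed-format TSV writer: 6-decimal numerics so re-runs diff cleanly.
write_tsv6 <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- formatC(df[[nm]], format = "f", digits = 6)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix6 <- function(m, path) {
  df <- data.frame(sample = rownames(m),
                   formatC(m, format = "f", digits = 6),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Chains the analysis stages over one community: alpha/beta diversity,
#' environmental drivers (RDA + PCNM + variation partitioning), the neutral
#' model, betaNTI/RCbray null models with process classification, and the
#' co-occurrence network with its random ensemble. Each stage writes
#' tab-separated outputs with fixed 6-decimal formatting into `out_dir`,
#' plus a run log recording the seed and parameters; the same inputs and
#' seed reproduce the bundle byte-for-byte.
#'
#' @param community community tibble or path to an OTU table TSV
#' @param tree [ape::phylo] or Newick path; required for `diversity`
#'   (Faith's PD skipped if absent) and hard-required for `assembly`
#' @param env environmental tibble or TSV path; required for `drivers`
#' @param out_dir output directory (created if needed)
#' @param stages subset of `c("diversity", "drivers", "neutral", "assembly",
#'   "network")`
#' @param seed integer seed used by every stochastic stage
#' @param n_null null draws for betaNTI and RCbray (default 999)
#' @param n_perm permutations for ANOSIM/envfit/Mantel tests (default 999)
#' @param groups optional named vector mapping sample to lake label (used
#'   when the community table has no `group` column)
#' @param rarefy rarefy to the minimum library size before analysis
#' @return (invisibly) named list of written file paths
#' @export
run_pipeline <- function(community, tree = NULL, env = NULL, out_dir,
                         stages = c("diversity", "drivers", "neutral",
                                    "assembly", "network"),
                         seed = 1L, n_null = 999, n_perm = 999,
                         groups = NULL, rarefy = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  comm <- if (is.character(community)) read_community(community, groups = groups) else community
  validate_community(comm)
  if (is.character(tree)) tree <- read_tree(tree)
  if (is.character(env)) env <- read_env(env)
  if ("assembly" %in% stages && is.null(tree)) {
    stop("assembly stage requires a phylogenetic tree", call. = FALSE)
  }
  if ("drivers" %in% stages && is.null(env)) {
    stop("drivers stage requires environmental metadata", call. = FALSE)
  }
  if (rarefy) comm <- rarefy_community(comm, seed = seed)
  if (!is.null(env)) {
    al <- align_samples(comm, env)
    comm <- al$community; env <- al$env
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grp <- comm_groups(comm)
  files <- list()
  out <- function(name) file.path(out_dir, name)

  if ("diversity" %in% stages) {
    at <- alpha_diversity(comm, tree = tree)
    files$alpha <- write_tsv6(at, out("alpha_diversity.tsv"))
    d <- bray_curtis(comm)
    files$bray <- write_matrix6(as.matrix(d), out("bray_curtis.tsv"))
    ord <- pcoa_ord(d, k = 2)
    files$pcoa <- write_tsv6(ord$points, out("pcoa_coordinates.tsv"))
    if (length(unique(grp)) >= 2 && min(table(grp)) >= 2) {
      files$anosim <- write_tsv6(anosim_test(d, grp, n_perm = n_perm, seed = seed),
                                 out("anosim.tsv"))
    }
  }

  if ("drivers" %in% stages) {
    water_vars <- setdiff(names(env)[vapply(env, is.numeric, logical(1))],
                          c("sample", "longitude", "latitude", "altitude"))
    vf <- vif_filter(env[c("sample", water_vars)])
    rd <- rda_drivers(comm, env, variables = vf$variable,
                      n_perm = n_perm, seed = seed)
    files$rda <- write_tsv6(rd$factor_tests, out("rda_factor_tests.tsv"))
    if (all(c("longitude", "latitude") %in% names(env))) {
      sp <- pcnm_axes(env)
      files$vpa <- write_tsv6(vpa(comm, sp, env[c("sample", vf$variable)]),
                              out("vpa_fractions.tsv"))
    }
  }

  if ("neutral" %in% stages) {
    nf <- fit_neutral(comm)
    files$neutral <- write_tsv6(tidy(nf), out("neutral_fit_otus.tsv"))
    files$neutral_summary <- write_tsv6(glance(nf), out("neutral_fit_summary.tsv"))
  }

  if ("assembly" %in% stages) {
    bn <- beta_nti(comm, tree, n_null = n_null, seed = seed)
    rc <- raup_crick(comm, n_null = n_null, seed = seed)
    files$bnti <- write_matrix6(unclass(bn), out("bnti_matrix.tsv"))
    files$rcbray <- write_matrix6(rc, out("rcbray_matrix.tsv"))
    res <- classify_processes(bn, rc, groups = setNames(grp, comm$sample))
    files$processes <- write_tsv6(res$fractions, out("process_fractions.tsv"))
    files$pairs <- write_tsv6(res$pairs, out("process_pairs.tsv"))
    if (!is.null(env)) {
      files$bnti_env <- write_tsv6(
        bnti_env_correlation(bn, env, n_perm = n_perm, seed = seed),
        out("bnti_env_correlation.tsv"))
    }
  }

  if ("network" %in% stages) {
    net <- build_network(comm)
    files$edges <- write_tsv6(net$edges, out("network_edges.tsv"))
    top <- net_topology(net)
    files$topology <- write_tsv6(top, out("network_topology.tsv"))
    if (igraph::ecount(net$graph) > 0) {
      files$graphml <- out("network.graphml")
      igraph::write_graph(net$graph, files$graphml, format = "graphml")
      ens <- er_ensemble(igraph::vcount(net$graph), igraph::ecount(net$graph),
                         n_rand = 1000, seed = seed)
      files$ensemble <- write_tsv6(ens$summary, out("network_random_ensemble.tsv"))
    }
  }

  log_lines <- c(
    paste("lakeassembly", as.character(utils::packageVersion("lakeassembly"))),
    paste("R", getRversion()),
    paste("seed", seed), paste("n_null", n_null), paste("n_perm", n_perm),
    paste("stages", paste(stages, collapse = ",")),
    paste("samples", nrow(comm)), paste("otus", length(otu_columns(comm))),
    paste("rarefied", rarefy))
  writeLines(log_lines, out("run_log.txt"))
  files$log <- out("run_log.txt")
  invisible(files)
}
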