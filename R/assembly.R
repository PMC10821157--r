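# Shared plumbing for the pairwise null models --------------------------------

# Weight matrix for betaMNTD: relative abundance (weighted) or 1/S_k over
# present taxa (unweighted).
bmntd_weights <- function(m, abundance_weighted) {
  if (abundance_weighted) {
    relabund(m)
  } else {
    pres <- m > 0
    sweep(pres * 1, 1, rowSums(pres), "/")
  }
}

check_tree_cover <- function(m, tree) {
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing) > 0) {
    stop("OTUs missing from tree: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
}

dist_to_matrix <- function(v, ids) {
  n <- length(ids)
  out <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  out[lower.tri(out)] <- v
  out[upper.tri(out)] <- t(out)[upper.tri(out)]
  diag(out) <- 0
  out
}

pair_index <- function(ids) {
  n <- length(ids)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
  new_tbl(sample_1 = ids[i], sample_2 = ids[j])
}

# betaMNTD ---------------------------------------------------------------------

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For each sample pair, the mean patristic distance from every taxon in one
#' community to its closest relative in the other, averaged over both
#' directions; abundance-weighted by default.
#'
#' @param comm community tibble
#' @param tree [ape::phylo] covering every OTU in `comm`
#' @param abundance_weighted weight taxa by relative abundance (default) or
#'   equally
#' @return `dist` over samples
#' @export
beta_mntd <- function(comm, tree, abundance_weighted = TRUE) {
  validate_community(comm)
  m <- as_count_matrix(comm)
  check_tree_cover(m, tree)
  tree <- prune_tree(tree, colnames(m))
  D <- ape::cophenetic.phylo(tree)[colnames(m), colnames(m)]
  W <- bmntd_weights(m, abundance_weighted)
  res <- bmntd_perms(D, W, matrix(seq_len(ncol(m)) - 1L, ncol = 1))
  stats::as.dist(dist_to_matrix(res[1, ], rownames(m)))
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of [beta_mntd()] against a null that shuffles
#' taxon labels across all tree tips: for each pair,
#' `betaNTI = (bMNTD_obs - mean(bMNTD_null)) / sd(bMNTD_null)`.
#' `|betaNTI| > 2` flags deterministic turnover (selection);
#' `betaNTI < -2` homogeneous and `betaNTI > 2` heterogeneous selection.
#' Pairs whose null spread is zero (e.g. a star phylogeny) are `NA` with a
#' warning.
#'
#' @inheritParams beta_mntd
#' @param n_null number of label shuffles (default 999)
#' @param seed integer seed
#' @return symmetric matrix of betaNTI values (diagonal 0); attribute
#'   `bmntd_obs` holds the observed betaMNTD `dist`
#' @export
beta_nti <- function(comm, tree, n_null = 999, seed = 1L,
                     abundance_weighted = TRUE) {
  validate_community(comm)
  m <- as_count_matrix(comm)
  check_tree_cover(m, tree)
  tree <- prune_tree(tree, colnames(m))
  S <- ncol(m)
  D <- ape::cophenetic.phylo(tree)[colnames(m), colnames(m)]
  W <- bmntd_weights(m, abundance_weighted)

  obs <- bmntd_perms(D, W, matrix(seq_len(S) - 1L, ncol = 1))[1, ]
  set.seed(seed)
  perms <- vapply(seq_len(n_null), function(i) sample.int(S) - 1L,
                  integer(S))
  nulls <- bmntd_perms(D, W, perms)  # n_null x npairs
  mu <- colMeans(nulls)
  sdv <- apply(nulls, 2, sd)
  bnti <- (obs - mu) / sdv
  degenerate <- sdv < 1e-12
  if (any(degenerate)) {
    warning(sum(degenerate), " pair(s) with zero null variance reported NA",
            call. = FALSE)
    bnti[degenerate] <- NA_real_
  }
  out <- dist_to_matrix(bnti, rownames(m))
  attr(out, "bmntd_obs") <- stats::as.dist(dist_to_matrix(obs, rownames(m)))
  out
}

# Raup-Crick -------------------------------------------------------------------

bray_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)

#' Abundance-based Raup-Crick dissimilarity (RCbray)
#'
#' For each sample pair, null communities are assembled by (1) drawing each
#' sample's observed richness of taxa with probability proportional to
#' metacommunity occurrence frequency, then (2) filling to the observed
#' library size with individuals drawn proportionally to metacommunity
#' relative abundance among the chosen taxa. RCbray is the fraction of null
#' Bray-Curtis values below the observed one (ties half-weighted), rescaled
#' to \[-1, 1\]. `RCbray > 0.95` flags dispersal limitation,
#' `RCbray < -0.95` homogeneous dispersal.
#'
#' @param comm community tibble (integer counts)
#' @param n_null null assemblies per pair (default 999)
#' @param seed integer seed
#' @param occurrence,abundance optional explicit metacommunity: per-OTU
#'   occurrence frequencies and relative abundances (named or in column
#'   order). By default both are estimated from `comm`; supply them when the
#'   samples are a subset of a larger survey whose pool defines the null.
#' @return symmetric matrix of RCbray values (diagonal `NA`)
#' @export
raup_crick <- function(comm, n_null = 999, seed = 1L,
                       occurrence = NULL, abundance = NULL) {
  validate_community(comm)
  m <- as_count_matrix(comm)
  if (any(rowSums(m > 0) > ncol(m))) {
    stop("sample richness exceeds metacommunity richness", call. = FALSE)
  }
  occ <- occurrence %||% colMeans(m > 0)
  ab <- abundance %||% (colSums(m) / sum(m))
  if (!is.null(names(occ))) occ <- occ[colnames(m)]
  if (!is.null(names(ab))) ab <- ab[colnames(m)]
  stopifnot(length(occ) == ncol(m), length(ab) == ncol(m),
            !anyNA(occ), !anyNA(ab))
  storage.mode(m) <- "integer"
  set.seed(seed)
  rc <- rcbray_pairs(m, occ, ab, n_null)
  dimnames(rc) <- list(rownames(m), rownames(m))
  rc
}

# Process classification -------------------------------------------------------

classify_pair <- function(bnti, rc) {
  dplyr::case_when(
    is.na(bnti) | (abs(bnti) <= 2 & is.na(rc)) ~ NA_character_,
    bnti < -2 ~ "homogeneous_selection",
    bnti > 2 ~ "heterogeneous_selection",
    rc > 0.95 ~ "dispersal_limitation",
    rc < -0.95 ~ "homogeneous_dispersal",
    TRUE ~ "undominated")
}

process_levels <- c("homogeneous_selection", "heterogeneous_selection",
                    "dispersal_limitation", "homogeneous_dispersal",
                    "undominated")

#' Classify assembly processes from betaNTI and RCbray
#'
#' Applies the standard two-step decision rule per sample pair, with strict
#' inequalities (boundary values fall through to the next rule):
#' `betaNTI < -2` homogeneous selection; `betaNTI > 2` heterogeneous
#' selection; otherwise `RCbray > 0.95` dispersal limitation,
#' `RCbray < -0.95` homogeneous dispersal, else undominated. Fractions are
#' percentages over all classified (non-`NA`) pairs.
#'
#' @param bnti symmetric betaNTI matrix (from [beta_nti()])
#' @param rc symmetric RCbray matrix (from [raup_crick()]), aligned
#' @param groups optional group label per sample (named by sample id)
#' @param within_group restrict pairs to same-group comparisons
#' @return an `assembly_result`: list with `pairs` (tibble: sample_1,
#'   sample_2, bnti, rcbray, process) and `fractions` (tibble: process, n,
#'   percent), plus `n_excluded`
#' @export
classify_processes <- function(bnti, rc, groups = NULL, within_group = FALSE) {
  stopifnot(identical(dim(bnti), dim(rc)))
  ids <- rownames(bnti) %||% paste0("s", seq_len(nrow(bnti)))
  pairs <- pair_index(ids)
  idx <- cbind(match(pairs$sample_1, ids), match(pairs$sample_2, ids))
  pairs$bnti <- bnti[idx]
  pairs$rcbray <- rc[idx]
  if (!is.null(groups)) {
    pairs$group_1 <- unname(groups[pairs$sample_1])
    pairs$group_2 <- unname(groups[pairs$sample_2])
    if (within_group) pairs <- dplyr::filter(pairs, .data$group_1 == .data$group_2)
  }
  pairs$process <- classify_pair(pairs$bnti, pairs$rcbray)
  n_excluded <- sum(is.na(pairs$process))
  done <- pairs[!is.na(pairs$process), ]
  counts <- table(factor(done$process, levels = process_levels))
  fractions <- new_tbl(process = process_levels,
                       n = as.integer(counts),
                       percent = 100 * as.integer(counts) / max(nrow(done), 1))
  structure(list(pairs = pairs, fractions = fractions,
                 n_excluded = n_excluded),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("Assembly process classification over", nrow(x$pairs), "sample pairs\n")
  if (x$n_excluded > 0) cat(" (", x$n_excluded, " pair(s) excluded as NA)\n", sep = "")
  print(x$fractions)
  invisible(x)
}

#' @export
tidy.assembly_result <- function(x, ...) x$pairs

#' @export
glance.assembly_result <- function(x, ...) {
  wide <- setNames(as.list(x$fractions$percent), x$fractions$process)
  dplyr::bind_cols(new_tbl(n_pairs = nrow(x$pairs), n_excluded = x$n_excluded),
                   tibble::as_tibble(wide))
}

# betaNTI vs environmental differences -----------------------------------------

#' Correlate betaNTI with pairwise environmental differences
#'
#' For each environmental variable, computes the absolute between-sample
#' difference for every pair and the Spearman correlation with the paired
#' betaNTI values; significance by Mantel-style permutation of sample
#' labels. A positive rho for a variable means growing differences in that
#' factor push pairs away from homogeneous selection toward stochasticity
#' (or heterogeneous selection).
#'
#' @param bnti symmetric betaNTI matrix
#' @param env environmental tibble with `sample` column
#' @param variables env columns to test (default all numeric)
#' @param n_perm Mantel permutations (default 999)
#' @param seed integer seed
#' @return tibble with `variable`, `rho`, `p_value`
#' @export
bnti_env_correlation <- function(bnti, env, variables = NULL, n_perm = 999,
                                 seed = 1L) {
  ids <- rownames(bnti)
  stopifnot(!is.null(ids), all(ids %in% env$sample))
  env <- env[match(ids, env$sample), ]
  vars <- variables %||%
    setdiff(names(env)[vapply(env, is.numeric, logical(1))], "sample")
  ut <- upper.tri(bnti)
  b <- bnti[ut]
  set.seed(seed)
  purrr::map_dfr(vars, function(v) {
    x <- env[[v]]
    if (sd(x, na.rm = TRUE) == 0 || anyNA(x)) {
      return(new_tbl(variable = v, rho = NA_real_, p_value = NA_real_))
    }
    dv <- abs(outer(x, x, "-"))
    ok <- !is.na(b)
    rho_obs <- cor(b[ok], dv[ut][ok], method = "spearman")
    perm_rho <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(length(x))
      dvp <- dv[p, p]
      cor(b[ok], dvp[ut][ok], method = "spearman")
    }, numeric(1))
    p <- (sum(abs(perm_rho) >= abs(rho_obs)) + 1) / (n_perm + 1)
    new_tbl(variable = v, rho = rho_obs, p_value = p)
  })
}
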