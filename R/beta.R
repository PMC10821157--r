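#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum|x - y| / sum(x + y)`, symmetric with zero diagonal,
#' bounded in \[0, 1\].
#'
#' @param comm community tibble (>= 2 samples)
#' @return a `dist` object over samples
#' @export
bray_curtis <- function(comm) {
  validate_community(comm)
  m <- as_count_matrix(comm)
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the Gower-centred dissimilarity matrix. Negative
#' eigenvalues are reported but excluded from the variance-explained
#' denominator (no Lingoes/Cailliez correction), so the printed proportions
#' follow the positive-eigenvalue convention.
#'
#' @param d a `dist` or symmetric matrix with zero diagonal
#' @param k number of axes to keep (default all positive-eigenvalue axes)
#' @return list with `points` (tibble: sample, Axis1...), `eigenvalues`,
#'   and `proportion` (share of the positive-eigenvalue total per kept axis)
#' @export
pcoa_ord <- function(d, k = NULL) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("dissimilarity matrix must be symmetric", call. = FALSE)
  n <- nrow(dm)
  fit <- suppressWarnings(cmdscale(as.dist(dm), k = n - 1, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  k <- min(k %||% npos, npos)
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(k))
  ids <- rownames(dm) %||% paste0("s", seq_len(n))
  list(points = dplyr::bind_cols(new_tbl(sample = ids), tibble::as_tibble(pts)),
       eigenvalues = eig,
       proportion = eig[seq_len(k)] / sum(eig[eig > 0]))
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based permutation test of between- versus within-group
#' dissimilarity: `R = (mean rank between - mean rank within) / (M/2)` with
#' `M = n(n-1)/2`, `R` in \[-1, 1\]; p-value from permutations of the group
#' labels.
#'
#' @param d `dist` over samples
#' @param groups group (lake) label per sample; >= 2 groups of >= 2
#' @param n_perm number of label permutations (default 999)
#' @param seed integer seed
#' @return tibble with `statistic` (R) and `p_value`
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1L) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2)) {
    stop("singleton group(s): ", paste(names(tab)[tab < 2], collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  fit <- vegan::anosim(d, grouping = groups, permutations = n_perm)
  new_tbl(statistic = unname(fit$statistic), p_value = unname(fit$signif),
          n_perm = n_perm)
}

#' Group comparisons of a per-sample quantity
#'
#' Kruskal-Wallis rank-sum test (with tie correction) across all groups,
#' plus pairwise two-sided Mann-Whitney U tests (normal approximation with
#' continuity correction) when `pairwise = TRUE` - the latter matching the
#' bacteria-versus-microeukaryote index comparisons.
#'
#' @param data data frame with the value and grouping columns
#' @param value name of the numeric column
#' @param group name of the grouping column
#' @param pairwise also run all pairwise Mann-Whitney U tests
#' @return tibble of test results (`test`, `contrast`, `statistic`, `p_value`)
#' @export
group_tests <- function(data, value, group = "group", pairwise = FALSE) {
  v <- data[[value]]
  g <- as.character(data[[group]])
  if (length(unique(g)) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(unique(v)) == 1) {
    # all observations tied: no rank variation, H = 0 by convention
    out <- new_tbl(test = "kruskal_wallis", contrast = "all groups",
                   statistic = 0, p_value = 1)
  } else {
    kw <- kruskal.test(v, factor(g))
    out <- new_tbl(test = "kruskal_wallis", contrast = "all groups",
                   statistic = unname(kw$statistic), p_value = kw$p.value)
  }
  if (pairwise) {
    pairs <- utils::combn(sort(unique(g)), 2, simplify = FALSE)
    mw <- purrr::map_dfr(pairs, function(pr) {
      w <- suppressWarnings(wilcox.test(v[g == pr[1]], v[g == pr[2]],
                                        alternative = "two.sided",
                                        exact = FALSE, correct = TRUE))
      new_tbl(test = "mann_whitney_u",
              contrast = paste(pr, collapse = " vs "),
              statistic = unname(w$statistic), p_value = w$p.value)
    })
    out <- dplyr::bind_rows(out, mw)
  }
  out
}

# Spearman rho and two-sided p via the t approximation (midranks for ties).
spearman_rp <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0) {
    return(c(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(x, y, method = "spearman")
  if (abs(rho) >= 1) return(c(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Spearman correlation screen between two per-sample tables
#'
#' All pairwise Spearman correlations between the numeric columns of `x`
#' (e.g. alpha-diversity indices) and of `y` (e.g. environmental factors),
#' aligned on the `sample` column. P-values use the t approximation;
#' significance stars at 0.05 / 0.01 / 0.001, optionally after
#' Benjamini-Hochberg adjustment over the whole screen.
#'
#' @param x,y data frames sharing a `sample` column; other numeric columns
#'   are screened
#' @param adjust apply BH adjustment before starring (default `FALSE`)
#' @return tibble with `var_x`, `var_y`, `rho`, `p_value`, `p_adj`, `stars`
#' @export
spearman_screen <- function(x, y, adjust = FALSE) {
  al <- align_samples(x, y)
  xs <- al$community; ys <- al$env
  if (nrow(xs) < 5) stop("need at least 5 aligned samples", call. = FALSE)
  xv <- names(xs)[vapply(xs, is.numeric, logical(1))]
  yv <- names(ys)[vapply(ys, is.numeric, logical(1))]
  grid <- tidyr::expand_grid(var_x = xv, var_y = yv)
  res <- purrr::pmap_dfr(grid, function(var_x, var_y) {
    rp <- spearman_rp(xs[[var_x]], ys[[var_y]])
    new_tbl(var_x = var_x, var_y = var_y, rho = rp[["rho"]], p_value = rp[["p"]])
  })
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  pp <- if (adjust) res$p_adj else res$p_value
  res$stars <- dplyr::case_when(is.na(pp) ~ "", pp < 0.001 ~ "***",
                                pp < 0.01 ~ "**", pp < 0.05 ~ "*",
                                TRUE ~ "")
  res
}
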