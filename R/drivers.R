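#' Iterative variance-inflation-factor screening
#'
#' Drops, one at a time, the environmental variable with the largest VIF
#' (`1 / (1 - R^2)` from regressing it on the remaining variables) until
#' all VIFs fall below `threshold`. Ties are broken alphabetically so the
#' retained set is deterministic.
#'
#' @param env environmental tibble (`sample` plus numeric columns)
#' @param threshold keep variables with VIF below this (default 10)
#' @return tibble with `variable`, `vif` (final VIFs of retained set) and
#'   attribute `dropped` listing removals in order
#' @export
vif_filter <- function(env, threshold = 10) {
  vars <- sort(setdiff(names(env)[vapply(env, is.numeric, logical(1))], "sample"))
  if (length(vars) < 2) stop("need at least 2 numeric variables", call. = FALSE)
  if (nrow(env) <= 2) stop("need more than 2 samples", call. = FALSE)
  X <- as.data.frame(env[vars])
  vif_of <- function(keep) {
    vapply(keep, function(v) {
      r2 <- suppressWarnings(
        summary(lm(stats::reformulate(setdiff(keep, v), v), data = X))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  dropped <- character(0)
  keep <- vars
  repeat {
    vifs <- vif_of(keep)
    if (max(vifs) < threshold) break
    worst <- sort(names(vifs)[vifs == max(vifs)])[1]  # alphabetical tie-break
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
    if (length(keep) == 1) break
  }
  out <- new_tbl(variable = keep,
                 vif = if (length(keep) >= 2) unname(vif_of(keep)) else NA_real_)
  attr(out, "dropped") <- dropped
  out
}

#' Redundancy analysis of a community on environmental factors
#'
#' Hellinger-transforms the counts, standardizes the (VIF-screened)
#' environmental variables, and fits a constrained ordination. Per-factor
#' significance comes from marginal permutation tests (simple row
#' permutation of the community data, seeded); `envfit` vector fitting on
#' the site scores is returned for display (arrow directions and r2), since
#' its permutation p-values against the model's own constrained axes are
#' circular.
#'
#' @param comm community tibble
#' @param env environmental tibble restricted to the factors of interest
#' @param variables which env columns to constrain on (default all numeric)
#' @param n_perm permutations for the per-factor tests (default 999)
#' @param seed integer seed
#' @param transform `"hellinger"` (default) or `"none"`
#' @return list: `ordination` (the vegan rda object), `constrained_prop`
#'   (share of community variance explained by the constraints),
#'   `factor_tests` (tibble: variable, r2, p_value), `site_scores` (tibble)
#' @export
rda_drivers <- function(comm, env, variables = NULL, n_perm = 999, seed = 1L,
                        transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  al <- align_samples(comm, env)
  m <- as_count_matrix(al$community)
  vars <- variables %||%
    setdiff(names(al$env)[vapply(al$env, is.numeric, logical(1))], "sample")
  X <- as.data.frame(scale(al$env[vars]))
  if (length(vars) > nrow(m) - 1) {
    stop("more constraints (", length(vars), ") than samples - 1", call. = FALSE)
  }
  Y <- if (transform == "hellinger") vegan::decostand(m, "hellinger") else m
  ord <- vegan::rda(Y ~ ., data = X)
  set.seed(seed)
  marg <- vegan::anova.cca(ord, by = "margin", permutations = n_perm)
  terms <- rownames(marg) != "Residual"
  set.seed(seed)
  ef <- suppressWarnings(
    vegan::envfit(ord, X, permutations = 0, display = "sites"))
  n_axes <- max(1, min(2, length(ord$CCA$eig)))
  sc <- vegan::scores(ord, display = "sites", choices = seq_len(n_axes))
  list(ordination = ord,
       constrained_prop = ord$CCA$tot.chi / ord$tot.chi,
       factor_tests = new_tbl(variable = rownames(marg)[terms],
                              variance = marg$Variance[terms],
                              F = marg$F[terms],
                              p_value = marg$`Pr(>F)`[terms]),
       envfit_arrows = new_tbl(variable = rownames(ef$vectors$arrows),
                               r2 = unname(ef$vectors$r)),
       site_scores = dplyr::bind_cols(new_tbl(sample = al$community$sample),
                                      tibble::as_tibble(sc)))
}

#' Spatial eigenfunctions (PCNM) from sample coordinates
#'
#' Builds the between-sample distance matrix - great-circle (haversine)
#' distances from longitude/latitude by default, Euclidean when
#' `planar = TRUE` - truncates it at the largest minimum-spanning-tree
#' edge (distances beyond the threshold are replaced by 4x threshold), and
#' returns the positive-eigenvalue eigenvectors of the Gower-centred
#' truncated matrix as spatial variables.
#'
#' @param env tibble with `sample`, `longitude`, `latitude` columns
#' @param planar treat coordinates as planar (Euclidean) instead of degrees
#' @return tibble with `sample` and `PCNM1`, `PCNM2`, ... columns;
#'   attributes `threshold` and `eigenvalues`
#' @export
pcnm_axes <- function(env, planar = FALSE) {
  stopifnot(all(c("sample", "longitude", "latitude") %in% names(env)))
  xy <- as.matrix(env[, c("longitude", "latitude")])
  if (nrow(unique(xy)) < 3) stop("need at least 3 unique locations", call. = FALSE)
  d <- if (planar) {
    dist(xy)
  } else {
    as.dist(geosphere::distm(xy, fun = geosphere::distHaversine) / 1000)  # km
  }
  if (max(d) == 0) stop("all samples at one location", call. = FALSE)
  p <- vegan::pcnm(d)
  vec <- p$vectors
  out <- dplyr::bind_cols(new_tbl(sample = env$sample), tibble::as_tibble(vec))
  attr(out, "threshold") <- p$threshold
  attr(out, "eigenvalues") <- p$values
  out
}

#' Variation partitioning of community composition
#'
#' Partitions the (Hellinger-transformed) community variance between two
#' explanatory sets - typically PCNM spatial eigenfunctions and water
#' physicochemistry - by adjusted R-squared inclusion-exclusion:
#' pure spatial, pure water, shared, and residual fractions that sum to 1.
#' Slightly negative adjusted fractions are reported as-is.
#'
#' @param comm community tibble
#' @param spatial tibble of spatial variables with `sample` column
#' @param water tibble of water physicochemical variables with `sample` column
#' @param transform `"hellinger"` (default) or `"none"`
#' @return tibble with columns `fraction` and `adj_r2`
#'   (pure_spatial, pure_water, shared, residual)
#' @export
vpa <- function(comm, spatial, water, transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  stopifnot("sample" %in% names(spatial), "sample" %in% names(water))
  al <- align_samples(comm, spatial)
  al2 <- align_samples(al$community, water)
  comm <- al2$community
  S <- as.data.frame(al$env[match(comm$sample, al$env$sample),
                            setdiff(names(spatial), "sample"), drop = FALSE])
  W <- as.data.frame(al2$env[, setdiff(names(water), "sample"), drop = FALSE])
  if (ncol(S) == 0 || ncol(W) == 0) stop("both variable sets must be non-empty", call. = FALSE)
  m <- as_count_matrix(comm)
  Y <- if (transform == "hellinger") vegan::decostand(m, "hellinger") else m
  # Each explanatory set must be full rank on its own; collinearity *between*
  # the sets is legitimate (it is exactly what the shared fraction measures).
  rank_ok <- function(X) qr(cbind(1, as.matrix(X)))$rank == ncol(X) + 1
  for (set in list(S, W)) {
    if (!rank_ok(set)) {
      stop("rank-deficient explanatory set; collinear columns among: ",
           paste(names(set), collapse = ", "), call. = FALSE)
    }
  }
  vp <- vegan::varpart(Y, S, W)
  fr <- vp$part$indfract$Adj.R.square
  new_tbl(fraction = c("pure_spatial", "shared", "pure_water", "residual"),
          adj_r2 = fr)
}
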