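#' Per-sample alpha diversity
#'
#' Computes, for every sample: observed richness, Shannon-Wiener index
#' (natural log by default), Simpson's diversity (1 - sum p^2), Chao1
#' richness, Pielou evenness, and - when a tree is supplied - Faith's
#' phylogenetic diversity (total branch length of the subtree spanning the
#' sample's taxa, root path included).
#'
#' Chao1 uses the classic estimator `S_obs + F1^2 / (2 F2)` with singleton
#' count F1 and doubleton count F2, switching to the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` only when F2 = 0. Pielou is
#' Shannon / ln(S_obs), reported `NA` for single-taxon samples rather
#' than 0.
#'
#' @param comm community tibble
#' @param tree optional [ape::phylo] covering every OTU with nonzero counts
#' @param base logarithm base for Shannon (and Pielou); default `exp(1)`
#' @return tibble with one row per sample
#' @export
alpha_diversity <- function(comm, tree = NULL, base = exp(1)) {
  validate_community(comm)
  m <- as_count_matrix(comm)
  p <- relabund(m)
  shannon <- apply(p, 1, function(x) {
    x <- x[x > 0]
    -sum(x * log(x, base = base))
  })
  simpson <- 1 - rowSums(p^2)
  richness <- rowSums(m > 0)
  chao1 <- apply(m, 1, function(x) {
    s <- sum(x > 0); f1 <- sum(x == 1); f2 <- sum(x == 2)
    if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
  })
  pielou <- ifelse(richness > 1, shannon / log(richness, base = base), NA_real_)

  out <- new_tbl(sample = comm$sample)
  if ("group" %in% names(comm)) out$group <- comm$group
  out <- dplyr::mutate(out, richness = unname(as.integer(richness)),
                       shannon = unname(shannon), simpson = unname(simpson),
                       chao1 = unname(chao1), pielou = unname(pielou))
  if (!is.null(tree)) {
    need <- colnames(m)[colSums(m) > 0]
    missing <- setdiff(need, tree$tip.label)
    if (length(missing) > 0) {
      stop("OTUs absent from tree: ", paste(head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    sub <- prune_tree(tree, need)
    pdres <- suppressWarnings(
      picante::pd(m[, need, drop = FALSE], sub,
                  include.root = ape::is.rooted(sub)))
    out$faith_pd <- pdres$PD[match(comm$sample, rownames(pdres))]
  }
  out
}
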