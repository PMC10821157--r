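# Small fixtures built in code; deterministic under fixed seeds.

toy_community <- function(n_samples = 6, n_otus = 20, seed = 1, lambda = 3,
                          groups = NULL) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus)
  m[rowSums(m) == 0, 1] <- 1L
  colnames(m) <- sprintf("OTU_%03d", seq_len(n_otus))
  out <- dplyr::bind_cols(
    tibble::tibble(sample = sprintf("s%02d", seq_len(n_samples))),
    tibble::as_tibble(m))
  if (!is.null(groups)) out <- dplyr::mutate(out, group = groups, .after = "sample")
  out[, c(names(out)[1:(1 + !is.null(groups))],
          colnames(m)[colSums(m) > 0])]
}

community_from_matrix <- function(m, groups = NULL) {
  out <- dplyr::bind_cols(tibble::tibble(sample = rownames(m)),
                          tibble::as_tibble(m))
  if (!is.null(groups)) out <- dplyr::mutate(out, group = groups, .after = "sample")
  out
}

# Naive double-loop betaMNTD oracle, straight from the definition.
bmntd_oracle <- function(m, D, weighted = TRUE) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    ta <- colnames(m)[m[a, ] > 0]; tb <- colnames(m)[m[b, ] > 0]
    wa <- if (weighted) m[a, ta] / sum(m[a, ]) else rep(1 / length(ta), length(ta))
    wb <- if (weighted) m[b, tb] / sum(m[b, ]) else rep(1 / length(tb), length(tb))
    s1 <- sum(wa * vapply(ta, function(i) min(D[i, tb]), numeric(1)))
    s2 <- sum(wb * vapply(tb, function(j) min(D[j, ta]), numeric(1)))
    out[a, b] <- 0.5 * (s1 + s2)
  }
  out
}
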