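#' Fit the Sloan neutral community model
#'
#' Relates each OTU's occurrence frequency across samples to its mean
#' relative abundance in the metacommunity. Under neutral drift with
#' immigration rate `m` into local communities of size `N_T` (the mean
#' library size), the local relative abundance of a taxon with regional
#' abundance `p` is Beta(`N_T m p`, `N_T m (1 - p)`) distributed, so its
#' expected detection frequency is the upper tail of that Beta at the
#' detection limit `d = 1/N_T`. `m` is fitted by bounded nonlinear least
#' squares of predicted against observed frequencies; goodness of fit is
#' `R^2 = 1 - SSE/SST`. A 95% band from Wilson score intervals around the
#' prediction partitions OTUs into those occurring more often (`above`),
#' as often (`within`), or less often (`below`) than neutrally expected.
#'
#' Higher `m` and `R^2` indicate weaker dispersal limitation and a larger
#' stochastic contribution to assembly.
#'
#' @param comm community tibble (integer counts; >= 10 samples recommended)
#' @param conf_level confidence level of the Wilson band (default 0.95)
#' @return a `neutral_fit` object; see [tidy.neutral_fit()] and
#'   [glance.neutral_fit()]
#' @export
fit_neutral <- function(comm, conf_level = 0.95) {
  validate_community(comm)
  m <- as_count_matrix(comm)
  n_samples <- nrow(m)
  N <- mean(rowSums(m))
  d <- 1 / N
  p <- colMeans(relabund(m))
  freq <- colMeans(m > 0)
  keep <- p > 0
  p <- p[keep]; freq <- freq[keep]
  if (sum(freq > 0 & freq < 1) < 5) {
    stop("fewer than 5 OTUs with intermediate occurrence frequency; ",
         "neutral fit unidentifiable", call. = FALSE)
  }
  dat <- data.frame(p = p, freq = freq)
  fit <- minpack.lm::nlsLM(
    freq ~ pbeta(d, N * mig * p, N * mig * (1 - p), lower.tail = FALSE),
    data = dat, start = list(mig = 0.1),
    lower = 1e-6, upper = 1,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  mig <- unname(stats::coef(fit)["mig"])
  pred <- pbeta(d, N * mig * p, N * mig * (1 - p), lower.tail = FALSE)
  sse <- sum((freq - pred)^2)
  sst <- sum((freq - mean(freq))^2)
  r2 <- 1 - sse / sst

  z <- qnorm(1 - (1 - conf_level) / 2)
  centre <- (pred + z^2 / (2 * n_samples)) / (1 + z^2 / n_samples)
  half <- z / (1 + z^2 / n_samples) *
    sqrt(pred * (1 - pred) / n_samples + z^2 / (4 * n_samples^2))
  lower <- pmax(0, centre - half)
  upper <- pmin(1, centre + half)
  partition <- dplyr::case_when(freq > upper ~ "above",
                                freq < lower ~ "below",
                                TRUE ~ "within")

  structure(list(
    m = mig, r2 = r2, N_T = N, n_samples = n_samples,
    otus = new_tbl(otu = names(p), mean_relabund = unname(p),
                   freq_observed = unname(freq), freq_predicted = unname(pred),
                   ci_lower = unname(lower), ci_upper = unname(upper),
                   partition = partition)),
    class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  m = %.4f, R^2 = %.3f, N_T = %.0f (%d samples, %d OTUs)\n",
              x$m, x$r2, x$N_T, x$n_samples, nrow(x$otus)))
  print(table(x$otus$partition))
  invisible(x)
}

#' Per-OTU detail of a neutral-model fit
#'
#' @param x a `neutral_fit`
#' @param ... unused
#' @return tibble with one row per OTU: mean relative abundance, observed
#'   and predicted occurrence frequency, Wilson band, and partition
#' @export
tidy.neutral_fit <- function(x, ...) x$otus

#' One-row summary of a neutral-model fit
#'
#' @param x a `neutral_fit`
#' @param ... unused
#' @return tibble with `m`, `r2`, `N_T`, `n_samples`, `n_otus`, and the
#'   share of OTUs above/within/below the neutral band
#' @export
glance.neutral_fit <- function(x, ...) {
  tab <- prop.table(table(factor(x$otus$partition,
                                 levels = c("above", "within", "below"))))
  new_tbl(m = x$m, r2 = x$r2, N_T = x$N_T, n_samples = x$n_samples,
          n_otus = nrow(x$otus),
          frac_above = unname(tab["above"]), frac_within = unname(tab["within"]),
          frac_below = unname(tab["below"]))
}
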