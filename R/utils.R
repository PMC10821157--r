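# Internal representation: a community table is a tibble whose first column
# is `sample`, whose optional `group` column carries the lake label, and whose
# remaining columns are non-negative integer OTU counts.

otu_columns <- function(comm) {
  setdiff(names(comm), c("sample", "group"))
}

#' Convert a community tibble to a samples x OTUs count matrix
#'
#' @param comm community tibble (`sample`, optional `group`, OTU count columns)
#' @return numeric matrix, rows named by sample, columns by OTU
#' @keywords internal
#' @noRd
as_count_matrix <- function(comm) {
  stopifnot(is.data.frame(comm), "sample" %in% names(comm))
  otus <- otu_columns(comm)
  if (length(otus) == 0L) stop("community table has no OTU columns", call. = FALSE)
  m <- as.matrix(comm[otus])
  if (!is.numeric(m)) stop("OTU columns must be numeric", call. = FALSE)
  rownames(m) <- comm$sample
  m
}

comm_groups <- function(comm) {
  if ("group" %in% names(comm)) as.character(comm$group) else rep("all", nrow(comm))
}

validate_community <- function(comm, call_name = "community") {
  if (!is.data.frame(comm) || !"sample" %in% names(comm)) {
    stop(call_name, ": expected a tibble with a `sample` column", call. = FALSE)
  }
  if (anyDuplicated(comm$sample)) {
    stop(call_name, ": duplicate sample identifiers: ",
         paste(unique(comm$sample[duplicated(comm$sample)]), collapse = ", "),
         call. = FALSE)
  }
  m <- as_count_matrix(comm)
  if (anyDuplicated(colnames(m))) {
    stop(call_name, ": duplicate OTU identifiers", call. = FALSE)
  }
  if (any(m < 0)) stop(call_name, ": negative counts", call. = FALSE)
  bad <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(call_name, ": non-integer count at sample '", rownames(m)[bad[1, 1]],
         "', OTU '", colnames(m)[bad[1, 2]], "' (value ", m[bad[1, 1], bad[1, 2]], ")",
         call. = FALSE)
  }
  if (any(rowSums(m) == 0)) {
    stop(call_name, ": samples with zero total counts: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "), call. = FALSE)
  }
  invisible(comm)
}

# Relative abundances per sample (rows sum to 1).
relabund <- function(m) sweep(m, 1, rowSums(m), "/")

new_tbl <- function(...) tibble::tibble(...)

`%||%` <- function(x, y) if (is.null(x)) y else x
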