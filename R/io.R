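#' Read an OTU abundance table
#'
#' Reads a tab-separated OTU count table. By the common amplicon convention
#' the file has OTUs as rows and samples as columns; set `otus_as_rows =
#' FALSE` for the transposed layout. Zero-sum rows and columns are dropped
#' with a warning. Non-integer counts and duplicate identifiers are hard
#' errors.
#'
#' @param path path to a TSV file whose first column holds identifiers
#' @param otus_as_rows logical; `TRUE` (default) means rows are OTUs
#' @param groups optional named character vector mapping sample id to lake
#'   (group) label; attached as a `group` column when supplied
#' @return a tibble with columns `sample`, optional `group`, and one integer
#'   column per OTU
#' @export
read_community <- function(path, otus_as_rows = TRUE, groups = NULL) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate identifiers in first column of ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(raw[-1])
  if (!is.numeric(m)) {
    idx <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m),
                 arr.ind = TRUE)
    stop("non-numeric count at row '", ids[idx[1, 1]], "', column '",
         colnames(m)[idx[1, 2]], "'", call. = FALSE)
  }
  rownames(m) <- ids
  if (otus_as_rows) m <- t(m)
  bad <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-integer count at sample '", rownames(m)[bad[1, 1]], "', OTU '",
         colnames(m)[bad[1, 2]], "' (value ", m[bad[1, 1], bad[1, 2]], ")",
         call. = FALSE)
  }
  zero_otu <- colSums(m) == 0
  if (any(zero_otu)) {
    warning(sum(zero_otu), " zero-sum OTU column(s) dropped: ",
            paste(head(colnames(m)[zero_otu], 5), collapse = ", "), call. = FALSE)
    m <- m[, !zero_otu, drop = FALSE]
  }
  zero_sample <- rowSums(m) == 0
  if (any(zero_sample)) {
    warning(sum(zero_sample), " zero-sum sample(s) dropped: ",
            paste(rownames(m)[zero_sample], collapse = ", "), call. = FALSE)
    m <- m[!zero_sample, , drop = FALSE]
  }
  comm <- dplyr::bind_cols(new_tbl(sample = rownames(m)),
                           tibble::as_tibble(m))
  if (!is.null(groups)) {
    comm <- dplyr::mutate(comm, group = unname(groups[.data$sample]),
                          .after = "sample")
  }
  validate_community(comm, "read_community")
  comm
}

#' Write a community tibble as a TSV (OTUs as rows)
#'
#' Inverse of [read_community()]: round-trips counts exactly.
#'
#' @param comm community tibble
#' @param path output path
#' @export
write_community <- function(comm, path) {
  validate_community(comm, "write_community")
  m <- t(as_count_matrix(comm))
  out <- data.frame(OTU_ID = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample environmental metadata
#'
#' Tab-separated file with a sample-identifier first column; all remaining
#' columns must parse as numeric (water physicochemistry, coordinates,
#' altitude). Missing values stay `NA`.
#'
#' @param path path to a TSV file
#' @return tibble with `sample` plus numeric variable columns
#' @export
read_env <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  env <- new_tbl(sample = as.character(raw[[1]]))
  if (anyDuplicated(env$sample)) stop("duplicate sample identifiers in ", path, call. = FALSE)
  for (nm in names(raw)[-1]) {
    v <- raw[[nm]]
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v) & v != "NA")) {
      stop("non-numeric value in metadata column '", nm, "'", call. = FALSE)
    }
    env[[nm]] <- num
  }
  env
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' @param path Newick file
#' @param prune_to optional character vector of tip labels to keep (e.g. the
#'   OTUs of a community table); other tips are pruned
#' @return an [ape::phylo] tree
#' @export
read_tree <- function(path, prune_to = NULL) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable Newick in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("unparseable Newick in ", path, call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch length in tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree", call. = FALSE)
  if (!is.null(prune_to)) tree <- prune_tree(tree, prune_to)
  tree
}

#' Prune a tree to a set of tip labels
#'
#' @param tree an [ape::phylo]
#' @param tips tip labels to keep
#' @return pruned tree
#' @export
prune_tree <- function(tree, tips) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0) {
    stop("tips absent from tree: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  ape::keep.tip(tree, tips)
}

#' Inner-join community and environmental tables on sample id
#'
#' Samples present in only one of the two tables are dropped; the counts on
#' each side are reported via a message so the drop is never silent.
#'
#' @param comm community tibble
#' @param env environmental tibble
#' @return list with aligned `community` and `env` tibbles in matching order
#' @export
align_samples <- function(comm, env) {
  shared <- intersect(comm$sample, env$sample)
  drop_c <- setdiff(comm$sample, shared)
  drop_e <- setdiff(env$sample, shared)
  if (length(drop_c) || length(drop_e)) {
    message("align_samples: dropped ", length(drop_c), " community-only and ",
            length(drop_e), " metadata-only sample(s)")
  }
  if (length(shared) == 0) stop("no shared samples between tables", call. = FALSE)
  list(
    community = comm[match(shared, comm$sample), , drop = FALSE],
    env = env[match(shared, env$sample), , drop = FALSE]
  )
}

#' Rarefy a community to a common library size
#'
#' Subsamples each sample without replacement to `depth` reads (default the
#' minimum library size). Not applied anywhere by default; exposed because
#' amplicon workflows differ on whether to rarefy before diversity and
#' null-model analysis.
#'
#' @param comm community tibble
#' @param depth target depth; defaults to the minimum library size
#' @param seed integer seed
#' @return rarefied community tibble (zero-sum OTU columns removed)
#' @export
rarefy_community <- function(comm, depth = NULL, seed = 1L) {
  validate_community(comm)
  m <- as_count_matrix(comm)
  depth <- depth %||% min(rowSums(m))
  if (any(rowSums(m) < depth)) stop("depth exceeds a library size", call. = FALSE)
  set.seed(seed)
  r <- t(apply(m, 1, function(x) {
    picked <- sample(rep.int(seq_along(x), x), depth)
    tabulate(picked, nbins = length(x))
  }))
  colnames(r) <- colnames(m)
  keep <- colSums(r) > 0
  out <- dplyr::bind_cols(comm[intersect(c("sample", "group"), names(comm))],
                          tibble::as_tibble(r[, keep, drop = FALSE]))
  out
}
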