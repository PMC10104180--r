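#' Construct a structural connectivity matrix
#'
#' Container for an FA-weighted, undirected region-by-region connectivity
#' matrix. Weights are defined only where a connection is present; absent
#' connections are `NA`. The diagonal carries no self-connections.
#'
#' @param weights Numeric square matrix of connection weights (FA units,
#'   each in (0, 1)); `NA` marks an absent connection.
#' @param region_ids Character or integer vector of region labels, one per
#'   row/column. Defaults to existing dimnames or `1:n`.
#' @return An object of class `connectivity_matrix`: a list with elements
#'   `weights`, `present` (logical matrix) and `region_ids`.
#' @export
connectivity_matrix <- function(weights, region_ids = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("connectivity matrix must be square")
  if (is.null(region_ids))
    region_ids <- rownames(weights) %||% as.character(seq_len(nrow(weights)))
  region_ids <- as.character(region_ids)
  if (length(region_ids) != nrow(weights))
    stop("region_ids length must match matrix dimension")
  diag(weights) <- NA_real_
  present <- !is.na(weights)
  if (!isTRUE(all.equal(present, t(present))) ||
      any(abs(weights - t(weights)) > 1e-10, na.rm = TRUE))
    stop("connectivity matrix must be symmetric in weights and presence")
  dimnames(weights) <- list(region_ids, region_ids)
  structure(list(weights = weights, present = present,
                 region_ids = region_ids),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d regions, %d connections\n",
              length(x$region_ids), sum(x$present[upper.tri(x$present)])))
  invisible(x)
}

#' Read / write a connectivity matrix as TSV
#'
#' Square tab-separated matrix with region ids as header row and first
#' column; empty cells or `NA` mark absent connections.
#'
#' @param path File path.
#' @return `read_connectivity_tsv` returns a `connectivity_matrix`.
#' @export
read_connectivity_tsv <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  connectivity_matrix(as.matrix(df), region_ids = rownames(df))
}

#' @rdname read_connectivity_tsv
#' @param x A `connectivity_matrix`.
#' @export
write_connectivity_tsv <- function(x, path) {
  stopifnot(inherits(x, "connectivity_matrix"))
  df <- as.data.frame(x$weights)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

# Edge index (upper triangle of the shared presence scaffold) for a list of
# connectivity matrices; errors if region orderings or scaffolds differ.
shared_edges <- function(mats) {
  ids <- mats[[1]]$region_ids
  for (m in mats) {
    if (!identical(m$region_ids, ids))
      stop("mismatched region orderings across connectivity matrices")
    if (!identical(m$present, mats[[1]]$present))
      stop("connectivity matrices do not share a presence scaffold")
  }
  ut <- which(upper.tri(mats[[1]]$present) & mats[[1]]$present, arr.ind = TRUE)
  data.frame(i = ut[, 1], j = ut[, 2],
             region_i = ids[ut[, 1]], region_j = ids[ut[, 2]],
             stringsAsFactors = FALSE)
}

#' Stack connectivity matrices into a subjects-by-connections table
#'
#' Vectorises the upper triangle of each subject's matrix over the shared
#' presence scaffold, the layout used by harmonisation and normative
#' modelling.
#'
#' @param mats List of `connectivity_matrix` objects sharing region order
#'   and presence scaffold.
#' @return List with `table` (subjects x connections numeric matrix) and
#'   `edges` (data frame mapping connection index to region pair).
#' @export
connectome_table <- function(mats) {
  edges <- shared_edges(mats)
  vals <- vapply(mats, function(m)
    m$weights[cbind(edges$i, edges$j)], numeric(nrow(edges)))
  tab <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1L)
  rownames(tab) <- names(mats)
  list(table = tab, edges = edges, region_ids = mats[[1]]$region_ids)
}
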