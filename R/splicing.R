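# Spliced training matrices: the adjacency matrix (or its transpose) joined
# column-wise with the matching integrated similarity matrix. Each row is one
# entity's feature vector and one VAE training sample.

#' Spliced feature matrix
#'
#' Container for the miRNA-side (`SSM`, `nm x (nd + nm)`) or disease-side
#' (`SSD`, `nd x (nm + nd)`) training matrix. The column map records which
#' columns hold association entries and which hold similarity entries, so the
#' scoring stage can slice reconstructions without re-deriving offsets.
#'
#' @param values numeric matrix in `[0,1]`.
#' @param side `"miRNA"` or `"disease"`.
#' @param assoc_cols,sim_cols integer column indices of the two blocks.
#' @return object of class `spliced_matrix`.
#' @export
spliced_matrix <- function(values, side = c("miRNA", "disease"),
                           assoc_cols, sim_cols) {
  side <- match.arg(side)
  values <- as.matrix(values)
  if (!setequal(c(assoc_cols, sim_cols), seq_len(ncol(values))))
    stop("spliced_matrix: column map does not cover the matrix")
  if (any(values < 0 | values > 1))
    stop("spliced_matrix: entries outside [0,1]")
  if (!all(values[, assoc_cols] %in% c(0, 1)))
    stop("spliced_matrix: association block must be binary")
  structure(list(values = values, side = side,
                 assoc_cols = as.integer(assoc_cols),
                 sim_cols = as.integer(sim_cols)),
            class = "spliced_matrix")
}

#' @export
print.spliced_matrix <- function(x, ...) {
  cat(sprintf("spliced_matrix [%s side]: %d x %d (%d association + %d similarity columns)\n",
              x$side, nrow(x$values), ncol(x$values),
              length(x$assoc_cols), length(x$sim_cols)))
  invisible(x)
}

#' Build the miRNA-side training matrix SSM
#'
#' Row `i` is `concat(A[i, ], SM[i, ])`: the first `nd` columns are miRNA
#' `i`'s association profile, the last `nm` columns its integrated similarity
#' to every miRNA. For the 495 x 383 reference dataset this gives the
#' 878-dimensional VAE input.
#'
#' @param A an [association_matrix()].
#' @param SM integrated miRNA similarity (`similarity_matrix`).
#' @return a [spliced_matrix()], miRNA side.
#' @export
build_ssm <- function(A, SM) {
  stopifnot(inherits(A, "association_matrix"), inherits(SM, "similarity_matrix"))
  if (!identical(A$mirna_ids, SM$entity_ids))
    stop("build_ssm: SM is not indexed by A's miRNA axis")
  nd <- length(A$disease_ids); nm <- length(A$mirna_ids)
  spliced_matrix(cbind(A$values, SM$values), "miRNA",
                 assoc_cols = seq_len(nd), sim_cols = nd + seq_len(nm))
}

#' Build the disease-side training matrix SSD
#'
#' Mirror of [build_ssm()]: row `j` is `concat(t(A)[j, ], SD[j, ])`, shape
#' `nd x (nm + nd)`.
#'
#' @param A an [association_matrix()].
#' @param SD integrated disease similarity (`similarity_matrix`).
#' @return a [spliced_matrix()], disease side.
#' @export
build_ssd <- function(A, SD) {
  stopifnot(inherits(A, "association_matrix"), inherits(SD, "similarity_matrix"))
  if (!identical(A$disease_ids, SD$entity_ids))
    stop("build_ssd: SD is not indexed by A's disease axis")
  nd <- length(A$disease_ids); nm <- length(A$mirna_ids)
  spliced_matrix(cbind(t(A$values), SD$values), "disease",
                 assoc_cols = seq_len(nm), sim_cols = nm + seq_len(nd))
}

#' Extract the association block of a spliced matrix
#'
#' @param x a [spliced_matrix()].
#' @return the binary association block (`A` for the miRNA side, `t(A)` for
#'   the disease side).
#' @export
association_block <- function(x) {
  stopifnot(inherits(x, "spliced_matrix"))
  x$values[, x$assoc_cols, drop = FALSE]
}
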