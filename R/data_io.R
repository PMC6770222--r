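#' @importFrom stats rnorm runif rbinom sd cor quantile uniroot cutree hclust dist plogis qlogis setNames
#' @importFrom utils head read.table
NULL

# ---- AssociationMatrix ------------------------------------------------------

#' Construct a binary miRNA-disease association matrix
#'
#' The adjacency matrix `A` has one row per miRNA and one column per disease;
#' `A[i, j] = 1` records an experimentally supported association between
#' miRNA `i` and disease `j`, 0 an unknown pair.
#'
#' @param values numeric matrix of 0/1 entries, `nm x nd`.
#' @param mirna_ids,disease_ids unique identifier vectors matching the matrix
#'   dimensions. Defaults to the dimnames of `values`.
#' @return an object of class `association_matrix` with fields `values`,
#'   `mirna_ids`, `disease_ids`.
#' @export
association_matrix <- function(values,
                               mirna_ids = rownames(values),
                               disease_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(mirna_ids) || is.null(disease_ids))
    stop("association_matrix: mirna_ids and disease_ids are required")
  mirna_ids <- as.character(mirna_ids)
  disease_ids <- as.character(disease_ids)
  if (length(mirna_ids) != nrow(values) || length(disease_ids) != ncol(values))
    stop("association_matrix: id lengths do not match matrix dimensions")
  if (anyDuplicated(mirna_ids) || anyDuplicated(disease_ids))
    stop("association_matrix: identifier lists must be unique")
  if (!all(values %in% c(0, 1)))
    stop("association_matrix: entries must be 0 or 1")
  storage.mode(values) <- "double"
  dimnames(values) <- list(mirna_ids, disease_ids)
  structure(list(values = values, mirna_ids = mirna_ids,
                 disease_ids = disease_ids),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix: %d miRNAs x %d diseases, %d known pairs\n",
              length(x$mirna_ids), length(x$disease_ids), sum(x$values)))
  invisible(x)
}

#' Read a known-association list into an adjacency matrix
#'
#' Reads a two-column TSV of `(mirna_id, disease_id)` pairs (the format of an
#' HMDD-style association dump) and builds the binary adjacency matrix.
#' Identifier order is first appearance in the file unless `sort_ids = TRUE`.
#'
#' @param path TSV file path.
#' @param header logical; whether the file carries a header row.
#' @param sort_ids sort identifiers lexicographically instead of
#'   first-appearance order.
#' @return an [association_matrix()].
#' @export
read_association_list <- function(path, header = FALSE, sort_ids = FALSE) {
  if (!file.exists(path)) stop("read_association_list: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines) >= 1) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("read_association_list: empty file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != 2L)
  if (length(bad) > 0)
    stop(sprintf("read_association_list: malformed row at line %d (expected 2 tab-separated fields, got %d)",
                 bad[1] + as.integer(header), nfield[bad[1]]))
  mir <- vapply(parts, `[[`, "", 1L)
  dis <- vapply(parts, `[[`, "", 2L)
  if (any(!nzchar(mir)) || any(!nzchar(dis))) {
    bad <- which(!nzchar(mir) | !nzchar(dis))[1]
    stop(sprintf("read_association_list: empty identifier at line %d",
                 bad + as.integer(header)))
  }
  dup <- duplicated(paste(mir, dis, sep = "\r"))
  if (any(dup)) {
    warning(sprintf("read_association_list: %d duplicate pair(s) collapsed", sum(dup)))
    mir <- mir[!dup]; dis <- dis[!dup]
  }
  mirna_ids <- unique(mir)
  disease_ids <- unique(dis)
  if (sort_ids) { mirna_ids <- sort(mirna_ids); disease_ids <- sort(disease_ids) }
  A <- matrix(0, length(mirna_ids), length(disease_ids),
              dimnames = list(mirna_ids, disease_ids))
  A[cbind(match(mir, mirna_ids), match(dis, disease_ids))] <- 1
  association_matrix(A)
}

# ---- SimilarityMatrix -------------------------------------------------------

.SIM_ROLES <- c("SS1", "SS2", "FS", "KD", "KM", "SD", "SM")

#' Construct a validated similarity matrix
#'
#' Square symmetric matrix with entries in `[0, 1]` and unit diagonal, tagged
#' with its role in the pipeline: semantic similarity (`SS1`, `SS2`),
#' functional similarity (`FS`), Gaussian interaction profile kernel
#' (`KD`, `KM`) or integrated similarity (`SD`, `SM`).
#'
#' @param values square numeric matrix.
#' @param entity_ids row/column identifiers (defaults to rownames).
#' @param role one of `r paste(.SIM_ROLES, collapse = ", ")`.
#' @return object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, entity_ids = rownames(values), role) {
  values <- as.matrix(values)
  role <- match.arg(role, .SIM_ROLES)
  if (nrow(values) != ncol(values))
    stop("similarity_matrix: matrix is not square")
  if (is.null(entity_ids)) entity_ids <- as.character(seq_len(nrow(values)))
  entity_ids <- as.character(entity_ids)
  if (length(entity_ids) != nrow(values) || anyDuplicated(entity_ids))
    stop("similarity_matrix: invalid entity ids")
  if (any(!is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("similarity_matrix: non-finite value at (%d,%d)", idx[1], idx[2]))
  }
  asym <- max(abs(values - t(values)))
  if (asym > 1e-9)
    stop(sprintf("similarity_matrix: asymmetry %.3g exceeds 1e-9", asym))
  if (any(values < 0 | values > 1)) {
    idx <- which(values < 0 | values > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("similarity_matrix: value %.6g outside [0,1] at (%d,%d)",
                 values[idx[1], idx[2]], idx[1], idx[2]))
  }
  if (max(abs(diag(values) - 1)) > 1e-9)
    stop("similarity_matrix: diagonal must be 1 for role ", role)
  dimnames(values) <- list(entity_ids, entity_ids)
  structure(list(values = values, entity_ids = entity_ids, role = role),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix [%s]: %d x %d\n", x$role,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a similarity matrix from CSV
#'
#' Expects a square numeric CSV with identifier header row and first column
#' (the layout of the published MISIM miRNA functional-similarity download).
#' Asymmetries up to `1e-6` are symmetrized by averaging; anything larger is
#' an error, as are values outside `[0, 1]` and non-finite cells.
#'
#' @param path CSV file path.
#' @param role role label, see [similarity_matrix()].
#' @return a `similarity_matrix`.
#' @export
read_similarity_matrix <- function(path, role) {
  if (!file.exists(path)) stop("read_similarity_matrix: file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop(sprintf("read_similarity_matrix: non-square table (%d x %d)", nrow(m), ncol(m)))
  if (!identical(ids, colnames(m)))
    stop("read_similarity_matrix: row ids do not match column ids")
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("read_similarity_matrix: non-numeric/NaN cell at (%s,%s)",
                 ids[idx[1]], ids[idx[2]]))
  }
  if (any(m < 0 | m > 1)) {
    idx <- which(m < 0 | m > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("read_similarity_matrix: value %.6g outside [0,1] at (%s,%s)",
                 m[idx[1], idx[2]], ids[idx[1]], ids[idx[2]]))
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6)
    stop(sprintf("read_similarity_matrix: asymmetry %.3g exceeds 1e-6", asym))
  m <- (m + t(m)) / 2
  rownames(m) <- ids
  similarity_matrix(m, ids, role)
}

#' Write a similarity matrix to CSV
#'
#' Inverse of [read_similarity_matrix()]; round-trips values to better than
#' `1e-9` (full double precision, '.' decimal, UTF-8).
#'
#' @param sim a `similarity_matrix`.
#' @param path output CSV path.
#' @export
write_similarity_matrix <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  dt <- data.table::as.data.table(sim$values, keep.rownames = "id")
  data.table::fwrite(dt, path, sep = ",")
  invisible(path)
}

# ---- DiseaseDAGSet ----------------------------------------------------------

#' Construct a set of per-disease ancestor DAGs
#'
#' Each disease with MeSH-style coverage carries a directed acyclic graph of
#' ancestor terms: `terms` is `T(d)` (including the disease's own term) and
#' `edges` is a `(child, parent)` table over those terms. Diseases without a
#' DAG are recorded with coverage `FALSE` so downstream similarity integration
#' can fall back to the interaction-profile kernel.
#'
#' @param dags named list (by disease id); each element a list with `terms`
#'   (character) and `edges` (data.frame with columns `child`, `parent`).
#' @param all_diseases full ordered disease id vector (defaults to the DAG
#'   names).
#' @return object of class `disease_dag_set` with fields `dags` and `coverage`
#'   (named logical over `all_diseases`).
#' @export
disease_dag_set <- function(dags, all_diseases = names(dags)) {
  all_diseases <- as.character(all_diseases)
  if (anyDuplicated(all_diseases)) stop("disease_dag_set: duplicate disease ids")
  if (!all(names(dags) %in% all_diseases))
    stop("disease_dag_set: DAG for unlisted disease: ",
         paste(setdiff(names(dags), all_diseases), collapse = ", "))
  for (d in names(dags)) {
    g <- dags[[d]]
    if (!d %in% g$terms)
      stop("disease_dag_set: disease term missing from its own DAG: ", d)
    if (nrow(g$edges) > 0 &&
        !all(c(g$edges$child, g$edges$parent) %in% g$terms))
      stop("disease_dag_set: edge endpoint outside term set for disease ", d)
    if (.has_cycle(g$edges))
      stop("disease_dag_set: cycle detected in DAG of disease ", d)
  }
  coverage <- stats::setNames(all_diseases %in% names(dags), all_diseases)
  structure(list(dags = dags, coverage = coverage),
            class = "disease_dag_set")
}

# DFS cycle check on a (child, parent) edge table
.has_cycle <- function(edges) {
  if (nrow(edges) == 0) return(FALSE)
  nodes <- unique(c(edges$child, edges$parent))
  adj <- split(edges$parent, factor(edges$child, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  for (start in nodes) {
    if (state[[start]] != 0L) next
    stack <- list(list(node = start, i = 0L))
    state[[start]] <- 1L
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      nbrs <- adj[[top$node]]
      if (is.null(nbrs) || top$i >= length(nbrs)) {
        state[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
      } else {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- nbrs[[top$i + 1L]]
        if (state[[nxt]] == 1L) return(TRUE)
        if (state[[nxt]] == 0L) {
          state[[nxt]] <- 1L
          stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
        }
      }
    }
  }
  FALSE
}

#' @export
print.disease_dag_set <- function(x, ...) {
  cat(sprintf("disease_dag_set: %d diseases, %d with DAG coverage\n",
              length(x$coverage), sum(x$coverage)))
  invisible(x)
}

#' Read per-disease DAG edge tables
#'
#' Reads a TSV of `(disease_id, child_term, parent_term)` rows, one edge of a
#' disease's ancestor DAG per row, and validates acyclicity. Diseases listed
#' in `all_diseases` that have no rows are flagged as lacking a DAG.
#'
#' @param path TSV file path.
#' @param all_diseases full disease id vector.
#' @param header logical; header row present.
#' @return a [disease_dag_set()].
#' @export
read_disease_dags <- function(path, all_diseases, header = FALSE) {
  if (!file.exists(path)) stop("read_disease_dags: file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = header,
                          col.names = c("disease", "child", "parent"),
                          colClasses = "character", quote = "")
  unknown <- setdiff(unique(df$disease), all_diseases)
  if (length(unknown) > 0)
    stop("read_disease_dags: edges reference diseases outside all_diseases: ",
         paste(unknown, collapse = ", "))
  dags <- lapply(split(df[c("child", "parent")], df$disease), function(e) {
    list(terms = unique(c(e$child, e$parent)), edges = e)
  })
  # ensure the disease's own term is present even if only named as a child
  for (d in names(dags))
    dags[[d]]$terms <- unique(c(d, dags[[d]]$terms))
  disease_dag_set(dags, all_diseases)
}

# ---- Score table output -----------------------------------------------------

#' Write association scores as a long-format table
#'
#' Emits one `(mirna_id, disease_id, score, is_known)` row per pair, grouped
#' by disease in matrix column order, sorted within disease by descending
#' score with ties broken by miRNA id. Byte-deterministic for fixed input.
#'
#' @param scores a [score_matrix()].
#' @param path output TSV path.
#' @param known an [association_matrix()] marking the known pairs.
#' @export
write_score_table <- function(scores, path, known) {
  stopifnot(inherits(scores, "score_matrix"), inherits(known, "association_matrix"))
  S <- scores$values
  if (!identical(dim(S), dim(known$values)))
    stop("write_score_table: score and association shapes disagree")
  rows <- lapply(seq_len(ncol(S)), function(j) {
    ord <- order(-S[, j], rownames(S), method = "radix")
    data.frame(mirna_id = rownames(S)[ord],
               disease_id = colnames(S)[j],
               score = sprintf("%.6f", S[ord, j]),
               is_known = as.integer(known$values[ord, j]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(out$mirna_id, out$disease_id, out$score, out$is_known,
                   sep = "\t"), con, sep = "\n")
  invisible(path)
}
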