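#' Markov Clustering parameters
#'
#' @param inflation granularity parameter (> 1): the elementwise power
#'   applied between expansion steps. Higher inflation gives more,
#'   smaller clusters. Values at or below 1 are rejected — identity
#'   inflation never contracts the flow to attractors.
#' @param expansion matrix-power of the expansion step (integer >= 2).
#' @param pruning_threshold entries below this are dropped (with
#'   re-normalization) after each iteration to keep the matrix sparse.
#' @param max_iterations iteration cap.
#' @param convergence_tol convergence when the largest elementwise
#'   change between successive iterates falls below this.
#' @param self_loop_weight self-loop weight added before the first
#'   normalization; `NULL` uses each column's maximum off-diagonal
#'   weight (standard MCL loop handling), which keeps the loop on the
#'   scale of the node's strongest edge.
#' @return A list of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 1.1, expansion = 2,
                       pruning_threshold = 1e-5, max_iterations = 200,
                       convergence_tol = 1e-6, self_loop_weight = NULL) {
  if (inflation <= 1 + 1e-6)
    stop_param("`inflation` must exceed 1 (got %g)", inflation)
  if (expansion < 2) stop_param("`expansion` must be >= 2")
  if (!is.null(self_loop_weight) && self_loop_weight < 0)
    stop_param("`self_loop_weight` must be >= 0")
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 pruning_threshold = pruning_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 self_loop_weight = self_loop_weight),
            class = "mcl_params")
}

col_normalize <- function(M) {
  s <- Matrix::colSums(M)
  s[s == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / s)
}

mcl_input_matrix <- function(x) {
  if (inherits(x, "assoc_matrix")) {
    m <- x$normalized %||% x$counts
  } else {
    m <- x
  }
  m <- as(as(m, "generalMatrix"), "CsparseMatrix")
  if (nrow(m) != ncol(m)) stop_param("MCL input must be square")
  if (length(m@x) && any(m@x < 0))
    stop_param("MCL input must be nonnegative")
  if (!Matrix::isSymmetric(m, tol = 1e-8))
    stop_param("MCL input must be symmetric")
  Matrix::diag(m) <- 0
  Matrix::drop0(m)
}

#' Markov Clustering (MCL) of a weighted association graph
#'
#' From-scratch sparse implementation of the MCL process, which
#' simulates flow through the weighted graph and reads clusters off the
#' attractor structure the flow converges to. Self-loops are added
#' (column maximum by default), columns are normalized to stochastic,
#' and the process iterates expansion (matrix power), inflation
#' (elementwise power followed by column re-normalization) and pruning
#' of negligible entries until the iterate stops changing. Clusters are
#' the weakly connected attractor systems of the converged flow matrix;
#' nodes of the input graph always receive exactly one cluster, and the
#' result is deterministic for a given input.
#'
#' @param x an `assoc_matrix` (normalized weights are used when present)
#'   or a symmetric nonnegative matrix / sparse Matrix with dimnames.
#' @param params an [mcl_params()]; `inflation` may be given directly.
#' @param inflation shorthand override for `params$inflation`.
#' @param keep_flow retain the converged flow matrix (column-stochastic)
#'   in the result, for inspection.
#' @return A list of class `cluster_solution`: `assignment` (data.frame
#'   `contig_id`, `cluster`), `n_clusters`, `converged`, `iterations`,
#'   `inflation` (and `flow` when `keep_flow`).
#' @export
mcl_cluster <- function(x, params = mcl_params(), inflation = NULL,
                        keep_flow = FALSE) {
  if (!is.null(inflation)) params$inflation <- inflation
  if (params$inflation <= 1 + 1e-6)
    stop_param("`inflation` must exceed 1 (got %g)", params$inflation)
  M <- mcl_input_matrix(x)
  ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
  n <- nrow(M)
  if (n == 0L) {
    return(structure(list(assignment = data.frame(contig_id = character(0),
                                                  cluster = integer(0)),
                          n_clusters = 0L, converged = TRUE,
                          iterations = 0L, inflation = params$inflation),
                     class = "cluster_solution"))
  }
  loop <- params$self_loop_weight
  if (is.null(loop)) {
    cm <- apply_col_max(M)
    cm[cm == 0] <- 1
    Matrix::diag(M) <- cm
  } else {
    Matrix::diag(M) <- max(loop, .Machine$double.eps)
  }
  M <- col_normalize(M)
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    prev <- M
    ## expansion
    E <- M
    for (k in seq_len(params$expansion - 1L)) E <- E %*% M
    ## inflation
    E <- as(E, "CsparseMatrix")
    E@x <- E@x^params$inflation
    E <- col_normalize(E)
    ## pruning + re-normalization
    E <- as(E, "CsparseMatrix")
    E <- Matrix::drop0(E * (E >= params$pruning_threshold))
    E <- col_normalize(E)
    M <- as(E, "CsparseMatrix")
    delta <- max(abs(M - prev))
    if (delta < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf(
      "MCL did not converge in %d iterations; returning best effort",
      params$max_iterations))
  ## clusters = weakly connected components of the converged flow
  S <- Matrix::drop0(M + Matrix::t(M))
  g <- igraph::graph_from_adjacency_matrix(S > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  ## deterministic labels: order clusters by their smallest member index
  first <- tapply(seq_len(n), comp, min)
  relabel <- match(comp, as.integer(names(sort(first))))
  structure(c(list(assignment = data.frame(contig_id = ids,
                                           cluster = relabel,
                                           stringsAsFactors = FALSE),
                   n_clusters = max(relabel), converged = converged,
                   iterations = iter, inflation = params$inflation),
              if (keep_flow) list(flow = M)),
            class = "cluster_solution")
}

# Column-wise maximum of a sparse nonnegative matrix.
apply_col_max <- function(M) {
  M <- as(M, "CsparseMatrix")
  p <- M@p
  out <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    if (p[j + 1L] > p[j]) out[j] <- max(M@x[(p[j] + 1L):p[j + 1L]])
  }
  out
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %d contigs in %d clusters (inflation %g%s)\n",
              nrow(x$assignment), x$n_clusters, x$inflation,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Cluster across a grid of inflation values
#'
#' @param x MCL input (see [mcl_cluster()]).
#' @param inflations numeric vector of inflation values (> 1).
#' @param params base [mcl_params()].
#' @return Named list of `cluster_solution`s, one per inflation value.
#' @export
sweep_inflation <- function(x, inflations, params = mcl_params()) {
  if (any(inflations <= 1 + 1e-6))
    stop_param("all inflation values must exceed 1")
  out <- lapply(inflations, function(r) mcl_cluster(x, params,
                                                    inflation = r))
  names(out) <- format(inflations)
  out
}

#' Append missing contigs to a solution as singleton clusters
#'
#' Contigs that were input to a clustering run but dropped out of the
#' clustered graph (e.g. all their edges were filtered) are added back
#' as singleton clusters.
#'
#' @param solution a `cluster_solution`.
#' @param contig_ids the full contig universe of the run.
#' @return The completed `cluster_solution`.
#' @export
complete_solution <- function(solution, contig_ids) {
  missing <- setdiff(contig_ids, solution$assignment$contig_id)
  if (length(missing) > 0) {
    extra <- data.frame(contig_id = missing,
                        cluster = solution$n_clusters + seq_along(missing),
                        stringsAsFactors = FALSE)
    solution$assignment <- rbind(solution$assignment, extra)
    solution$n_clusters <- solution$n_clusters + length(missing)
  }
  solution
}

#' Write/read cluster assignments as TSV
#'
#' @param solution a `cluster_solution`.
#' @param path output path (`contig_id cluster`).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(solution, path) {
  utils::write.table(solution$assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
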