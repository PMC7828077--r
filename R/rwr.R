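#' Random walk with restart: stationary visit-probability profile
#'
#' Computes the fixed point of the restart walk
#' \deqn{p \leftarrow \alpha e + (1-\alpha) W^\top p,}
#' where `e` is the restart distribution (uniform over `restart_nodes`) and
#' `W` the row-stochastic transition matrix, by power iteration.  This is
#' topic-specific PageRank with the restart set forced to the given nodes;
#' the resulting vector scores every graph node's relevance to the restart
#' set, one element per node in graph order.  Transition mass sitting on
#' dangling (neighbourless) nodes is redirected to the restart
#' distribution so probability is conserved.
#'
#' @param transition A `kg_transition` from [kg_transition()].
#' @param restart_nodes Non-empty character vector of node ids to restart
#'   at; the restart distribution is uniform over them.
#' @param alpha Jump (restart) probability, strictly in (0, 1); default 0.1.
#' @param tol Convergence tolerance on the L1 change between successive
#'   iterates; default 1e-10.
#' @param max_iter Maximum iterations before failing; default 1000.
#' @return An `rwr_profile`: list with `values` (named numeric, sums to 1),
#'   `restart_nodes`, `alpha`, `iterations`, `residual`.
#' @seealso [rwr_profile_exact()] for the dense closed-form solve used as
#'   an oracle in tests, [rwr_matrix()] for one profile per gene.
#' @examples
#' kg <- kg_graph(
#'   data.frame(node_id = c("a", "b"), node_type = "Gene",
#'              name = c("a", "b")),
#'   data.frame(source = "a", target = "b", edge_type = "interacts"))
#' pr <- rwr_profile(kg_transition(kg), "a", alpha = 0.1)
#' pr$values  # a: 0.1/0.19, b: 0.09/0.19
#' @export
rwr_profile <- function(transition, restart_nodes, alpha = 0.1,
                        tol = 1e-10, max_iter = 1000L) {
  rs <- rwr_restart_vector(transition, restart_nodes, alpha)
  check_pos(tol, "tol")
  P <- rwr_iterate(transition, matrix(rs$e, ncol = 1), alpha, tol, max_iter)
  structure(
    list(values = stats::setNames(as.vector(P$P), transition$node_ids),
         restart_nodes = rs$restart_nodes, alpha = alpha,
         iterations = P$iterations, residual = P$residual),
    class = "rwr_profile"
  )
}

#' @export
print.rwr_profile <- function(x, ...) {
  cat(sprintf(
    "<rwr_profile> %d nodes, restart {%s}, alpha %.3g, %d iters, resid %.2e\n",
    length(x$values), paste(utils::head(x$restart_nodes, 3), collapse = ","),
    x$alpha, x$iterations, x$residual))
  invisible(x)
}

# Validate restart spec and build the restart distribution e.
rwr_restart_vector <- function(transition, restart_nodes, alpha) {
  restart_nodes <- unique(as.character(restart_nodes))
  if (length(restart_nodes) == 0) stop("empty restart set", call. = FALSE)
  missing <- setdiff(restart_nodes, transition$node_ids)
  if (length(missing) > 0) {
    stop("restart node(s) not in graph: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be strictly between 0 and 1", call. = FALSE)
  }
  e <- numeric(length(transition$node_ids))
  e[match(restart_nodes, transition$node_ids)] <- 1 / length(restart_nodes)
  list(e = e, restart_nodes = restart_nodes)
}

check_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || x <= 0) {
    stop(what, " must be a positive number", call. = FALSE)
  }
}

# Power iteration on a column-block of restart distributions E (N x k).
# Dangling mass is redirected to each column's own restart distribution.
rwr_iterate <- function(transition, E, alpha, tol, max_iter) {
  WT <- Matrix::t(transition$W)
  dang <- transition$dangling
  P <- E  # start at the restart distribution
  for (it in seq_len(max_iter)) {
    lost <- if (any(dang)) colSums(P[dang, , drop = FALSE]) else
      numeric(ncol(P))
    P_new <- alpha * E + (1 - alpha) *
      (as.matrix(WT %*% P) + E %*% diag(lost, nrow = length(lost)))
    resid <- max(colSums(abs(P_new - P)))
    P <- P_new
    if (resid < tol) {
      return(list(P = P, iterations = it, residual = resid))
    }
  }
  stop(sprintf(
    "random-walk iteration did not converge in %d iterations (residual %.3e)",
    max_iter, resid), call. = FALSE)
}

#' Closed-form restart-walk profile (dense solve)
#'
#' Solves \eqn{(I - (1-\alpha) W^\top) p = \alpha e} directly with a dense
#' linear solve.  Exact up to floating point; intended as an independent
#' oracle for [rwr_profile()] on graphs of at most 500 nodes.  Dangling
#' mass is redirected to the restart distribution, matching the iterative
#' solver.
#'
#' @inheritParams rwr_profile
#' @return An `rwr_profile` with `iterations = NA`.
#' @export
rwr_profile_exact <- function(transition, restart_nodes, alpha = 0.1) {
  n <- length(transition$node_ids)
  if (n > 500) stop("dense solve limited to graphs of at most 500 nodes",
                    call. = FALSE)
  rs <- rwr_restart_vector(transition, restart_nodes, alpha)
  # dangling rows: walker jumps to restart distribution e
  W <- as.matrix(transition$W)
  if (any(transition$dangling)) {
    W[transition$dangling, ] <- matrix(rs$e, nrow = sum(transition$dangling),
                                       ncol = n, byrow = TRUE)
  }
  A <- diag(n) - (1 - alpha) * t(W)
  p <- solve(A, alpha * rs$e)
  structure(
    list(values = stats::setNames(as.vector(p), transition$node_ids),
         restart_nodes = rs$restart_nodes, alpha = alpha,
         iterations = NA_integer_, residual = 0),
    class = "rwr_profile"
  )
}

#' Per-gene propagation profile matrix
#'
#' One restart-walk profile per gene, each restarting at that single Gene
#' node: the matrix of stationary visit probabilities (genes x all graph
#' nodes) that downstream fold-change embedding consumes.  Columns follow
#' the graph's node order; each row sums to 1.
#'
#' @param kg A `kg` object.
#' @param gene_ids Character vector of node ids; every one must be a node
#'   of type `Gene`.
#' @param alpha,tol,max_iter Passed to the walk (see [rwr_profile()]).
#' @param orientation Edge-traversal policy for [kg_transition()].
#' @return Numeric matrix with `rownames = gene_ids` (in input order) and
#'   `colnames` = node ids in graph order.
#' @export
rwr_matrix <- function(kg, gene_ids, alpha = 0.1, tol = 1e-10,
                       max_iter = 1000L,
                       orientation = c("undirected", "directed")) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0) stop("no genes given", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicated gene_ids", call. = FALSE)
  types <- kg$nodes$node_type[match(gene_ids, kg$nodes$node_id)]
  if (anyNA(types)) {
    stop("gene id(s) not in graph: ",
         paste(utils::head(gene_ids[is.na(types)], 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(types != "Gene")) {
    stop("restart node(s) not of type Gene: ",
         paste(utils::head(gene_ids[types != "Gene"], 5), collapse = ", "),
         call. = FALSE)
  }
  transition <- kg_transition(kg, match.arg(orientation))
  n <- length(transition$node_ids)
  E <- matrix(0, n, length(gene_ids))
  E[cbind(match(gene_ids, transition$node_ids), seq_along(gene_ids))] <- 1
  check_pos(tol, "tol")
  rwr_restart_vector(transition, gene_ids[1], alpha)  # validates alpha
  res <- rwr_iterate(transition, E, alpha, tol, max_iter)
  M <- t(res$P)
  dimnames(M) <- list(gene_ids, transition$node_ids)
  M
}

#' Write / read a propagation-profile matrix as TSV
#'
#' Dense TSV with a `gene_id` first column and one column per graph node
#' in graph order.
#'
#' @param mat Matrix from [rwr_matrix()].
#' @param path Output path.
#' @return The matrix (read) or `mat` invisibly (write).
#' @export
write_rwr_matrix <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(mat)
}

#' @rdname write_rwr_matrix
#' @export
read_rwr_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()))
  m <- as.matrix(df[-1])
  rownames(m) <- df$gene_id
  m
}
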