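#' Admissible node types of the knowledge-graph schema
#'
#' The twelve biomedical categories a node may belong to.  Any other label
#' is rejected when a graph is constructed or loaded.
#'
#' @return Character vector of the 12 admissible node-type labels.
#' @export
kg_node_types <- function() {
  c("Anatomy", "BiologicalProcess", "CellularComponent", "Compound",
    "Disease", "Gene", "MolecularFunction", "Pathway",
    "PharmacologicalClass", "Protein", "SideEffect", "Symptom")
}

#' Construct a typed heterogeneous knowledge graph
#'
#' Validates node and edge tables and assembles them into a `kg` object.
#' Nodes are re-ordered lexicographically by `node_id` so that vector and
#' matrix positions derived from the graph are reproducible across runs and
#' platforms.  Self-loops are rejected; edges must reference known nodes;
#' node types must be one of [kg_node_types()].  A warning is emitted when
#' the graph is not connected under undirected traversal.
#'
#' @param nodes Data frame with columns `node_id`, `node_type`, `name`.
#' @param edges Data frame with columns `source`, `target`, `edge_type`.
#' @return A `kg` object: list with tibbles `nodes` (sorted by `node_id`)
#'   and `edges`, and `n_nodes`.
#' @examples
#' kg <- kg_graph(
#'   nodes = data.frame(node_id = c("g1", "s1"),
#'                      node_type = c("Gene", "Symptom"),
#'                      name = c("gene 1", "symptom 1")),
#'   edges = data.frame(source = "g1", target = "s1",
#'                      edge_type = "associates")
#' )
#' @export
kg_graph <- function(nodes, edges) {
  need_n <- c("node_id", "node_type", "name")
  need_e <- c("source", "target", "edge_type")
  if (!all(need_n %in% names(nodes))) {
    stop("node table must have columns: ", paste(need_n, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_e %in% names(edges))) {
    stop("edge table must have columns: ", paste(need_e, collapse = ", "),
         call. = FALSE)
  }
  nodes <- tibble::as_tibble(nodes)[need_n]
  edges <- tibble::as_tibble(edges)[need_e]
  nodes <- dplyr::mutate(nodes, dplyr::across(dplyr::everything(),
                                              as.character))
  edges <- dplyr::mutate(edges, dplyr::across(dplyr::everything(),
                                              as.character))

  if (anyDuplicated(nodes$node_id)) {
    dup <- unique(nodes$node_id[duplicated(nodes$node_id)])
    stop("duplicate node_id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  bad_type <- setdiff(unique(nodes$node_type), kg_node_types())
  if (length(bad_type) > 0) {
    stop("unknown node_type(s): ", paste(bad_type, collapse = ", "),
         "; admissible types are the 12 labels of kg_node_types()",
         call. = FALSE)
  }
  unknown <- !(edges$source %in% nodes$node_id) |
    !(edges$target %in% nodes$node_id)
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop(sprintf(
      "edge row %d (%s -> %s, %s) references a node_id not in the node table",
      i, edges$source[i], edges$target[i], edges$edge_type[i]), call. = FALSE)
  }
  if (any(edges$source == edges$target)) {
    i <- which(edges$source == edges$target)[1]
    stop(sprintf("self-loop at edge row %d (%s): self-loops are rejected",
                 i, edges$source[i]), call. = FALSE)
  }

  nodes <- dplyr::arrange(nodes, .data$node_id)
  g <- structure(
    list(nodes = nodes, edges = edges, n_nodes = nrow(nodes)),
    class = "kg"
  )
  comp <- kg_components(g)
  if (length(comp) > 1) {
    sizes <- lengths(comp)
    small <- comp[order(sizes)][seq_len(min(3L, length(comp) - 1L))]
    warning(sprintf(
      "graph is not connected: %d components; smallest component(s): %s",
      length(comp),
      paste(vapply(small, function(x) paste(utils::head(x, 4), collapse = ","),
                   ""), collapse = " | ")), call. = FALSE)
  }
  g
}

# Connected components under undirected traversal, as lists of node ids.
kg_components <- function(kg) {
  ig <- kg_igraph(kg)
  cm <- igraph::components(ig, mode = "weak")
  split(names(cm$membership), cm$membership)
}

# igraph view of the graph (undirected, parallel edges kept; edge_type attr).
kg_igraph <- function(kg) {
  igraph::graph_from_data_frame(
    kg$edges, directed = FALSE,
    vertices = data.frame(name = kg$nodes$node_id,
                          node_type = kg$nodes$node_type)
  )
}

#' @export
print.kg <- function(x, ...) {
  cat(sprintf("<kg> %d nodes (%d types), %d edges (%d edge types)\n",
              x$n_nodes, dplyr::n_distinct(x$nodes$node_type),
              nrow(x$edges), dplyr::n_distinct(x$edges$edge_type)))
  invisible(x)
}

#' Node-id to position lookup
#'
#' Positions follow the deterministic lexicographic node ordering, so the
#' i-th element of any propagation or rank vector corresponds to
#' `kg$nodes$node_id[i]`.
#'
#' @param kg A `kg` object.
#' @return Named integer vector mapping `node_id` to 1-based position.
#' @export
kg_node_index <- function(kg) {
  stats::setNames(seq_len(kg$n_nodes), kg$nodes$node_id)
}

#' Count nodes per type
#'
#' @param kg A `kg` object.
#' @return Tibble with columns `node_type` and `n`; types with zero nodes
#'   are absent.  Counts sum to the total node count.
#' @export
node_type_counts <- function(kg) {
  dplyr::count(kg$nodes, .data$node_type, name = "n")
}

#' Read a knowledge graph from node and edge TSV files
#'
#' Node TSV columns: `node_id`, `node_type`, `name`; edge TSV columns:
#' `source`, `target`, `edge_type`.  Both files are tab-separated with a
#' header row.
#'
#' @param node_path,edge_path Paths to the node and edge tables.
#' @return A validated `kg` object (see [kg_graph()]).
#' @export
read_kg <- function(node_path, edge_path) {
  nodes <- readr::read_tsv(node_path, col_types = readr::cols(
    .default = readr::col_character()))
  edges <- readr::read_tsv(edge_path, col_types = readr::cols(
    .default = readr::col_character()))
  kg_graph(nodes, edges)
}

#' Write a knowledge graph to node and edge TSV files
#'
#' Inverse of [read_kg()]: a write/read round trip reproduces the graph
#' exactly, including node order.
#'
#' @param kg A `kg` object.
#' @param node_path,edge_path Output paths.
#' @return `kg`, invisibly.
#' @export
write_kg <- function(kg, node_path, edge_path) {
  readr::write_tsv(kg$nodes, node_path)
  readr::write_tsv(kg$edges, edge_path)
  invisible(kg)
}

#' Summarise a knowledge graph as counts per node and edge type
#'
#' @param kg A `kg` object.
#' @return List with `n_nodes`, `n_edges`, `nodes_by_type`,
#'   `edges_by_type`; serialisable to JSON as a run report.
#' @export
kg_summary <- function(kg) {
  list(
    n_nodes = kg$n_nodes,
    n_edges = nrow(kg$edges),
    nodes_by_type = as.list(stats::setNames(
      node_type_counts(kg)$n, node_type_counts(kg)$node_type)),
    edges_by_type = as.list(table(kg$edges$edge_type))
  )
}

#' Build the random-walk transition model of a graph
#'
#' Collapses parallel edges between the same node pair to a single
#' adjacency (degree counts distinct neighbours, not edges — multiply-typed
#' pairs would otherwise dominate the walk; edge types are kept on the `kg`
#' for path reporting) and assigns each neighbour of a degree-d node
#' transition probability 1/d.  Under the default `"undirected"` policy
#' every edge is traversable both ways; `"directed"` follows stored edge
#' direction only.  Nodes with no neighbours are flagged dangling and get
#' an all-zero row.
#'
#' @param kg A `kg` object with at least one node.
#' @param orientation `"undirected"` (default) or `"directed"`.
#' @return A `kg_transition` object: list with `W` (sparse row-stochastic
#'   N x N dgCMatrix in node order), `dangling` (logical N), `node_ids`,
#'   and `orientation`.
#' @export
kg_transition <- function(kg, orientation = c("undirected", "directed")) {
  orientation <- match.arg(orientation)
  if (kg$n_nodes == 0) stop("empty graph", call. = FALSE)
  idx <- kg_node_index(kg)
  n <- kg$n_nodes
  i <- unname(idx[kg$edges$source])
  j <- unname(idx[kg$edges$target])
  if (orientation == "undirected") {
    pairs <- unique(cbind(pmin(i, j), pmax(i, j)))
    i2 <- c(pairs[, 1], pairs[, 2])
    j2 <- c(pairs[, 2], pairs[, 1])
  } else {
    pairs <- unique(cbind(i, j))
    i2 <- pairs[, 1]
    j2 <- pairs[, 2]
  }
  A <- Matrix::sparseMatrix(i = i2, j = j2, x = 1, dims = c(n, n),
                            dimnames = list(kg$nodes$node_id,
                                            kg$nodes$node_id))
  deg <- Matrix::rowSums(A)
  dangling <- deg == 0
  inv <- ifelse(dangling, 0, 1 / deg)
  W <- Matrix::Diagonal(n, inv) %*% A
  dimnames(W) <- dimnames(A)
  structure(
    list(W = methods::as(W, "CsparseMatrix"),
         dangling = stats::setNames(as.vector(dangling), kg$nodes$node_id),
         node_ids = kg$nodes$node_id,
         orientation = orientation),
    class = "kg_transition"
  )
}

#' @export
print.kg_transition <- function(x, ...) {
  cat(sprintf("<kg_transition> %d nodes, %s walk, %d dangling\n",
              length(x$node_ids), x$orientation, sum(x$dangling)))
  invisible(x)
}
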