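# Shared fixture builders and independent oracles.

# Small typed graph from an edge list; all unnamed nodes default to Gene.
toy_kg <- function(edges, types = NULL) {
  ids <- sort(unique(c(edges$source, edges$target)))
  ty <- rep("Gene", length(ids))
  names(ty) <- ids
  if (!is.null(types)) ty[names(types)] <- types
  suppressWarnings(kg_graph(
    nodes = data.frame(node_id = ids, node_type = unname(ty[ids]),
                       name = ids),
    edges = edges))
}

edge_df <- function(...) {
  pairs <- list(...)
  data.frame(
    source = vapply(pairs, `[[`, "", 1),
    target = vapply(pairs, `[[`, "", 2),
    edge_type = vapply(pairs, function(p)
      if (length(p) > 2) p[[3]] else "link", ""))
}

# Random connected graph of n Gene nodes: random spanning tree plus
# extra Bernoulli edges.
random_connected_kg <- function(n, p_extra = 0.05, seed = 1) {
  withr::local_seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  tree <- data.frame(
    source = ids[2:n],
    target = ids[vapply(2:n, function(i) sample.int(i - 1, 1), 0L)],
    edge_type = "link")
  extra <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(extra)) < p_extra
  edges <- unique(rbind(tree, data.frame(
    source = extra[keep, 1], target = extra[keep, 2],
    edge_type = "link")))
  toy_kg(edges)
}

# Brute-force recursive enumeration of simple paths with <= max_edges
# edges, ignoring edge direction.  Returns sorted "a|b|c" strings.
dfs_paths_oracle <- function(kg, from, to, max_edges) {
  adj <- list()
  for (i in seq_len(nrow(kg$edges))) {
    s <- kg$edges$source[i]
    t <- kg$edges$target[i]
    adj[[s]] <- union(adj[[s]], t)
    adj[[t]] <- union(adj[[t]], s)
  }
  out <- character()
  recurse <- function(path) {
    head <- path[length(path)]
    if (head == to) {
      out <<- c(out, paste(path, collapse = "|"))
      return()
    }
    if (length(path) > max_edges) return()
    for (nb in adj[[head]]) {
      if (!(nb %in% path)) recurse(c(path, nb))
    }
  }
  recurse(from)
  sort(out)
}

# Complete graph on the first k letters, all Gene nodes.
complete_kg <- function(k) {
  cb <- utils::combn(letters[seq_len(k)], 2)
  toy_kg(data.frame(source = cb[1, ], target = cb[2, ],
                    edge_type = "link"))
}

# Long fold-change table row builder.
fc_row <- function(study, comp, group, gene, fc, pval = 0.5) {
  data.frame(study_id = study, comparison_id = comp, group_label = group,
             gene_id = gene, fc = fc, pval = pval)
}

# Minimal pooled-rank object for significance tests.
fake_pooled <- function(ranks, labels) {
  structure(list(
    ranks = ranks,
    meta = tibble::tibble(
      study_id = "s", comparison_id = sprintf("c%d", seq_along(labels)),
      group_label = labels)),
    class = "kg_pooled")
}
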