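#' Correlate gene fold changes with node ranks across comparisons
#'
#' A gene whose fold change tracks a node's embedded rank across the
#' pooled comparisons is a candidate driver of that node's
#' prioritisation.  Genes must be present (non-missing fold change) in
#' strictly more than `min_presence` of all pooled comparisons; the
#' correlation for a retained (gene, node) pair is computed over the
#' comparisons where the gene is present and is `NA` ("unavailable") with
#' fewer than 3 paired observations or zero variance on either side.
#'
#' @param fc_tbl Long fold-change table covering the pooled studies, in
#'   the same gene space used for embedding (typically mapped and
#'   direction-filtered); keyed by (`study_id`, `comparison_id`) matching
#'   `pooled$meta`.
#' @param pooled A `kg_pooled` of embedded ranks.
#' @param node_ids Nodes to correlate against (usually the top nodes).
#' @param min_presence Presence fraction a gene must exceed (default 0.2).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble: `gene_id`, `node_id`, `r`, `n_obs`, `mean_fc`.
#' @export
gene_node_correlation <- function(fc_tbl, pooled, node_ids,
                                  min_presence = 0.2,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  fc_tbl <- fc_validate(fc_tbl)
  node_ids <- as.character(node_ids)
  missing <- setdiff(node_ids, colnames(pooled$ranks))
  if (length(missing) > 0) {
    stop("node(s) absent from the pooled embedding: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(pooled$meta$study_id, pooled$meta$comparison_id)
  n_comp <- length(key)
  fc_tbl <- dplyr::mutate(fc_tbl,
                          .key = paste(.data$study_id, .data$comparison_id))
  fc_tbl <- dplyr::filter(fc_tbl, .data$.key %in% key)
  genes <- sort(unique(fc_tbl$gene_id))
  # genes x pooled-comparisons fold-change matrix; absent rows stay NA
  fc_m <- matrix(NA_real_, length(genes), n_comp,
                 dimnames = list(genes, key))
  fc_m[cbind(match(fc_tbl$gene_id, genes), match(fc_tbl$.key, key))] <-
    fc_tbl$fc
  present <- rowMeans(!is.na(fc_m))
  keep <- genes[present > min_presence]
  R <- pooled$ranks[, node_ids, drop = FALSE]
  out <- purrr::map_dfr(keep, function(g) {
    obs <- which(!is.na(fc_m[g, ]))
    x <- fc_m[g, obs]
    r <- if (length(obs) < 3 || stats::sd(x) == 0) {
      rep(NA_real_, length(node_ids))
    } else {
      unname(vapply(node_ids, function(nd) {
        y <- R[obs, nd]
        if (stats::sd(y) == 0) NA_real_ else
          stats::cor(x, y, method = method)
      }, numeric(1)))
    }
    tibble::tibble(gene_id = g, node_id = node_ids, r = r,
                   n_obs = length(obs), mean_fc = mean(x))
  })
  out
}

#' Filter gene-node pairs by correlation and sign concordance
#'
#' Keeps pairs with correlation strictly above `r_threshold` whose gene
#' mean fold change agrees in sign with the node's Welch t-statistic (the
#' t of the contrast with the smaller p-value — the contrast that made
#' the node significant).  `sign_filter = "concordant"` (default) accepts
#' +/+ and -/- pairs; `"positive_only"` accepts only +/+.
#'
#' @param correlations Tibble from [gene_node_correlation()].
#' @param node_tests A `kg_nodetests`/`kg_topnodes` with `t_svb`, `p_svb`,
#'   `t_svg`, `p_svg` per node.
#' @param r_threshold Correlation threshold (default 0.6, strict).
#' @param sign_filter `"concordant"` or `"positive_only"`.
#' @return `correlations` plus `node_t` and logical `kept`.
#' @export
filter_gene_node_pairs <- function(correlations, node_tests,
                                   r_threshold = 0.6,
                                   sign_filter = c("concordant",
                                                   "positive_only")) {
  sign_filter <- match.arg(sign_filter)
  tsel <- node_tests |>
    dplyr::mutate(node_t = dplyr::case_when(
      is.na(.data$p_svg) ~ .data$t_svb,
      is.na(.data$p_svb) ~ .data$t_svg,
      .data$p_svb <= .data$p_svg ~ .data$t_svb,
      TRUE ~ .data$t_svg
    )) |>
    dplyr::select("node_id", "node_t")
  out <- dplyr::left_join(correlations, tsel, by = "node_id")
  sign_ok <- if (sign_filter == "concordant") {
    sign(out$mean_fc) * sign(out$node_t) > 0
  } else {
    out$mean_fc > 0 & out$node_t > 0
  }
  dplyr::mutate(out, kept = !is.na(.data$r) & .data$r > r_threshold &
                  !is.na(.data$node_t) & sign_ok)
}

#' Enumerate short simple paths between two nodes
#'
#' All simple paths (no repeated nodes) of at most `max_edges` edges
#' between `source` and `target`, traversing edges without regard to
#' direction.  When the number of such paths reaches `max_paths` the pair
#' is flagged overflow and no paths are reported — pairs with too many
#' path combinations are not usefully visualisable.  Paths are ordered by
#' (length, lexicographic node sequence).  For a step between two nodes
#' joined by several typed edges, all edge types are reported joined by
#' `&`.
#'
#' @param kg A `kg` object.
#' @param source,target Distinct node ids.
#' @param max_edges Maximum path length in edges (default 3).
#' @param max_paths Overflow bound (default 100): pairs with >=
#'   `max_paths` simple paths are flagged and excluded from reporting.
#' @return List with `paths` (tibble: `nodes` and `edge_types`,
#'   pipe-delimited; `n_edges`), `n_paths` (count before the overflow
#'   cut), and `overflow`.
#' @export
enumerate_paths <- function(kg, source, target, max_edges = 3,
                            max_paths = 100) {
  if (identical(source, target)) {
    stop("source and target must differ", call. = FALSE)
  }
  for (v in c(source, target)) {
    if (!(v %in% kg$nodes$node_id)) {
      stop("node not in graph: ", v, call. = FALSE)
    }
  }
  ig <- igraph::simplify(kg_igraph(kg), remove.multiple = TRUE)
  vs <- suppressWarnings(igraph::all_simple_paths(
    ig, from = source, to = target, mode = "all", cutoff = max_edges))
  seqs <- lapply(vs, function(p) names(p))
  ord <- order(lengths(seqs),
               vapply(seqs, paste, "", collapse = "|"))
  seqs <- seqs[ord]
  n_paths <- length(seqs)
  if (n_paths >= max_paths) {
    return(list(paths = empty_paths_tbl(), n_paths = n_paths,
                overflow = TRUE))
  }
  paths <- purrr::map_dfr(seqs, function(s) {
    tibble::tibble(
      nodes = paste(s, collapse = "|"),
      edge_types = paste(
        vapply(seq_len(length(s) - 1),
               function(i) step_edge_types(kg, s[i], s[i + 1]), ""),
        collapse = "|"),
      n_edges = length(s) - 1L)
  })
  if (n_paths == 0) paths <- empty_paths_tbl()
  list(paths = paths, n_paths = n_paths, overflow = FALSE)
}

empty_paths_tbl <- function() {
  tibble::tibble(nodes = character(), edge_types = character(),
                 n_edges = integer())
}

# All edge types between two adjacent nodes (either direction), sorted,
# joined by "&".
step_edge_types <- function(kg, a, b) {
  hit <- (kg$edges$source == a & kg$edges$target == b) |
    (kg$edges$source == b & kg$edges$target == a)
  paste(sort(unique(kg$edges$edge_type[hit])), collapse = "&")
}

#' Trace explanatory paths for kept gene-node pairs
#'
#' Runs [enumerate_paths()] for every kept pair, annotates the pair table
#' with path counts and overflow flags, and returns the combined path
#' table in the deterministic reporting order: path length, then
#' decreasing |mean fold change| of the driving gene, then lexicographic
#' node sequence.
#'
#' @param kg A `kg` object.
#' @param pairs Tibble from [filter_gene_node_pairs()] (uses rows with
#'   `kept`).
#' @param max_edges,max_paths See [enumerate_paths()].
#' @return List with `pairs` (input plus `n_paths`, `overflow`) and
#'   `paths` (tibble: `gene_id`, `node_id`, `nodes`, `edge_types`,
#'   `n_edges`, `mean_fc`).
#' @export
trace_paths <- function(kg, pairs, max_edges = 3, max_paths = 100) {
  pairs <- dplyr::mutate(pairs, n_paths = NA_integer_, overflow = NA)
  kept <- which(pairs$kept & pairs$gene_id != pairs$node_id)
  all_paths <- list()
  for (i in kept) {
    res <- enumerate_paths(kg, pairs$gene_id[i], pairs$node_id[i],
                           max_edges = max_edges, max_paths = max_paths)
    pairs$n_paths[i] <- res$n_paths
    pairs$overflow[i] <- res$overflow
    if (!res$overflow && nrow(res$paths) > 0) {
      all_paths[[length(all_paths) + 1]] <- dplyr::mutate(
        res$paths, gene_id = pairs$gene_id[i], node_id = pairs$node_id[i],
        mean_fc = pairs$mean_fc[i], .before = 1)
    }
  }
  paths <- if (length(all_paths) > 0) {
    dplyr::bind_rows(all_paths) |>
      dplyr::arrange(.data$n_edges, dplyr::desc(abs(.data$mean_fc)),
                     .data$nodes)
  } else {
    dplyr::mutate(empty_paths_tbl(), gene_id = character(),
                  node_id = character(), mean_fc = numeric(), .before = 1)
  }
  list(pairs = pairs, paths = paths)
}

#' Combine p-values with Stouffer's method
#'
#' Converts each p-value to a normal quantile z = qnorm(1 - p), averages
#' them scaled by sqrt(k), and maps back: combined p =
#' 1 - pnorm(sum(z)/sqrt(k)).  The k = 1 case is the identity.  All
#' inputs must lie strictly inside (0, 1).
#'
#' @param p Numeric vector of p-values in (0, 1); length >= 1.
#' @return Combined p-value.
#' @examples
#' stouffer_combine(c(0.05, 0.05))  # ~0.00999
#' @export
stouffer_combine <- function(p) {
  if (length(p) == 0) stop("no p-values to combine", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p-values must lie strictly in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(p, lower.tail = FALSE)
  stats::pnorm(sum(z) / sqrt(length(p)), lower.tail = FALSE)
}

#' Score gene fold changes across comparison groups
#'
#' Positions every gene on two axes summarising whether its expression
#' shift is spaceflight-specific.  y: the gene's per-comparison p-values
#' — made one-sided in the direction of the gene's overall mean fold
#' change — are Stouffer-combined over the two spaceflight groups pooled
#' and, separately, over the ground-control group; reported as both
#' combined p-values, their log10 difference (`y`, positive when the
#' spaceflight combination is more significant) and a boolean.  x: Welch
#' t of the gene's fold-change values in each spaceflight group against
#' the ground-control group, computed per group and then averaged
#' (a single available contrast stands alone).
#'
#' @param fc_tbl Long fold-change table with p-values across the pooled
#'   studies.
#' @param p_clamp P-values are clamped into (`p_clamp`, 1 - `p_clamp`)
#'   before the normal-quantile transform (default 1e-15).
#' @return Tibble: `gene_id`, `x`, `y`, `p_space`, `p_ground`,
#'   `space_more_significant`, `n_ground`, `n_space`.  Genes lacking a
#'   usable observation in either the ground or a spaceflight group are
#'   skipped with a warning.
#' @export
score_gene_fc <- function(fc_tbl, p_clamp = 1e-15) {
  fc_tbl <- fc_validate(fc_tbl)
  fc_tbl <- dplyr::filter(fc_tbl, !is.na(.data$fc), !is.na(.data$pval))
  skipped <- 0L
  out <- purrr::map_dfr(split(fc_tbl, fc_tbl$gene_id), function(d) {
    ground <- d[d$group_label == "GroundVsBaseline", ]
    space <- d[d$group_label != "GroundVsBaseline", ]
    if (nrow(ground) < 1 || nrow(space) < 1) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    dir <- sign(mean(d$fc))
    if (dir == 0) dir <- 1
    one_sided <- function(p, fc) {
      p1 <- ifelse(sign(fc) == dir, p / 2,
                   ifelse(fc == 0, 0.5, 1 - p / 2))
      pmin(pmax(p1, p_clamp), 1 - p_clamp)
    }
    p_space <- stouffer_combine(one_sided(space$pval, space$fc))
    p_ground <- stouffer_combine(one_sided(ground$pval, ground$fc))
    ts <- c(
      svb = welch_or_na(space$fc[space$group_label == "SpaceVsBaseline"],
                        ground$fc),
      svg = welch_or_na(space$fc[space$group_label == "SpaceVsGround"],
                        ground$fc))
    x <- if (all(is.na(ts))) NA_real_ else mean(ts, na.rm = TRUE)
    tibble::tibble(
      gene_id = d$gene_id[1], x = x,
      y = log10(p_ground) - log10(p_space),
      p_space = p_space, p_ground = p_ground,
      space_more_significant = p_space < p_ground,
      n_ground = nrow(ground), n_space = nrow(space))
  })
  if (skipped > 0) {
    warning(sprintf(
      "%d gene(s) skipped: no observation in ground or spaceflight group",
      skipped), call. = FALSE)
  }
  out
}

# Welch t or NA when a side has < 2 observations or both variances are 0.
welch_or_na <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (stats::var(a) == 0 && stats::var(b) == 0) return(NA_real_)
  welch_t(a, b)$t
}
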