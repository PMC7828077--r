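#' Pool study embeddings into comparison groups
#'
#' Concatenates the rank rows of several study embeddings, keeping
#' per-row provenance (study, comparison, group label).  All embeddings
#' must share the same node ordering.
#'
#' @param embeddings List of `kg_embedding` objects.
#' @return A `kg_pooled`: list with `ranks` (pooled rows x nodes) and
#'   `meta` tibble (`study_id`, `comparison_id`, `group_label`) aligned to
#'   rows.
#' @export
pool_embeddings <- function(embeddings) {
  if (length(embeddings) == 0) stop("no embeddings to pool", call. = FALSE)
  cols <- colnames(embeddings[[1]]$ranks)
  for (e in embeddings) {
    if (!identical(colnames(e$ranks), cols)) {
      stop("embeddings disagree on node ordering; pool refused",
           call. = FALSE)
    }
  }
  ranks <- do.call(rbind, lapply(embeddings, function(e) e$ranks))
  meta <- dplyr::bind_rows(lapply(embeddings, function(e) e$meta))
  rownames(ranks) <- paste(meta$study_id, meta$comparison_id, sep = ":")
  structure(list(ranks = ranks, meta = meta), class = "kg_pooled")
}

#' @export
print.kg_pooled <- function(x, ...) {
  tab <- table(x$meta$group_label)
  cat(sprintf("<kg_pooled> %d comparisons x %d nodes (%s)\n",
              nrow(x$ranks), ncol(x$ranks),
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Tidy pooled ranks into a long tibble
#'
#' @param x A `kg_pooled`.
#' @param ... Unused.
#' @return Tibble with `study_id`, `comparison_id`, `group_label`,
#'   `node_id`, `rank`.
#' @exportS3Method generics::tidy
tidy.kg_pooled <- function(x, ...) {
  tibble::as_tibble(x$ranks) |>
    dplyr::mutate(study_id = x$meta$study_id,
                  comparison_id = x$meta$comparison_id,
                  group_label = x$meta$group_label) |>
    tidyr::pivot_longer(
      -c("study_id", "comparison_id", "group_label"),
      names_to = "node_id", values_to = "rank")
}

#' Centre pooled ranks on the ground-control mean
#'
#' Subtracts, per node, the node's mean rank in the `GroundVsBaseline`
#' group from every pooled row.  A display transform (used for
#' violin-plot exports) that sets the ground-control mean to zero per
#' node; Welch tests are invariant to it since the same shift is applied
#' to both samples.
#'
#' @param pooled A `kg_pooled` with a non-empty `GroundVsBaseline` group.
#' @return A `kg_pooled` of adjusted (no longer 1..N) rank values.
#' @export
adjust_ranks_by_baseline_mean <- function(pooled) {
  base <- pooled$meta$group_label == "GroundVsBaseline"
  if (!any(base)) stop("no GroundVsBaseline rows to centre on",
                       call. = FALSE)
  mu <- colMeans(pooled$ranks[base, , drop = FALSE])
  out <- pooled
  out$ranks <- sweep(pooled$ranks, 2, mu, "-")
  out
}

#' Welch's unequal-variance two-sample t-test
#'
#' Computes t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb), the
#' Welch–Satterthwaite degrees of freedom, and the two-sided p-value from
#' the t distribution.  Both samples need at least two values, and at
#' least one must have nonzero variance.
#'
#' @param a,b Numeric vectors (NA values dropped).
#' @return One-row tibble with `t`, `df`, `p`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    stop("both samples have zero variance; t undefined", call. = FALSE)
  }
  sa <- va / length(a)
  sb <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  tibble::tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Vectorised Welch over the columns of two rank matrices.
# Returns tibble(t, df, p) with one row per column; columns where both
# groups have zero variance come back NA.
welch_t_cols <- function(A, B) {
  na <- nrow(A)
  nb <- nrow(B)
  ma <- colMeans(A)
  mb <- colMeans(B)
  va <- colSums(sweep(A, 2, ma, "-")^2) / (na - 1)
  vb <- colSums(sweep(B, 2, mb, "-")^2) / (nb - 1)
  sa <- va / na
  sb <- vb / nb
  degenerate <- (va == 0 & vb == 0)
  t <- ifelse(degenerate, NA_real_, (ma - mb) / sqrt(sa + sb))
  df <- ifelse(degenerate, NA_real_,
               (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1)))
  tibble::tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Per-node rank-shift tests between spaceflight and ground groups
#'
#' For every graph node, Welch-tests the node's pooled rank sample in
#' each spaceflight group against the `GroundVsBaseline` sample:
#' `svb` = SpaceVsBaseline vs GroundVsBaseline and `svg` = SpaceVsGround
#' vs GroundVsBaseline.  Positive t means the node ranks higher (more
#' important) in spaceflight.  Nodes with zero rank variance in both
#' samples of a contrast get `NA` results for it (with a warning); a
#' missing spaceflight group leaves that contrast's columns `NA`.
#'
#' @param pooled A `kg_pooled`; the `GroundVsBaseline` group and at least
#'   one spaceflight group must have >= 2 rows.
#' @param kg Optional `kg` supplying `node_type` for the result.
#' @return A `kg_nodetests` tibble: `node_id`, `node_type` (if `kg`
#'   given), `t_svb`, `df_svb`, `p_svb`, `t_svg`, `df_svg`, `p_svg`.
#' @export
compare_groups <- function(pooled, kg = NULL) {
  labs <- pooled$meta$group_label
  base <- pooled$ranks[labs == "GroundVsBaseline", , drop = FALSE]
  if (nrow(base) < 2) {
    stop("GroundVsBaseline group needs at least 2 pooled comparisons",
         call. = FALSE)
  }
  one_contrast <- function(label) {
    M <- pooled$ranks[labs == label, , drop = FALSE]
    if (nrow(M) < 2) {
      return(tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                            .rows = ncol(pooled$ranks)))
    }
    res <- welch_t_cols(M, base)
    if (anyNA(res$t)) {
      warning(sprintf(
        "%d node(s) with zero rank variance excluded from the %s contrast",
        sum(is.na(res$t)), label), call. = FALSE)
    }
    res
  }
  svb <- one_contrast("SpaceVsBaseline")
  svg <- one_contrast("SpaceVsGround")
  if (all(is.na(svb$t)) && all(is.na(svg$t))) {
    stop("no spaceflight group with at least 2 pooled comparisons",
         call. = FALSE)
  }
  out <- tibble::tibble(
    node_id = colnames(pooled$ranks),
    t_svb = svb$t, df_svb = svb$df, p_svb = svb$p,
    t_svg = svg$t, df_svg = svg$df, p_svg = svg$p
  )
  if (!is.null(kg)) {
    out <- dplyr::mutate(
      out,
      node_type = kg$nodes$node_type[match(.data$node_id,
                                           kg$nodes$node_id)],
      .after = "node_id")
  }
  class(out) <- c("kg_nodetests", class(out))
  out
}

#' Flag the most significant nodes per type
#'
#' Two-stage selection of "top" nodes.  Prescreen: p < `prescreen_p` in
#' either spaceflight contrast.  Per node type and per contrast, the
#' `ceiling(top_frac * type count)` nodes with the smallest p-values are
#' flagged (ties broken by node id for determinism); `top` requires being
#' flagged in at least one contrast *and* passing the prescreen.  No
#' multiple-testing correction is applied; thresholds act on raw
#' p-values.
#'
#' @param results A `kg_nodetests` from [compare_groups()], with
#'   `node_type` present (pass `kg` there), or supply `type_counts`.
#' @param type_counts Tibble `node_type`, `n` from [node_type_counts()];
#'   defaults to counting the nodes present in `results`.
#' @param prescreen_p Prescreen p-value threshold (default 0.025).
#' @param top_frac Per-type fraction kept per contrast (default 0.025).
#' @return A `kg_topnodes` tibble: `results` plus logical `prescreen`,
#'   `top_svb`, `top_svg`, `top`.
#' @export
select_top_nodes <- function(results, type_counts = NULL,
                             prescreen_p = 0.025, top_frac = 0.025) {
  if (!("node_type" %in% names(results))) {
    stop("results must carry node_type (call compare_groups with kg)",
         call. = FALSE)
  }
  if (is.null(type_counts)) {
    type_counts <- dplyr::count(results, .data$node_type, name = "n")
  }
  quota <- stats::setNames(as.integer(ceiling(top_frac * type_counts$n)),
                           type_counts$node_type)
  flag_contrast <- function(p) {
    flagged <- logical(nrow(results))
    for (ty in unique(results$node_type)) {
      rows <- which(results$node_type == ty & !is.na(p))
      k <- min(quota[[ty]], length(rows))
      if (k > 0) {
        ord <- rows[order(p[rows], results$node_id[rows])]
        flagged[ord[seq_len(k)]] <- TRUE
      }
    }
    flagged
  }
  out <- results |>
    dplyr::mutate(
      prescreen = (!is.na(.data$p_svb) & .data$p_svb < prescreen_p) |
        (!is.na(.data$p_svg) & .data$p_svg < prescreen_p),
      top_svb = flag_contrast(.data$p_svb),
      top_svg = flag_contrast(.data$p_svg),
      top = (.data$top_svb | .data$top_svg) & .data$prescreen
    )
  class(out) <- c("kg_topnodes", setdiff(class(out), "kg_topnodes"))
  out
}

#' @exportS3Method generics::tidy
tidy.kg_topnodes <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), c("kg_topnodes", "kg_nodetests"))
  out
}

#' Summarise a top-node selection
#'
#' @param x A `kg_topnodes`.
#' @param ... Unused.
#' @return One-row tibble: node counts, prescreen and top counts, and the
#'   top fraction.
#' @exportS3Method generics::glance
glance.kg_topnodes <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x),
    n_tested = sum(!is.na(x$p_svb) | !is.na(x$p_svg)),
    n_prescreen = sum(x$prescreen),
    n_top = sum(x$top),
    frac_top = sum(x$top) / nrow(x)
  )
}
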