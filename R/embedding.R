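#' Normalise and rank propagation profiles for a gene set
#'
#' Restricts the propagation-profile matrix to the study's genes,
#' z-scores it, and converts each gene's profile to within-profile ranks:
#' the node most visited from that gene gets rank N (the node count) and
#' the least visited rank 1, with average ranks on ties.
#'
#' The default z-score axis is per node (column) across the selected
#' genes — node importance is made comparable between genes before the
#' fold-change weighting sums over genes; `axis = "gene"` z-scores within
#' each profile instead.  Columns (or rows) with zero variance are set to
#' 0.
#'
#' @param rwr_mat Matrix from [rwr_matrix()] (genes x nodes).
#' @param gene_ids At least two gene ids, all present among the matrix
#'   rows.
#' @param axis `"node"` (default) or `"gene"`: the axis z-scored before
#'   ranking.
#' @return Matrix of ranks (genes x nodes); every row is a permutation of
#'   1..N up to tie-averaging.
#' @export
normalize_rank_profiles <- function(rwr_mat, gene_ids,
                                    axis = c("node", "gene")) {
  axis <- match.arg(axis)
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) < 2) {
    stop("need at least 2 genes to z-score", call. = FALSE)
  }
  missing <- setdiff(gene_ids, rownames(rwr_mat))
  if (length(missing) > 0) {
    stop("gene(s) absent from the profile matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  m <- rwr_mat[gene_ids, , drop = FALSE]
  z <- if (axis == "node") zscore_cols(m) else t(zscore_cols(t(m)))
  ranks <- t(apply(z, 1, rank, ties.method = "average"))
  dimnames(ranks) <- dimnames(m)
  ranks
}

# Column z-scores with sample SD; constant columns -> 0.
zscore_cols <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  z <- sweep(sweep(m, 2, mu, "-"), 2, ifelse(sd == 0, 1, sd), "/")
  z[, sd == 0] <- 0
  z
}

#' Embed a study's comparisons as node-rank vectors
#'
#' For each comparison, weights every gene's normalised rank profile by
#' the gene's fold change and sums over genes, giving one aggregate score
#' per graph node; the aggregate vector is then ranked 1..N (highest
#' aggregate = N, average ranks on ties).  Equivalently the dot product of
#' the comparisons-x-genes fold-change matrix with the genes-x-nodes
#' normalised profile matrix, followed by row-wise ranking.  A missing
#' fold change contributes 0.  The gene sets of the fold-change table and
#' the profile matrix must be identical; mismatches are an error, never
#' silently reordered.
#'
#' @param fc_tbl Long fold-change table for one study, in human gene
#'   space (after [map_homologs()] and [filter_direction_consistent()]).
#' @param norm_profiles Matrix from [normalize_rank_profiles()] whose rows
#'   cover exactly the genes of `fc_tbl`.
#' @return A `kg_embedding`: list with `ranks` (comparisons x nodes rank
#'   matrix), `meta` (tibble `study_id`, `comparison_id`, `group_label`
#'   aligned to rows), and `study_id`.
#' @export
embed_study <- function(fc_tbl, norm_profiles) {
  fc_tbl <- fc_validate(fc_tbl)
  study <- unique(fc_tbl$study_id)
  if (length(study) != 1) {
    stop("embed_study expects a single study; got: ",
         paste(study, collapse = ", "), call. = FALSE)
  }
  genes <- rownames(norm_profiles)
  tbl_genes <- unique(fc_tbl$gene_id)
  if (!setequal(genes, tbl_genes)) {
    stop(sprintf(
      "gene sets differ between fold-change table (%d) and profiles (%d)",
      length(tbl_genes), length(genes)), call. = FALSE)
  }
  meta <- dplyr::distinct(fc_tbl, .data$study_id, .data$comparison_id,
                          .data$group_label)
  # comparisons x genes, in profile row order; missing FC -> 0
  FC <- fc_tbl |>
    dplyr::select("comparison_id", "gene_id", "fc") |>
    tidyr::pivot_wider(names_from = "gene_id", values_from = "fc")
  fc_m <- as.matrix(FC[, genes, drop = FALSE])
  rownames(fc_m) <- FC$comparison_id
  fc_m[is.na(fc_m)] <- 0
  fc_m <- fc_m[meta$comparison_id, , drop = FALSE]
  agg <- fc_m %*% norm_profiles
  ranks <- t(apply(agg, 1, rank, ties.method = "average"))
  dimnames(ranks) <- list(meta$comparison_id, colnames(norm_profiles))
  structure(list(ranks = ranks, meta = meta, study_id = study),
            class = "kg_embedding")
}

#' @export
print.kg_embedding <- function(x, ...) {
  cat(sprintf("<kg_embedding> study %s: %d comparisons x %d nodes\n",
              x$study_id, nrow(x$ranks), ncol(x$ranks)))
  invisible(x)
}

#' Tidy an embedding into a long tibble
#'
#' @param x A `kg_embedding`.
#' @param ... Unused.
#' @return Tibble with `study_id`, `comparison_id`, `group_label`,
#'   `node_id`, `rank`.
#' @exportS3Method generics::tidy
tidy.kg_embedding <- function(x, ...) {
  tibble::as_tibble(x$ranks, rownames = "comparison_id") |>
    tidyr::pivot_longer(-"comparison_id", names_to = "node_id",
                        values_to = "rank") |>
    dplyr::left_join(x$meta, by = "comparison_id") |>
    dplyr::select("study_id", "comparison_id", "group_label", "node_id",
                  "rank")
}

#' Write / read an embedding as TSV plus a group-label sidecar JSON
#'
#' The TSV holds one row per comparison and one column per node; the JSON
#' sidecar (same path with extension `.json`) records `study_id` and the
#' row-aligned group labels.
#'
#' @param embedding A `kg_embedding`.
#' @param path TSV output path.
#' @return The embedding, invisibly (write) or reconstructed (read).
#' @export
write_embedding <- function(embedding, path) {
  df <- tibble::as_tibble(embedding$ranks, rownames = "comparison_id")
  readr::write_tsv(df, path)
  jsonlite::write_json(
    list(study_id = embedding$study_id, meta = embedding$meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(embedding)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    comparison_id = readr::col_character(), .default = readr::col_double()))
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  ranks <- as.matrix(df[-1])
  rownames(ranks) <- df$comparison_id
  structure(list(ranks = ranks, meta = tibble::as_tibble(side$meta),
                 study_id = side$study_id),
            class = "kg_embedding")
}

sidecar_path <- function(path) paste0(sub("\\.tsv$", "", path), ".json")
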