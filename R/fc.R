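#' @importFrom rlang .data
NULL

# The three comparison group labels the pipeline recognises.
fc_group_labels <- function() {
  c("GroundVsBaseline", "SpaceVsBaseline", "SpaceVsGround")
}

#' Validate a long fold-change table
#'
#' The package represents per-study differential-expression results as a
#' long tibble with one row per (comparison, gene): columns `study_id`,
#' `comparison_id`, `group_label`, `gene_id`, `fc` (signed fold-change
#' score, the -log2 FC scale of the upstream differential-expression
#' tooling), `pval`.  `NA` in `fc` marks a gene not measured in that
#' comparison; a gene may also simply be absent from a comparison's rows.
#'
#' @param fc_tbl Data frame in the long format above.
#' @return The table as a tibble, invisibly checked: required columns
#'   present, group labels admissible, no duplicated (comparison, gene)
#'   rows, p-values in (0, 1] where present.
#' @export
fc_validate <- function(fc_tbl) {
  need <- c("study_id", "comparison_id", "group_label", "gene_id", "fc",
            "pval")
  if (!all(need %in% names(fc_tbl))) {
    stop("fold-change table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  fc_tbl <- tibble::as_tibble(fc_tbl)
  bad <- setdiff(unique(fc_tbl$group_label), fc_group_labels())
  if (length(bad) > 0) {
    stop("unknown group_label(s): ", paste(bad, collapse = ", "),
         "; admissible: ", paste(fc_group_labels(), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(fc_tbl$study_id, fc_tbl$comparison_id, fc_tbl$gene_id)
  if (anyDuplicated(key)) {
    stop("duplicated (study, comparison, gene) rows in fold-change table",
         call. = FALSE)
  }
  p <- fc_tbl$pval[!is.na(fc_tbl$pval)]
  if (any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  fc_tbl
}

#' Read / write long fold-change tables as TSV
#'
#' @param path TSV path with the columns described in [fc_validate()].
#' @return A validated tibble.
#' @export
read_fc_table <- function(path) {
  fc_validate(readr::read_tsv(path, col_types = readr::cols(
    study_id = readr::col_character(),
    comparison_id = readr::col_character(),
    group_label = readr::col_character(),
    gene_id = readr::col_character(),
    fc = readr::col_double(),
    pval = readr::col_double())))
}

#' @rdname read_fc_table
#' @param fc_tbl Table to write.
#' @export
write_fc_table <- function(fc_tbl, path) {
  readr::write_tsv(fc_validate(fc_tbl), path)
  invisible(fc_tbl)
}

#' Read a homolog mapping table
#'
#' TSV with columns `mouse_gene_id`, `human_gene_id`; many mouse genes may
#' map to one human gene.
#'
#' @param path TSV path.
#' @param kg Optional `kg` object; when given, every `human_gene_id` must
#'   be a Gene node of the graph.
#' @return Tibble with the two columns.
#' @export
read_homolog_map <- function(path, kg = NULL) {
  hm <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  homolog_validate(hm, kg)
}

homolog_validate <- function(homolog_map, kg = NULL) {
  need <- c("mouse_gene_id", "human_gene_id")
  if (!all(need %in% names(homolog_map))) {
    stop("homolog map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  homolog_map <- tibble::as_tibble(homolog_map)[need]
  if (anyDuplicated(homolog_map$mouse_gene_id)) {
    stop("a mouse gene may map to only one human gene", call. = FALSE)
  }
  if (!is.null(kg)) {
    type <- kg$nodes$node_type[match(homolog_map$human_gene_id,
                                     kg$nodes$node_id)]
    if (any(is.na(type) | type != "Gene")) {
      bad <- homolog_map$human_gene_id[is.na(type) | type != "Gene"]
      stop("human_gene_id(s) not Gene nodes of the graph: ",
           paste(utils::head(unique(bad), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  homolog_map
}

#' Map mouse fold changes onto human gene nodes
#'
#' Re-indexes a mouse-gene fold-change table by the human Gene nodes of
#' the knowledge graph via a homolog map.  When several mouse genes map to
#' the same human gene, the human fold change per comparison is the
#' arithmetic mean of the contributing (non-missing) mouse fold changes,
#' and the p-value is the minimum of the contributing p-values —
#' "any contributing homolog significant" semantics for downstream
#' scoring.  Mouse genes without a mapping are dropped (their count is
#' recorded in the `n_unmapped` attribute).
#'
#' @param fc_tbl Long mouse-gene fold-change table (see [fc_validate()]).
#' @param homolog_map Tibble with `mouse_gene_id`, `human_gene_id`.
#' @param kg Optional graph for validating the mapped human genes.
#' @return Long fold-change table in human gene space, with attributes
#'   `n_unmapped` (mouse genes dropped) and `n_mapped`.
#' @export
map_homologs <- function(fc_tbl, homolog_map, kg = NULL) {
  fc_tbl <- fc_validate(fc_tbl)
  homolog_map <- homolog_validate(homolog_map, kg)
  mapped <- dplyr::inner_join(fc_tbl, homolog_map,
                              by = c(gene_id = "mouse_gene_id"))
  if (nrow(mapped) == 0) {
    stop("no mouse gene in the fold-change table maps to a human gene",
         call. = FALSE)
  }
  out <- mapped |>
    dplyr::group_by(.data$study_id, .data$comparison_id, .data$group_label,
                    gene_id = .data$human_gene_id) |>
    dplyr::summarise(
      fc = mean_or_na(.data$fc),
      pval = min_or_na(.data$pval),
      .groups = "drop"
    )
  in_genes <- unique(fc_tbl$gene_id)
  attr(out, "n_unmapped") <- length(setdiff(in_genes,
                                            homolog_map$mouse_gene_id))
  attr(out, "n_mapped") <- length(intersect(in_genes,
                                            homolog_map$mouse_gene_id))
  out
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

min_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else min(x)
}

#' Drop genes whose fold changes flip sign within a study
#'
#' Within each study, a gene measured in several comparisons is removed
#' when its non-missing fold changes are not all of the same direction
#' (some strictly positive and some strictly negative).  Exact zeros are
#' sign-agnostic and compatible with either direction.  This keeps the
#' gene set whose response is consistent during spaceflight: by default
#' only the spaceflight comparisons (Space vs. Baseline, Space vs.
#' Ground — e.g. several flight time points of one study) are examined
#' for sign conflicts; `scope = "all"` also includes the Ground vs.
#' Baseline comparisons.  Whole rows of dropped genes are removed from
#' every comparison of the study; single-comparison studies pass through
#' unchanged.
#'
#' @param fc_tbl Long fold-change table.
#' @param scope `"space"` (default) or `"all"`: which of a study's
#'   comparisons are examined for sign conflicts.
#' @return Filtered table with attribute `n_dropped` = number of
#'   (study, gene) combinations removed.
#' @export
filter_direction_consistent <- function(fc_tbl, scope = c("space", "all")) {
  scope <- match.arg(scope)
  fc_tbl <- fc_validate(fc_tbl)
  examined <- if (scope == "space") {
    dplyr::filter(fc_tbl, .data$group_label != "GroundVsBaseline")
  } else {
    fc_tbl
  }
  flags <- examined |>
    dplyr::group_by(.data$study_id, .data$gene_id) |>
    dplyr::summarise(
      inconsistent = any(.data$fc > 0, na.rm = TRUE) &&
        any(.data$fc < 0, na.rm = TRUE),
      .groups = "drop"
    )
  out <- fc_tbl |>
    dplyr::left_join(flags, by = c("study_id", "gene_id")) |>
    dplyr::filter(!dplyr::coalesce(.data$inconsistent, FALSE)) |>
    dplyr::select(-"inconsistent")
  attr(out, "n_dropped") <- sum(flags$inconsistent)
  out
}
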