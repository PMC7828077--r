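#' Default pipeline parameters
#'
#' The analysis parameters with their standard values: restart
#' probability `alpha = 0.1`, prescreen p-value 0.025, per-type top
#' fraction 0.025, gene-node correlation threshold 0.6, path bound 3
#' edges / 100 combinations, gene presence fraction 0.2.
#'
#' @return Named list of defaults, overridable per run via the `params`
#'   block of the pipeline configuration.
#' @export
pipeline_defaults <- function() {
  list(
    alpha = 0.1, tol = 1e-10, max_iter = 1000L,
    orientation = "undirected", zscore_axis = "node",
    prescreen_p = 0.025, top_frac = 0.025,
    r_threshold = 0.6, sign_filter = "concordant",
    correlation = "pearson", min_presence = 0.2,
    max_edges = 3L, max_paths = 100L
  )
}

#' Run the full propagation pipeline
#'
#' Executes the end-to-end analysis: load (or synthesise) the knowledge
#' graph, fold-change tables and homolog map; compute per-gene
#' restart-walk profiles; per study, map homologs, drop
#' direction-inconsistent genes, normalise/rank profiles and embed each
#' comparison as a node-rank vector; pool across studies, Welch-test each
#' node's rank shift between spaceflight and ground groups and flag top
#' nodes per type; correlate gene fold changes with top-node ranks and
#' retrace short explanatory paths; score gene fold changes across
#' groups.  All stage outputs are written as TSV/JSON into `out_dir`
#' together with a run manifest; a failed stage removes this run's
#' partial outputs and aborts with the stage name.
#'
#' @param config A list (or path to a YAML file) with either a
#'   `synthetic` block (arguments for [synth_config()]; `seed` falls back
#'   to the top-level `seed`) or an `inputs` block (`nodes`, `edges`,
#'   `fc`, `homologs` file paths), an optional `params` block overriding
#'   [pipeline_defaults()], and an integer `seed`.
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress per-stage progress messages (default FALSE).
#' @return Invisibly, a list with the in-memory stage results (`kg`,
#'   `pooled`, `top_nodes`, `pairs`, `paths`, `gene_scores`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  params <- utils::modifyList(pipeline_defaults(),
                              config$params %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  made <- character()
  note <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  out <- function(name) {
    p <- file.path(out_dir, name)
    made <<- c(made, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(made)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- inputs ------------------------------------------------------------
  input_paths <- stage("inputs", {
    if (!is.null(config$synthetic)) {
      sc_args <- config$synthetic
      sc_args$seed <- sc_args$seed %||% config$seed
      sc <- do.call(synth_config, sc_args)
      fix_dir <- file.path(out_dir, "inputs")
      p <- synth_write(sc, fix_dir)
      made <- c(made, unlist(p))
      p
    } else {
      p <- config$inputs
      need <- c("nodes", "edges", "fc", "homologs")
      if (is.null(p) || !all(need %in% names(p))) {
        stop("config needs a 'synthetic' block or an 'inputs' block with ",
             paste(need, collapse = ", "))
      }
      for (f in unlist(p[need])) {
        if (!file.exists(f)) stop("input file not found: ", f)
      }
      p
    }
  })
  synthetic <- !is.null(config$synthetic)

  kg <- stage("load_graph", read_kg(input_paths$nodes, input_paths$edges))
  note("graph: %d nodes, %d edges", kg$n_nodes, nrow(kg$edges))
  hm <- stage("load_homologs", read_homolog_map(input_paths$homologs, kg))
  fc_all <- stage("load_fc", read_fc_table(input_paths$fc))
  fc_by_study <- split(fc_all, fc_all$study_id)
  note("fold changes: %d studies, %d comparisons, %d mouse genes",
       length(fc_by_study),
       dplyr::n_distinct(fc_all$comparison_id),
       dplyr::n_distinct(fc_all$gene_id))

  # --- per-study mapping / filtering -------------------------------------
  mapped <- stage("map_homologs",
                  lapply(fc_by_study, map_homologs, homolog_map = hm,
                         kg = kg))
  filtered <- stage("direction_filter",
                    lapply(mapped, filter_direction_consistent))
  for (s in names(filtered)) {
    note("%s: %d genes mapped, %d dropped by direction filter, %d kept",
         s, dplyr::n_distinct(mapped[[s]]$gene_id),
         attr(filtered[[s]], "n_dropped"),
         dplyr::n_distinct(filtered[[s]]$gene_id))
  }

  # --- propagation profiles ----------------------------------------------
  genes_used <- sort(unique(unlist(lapply(filtered,
                                          function(d) d$gene_id))))
  if (length(genes_used) < 2) {
    stage("profiles", stop("fewer than 2 genes survive mapping/filtering"))
  }
  profiles <- stage("profiles", rwr_matrix(
    kg, genes_used, alpha = params$alpha, tol = params$tol,
    max_iter = params$max_iter, orientation = params$orientation))
  note("profiles: %d genes x %d nodes (alpha = %g)",
       nrow(profiles), ncol(profiles), params$alpha)

  # --- embedding + pooling -----------------------------------------------
  embeddings <- stage("embed", lapply(filtered, function(d) {
    norm <- normalize_rank_profiles(profiles, sort(unique(d$gene_id)),
                                    axis = params$zscore_axis)
    embed_study(d, norm)
  }))
  pooled <- stage("pool", pool_embeddings(unname(embeddings)))

  # --- node significance --------------------------------------------------
  top <- stage("node_significance", {
    res <- compare_groups(pooled, kg)
    select_top_nodes(res, node_type_counts(kg),
                     prescreen_p = params$prescreen_p,
                     top_frac = params$top_frac)
  })
  note("nodes: %d prescreened, %d top", sum(top$prescreen), sum(top$top))

  # --- path retracing -----------------------------------------------------
  fc_used <- dplyr::bind_rows(filtered)
  # retrace against top nodes of the phenotype-side types only
  retrace_types <- c("Anatomy", "BiologicalProcess", "CellularComponent",
                     "MolecularFunction", "Pathway", "Symptom")
  top_ids <- top$node_id[top$top & top$node_type %in% retrace_types]
  retrace <- stage("path_retrace", {
    if (length(top_ids) == 0) {
      list(correlations = tibble::tibble(),
           pairs = tibble::tibble(), paths = empty_paths_tbl())
    } else {
      corr <- gene_node_correlation(fc_used, pooled, top_ids,
                                    min_presence = params$min_presence,
                                    method = params$correlation)
      pairs <- filter_gene_node_pairs(corr, top,
                                      r_threshold = params$r_threshold,
                                      sign_filter = params$sign_filter)
      tp <- trace_paths(kg, pairs, max_edges = params$max_edges,
                        max_paths = params$max_paths)
      list(correlations = corr, pairs = tp$pairs, paths = tp$paths)
    }
  })
  note("pairs: %d kept of %d; paths: %d",
       sum(retrace$pairs$kept %||% FALSE),
       nrow(retrace$pairs), nrow(retrace$paths))
  scores <- stage("gene_scores",
                  suppressWarnings(score_gene_fc(dplyr::bind_rows(mapped))))

  # --- outputs ------------------------------------------------------------
  stage("write_outputs", {
    jsonlite::write_json(kg_summary(kg), out("graph_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_tsv(tidy(top), out("top_nodes.tsv"))
    readr::write_tsv(retrace$pairs, out("pairs.tsv"))
    readr::write_tsv(retrace$paths, out("paths.tsv"))
    readr::write_tsv(scores, out("gene_scores.tsv"))
    adj <- adjust_ranks_by_baseline_mean(pooled)
    adj_long <- tidy(adj)
    if (length(top_ids) > 0) {
      adj_long <- dplyr::filter(adj_long, .data$node_id %in% top_ids)
    }
    readr::write_tsv(adj_long, out("adjusted_ranks.tsv"))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("walkrank")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    synthetic = synthetic,
    planted = if (synthetic)
      jsonlite::read_json(input_paths$planted, simplifyVector = TRUE),
    params = params,
    input_md5 = as.list(tools::md5sum(unlist(input_paths[
      c("nodes", "edges", "fc", "homologs")]))),
    counts = list(
      n_nodes = kg$n_nodes, n_edges = nrow(kg$edges),
      n_studies = length(fc_by_study),
      n_comparisons = nrow(pooled$meta),
      genes_used = length(genes_used),
      nodes_prescreened = sum(top$prescreen),
      nodes_top = sum(top$top),
      top_by_type = as.list(table(top$node_type[top$top])),
      pairs_kept = sum(retrace$pairs$kept %||% FALSE),
      paths_found = nrow(retrace$paths),
      genes_scored = nrow(scores))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(kg = kg, profiles = profiles, embeddings = embeddings,
                 pooled = pooled, top_nodes = top,
                 correlations = retrace$correlations,
                 pairs = retrace$pairs, paths = retrace$paths,
                 gene_scores = scores, manifest = manifest,
                 out_dir = out_dir))
}

#' Summarise a completed pipeline run
#'
#' Reads the manifest and top-node table of a run directory and prints a
#' compact summary: top nodes per type with their Welch statistics and,
#' for synthetic runs, whether the planted target was recovered.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param json_path Optional path to also write the summary as JSON.
#' @return Invisibly, the summary list.
#' @export
pipeline_report <- function(out_dir, json_path = NULL) {
  man_path <- file.path(out_dir, "manifest.json")
  top_path <- file.path(out_dir, "top_nodes.tsv")
  if (!file.exists(man_path) || !file.exists(top_path)) {
    stop("incomplete run directory: ", out_dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  top <- readr::read_tsv(top_path, col_types = readr::cols())
  top_rows <- dplyr::filter(top, .data$top)
  summary <- list(
    out_dir = out_dir,
    counts = manifest$counts,
    top_nodes = top_rows |>
      dplyr::select(dplyr::any_of(c("node_id", "node_type", "t_svb",
                                    "p_svb", "t_svg", "p_svg"))) |>
      dplyr::arrange(.data$node_type, .data$node_id)
  )
  cat(sprintf("pipeline run: %s\n", out_dir))
  cat(sprintf("  %d nodes, %d pooled comparisons, %d genes used\n",
              manifest$counts$n_nodes, manifest$counts$n_comparisons,
              manifest$counts$genes_used))
  cat(sprintf("  %d nodes prescreened, %d top\n",
              manifest$counts$nodes_prescreened,
              manifest$counts$nodes_top))
  if (nrow(top_rows) == 0) {
    cat("  top-node set is empty\n")
  } else {
    for (ty in unique(top_rows$node_type)) {
      ids <- top_rows$node_id[top_rows$node_type == ty]
      cat(sprintf("  top %s: %s\n", ty, paste(ids, collapse = ", ")))
    }
  }
  if (isTRUE(manifest$synthetic)) {
    target <- manifest$planted$target_node
    hit <- target %in% top_rows$node_id
    summary$planted_target <- target
    summary$planted_target_recovered <- hit
    cat(sprintf("  planted target %s recovered: %s\n", target, hit))
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(summary)
}
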