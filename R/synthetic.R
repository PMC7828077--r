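#' Configuration for the synthetic knowledge graph and fold-change studies
#'
#' Bundles every tunable of the generator with the package's default
#' study conditions: a 500-node graph over the 12 node types, and three
#' studies of six comparisons each — three Ground vs. Baseline
#' comparisons (rodent spaceflight studies typically carry several
#' ground-control arms: basal, vivarium and ground-habitat), two Space
#' vs. Baseline flight time points, and one Space vs. Ground — plus a
#' planted module of 8 genes wired within two edges of a target Symptom
#' node whose fold changes shift by `delta` in spaceflight comparisons.
#'
#' @param seed Integer seed; mandatory — every generator output is a pure
#'   function of the configuration including the seed.
#' @param type_counts Named integer vector of node counts per type
#'   (defaults sum to 500; at least 10 Gene nodes required).
#' @param n_studies Number of studies (default 3).
#' @param study_design Character vector of group labels, one comparison
#'   each, replicated per study.
#' @param delta Mean fold-change shift of module genes in spaceflight
#'   comparisons (default 2).
#' @param sigma Fold-change noise standard deviation for all genes
#'   (default 0.5).
#' @param n_module_genes Number of planted module genes (default 8).
#' @param missing_rate Fraction of (comparison, gene) entries marked
#'   missing at random (default 0.05).
#' @param pseudo_n Pseudo sample size behind the generated p-values:
#'   p = 2 * pnorm(-|fc| * sqrt(pseudo_n) / sigma).  The default 1 makes
#'   p-values exactly uniform for null genes.
#' @param multi_homolog_frac Fraction of human genes given a second mouse
#'   homolog (default 0.1), exercising the fold-change averaging rule.
#' @param edge_densities Data frame `type_a`, `type_b`, `edge_type`,
#'   `density` describing the Bernoulli edge probability per type pair;
#'   defaults follow a biomedical-schema shape (Gene-Protein,
#'   Protein-Protein, Disease-Symptom, ...).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed,
                         type_counts = c(
                           Gene = 120, Protein = 100,
                           BiologicalProcess = 60, Pathway = 40,
                           Anatomy = 25, Symptom = 25, Disease = 20,
                           CellularComponent = 20, MolecularFunction = 20,
                           Compound = 30, PharmacologicalClass = 10,
                           SideEffect = 30),
                         n_studies = 3,
                         study_design = c("GroundVsBaseline",
                                          "GroundVsBaseline",
                                          "GroundVsBaseline",
                                          "SpaceVsBaseline",
                                          "SpaceVsBaseline",
                                          "SpaceVsGround"),
                         delta = 2, sigma = 0.5, n_module_genes = 8,
                         missing_rate = 0.05, pseudo_n = 1,
                         multi_homolog_frac = 0.1,
                         edge_densities = synth_edge_densities()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      is.na(seed)) {
    stop("a single integer seed is mandatory", call. = FALSE)
  }
  bad <- setdiff(names(type_counts), kg_node_types())
  if (length(bad) > 0) {
    stop("unknown node type(s) in type_counts: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(type_counts < 0)) stop("type counts must be >= 0", call. = FALSE)
  if (is.na(type_counts["Gene"]) || type_counts[["Gene"]] < 10) {
    stop("at least 10 Gene nodes required", call. = FALSE)
  }
  stopifnot(all(study_design %in% fc_group_labels()),
            sigma > 0, missing_rate >= 0, missing_rate < 1,
            pseudo_n > 0, multi_homolog_frac >= 0, multi_homolog_frac <= 1,
            n_module_genes >= 1)
  structure(list(
    seed = as.integer(seed), type_counts = type_counts,
    n_studies = as.integer(n_studies), study_design = study_design,
    delta = delta, sigma = sigma,
    n_module_genes = as.integer(n_module_genes),
    missing_rate = missing_rate, pseudo_n = pseudo_n,
    multi_homolog_frac = multi_homolog_frac,
    edge_densities = tibble::as_tibble(edge_densities)
  ), class = "synth_config")
}

#' Default per-type-pair edge densities of the synthetic schema
#'
#' @return Tibble `type_a`, `type_b`, `edge_type`, `density`.
#' @export
synth_edge_densities <- function() {
  tibble::tribble(
    ~type_a, ~type_b, ~edge_type, ~density,
    "Gene", "Protein", "encodes", 0.010,
    "Protein", "Protein", "interacts", 0.010,
    "Protein", "BiologicalProcess", "participates_in", 0.010,
    "BiologicalProcess", "Pathway", "part_of", 0.020,
    "Gene", "Pathway", "member_of", 0.010,
    "Anatomy", "Gene", "expresses", 0.020,
    "Protein", "CellularComponent", "localizes_to", 0.010,
    "Protein", "MolecularFunction", "enables", 0.010,
    "Disease", "Gene", "associates", 0.050,
    "Disease", "Symptom", "presents", 0.150,
    "Disease", "Disease", "resembles", 0.020,
    "Compound", "Disease", "treats", 0.020,
    "Compound", "SideEffect", "causes", 0.020,
    "PharmacologicalClass", "Compound", "includes", 0.030,
    "Compound", "Gene", "affects", 0.005,
    "Gene", "Gene", "covaries", 0.002
  )
}

# Deterministic node ids: gene_0001, protein_0001, ...
synth_node_ids <- function(type_counts) {
  purrr::imap_dfr(as.list(type_counts), function(n, ty) {
    if (n == 0) return(NULL)
    tibble::tibble(
      node_id = sprintf("%s_%04d", tolower(ty), seq_len(n)),
      node_type = ty,
      name = sprintf("%s %d", ty, seq_len(n)))
  })
}

#' Generate a synthetic typed knowledge graph with a planted module
#'
#' Draws Bernoulli edges per type pair at the configured densities,
#' connects stray components to the giant component (edge type
#' `related_to`), and plants the signal structure: a target Symptom node,
#' a hub Disease node presenting it, and `n_module_genes` module genes
#' associated with the hub — so every module gene reaches the target
#' within 2 edges (gene - disease - symptom).  Deterministic given the
#' configuration seed.
#'
#' @param config A `synth_config`.
#' @return A `kg` object with an extra element `planted`: list with
#'   `target_node`, `hub`, `module_genes`.
#' @export
synth_kg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::local_seed(config$seed)
  nodes <- synth_node_ids(config$type_counts)
  by_type <- split(nodes$node_id, nodes$node_type)

  edges <- purrr::pmap_dfr(config$edge_densities,
                           function(type_a, type_b, edge_type, density) {
    a <- by_type[[type_a]]
    b <- by_type[[type_b]]
    if (is.null(a) || is.null(b)) return(NULL)
    pairs <- if (type_a == type_b) {
      if (length(a) < 2) return(NULL)
      t(utils::combn(a, 2))
    } else {
      as.matrix(expand.grid(a, b, stringsAsFactors = FALSE))
    }
    hit <- stats::runif(nrow(pairs)) < density
    if (!any(hit)) return(NULL)
    tibble::tibble(source = pairs[hit, 1], target = pairs[hit, 2],
                   edge_type = edge_type)
  })

  # planted structure: module genes -- hub disease -- target symptom
  target <- sample(by_type$Symptom, 1)
  hub <- sample(by_type$Disease, 1)
  module_genes <- sort(sample(by_type$Gene, config$n_module_genes))
  edges <- dplyr::bind_rows(
    edges,
    tibble::tibble(source = hub, target = module_genes,
                   edge_type = "associates"),
    tibble::tibble(source = hub, target = target, edge_type = "presents"))
  edges <- dplyr::distinct(edges)

  # attach every stray component to the giant one
  ig <- igraph::graph_from_data_frame(
    edges[1:2], directed = FALSE, vertices = nodes$node_id)
  cm <- igraph::components(ig)
  if (cm$no > 1) {
    giant <- which.max(cm$csize)
    anchor_pool <- nodes$node_id[cm$membership == giant]
    extra <- purrr::map_dfr(setdiff(seq_len(cm$no), giant), function(ci) {
      members <- nodes$node_id[cm$membership == ci]
      tibble::tibble(source = sample(members, 1),
                     target = sample(anchor_pool, 1),
                     edge_type = "related_to")
    })
    edges <- dplyr::bind_rows(edges, extra)
  }

  g <- kg_graph(nodes, edges)
  g$planted <- list(target_node = target, hub = hub,
                    module_genes = module_genes)
  g
}

#' Generate a mouse-to-human homolog map for a synthetic graph
#'
#' Every human Gene node receives one synthetic mouse homolog
#' (`mgene_0001`, ...); a configured fraction receive a second one so the
#' many-to-one fold-change averaging rule is exercised.
#'
#' @param config A `synth_config`.
#' @param kg Graph from [synth_kg()] under the same config.
#' @return Tibble `mouse_gene_id`, `human_gene_id`.
#' @export
synth_homolog_map <- function(config, kg) {
  withr::local_seed(config$seed + 1L)
  human <- kg$nodes$node_id[kg$nodes$node_type == "Gene"]
  n_extra <- floor(config$multi_homolog_frac * length(human))
  doubled <- sort(sample(human, n_extra))
  targets <- c(human, doubled)
  tibble::tibble(
    mouse_gene_id = sprintf("mgene_%04d", seq_along(targets)),
    human_gene_id = targets)
}

#' Generate per-study mouse fold-change tables with a planted shift
#'
#' Background fold changes are Normal(0, sigma) everywhere; mouse
#' homologs of the planted module genes are shifted to
#' Normal(delta, sigma) in spaceflight-labelled comparisons (Space vs.
#' Baseline, Space vs. Ground) and remain null in Ground vs. Baseline.
#' P-values come from the two-sided normal tail of fc * sqrt(pseudo_n) /
#' sigma, and a `missing_rate` fraction of entries is marked missing at
#' random.
#'
#' @param config A `synth_config`.
#' @param kg Graph from [synth_kg()] (supplies the planted module).
#' @param homolog_map Map from [synth_homolog_map()].
#' @return Named list of long fold-change tibbles, one per study
#'   (`study_1`, ...), in mouse gene space.
#' @export
synth_fc_studies <- function(config, kg, homolog_map) {
  withr::local_seed(config$seed + 2L)
  module_mouse <- homolog_map$mouse_gene_id[
    homolog_map$human_gene_id %in% kg$planted$module_genes]
  mice <- homolog_map$mouse_gene_id
  studies <- lapply(seq_len(config$n_studies), function(s) {
    purrr::imap_dfr(config$study_design, function(label, ci) {
      shift <- ifelse(label != "GroundVsBaseline" & mice %in% module_mouse,
                      config$delta, 0)
      fc <- stats::rnorm(length(mice), mean = shift, sd = config$sigma)
      pval <- 2 * stats::pnorm(-abs(fc) * sqrt(config$pseudo_n) /
                                 config$sigma)
      pval <- pmax(pval, 1e-300)
      drop <- stats::runif(length(mice)) < config$missing_rate
      fc[drop] <- NA_real_
      pval[drop] <- NA_real_
      tibble::tibble(
        study_id = sprintf("study_%d", s),
        comparison_id = sprintf("study_%d_c%d", s, ci),
        group_label = label, gene_id = mice, fc = fc, pval = pval)
    })
  })
  stats::setNames(studies, sprintf("study_%d", seq_len(config$n_studies)))
}

#' Write a self-contained synthetic fixture directory
#'
#' Materialises one seed's graph, homolog map and fold-change tables as
#' the TSV formats the loaders consume, plus the configuration as YAML
#' and the planted-signal description as JSON.
#'
#' @param config A `synth_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
synth_write <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kg <- synth_kg(config)
  hm <- synth_homolog_map(config, kg)
  fcs <- synth_fc_studies(config, kg, hm)
  paths <- list(
    nodes = file.path(dir, "nodes.tsv"),
    edges = file.path(dir, "edges.tsv"),
    homologs = file.path(dir, "homologs.tsv"),
    fc = file.path(dir, "fold_changes.tsv"),
    config = file.path(dir, "config.yaml"),
    planted = file.path(dir, "planted.json"))
  write_kg(kg, paths$nodes, paths$edges)
  readr::write_tsv(hm, paths$homologs)
  write_fc_table(dplyr::bind_rows(fcs), paths$fc)
  cfg <- config
  cfg$type_counts <- as.list(cfg$type_counts)
  cfg$edge_densities <- NULL  # reproducible from synth_edge_densities()
  yaml::write_yaml(unclass(cfg), paths$config)
  jsonlite::write_json(kg$planted, paths$planted, auto_unbox = TRUE)
  invisible(paths)
}
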