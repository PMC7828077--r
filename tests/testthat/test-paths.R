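test_that("path enumeration matches hand-countable cases", {
  kg <- toy_kg(edge_df(c("a", "b"), c("b", "c"), c("a", "c"), c("c", "d")))
  res <- enumerate_paths(kg, "a", "d", max_edges = 3)
  expect_equal(res$n_paths, 2)
  expect_false(res$overflow)
  expect_equal(res$paths$nodes, c("a|c|d", "a|b|c|d"))  # sorted by length
  expect_equal(res$paths$n_edges, c(2L, 3L))

  direct <- enumerate_paths(toy_kg(edge_df(c("a", "b"))), "a", "b",
                            max_edges = 1)
  expect_equal(direct$paths$nodes, "a|b")

  # complete graph on 8 nodes: 1 + 6 + 6*5 = 37 paths of <= 3 edges
  k8 <- complete_kg(8)
  res8 <- enumerate_paths(k8, "a", "b", max_edges = 3)
  expect_equal(res8$n_paths, 37)
  expect_equal(dfs_paths_oracle(k8, "a", "b", 3), sort(res8$paths$nodes))
})

test_that("path enumeration equals the brute-force oracle on random graphs", {
  for (s in 1:10) {
    kg <- random_connected_kg(10 + 2 * s, p_extra = 0.15, seed = 100 + s)
    ids <- kg$nodes$node_id
    from <- ids[1]
    to <- ids[length(ids)]
    res <- enumerate_paths(kg, from, to, max_edges = 3, max_paths = 1e6)
    expect_equal(sort(res$paths$nodes), dfs_paths_oracle(kg, from, to, 3))
  }
})

test_that("path output is independent of edge-table row order", {
  e <- edge_df(c("a", "b"), c("b", "c"), c("a", "c"), c("c", "d"),
               c("b", "d"))
  kg1 <- toy_kg(e)
  kg2 <- toy_kg(e[rev(seq_len(nrow(e))), ])
  expect_equal(enumerate_paths(kg1, "a", "d", 3)$paths,
               enumerate_paths(kg2, "a", "d", 3)$paths)
})

test_that("overflowing pairs are flagged and excluded from reporting", {
  k8 <- complete_kg(8)
  res <- enumerate_paths(k8, "a", "b", max_edges = 3, max_paths = 30)
  expect_true(res$overflow)
  expect_equal(nrow(res$paths), 0)
  expect_equal(res$n_paths, 37)
  expect_error(enumerate_paths(k8, "a", "a"), "must differ")
  expect_error(enumerate_paths(k8, "a", "zz"), "not in graph")
})

test_that("parallel edge types are reported together on a path step", {
  kg <- toy_kg(edge_df(c("a", "b", "treats"), c("a", "b", "affects"),
                       c("b", "c", "presents")))
  res <- enumerate_paths(kg, "a", "c", max_edges = 2)
  expect_equal(res$paths$edge_types, "affects&treats|presents")
})

test_that("Stouffer combination matches reference values and is monotone", {
  expect_equal(stouffer_combine(0.05), 0.05)  # k = 1 identity
  # reference values from an independent meta-analysis implementation
  expect_equal(stouffer_combine(c(0.05, 0.05)), 0.010004626858059,
               tolerance = 1e-10)
  expect_equal(stouffer_combine(c(0.01, 0.2, 0.5)), 0.0336977205889977,
               tolerance = 1e-10)
  expect_equal(stouffer_combine(c(0.5, 0.5)), 0.5)

  withr::local_seed(2)
  for (i in 1:50) {
    p <- stats::runif(sample(2:6, 1), 0.01, 0.99)
    j <- sample(length(p), 1)
    p_lower <- p
    p_lower[j] <- p[j] * 0.5
    expect_lt(stouffer_combine(p_lower), stouffer_combine(p))
  }
  expect_error(stouffer_combine(numeric(0)), "no p-values")
  expect_error(stouffer_combine(c(0.2, 0)), "strictly")
  expect_error(stouffer_combine(1), "strictly")
})

test_that("gene-node correlation enforces presence and flags degeneracy", {
  ranks <- cbind(lin = c(10, 20, 30, 40), const = rep(7, 4))
  pooled <- fake_pooled(ranks, rep(c("GroundVsBaseline",
                                     "SpaceVsBaseline"), 2))
  fc <- do.call(rbind, lapply(1:4, function(i) rbind(
    fc_row("s", sprintf("c%d", i), pooled$meta$group_label[i], "gA",
           i),
    fc_row("s", sprintf("c%d", i), pooled$meta$group_label[i], "gB",
           if (i == 1) 1 else NA))))
  out <- gene_node_correlation(fc, pooled, c("lin", "const"),
                               min_presence = 0.2)
  expect_equal(out$r[out$gene_id == "gA" & out$node_id == "lin"], 1.0)
  expect_true(is.na(out$r[out$gene_id == "gA" & out$node_id == "const"]))
  # gB present in 1 of 4 comparisons (25% needed strictly > 20%... 1/4 > 0.2)
  expect_true("gB" %in% out$gene_id)
  expect_true(all(is.na(out$r[out$gene_id == "gB"])))  # < 3 observations

  # presence strictly above the threshold is required
  out2 <- gene_node_correlation(fc, pooled, "lin", min_presence = 0.25)
  expect_false("gB" %in% out2$gene_id)
  expect_error(gene_node_correlation(fc, pooled, "zz"), "absent")
})

test_that("pair filter keeps high sign-concordant correlations", {
  corr <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    node_id = "node",
    r = c(0.7, 0.59, 0.8, 0.9),
    n_obs = 5,
    mean_fc = c(0.4, 0.4, 0.4, -0.4))
  tests <- tibble::tibble(node_id = "node", t_svb = 2.1, p_svb = 0.01,
                          t_svg = -1.0, p_svg = 0.5)
  out <- filter_gene_node_pairs(corr, tests)
  expect_equal(out$kept, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unique(out$node_t), 2.1)  # contrast with the smaller p

  # negative-concordant pair kept by default, dropped as positive_only
  tests_neg <- tibble::tibble(node_id = "node", t_svb = -2.1,
                              p_svb = 0.01, t_svg = 1.0, p_svg = 0.5)
  out_neg <- filter_gene_node_pairs(corr, tests_neg)
  expect_equal(out_neg$kept, c(FALSE, FALSE, FALSE, TRUE))
  out_pos <- filter_gene_node_pairs(corr, tests_neg,
                                    sign_filter = "positive_only")
  expect_false(any(out_pos$kept))
})

test_that("trace_paths annotates pairs and orders reported paths", {
  kg <- toy_kg(edge_df(c("g1", "d1"), c("d1", "s1"), c("g1", "s1"),
                       c("g2", "d1")),
               types = c(d1 = "Disease", s1 = "Symptom"))
  pairs <- tibble::tibble(
    gene_id = c("g1", "g2"), node_id = "s1",
    r = c(0.9, 0.8), n_obs = 5, mean_fc = c(2, 1), node_t = 3,
    kept = TRUE)
  tr <- trace_paths(kg, pairs)
  expect_equal(tr$pairs$n_paths, c(2L, 2L))
  expect_false(any(tr$pairs$overflow))
  # shortest first; ties by |mean_fc| descending
  expect_equal(tr$paths$nodes[1], "g1|s1")
  expect_true(all(diff(tr$paths$n_edges) >= 0))
  # self pairs are never traced
  self <- tibble::tibble(gene_id = "s1", node_id = "s1", r = 1,
                         n_obs = 5, mean_fc = 1, node_t = 1, kept = TRUE)
  tr2 <- trace_paths(kg, self)
  expect_equal(nrow(tr2$paths), 0)
})

test_that("gene scoring separates planted from null genes", {
  # identical distributions in balanced groups: x small, y exactly 0
  fc_null <- rbind(
    fc_row("s", "c1", "GroundVsBaseline", "g", 1.0, 0.5),
    fc_row("s", "c2", "GroundVsBaseline", "g", 1.1, 0.5),
    fc_row("s", "c3", "SpaceVsBaseline", "g", 0.9, 0.5),
    fc_row("s", "c4", "SpaceVsBaseline", "g", 1.05, 0.5))
  sc <- score_gene_fc(fc_null)
  expect_lt(abs(sc$x), 2)
  expect_equal(sc$y, 0)
  expect_equal(sc$n_ground, 2)
  expect_equal(sc$n_space, 2)

  # only one space group present: x equals that single contrast's t
  fc_one <- rbind(
    fc_row("s", "c1", "GroundVsBaseline", "g", 0.1, 0.8),
    fc_row("s", "c2", "GroundVsBaseline", "g", -0.1, 0.9),
    fc_row("s", "c3", "SpaceVsBaseline", "g", 2.0, 0.01),
    fc_row("s", "c4", "SpaceVsBaseline", "g", 2.2, 0.01))
  sc_one <- score_gene_fc(fc_one)
  expect_equal(sc_one$x, welch_t(c(2.0, 2.2), c(0.1, -0.1))$t)

  # strongly space-shifted gene scores positive on both axes
  withr::local_seed(33)
  mk <- function(gene, shift) do.call(rbind, lapply(1:12, function(i) {
    lab <- c("GroundVsBaseline", "SpaceVsBaseline",
             "SpaceVsGround")[(i - 1) %% 3 + 1]
    mu <- if (lab == "GroundVsBaseline") 0 else shift
    fc <- stats::rnorm(1, mu, 0.5)
    fc_row("s", sprintf("c%d", i), lab, gene, fc,
           pval = max(2 * stats::pnorm(-abs(fc) / 0.5), 1e-12))
  }))
  sc2 <- score_gene_fc(mk("planted", 2))
  expect_gt(sc2$x, 2)
  expect_gt(sc2$y, 0)
  expect_true(sc2$space_more_significant)

  # a gene with no usable ground observation is skipped with a warning
  expect_warning(
    out <- score_gene_fc(rbind(mk("ok", 1),
                               fc_row("s", "c1", "SpaceVsBaseline",
                                      "lonely", 1, 0.1))),
    "skipped")
  expect_false("lonely" %in% out$gene_id)
})
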