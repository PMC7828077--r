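test_that("homolog mapping averages fold changes and keeps the min p", {
  hm <- data.frame(mouse_gene_id = c("m1", "m2", "m3"),
                   human_gene_id = c("HG1", "HG1", "HG2"))
  fc <- rbind(fc_row("s1", "c1", "SpaceVsBaseline", "m1", 1.0, 0.20),
              fc_row("s1", "c1", "SpaceVsBaseline", "m2", 3.0, 0.04),
              fc_row("s1", "c1", "SpaceVsBaseline", "m3", 0.7, 0.50))
  out <- map_homologs(fc, hm)
  expect_equal(out$fc[out$gene_id == "HG1"], 2.0)      # mean of 1 and 3
  expect_equal(out$pval[out$gene_id == "HG1"], 0.04)   # min of contributors
  expect_equal(out$fc[out$gene_id == "HG2"], 0.7)      # mean of one

  # a missing contributor is excluded from the mean
  fc_na <- fc
  fc_na$fc[1] <- NA
  out_na <- map_homologs(fc_na, hm)
  expect_equal(out_na$fc[out_na$gene_id == "HG1"], 3.0)

  expect_error(
    map_homologs(fc_row("s1", "c1", "SpaceVsBaseline", "mX", 1, 0.5), hm),
    "no mouse gene")
  expect_equal(attr(out, "n_unmapped"), 0)
  expect_equal(attr(out, "n_mapped"), 3)
})

test_that("direction filter removes sign-flipping genes within a study", {
  fc <- rbind(
    fc_row("s1", "c1", "SpaceVsBaseline", "flip", +0.5),
    fc_row("s1", "c2", "SpaceVsGround", "flip", -0.2),
    fc_row("s1", "c1", "SpaceVsBaseline", "same", +0.5),
    fc_row("s1", "c2", "SpaceVsGround", "same", +0.1),
    fc_row("s1", "c1", "SpaceVsBaseline", "zero", 0.0),
    fc_row("s1", "c2", "SpaceVsGround", "zero", -0.3))
  out <- filter_direction_consistent(fc)
  expect_setequal(unique(out$gene_id), c("same", "zero"))  # zero is agnostic
  expect_equal(attr(out, "n_dropped"), 1)

  # default scope ignores ground-control comparisons
  fc2 <- rbind(fc_row("s1", "c0", "GroundVsBaseline", "g", -0.4),
               fc_row("s1", "c1", "SpaceVsBaseline", "g", +0.5),
               fc_row("s1", "c2", "SpaceVsGround", "g", +0.2))
  expect_equal(unique(filter_direction_consistent(fc2)$gene_id), "g")
  expect_equal(nrow(filter_direction_consistent(fc2, scope = "all")), 0)

  # single-comparison studies pass unchanged
  one <- fc_row("s1", "c1", "SpaceVsBaseline", "only", -2)
  expect_equal(filter_direction_consistent(one)$gene_id, "only")

  # whole gene removed from every comparison, including ground rows
  expect_false("flip" %in% filter_direction_consistent(fc)$gene_id)
})

test_that("profile normalisation z-scores per node then ranks per gene", {
  m <- rbind(g1 = c(1, 3, 2), g2 = c(3, 1, 2))
  colnames(m) <- c("A", "B", "C")
  nr <- normalize_rank_profiles(m, c("g1", "g2"))
  # column C is constant -> z 0; columns A,B are +-0.707
  expect_equal(unname(nr["g1", ]), c(1, 3, 2))
  expect_equal(unname(nr["g2", ]), c(3, 1, 2))

  # ties get average ranks
  mt <- rbind(g1 = c(2, 2, 1), g2 = c(1, 1, 2))
  colnames(mt) <- c("A", "B", "C")
  nt <- normalize_rank_profiles(mt, c("g1", "g2"))
  expect_equal(unname(nt["g1", ]), c(2.5, 2.5, 1))
  expect_equal(unname(nt["g2", ]), c(1.5, 1.5, 3))

  # every row is a permutation of 1..N up to tie-averaging
  kg <- synth_kg(synth_config(2))
  genes <- kg$nodes$node_id[kg$nodes$node_type == "Gene"][1:10]
  big <- normalize_rank_profiles(rwr_matrix(kg, genes), genes)
  expect_true(all(abs(rowSums(big) -
                        kg$n_nodes * (kg$n_nodes + 1) / 2) < 1e-9))

  expect_error(normalize_rank_profiles(m, "g1"), "at least 2")
  expect_error(normalize_rank_profiles(m, c("g1", "zz")), "absent")
})

test_that("embedding weights profiles by fold change and ranks the sums", {
  norm <- rbind(g1 = c(1, 2, 3), g2 = c(3, 2, 1))
  colnames(norm) <- c("A", "B", "C")
  fc <- rbind(fc_row("s1", "c1", "SpaceVsBaseline", "g1", 1),
              fc_row("s1", "c1", "SpaceVsBaseline", "g2", -1))
  emb <- embed_study(fc, norm)
  # aggregate (-2, 0, 2) -> ranks (1, 2, 3)
  expect_equal(unname(emb$ranks["c1", ]), c(1, 2, 3))
  expect_equal(emb$meta$group_label, "SpaceVsBaseline")

  # all-zero fold changes tie every node at (N+1)/2
  fc0 <- transform(fc, fc = 0)
  expect_equal(unname(embed_study(fc0, norm)$ranks["c1", ]), rep(2, 3))

  # missing fold change contributes zero
  fc_na <- fc
  fc_na$fc[2] <- NA
  expect_equal(unname(embed_study(fc_na, norm)$ranks["c1", ]), c(1, 2, 3))

  expect_error(embed_study(fc[fc$gene_id == "g1", ], norm),
               "gene sets differ")
})

test_that("embedded ranks are invariant to FC scaling and gene order", {
  withr::local_seed(7)
  n_nodes <- 40
  genes <- sprintf("g%02d", 1:6)
  norm <- t(vapply(genes, function(g) rank(stats::rnorm(n_nodes)),
                   numeric(n_nodes)))
  colnames(norm) <- sprintf("node%02d", 1:n_nodes)
  fc <- do.call(rbind, lapply(genes, function(g)
    fc_row("s1", "c1", "SpaceVsGround", g, stats::rnorm(1))))
  base <- embed_study(fc, norm)

  # rank conservation: each row sums to N(N+1)/2 exactly
  expect_equal(unname(rowSums(base$ranks)), n_nodes * (n_nodes + 1) / 2)

  # positive rescaling leaves ranks unchanged
  fc3 <- transform(fc, fc = fc * 3.7)
  expect_equal(embed_study(fc3, norm)$ranks, base$ranks)

  # consistent permutation of gene order leaves ranks unchanged
  perm <- sample(length(genes))
  expect_equal(embed_study(fc[perm, ], norm[perm, ])$ranks, base$ranks)
})

test_that("raising a gene's FC raises the aggregate of nodes it loads on", {
  norm <- rbind(g1 = c(3, 1, 2), g2 = c(1, 3, 2))
  agg <- function(f) f %*% norm
  expect_gt(agg(c(2, 1))[1, 1], agg(c(1, 1))[1, 1])
})

test_that("fold-change table and embedding TSV round trips", {
  fc <- rbind(fc_row("s1", "c1", "SpaceVsBaseline", "g1", 1.5, 0.01),
              fc_row("s1", "c1", "SpaceVsBaseline", "g2", NA, NA))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_fc_table(fc, p)
  expect_equal(as.data.frame(read_fc_table(p)), fc)

  norm <- rbind(g1 = c(1, 2, 3), g2 = c(3, 2, 1))
  colnames(norm) <- c("A", "B", "C")
  emb <- embed_study(fc_rowbind <- rbind(
    fc_row("s1", "c1", "SpaceVsBaseline", "g1", 1),
    fc_row("s1", "c1", "SpaceVsBaseline", "g2", -1)), norm)
  pe <- withr::local_tempfile(fileext = ".tsv")
  write_embedding(emb, pe)
  back <- read_embedding(pe)
  expect_equal(back$ranks, emb$ranks)
  expect_equal(back$meta, emb$meta)
})

test_that("malformed fold-change tables are rejected", {
  expect_error(fc_validate(data.frame(gene_id = "g")), "must have columns")
  bad_lab <- fc_row("s", "c", "SpaceVsMars", "g", 1)
  expect_error(fc_validate(bad_lab), "unknown group_label")
  dup <- rbind(fc_row("s", "c", "SpaceVsGround", "g", 1),
               fc_row("s", "c", "SpaceVsGround", "g", 2))
  expect_error(fc_validate(dup), "duplicated")
  badp <- fc_row("s", "c", "SpaceVsGround", "g", 1, pval = 0)
  expect_error(fc_validate(badp), "p-values")
})
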