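random_scoring_instance <- function(n_feat = 12, n_set = 3, seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(2 * n_feat), nrow = 2,
                   dimnames = list(c("s1", "s2"), sprintf("f%02d", 1:n_feat)))
    members <- sample(colnames(vals), n_set)
  })
  list(m = expr_matrix(vals, "coding"), set = gene_set("S", members))
}

test_that("ssGSEA matches the brute-force running-sum oracle", {
  for (seed in 1:20) {
    inst <- random_scoring_instance(n_feat = sample(6:30, 1), n_set = sample(2:5, 1),
                                    seed = seed)
    es <- ssgsea(inst$m, inst$set)
    for (s in rownames(inst$m$values)) {
      expect_equal(es[[s]],
                   ssgsea_oracle(inst$m$values[s, ], inst$m$feature_ids,
                                 inst$set$members),
                   tolerance = 1e-10)
    }
  }
})

test_that("ssGSEA is invariant to strictly monotone transforms", {
  inst <- random_scoring_instance(n_feat = 20, n_set = 4, seed = 3)
  es <- ssgsea(inst$m, inst$set)
  trans <- expr_matrix(exp(inst$m$values * 2) + 5, "coding")
  expect_equal(ssgsea(trans, inst$set), es, tolerance = 1e-12)
})

test_that("a singleton set scores higher on the top-ranked gene", {
  vals <- matrix(seq(1, 6), nrow = 1,
                 dimnames = list("s1", sprintf("f%d", 1:6)))
  m <- expr_matrix(vals, "coding")
  top <- ssgsea(m, gene_set("top", "f6"))
  bottom <- ssgsea(m, gene_set("bottom", "f1"))
  expect_gt(top[["s1"]], bottom[["s1"]])
})

test_that("scoring samples one-by-one equals scoring the whole matrix", {
  inst <- random_scoring_instance(n_feat = 15, n_set = 4, seed = 6)
  whole <- ssgsea(inst$m, inst$set)
  for (s in inst$m$sample_ids) {
    one <- expr_matrix(inst$m$values[s, , drop = FALSE], "coding")
    expect_equal(ssgsea(one, inst$set)[[s]], whole[[s]], tolerance = 1e-12)
  }
})

test_that("degenerate gene sets are refused and scaling is exact", {
  inst <- random_scoring_instance(n_feat = 8, n_set = 3, seed = 9)
  all_set <- gene_set("all", inst$m$feature_ids)
  expect_error(ssgsea(inst$m, all_set), "covers all")
  none <- gene_set("none", c("zz1", "zz2"))
  expect_error(suppressMessages(ssgsea(inst$m, none)), "no member")

  withr::with_seed(2, {
    vals <- matrix(rnorm(10 * 30), nrow = 10,
                   dimnames = list(sprintf("s%02d", 1:10), sprintf("f%02d", 1:30)))
  })
  m <- expr_matrix(vals, "coding")
  tab <- score_signatures(m, list(A = gene_set("A", c("f01", "f05", "f09")),
                                  B = gene_set("B", c("f02", "f11"))))
  for (sig in c("A", "B")) {
    sc <- tab$es_scaled[tab$signature == sig]
    expect_equal(mean(sc), 0, tolerance = 1e-12)
    expect_equal(sd(sc), 1, tolerance = 1e-12)
  }
})

test_that("ESTIMATE-style scores are the sum of their parts", {
  inst <- random_scoring_instance(n_feat = 20, n_set = 4, seed = 12)
  s1 <- gene_set("stromal", inst$m$feature_ids[1:4])
  s2 <- gene_set("immune", inst$m$feature_ids[5:8])
  est <- estimate_style_scores(inst$m, s1, s2)
  expect_equal(est$combined, est$stromal + est$immune, tolerance = 1e-12)
  same <- estimate_style_scores(inst$m, s1, s1)
  expect_equal(same$stromal, same$immune, tolerance = 1e-12)
})

test_that("the immune score tracks the latent hot phenotype", {
  rs <- vapply(1:10, function(seed) {
    co <- small_cohort(seed = seed)
    imm <- ssgsea(co$expression, co$sets$icr)
    hot <- as.integer(co$truth$latent_phenotype[names(imm)] == "hot")
    cor(imm, hot)
  }, numeric(1))
  expect_true(all(rs > 0.5))
})

test_that("KS-like permutation p-values are exact for an extreme pathway", {
  # pathway = the k top-walkscore genes exclusively -> no permutation beats it
  ws <- data.frame(node = sprintf("g%02d", 1:20), class = "coding",
                   walkscore = withr::with_seed(1, sort(runif(20, 0.01, 1),
                                                        decreasing = TRUE)),
                   stringsAsFactors = FALSE)
  pw <- gene_set("top5", ws$node[1:5])
  res <- ks_pathway_enrichment(ws, pw, B = 999, seed = 4)
  expect_equal(res$p, 1 / 1000)
  # determinism under the seed
  res2 <- ks_pathway_enrichment(ws, pw, B = 999, seed = 4)
  expect_identical(res, res2)
  # p can never drop below 1/(B+1)
  expect_gte(ks_pathway_enrichment(ws, pw, B = 49, seed = 1)$p, 1 / 50)
})

test_that("KS permutation p-values are uniform under the null", {
  ws <- data.frame(node = sprintf("g%02d", 1:40), class = "coding",
                   walkscore = rep(0.025, 40), stringsAsFactors = FALSE)
  ps <- vapply(1:200, function(seed) {
    pw <- gene_set("rand", withr::with_seed(seed * 13, sample(ws$node, 10)))
    ks_pathway_enrichment(ws, pw, B = 499, seed = seed)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("hypergeometric ORA reproduces exact enumeration", {
  uni <- sprintf("u%02d", 1:10)
  pw <- gene_set("pw", uni[1:5])
  res <- ora_hypergeometric(uni[1:5], pw, uni)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  # zero overlap cannot beat chance
  res0 <- ora_hypergeometric(uni[6:10], pw, uni)
  expect_equal(res0$p, 1)
  # the whole universe as list is uninformative
  resU <- ora_hypergeometric(uni, pw, uni)
  expect_equal(resU$p, 1)
  expect_error(ora_hypergeometric(character(0), pw, uni), "empty")
  expect_error(ora_hypergeometric("zz", pw, uni), "subset")
})

test_that("pathway-collection enrichment adds BH q and direction summaries", {
  ws <- data.frame(node = sprintf("g%02d", 1:20), class = "coding",
                   walkscore = seq(1, 0.05, length.out = 20),
                   stringsAsFactors = FALSE)
  pws <- list(top = gene_set("top", ws$node[1:4]),
              mid = gene_set("mid", ws$node[9:12]))
  de <- data.frame(feature_id = ws$node, log2fc = rep(c(2, -2), 10),
                   t_mod = 1, p = 0.01, q = 0.01,
                   direction = rep(c("up", "down"), 10),
                   stringsAsFactors = FALSE)
  res <- enrich_pathways(ws, pws, mode = "ks", B = 199, seed = 8, de = de)
  expect_identical(nrow(res), 2L)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_equal(res$frac_up + res$frac_down, c(1, 1))
  ora <- suppressMessages(enrich_pathways(ws, pws, mode = "ora", cutoff = 0.5))
  expect_identical(nrow(ora), 2L)
  expect_lt(ora$p[1], ora$p[2])
})
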