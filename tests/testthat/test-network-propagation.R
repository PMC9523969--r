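line_network <- function() {
  # A - B - C chain, unit weights; A,C coding, B lncRNA
  A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  A["a", "b"] <- A["b", "a"] <- 1
  A["b", "c"] <- A["c", "b"] <- 1
  cnc_network(A, c(a = "coding", b = "lncRNA", c = "coding"))
}

test_that("co-expression edges follow the |r| >= r_min rule", {
  withr::with_seed(2, {
    base <- rnorm(50)
    x <- cbind(g1 = base, g2 = base * 2 + 1,          # r = 1 with g1
               g3 = rnorm(50))                         # independent
    l <- cbind(l1 = -base + rnorm(50, sd = 0.1),       # strong negative
               l2 = rnorm(50))
  })
  rownames(x) <- rownames(l) <- sprintf("s%02d", 1:50)
  net <- build_cnc_network(ex_matrix(x, "coding"), ex_matrix(l, "lncRNA"),
                           r_min = 0.5)
  expect_equal(net$adjacency["g1", "g2"], 1)            # perfect correlation
  expect_equal(diag(net$adjacency), setNames(rep(0, 5), net$nodes)) # no self-edges
  expect_gt(net$adjacency["g1", "l1"], 0.9)             # |r| of negative corr
  expect_equal(net$adjacency["g3", "l2"], 0)
  # every transition column sums to one
  expect_equal(unname(colSums(net$transition)), rep(1, 5), tolerance = 1e-12)
})

test_that("zero-variance features are excluded and columns stay stochastic", {
  withr::with_seed(4, x <- cbind(g1 = rnorm(30), g2 = rep(1, 30)))
  l <- cbind(l1 = x[, "g1"] + rnorm(30, sd = 0.1))
  rownames(x) <- rownames(l) <- sprintf("s%02d", 1:30)
  expect_message(net <- build_cnc_network(ex_matrix(x, "coding"),
                                          ex_matrix(l, "lncRNA")),
                 "zero-variance")
  expect_false("g2" %in% net$nodes)
  expect_equal(unname(colSums(net$transition)), rep(1, 2), tolerance = 1e-12)
})

test_that("independent features produce almost no edges at r_min = 0.5", {
  withr::with_seed(6, {
    x <- matrix(rnorm(200 * 30), 200, dimnames = list(NULL, sprintf("g%02d", 1:30)))
    l <- matrix(rnorm(200 * 10), 200, dimnames = list(NULL, sprintf("l%02d", 1:10)))
  })
  rownames(x) <- rownames(l) <- sprintf("s%03d", 1:200)
  net <- build_cnc_network(ex_matrix(x, "coding"), ex_matrix(l, "lncRNA"),
                           r_min = 0.5)
  n_nodes <- length(net$nodes)
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  n_edges <- sum(net$adjacency[upper.tri(net$adjacency)] > 0)
  expect_lt(n_edges / n_pairs, 0.01)
})

test_that("restart-only walk returns the seed vector exactly", {
  net <- line_network()
  ws <- rwr(net, "a", restart_r = 1)
  expect_equal(ws$walkscore, c(1, 0, 0))
})

test_that("two-node walk solves to (2/3, 1/3) at r = 0.5", {
  A <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  net <- cnc_network(A, c(a = "lncRNA", b = "coding"))
  ws <- rwr(net, "a", restart_r = 0.5, tol = 1e-14)
  expect_equal(ws$walkscore, c(2 / 3, 1 / 3), tolerance = 1e-10)
})

test_that("walkscores conserve unit mass and match the dense linear solve", {
  withr::with_seed(10, {
    for (rep in 1:10) {
      n <- sample(10:60, 1)
      A <- matrix(0, n, n)
      idx <- which(upper.tri(A))
      on <- sample(idx, max(n, round(length(idx) * 0.1)))
      A[on] <- runif(length(on), 0.2, 1)
      A <- A + t(A)
      ids <- sprintf("n%03d", seq_len(n))
      dimnames(A) <- list(ids, ids)
      cls <- sample(c("coding", "lncRNA"), n, replace = TRUE)
      net <- cnc_network(A, setNames(cls, ids))
      seeds <- sample(ids, sample(1:4, 1))
      r <- runif(1, 0.1, 0.9)
      ws <- rwr(net, seeds, restart_r = r, tol = 1e-14)
      expect_equal(sum(ws$walkscore), 1, tolerance = 1e-9)
      p0 <- as.numeric(ids %in% seeds) / length(seeds)
      expect_equal(ws$walkscore, rwr_oracle(net$transition, p0, r),
                   tolerance = 1e-8)
    }
  })
})

test_that("seed order does not change walkscores; absent seeds are dropped", {
  net <- line_network()
  a <- rwr(net, c("a", "c"), restart_r = 0.4)
  b <- rwr(net, c("c", "a"), restart_r = 0.4)
  expect_equal(a$walkscore, b$walkscore, tolerance = 1e-12)
  expect_message(d <- rwr(net, c("a", "zz"), restart_r = 0.4), "dropping")
  expect_equal(d$walkscore, rwr(net, "a", restart_r = 0.4)$walkscore,
               tolerance = 1e-12)
  expect_error(rwr(net, "zz"), "no seed")
})

test_that("adding a seed-to-gene edge never lowers that gene's walkscore", {
  # enumerate all 5-node graphs on a fixed random base, toggling edge (s, g)
  withr::with_seed(12, {
    for (rep in 1:20) {
      A <- matrix(0, 5, 5)
      idx <- which(upper.tri(A))
      on <- sample(idx, 4)
      A[on] <- 1
      A <- A + t(A)
      ids <- letters[1:5]
      dimnames(A) <- list(ids, ids)
      A["a", "e"] <- A["e", "a"] <- 0     # the toggled edge
      base <- cnc_network(A, setNames(rep("coding", 5), ids))
      ws0 <- rwr(base, "a", restart_r = 0.5, tol = 1e-13)
      A2 <- A; A2["a", "e"] <- A2["e", "a"] <- 1
      with_edge <- cnc_network(A2, setNames(rep("coding", 5), ids))
      ws1 <- rwr(with_edge, "a", restart_r = 0.5, tol = 1e-13)
      expect_gte(ws1$walkscore[ws1$node == "e"] - ws0$walkscore[ws0$node == "e"],
                 -1e-10)
    }
  })
})

test_that("proxy selection applies the walkscore cutoff and ordering", {
  ws <- data.frame(node = c("g1", "g2", "l1"),
                   class = c("coding", "coding", "lncRNA"),
                   walkscore = c(0.02, 0.009, 0.5),
                   stringsAsFactors = FALSE)
  expect_identical(select_proxy_genes(ws), "g1")
  expect_identical(select_proxy_genes(ws, cutoff = 0), c("g1", "g2"))
  ws$walkscore <- c(0.02, 0.02, 0.5)
  expect_identical(select_proxy_genes(ws), c("g1", "g2"))  # tie by id
})

test_that("edge lists round-trip through the TSV writer", {
  net <- line_network()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path, net$node_class)
  expect_equal(back$adjacency, net$adjacency)
  expect_equal(back$transition, net$transition)
})

test_that("planted proxies dominate the walkscore selection across seeds", {
  ps <- vapply(1:10, function(seed) {
    co <- small_cohort(seed = seed)
    net <- suppressMessages(build_cnc_network(
      subset_class(co$expression, "coding"),
      subset_class(co$expression, "lncRNA"), r_min = 0.7))
    ws <- rwr(net, co$truth$planted_ir_lncrnas$id, restart_r = 0.3)
    sel <- select_proxy_genes(ws)
    if (!length(sel)) return(1)
    universe <- ws$node[ws$class == "coding"]
    ora_hypergeometric(sel, gene_set("plants", co$truth$planted_proxies$id),
                       universe)$p
  }, numeric(1))
  expect_true(all(ps < 0.01))
})
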