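test_that("log fold change is the difference of group means", {
  expect_equal(log_fold_change(c(10, 10), c(7, 7)), 3.0)
  expect_equal(log_fold_change(c(8, 9, 10), c(8, 9, 10)), 0.0)
  expect_equal(log_fold_change(c(5.1, 5.3), c(2.0, 2.2)), 3.1)
  # antisymmetric under group swap
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(7)
    expect_equal(log_fold_change(x, y), -log_fold_change(y, x))
  }
  expect_error(log_fold_change(numeric(0), 1:3), "empty group")
  expect_error(log_fold_change(c(1, NA), c(1, 2)), "non-finite")
})

test_that("pooled t-test matches t.test and handles degenerate groups", {
  res <- two_group_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(res$t_stat, 3.674, tolerance = 1e-3)
  expect_equal(res$p_raw, 0.021, tolerance = 3e-2)
  expect_equal(res$p_raw, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(res$df, 4)

  # cross-check against stats::t.test on random draws, both flavors
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(4 + i %% 4); y <- rnorm(3 + i %% 5, mean = 0.5)
    mine <- two_group_t_test(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-12)
    minew <- two_group_t_test(x, y, welch = TRUE)
    refw <- t.test(x, y)
    expect_equal(minew$t_stat, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(minew$p_raw, refw$p.value, tolerance = 1e-12)
    # swapping groups negates t, preserves p
    swap <- two_group_t_test(y, x)
    expect_equal(swap$t_stat, -mine$t_stat)
    expect_equal(swap$p_raw, mine$p_raw)
  }

  ident <- two_group_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t_stat, 0)
  expect_equal(ident$p_raw, 1)

  degen <- two_group_t_test(c(2, 2), c(2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$t_stat, 0)
  expect_equal(degen$p_raw, 1)

  degen2 <- two_group_t_test(c(3, 3), c(1, 1))
  expect_true(degen2$degenerate)
  expect_equal(degen2$p_raw, 0)

  expect_error(two_group_t_test(1, c(1, 2)), ">= 2 values")
})

test_that("t-test null p-values are uniform", {
  set.seed(2024)
  pvals <- replicate(2000, {
    two_group_t_test(rnorm(5), rnorm(5))$p_raw
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.5), 0.5)
  expect_equal(benjamini_hochberg(c(1, 1, 1)), c(1, 1, 1))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "invalid p-value")

  set.seed(7)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))               # never below raw
    expect_true(all(adj >= 0 & adj <= 1))
    # order-preserving on sorted input
    expect_false(is.unsorted(benjamini_hochberg(sort(p))))
  }
})

test_that("DEG classification uses strict thresholds in both directions", {
  df <- data.frame(gene = c("A", "B", "C", "D", "E"),
                   logFC = c(3, -2.5, 2.0, 5, 0.1),
                   p_adj = c(0.01, 0.01, 0.01, 0.05, 0.001))
  out <- classify_degs(df)
  expect_equal(out$status, c("up", "down", "ns", "ns", "ns"))
  # boundary: p_adj exactly alpha is not significant; logFC exactly the
  # cut is not called
  expect_equal(classify_degs(data.frame(logFC = -2, p_adj = 0.01))$status,
               "ns")
  # invariant to gene order
  perm <- sample(nrow(df))
  expect_equal(classify_degs(df[perm, ])$status, out$status[perm])
})

test_that("deg_screen maps case/control swap to up/down swap", {
  sim <- simulate_expression(expression_sim_spec(
    n_genes = 60, n_de = 10, true_lfc = 3, noise_sd = 0.5,
    n_per_group = 6, seed = 91))
  ds <- sim$dataset
  tab <- deg_screen(ds)
  flipped <- ds
  flipped$groups <- ifelse(ds$groups == "case", "control", "case")
  names(flipped$groups) <- names(ds$groups)
  tab2 <- deg_screen(flipped)
  expect_equal(tab2$logFC, -tab$logFC)
  expect_equal(tab2$p_adj, tab$p_adj)
  expect_equal(tab$gene[tab$status == "up"],
               tab2$gene[tab2$status == "down"])
})

test_that("integration unions calls, tracks provenance and conflicts", {
  mk <- function(genes, status, dataset) {
    structure(data.frame(gene = genes, dataset = dataset,
                         logFC = ifelse(status == "up", 3, -3),
                         t = 5, p_raw = 0.001, p_adj = 0.01,
                         status = status, stringsAsFactors = FALSE),
              class = c("deg_table", "data.frame"))
  }
  t1 <- mk(c("A", "B", "X", "Y"), c("up", "up", "up", "up"), "d1")
  t2 <- mk(c("C", "X", "Y"), c("down", "up", "down"), "d2")
  out <- integrate_degs(list(t1, t2))
  expect_setequal(out$gene, c("A", "B", "C", "X", "Y"))
  # duplicate up call collapses to one row listing both datasets
  x <- out[out$gene == "X", ]
  expect_equal(x$direction, "up")
  expect_equal(x$datasets, "d1,d2")
  expect_equal(x$n_datasets, 2L)
  # opposite directions flagged, not dropped
  expect_equal(out$direction[out$gene == "Y"], "conflict")
  # ns genes never enter the union
  t3 <- mk("Z", "up", "d3"); t3$status <- "ns"
  expect_false("Z" %in% integrate_degs(list(t1, t3))$gene)
  expect_error(integrate_degs(list()), "no DEG tables")
})

test_that("expression_dataset validates and drops non-finite genes", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  grp <- setNames(c("tumor", "tumor", "normal", "normal"),
                  paste0("s", 1:4))
  ds <- expression_dataset(m, grp)
  expect_equal(unname(ds$groups), c("case", "case", "control", "control"))
  expect_equal(rownames(ds$values), c("G1", "G2", "G3"))

  m2 <- m; m2[2, 3] <- NA
  ds2 <- expression_dataset(m2, grp)
  expect_equal(nrow(ds2$values), 2L)
  expect_equal(attr(ds2, "dropped_genes"), "G2")

  m3 <- m; rownames(m3) <- c("g1", "G1", "g3")
  expect_error(expression_dataset(m3, grp), "duplicate gene symbols")
  expect_error(expression_dataset(m, grp[1:3]), "without a group")
  expect_error(expression_dataset(m, setNames(rep("tumor", 4),
                                              paste0("s", 1:4))),
               "at least 2 samples")
})
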