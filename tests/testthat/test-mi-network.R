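# Mutual-information estimation, threshold calibration, DPI pruning,
# bootstrap consensus, and probe collapsing.

test_that("MI estimate is symmetric, rank-invariant, and maximal on self-pairs", {
  withr::with_seed(21, {
    x <- rnorm(100)
    ys <- replicate(8, rnorm(100), simplify = FALSE)
  })
  for (y in ys) {
    expect_identical(estimate_mi(x, y), estimate_mi(y, x))
    # invariant under strictly monotone transforms of either argument
    expect_equal(estimate_mi(x, y), estimate_mi(exp(x), y))
    expect_equal(estimate_mi(x, y), estimate_mi(x, y^3 + 2 * y))
    expect_lte(estimate_mi(x, y), estimate_mi(x, x))
  }
  expect_warning(mi0 <- estimate_mi(x, rep(1, 100)), "constant")
  expect_identical(mi0, 0)
  expect_error(estimate_mi(x, rnorm(50)), "length")
  expect_error(estimate_mi(rnorm(5), rnorm(5)), "at least 8")
})

test_that("MI of independent variables is near zero", {
  meds <- vapply(1:10, function(s) withr::with_seed(s, {
    estimate_mi(rnorm(1000), rnorm(1000))
  }), 0)
  expect_lt(median(meds), 0.05)
})

test_that("MI threshold rises with the Bonferroni test count and lies in the null range", {
  t1 <- mi_threshold(100, n_tests = 100, n_perm = 1000, seed = 3)
  t2 <- mi_threshold(100, n_tests = 200, n_perm = 1000, seed = 3)
  expect_gt(t2$threshold_mi, t1$threshold_mi)
  expect_gt(t1$tail_scale, 0)
  # a mild corrected level keeps the threshold inside the permuted sample range
  t3 <- mi_threshold(100, n_tests = 2, alpha = 0.05, n_perm = 2000, seed = 3)
  null_range <- withr::with_seed(99, {
    range(vapply(1:2000, function(i) estimate_mi(runif(100), runif(100)), 0))
  })
  expect_gt(t3$threshold_mi, 0)
  expect_lt(t3$threshold_mi, null_range[2] * 1.5)
})

test_that("DPI removes the weakest edge of a triangle, never ties", {
  tri <- data.frame(regulator = c("A", "B", "A"), target = c("B", "C", "C"),
                    mi = c(0.5, 0.4, 0.2))
  kept <- apply_dpi(tri, 0)
  expect_setequal(paste(kept$regulator, kept$target), c("A B", "B C"))

  tie <- data.frame(regulator = c("A", "B", "A"), target = c("B", "C", "C"),
                    mi = c(0.4, 0.4, 0.4))
  expect_identical(nrow(apply_dpi(tie, 0)), 3L)
})

test_that("DPI agrees with the brute-force triangle oracle on random graphs", {
  for (case in 1:100) {
    g <- withr::with_seed(1000 + case, {
      nodes <- sprintf("n%02d", 1:15)
      pairs <- t(combn(nodes, 2))
      keep <- runif(nrow(pairs)) < 0.35
      data.frame(regulator = pairs[keep, 1], target = pairs[keep, 2],
                 mi = runif(sum(keep), 0.01, 1))
    })
    eps <- c(0, 0.1, 0.2)[case %% 3 + 1]
    ours <- apply_dpi(g, eps)
    theirs <- oracle_dpi(g, eps)
    expect_identical(paste(ours$regulator, ours$target),
                     paste(theirs$regulator, theirs$target))
  }
})

test_that("DPI output is a subset of its input and idempotent", {
  g <- withr::with_seed(5, {
    nodes <- sprintf("n%d", 1:12)
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.5
    data.frame(regulator = pairs[keep, 1], target = pairs[keep, 2],
               mi = runif(sum(keep)))
  })
  once <- apply_dpi(g, 0)
  expect_lte(nrow(once), nrow(g))
  expect_true(all(paste(once$regulator, once$target) %in%
                  paste(g$regulator, g$target)))
  expect_identical(apply_dpi(once, 0), once)
})

test_that("single-network inference drops indirect chain edges and honors thresholds", {
  # planted chain TF1 -> TF2 -> G: the indirect TF1-G edge must fall to DPI
  vals <- withr::with_seed(8, {
    tf1 <- rnorm(150)
    tf2 <- tf1 + rnorm(150, 0, 0.3)
    g <- tf2 + rnorm(150, 0, 0.3)
    rbind(TF1 = tf1, TF2 = tf2, G = g) + 7
  })
  colnames(vals) <- sprintf("s%03d", 1:150)
  expr <- expression_matrix(vals, "chain")
  edges <- infer_single_network(expr, c("TF1", "TF2"), threshold = 0.05)
  keys <- undirected_keys(edges$regulator, edges$target)
  expect_true("TF1 TF2" %in% keys)
  expect_true("G TF2" %in% keys)
  expect_false("G TF1" %in% keys)

  expect_identical(nrow(infer_single_network(expr, c("TF1", "TF2"), Inf)), 0L)
  expect_error(infer_single_network(expr, character(0)), "empty TF list")
  expect_warning(infer_single_network(expr, c("TF1", "TF2", "TF99"), 0.05),
                 "TF99")
})

consensus_small <- function() cached("consensus-small", function() {
  cfg <- cohort_config(n_samples = 120, n_tfs = 4, n_targets = 20,
                       n_background = 30, n_signature = 8,
                       regulon_size_range = c(4, 8), noise_sd = 0.1, seed = 31)
  st <- simulate_study(cfg, "one")
  net <- bootstrap_consensus(st$cohorts$one$expr, st$truth$tf_ids, B = 10,
                             alpha = 0.05, seed = 5, n_perm = 400)
  list(study = st, net = net)
})

test_that("bootstrap consensus keeps strong planted edges and is reproducible", {
  study <- consensus_small()
  truth <- study$study$truth
  net <- study$net
  planted <- undirected_keys(truth$edges$tf, truth$edges$target)
  inferred <- undirected_keys(net$edges$regulator, net$edges$target)
  # strong signal, low noise: most planted edges voted in; the conservative
  # resampling-aware threshold and triangle pruning among densely shared
  # targets cost some true edges at this small B and cohort size
  expect_gte(mean(planted %in% inferred), 0.5)
  expect_true(all(net$edges$support >= 1 & net$edges$support <= 10))
  strong <- net$edges$support[paste(net$edges$regulator, net$edges$target) %in%
                              paste(truth$edges$tf, truth$edges$target)]
  expect_gte(mean(strong == 10), 0.8)

  net2 <- bootstrap_consensus(study$study$cohorts$one$expr, truth$tf_ids,
                              B = 10, alpha = 0.05, seed = 5, n_perm = 400)
  expect_identical(net$edges, net2$edges)
})

test_that("consensus edge set shrinks weakly as alpha decreases", {
  study <- consensus_small()
  expr <- study$study$cohorts$one$expr
  tfs <- study$study$truth$tf_ids
  loose <- bootstrap_consensus(expr, tfs, B = 6, alpha = 0.05, seed = 2,
                               n_perm = 300)
  strict <- bootstrap_consensus(expr, tfs, B = 6, alpha = 0.002, seed = 2,
                                n_perm = 300)
  expect_lte(nrow(strict$edges), nrow(loose$edges))
  expect_true(all(paste(strict$edges$regulator, strict$edges$target) %in%
                  paste(loose$edges$regulator, loose$edges$target)))
})

test_that("probe collapsing merges duplicates by max MI and drops self-pairs", {
  edges <- data.frame(
    regulator = c("p1a", "p1b", "p1a", "p2a"),
    target = c("p2a", "p2a", "p1b", "p3a"),
    mi = c(0.3, 0.5, 0.9, 0.4),
    support = c(3L, 7L, 9L, 5L))
  net <- consensus_network(edges, B = 10, level = "probe")
  map <- data.frame(probe = c("p1a", "p1b", "p2a", "p3a"),
                    gene = c("G1", "G1", "G2", "G3"))
  out <- collapse_probes(net, map)
  expect_identical(out$level, "gene")
  expect_identical(nrow(out$edges), 2L)
  g12 <- out$edges[out$edges$regulator == "G1", ]
  expect_equal(g12$mi, 0.5)      # max of 0.3 and 0.5
  expect_identical(g12$support, 7L)
  expect_false(any(out$edges$regulator == out$edges$target))

  bad_map <- map[map$probe != "p3a", ]
  expect_error(collapse_probes(net, bad_map), "p3a")
})

test_that("probe collapsing matches a group-by oracle on random multiplicities", {
  for (case in 1:20) {
    sim <- withr::with_seed(400 + case, {
      genes <- sprintf("G%d", 1:6)
      map <- data.frame(
        probe = sprintf("pr%02d", 1:14),
        gene = sample(genes, 14, replace = TRUE))
      pairs <- t(combn(map$probe, 2))
      keep <- runif(nrow(pairs)) < 0.3
      edges <- data.frame(regulator = pairs[keep, 1], target = pairs[keep, 2],
                          mi = runif(sum(keep)),
                          support = sample(1:10, sum(keep), TRUE))
      list(map = map, edges = edges)
    })
    if (!nrow(sim$edges)) next
    net <- consensus_network(sim$edges, B = 10, level = "probe")
    out <- collapse_probes(net, sim$map)
    g <- setNames(sim$map$gene, sim$map$probe)
    rg <- g[sim$edges$regulator]; tg <- g[sim$edges$target]
    ok <- rg != tg
    expected_n <- length(unique(paste(rg[ok], tg[ok])))
    expect_identical(nrow(out$edges), expected_n)
    agg <- tapply(sim$edges$mi[ok], paste(rg[ok], tg[ok]), max)
    expect_equal(sort(as.vector(agg)), sort(out$edges$mi))
  }
})
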