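test_that("low-count filter keeps genes supported by enough samples", {
  k <- rbind(
    sparse  = c(rep(10L, 2), rep(0L, 16)),   # 10 counts in 2/18 samples
    allzero = rep(0L, 18),
    nine    = rep(9L, 18),                   # 9 counts everywhere
    strong  = rep(50L, 18))
  out <- filterLowCounts(k, min_count = 10, min_sample_frac = 0.10)
  expect_identical(rownames(out), c("sparse", "strong"))
  expect_warning(filterLowCounts(matrix(0L, 3, 18)), "no gene")
})

test_that("the log transform is a normalization identity", {
  k <- matrix(c(0L, 7L, 15L), 3, 1)
  expect_equal(unname(transformCounts(k, 1)[, 1]),
               c(0, 3, 4))
  k2 <- matrix(c(14L), 1, 1)
  expect_equal(transformCounts(k2, 2), transformCounts(matrix(7L), 1))
})

test_that("unsigned similarity and soft threshold behave as defined", {
  x <- seq(1, 18)
  expr <- rbind(g1 = x + rnorm(18, 0, 1e-3),
                g2 = -x + rnorm(18, 0, 1e-3),
                g3 = rnorm(18))
  net <- buildNetwork(expr, beta = 9)
  ## perfect anticorrelation keeps full similarity in an unsigned network
  expect_gt(net@similarity["g1", "g2"], 0.999)
  expect_gt(net@adjacency["g1", "g2"], 0.99)
  expect_equal(net@adjacency, net@similarity^9,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(0.5^9, 0.001953125)
  expect_error(buildNetwork(rbind(a = rep(3, 18), b = rnorm(18))),
               "zero-variance")
  expect_error(buildNetwork(expr[, 1:3]), "4 samples")
})

test_that("topological overlap matches the hand-computed example", {
  a <- matrix(c(1, 0.8, 0.2,
                0.8, 1, 0.2,
                0.2, 0.2, 1), 3, 3, byrow = TRUE)
  tom <- tomFromAdjacency(a)
  expect_equal(tom[1, 2], 0.7)
  expect_equal(diag(tom), rep(1, 3))
  expect_equal(tom, t(tom))
})

test_that("topological overlap stays within [0,1] on random adjacencies", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    s <- matrix(runif(n * n), n, n)
    s <- (s + t(s)) / 2
    diag(s) <- 1
    tom <- tomFromAdjacency(s)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-12)
  }
})

.planted_expr <- function(seed, n_blocks = 3, block = 120, noise = 300) {
  cfg <- simulationConfig(n_genes = n_blocks * block + noise,
                          de_fraction_per_stage = 0,
                          n_modules = n_blocks, module_size = block,
                          module_cor = 0.7, seed = seed)
  sim <- simulateCounts(cfg)
  k <- SummarizedExperiment::assay(sim$se)
  sf <- sizeFactorsMedianRatios(k)
  expr <- transformCounts(k, sf)
  expr <- expr[apply(expr, 1, var) > 0, , drop = FALSE]
  list(expr = expr, truth = sim$truth,
       condition = SummarizedExperiment::colData(sim$se)$condition)
}

test_that("planted co-expression blocks are recovered as modules", {
  skip_if_not_installed("mclust")
  d <- .planted_expr(101)
  net <- buildNetwork(d$expr, beta = 9)
  mods <- detectModules(net, d$expr, min_cluster_size = 100,
                        deep_split = 2)
  expect_length(mods@sizes, 3)
  truth <- d$truth$module_labels[names(moduleLabels(mods))]
  ari <- mclust::adjustedRandIndex(moduleLabels(mods), truth)
  expect_gte(ari, 0.9)
  ## permuting gene order permutes labels identically
  perm <- sample(nrow(d$expr))
  net_p <- buildNetwork(d$expr[perm, ], beta = 9)
  mods_p <- detectModules(net_p, d$expr[perm, ],
                          min_cluster_size = 100, deep_split = 2)
  expect_identical(moduleLabels(mods_p)[names(moduleLabels(mods))],
                   moduleLabels(mods))
})

test_that("uncorrelated genes yield no module and small blocks are gated", {
  set.seed(33)
  expr <- matrix(rnorm(300 * 18), 300, 18,
                 dimnames = list(sprintf("g%03d", 1:300), NULL))
  net <- buildNetwork(expr, beta = 9)
  mods <- detectModules(net, expr, min_cluster_size = 100,
                        deep_split = 2)
  expect_length(mods@sizes, 0)
  expect_true(all(moduleLabels(mods) == 0))

  d <- .planted_expr(55, n_blocks = 1, block = 50, noise = 150)
  net2 <- buildNetwork(d$expr, beta = 9)
  mods2 <- detectModules(net2, d$expr, min_cluster_size = 100,
                         deep_split = 2)
  expect_length(mods2@sizes, 0)
})

test_that("eigengenes are unit norm and positively oriented", {
  d <- .planted_expr(77, n_blocks = 2, block = 60, noise = 100)
  net <- buildNetwork(d$expr, beta = 9)
  mods <- detectModules(net, d$expr, min_cluster_size = 50,
                        deep_split = 2)
  E <- moduleEigengenes(mods)
  expect_gt(ncol(E), 0)
  for (m in seq_len(ncol(E))) {
    expect_equal(sum(E[, m]^2), 1)
    g <- names(moduleLabels(mods))[moduleLabels(mods) == m]
    cors <- cor(E[, m], t(d$expr[g, ]))
    expect_gte(mean(cors), 0)
  }
})

test_that("modules driven by one factor merge; orthogonal ones do not", {
  set.seed(9)
  f1 <- rnorm(18); f2 <- rnorm(18)
  mk <- function(f, n) t(replicate(n, 2 * f + rnorm(18, 0, 0.7)))
  expr <- rbind(mk(f1, 60), mk(f1, 60), mk(f2, 60))
  rownames(expr) <- sprintf("g%03d", 1:180)
  net <- buildNetwork(expr, beta = 9)
  mods <- detectModules(net, expr, min_cluster_size = 40,
                        deep_split = 4, kme_min = 0)
  merged <- mergeSimilarModules(mods, expr, merge_cor = 0.85)
  lb <- moduleLabels(merged)
  ## the two f1 blocks collapse to one label, f2 stays separate
  expect_length(unique(lb[1:120]), 1)
  expect_false(lb[150] == lb[1])
  ## an unattainable threshold changes nothing
  same <- mergeSimilarModules(mods, expr, merge_cor = 1.0)
  expect_equal(sort(unname(table(moduleLabels(same)))),
               sort(unname(table(moduleLabels(mods)))))
})

test_that("stage specificity calls the planted peak and only it", {
  d <- .planted_expr(101)
  net <- buildNetwork(d$expr, beta = 9)
  mods <- detectModules(net, d$expr, min_cluster_size = 100,
                        deep_split = 2)
  mods <- stageSpecificity(mods, d$condition)
  truth <- d$truth$module_labels[names(moduleLabels(mods))]
  for (m in seq_along(mods@sizes)) {
    blk <- as.integer(names(which.max(table(
      truth[moduleLabels(mods) == m]))))
    expect_identical(unname(specificStages(mods)[m]),
                     unname(d$truth$module_peak_stage[blk]))
  }
  expect_error(stageSpecificity(mods, factor(c("a", rep("b", 17)))),
               "at least 2")
})

test_that("flat and two-peak eigengenes are not called stage-specific", {
  cond <- factor(rep(c("control", "dpl1", "dpl3", "dpl14"),
                     c(5, 4, 4, 5)))
  labels <- setNames(rep(1L, 30), sprintf("g%02d", 1:30))
  flat <- matrix(rep(seq(-1, 1, length.out = 18), 30), 30, 18,
                 byrow = TRUE)
  flat <- flat + matrix(rnorm(30 * 18, 0, 1e-3), 30)
  rownames(flat) <- names(labels)
  asn <- regenCompare:::.newAssignment(labels, flat)
  ## overwrite the eigengene with hand-built profiles
  two_peak <- ifelse(cond %in% c("dpl1", "dpl3"), 1, -1)
  asn@eigengenes[, 1] <- two_peak / sqrt(sum(two_peak^2))
  out <- stageSpecificity(asn, cond)
  expect_true(is.na(specificStages(out)[1]))

  flat_e <- rnorm(18, 0, 1e-6) + 0.1
  asn@eigengenes[, 1] <- flat_e / sqrt(sum(flat_e^2))
  out2 <- stageSpecificity(asn, cond)
  expect_true(is.na(specificStages(out2)[1]))
})
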