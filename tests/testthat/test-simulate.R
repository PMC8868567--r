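test_that("simulation is a pure function of configuration and seed", {
  cfg <- simulationConfig(n_genes = 300, seed = 7,
                          n_modules = 1, module_size = 40)
  a <- simulateCounts(cfg)
  b <- simulateCounts(cfg)
  expect_identical(SummarizedExperiment::assay(a$se),
                   SummarizedExperiment::assay(b$se))
  expect_identical(a$truth, b$truth)

  o1 <- simulateOrthology(50, seed = 3)
  o2 <- simulateOrthology(50, seed = 3)
  expect_identical(o1, o2)

  g <- sprintf("g%03d", 1:60)
  t1 <- simulateAnnotation(g, n_terms = 10, seed = 5)
  t2 <- simulateAnnotation(g, n_terms = 10, seed = 5)
  expect_identical(t1, t2)
})

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(groups = c(a = 1L, b = 4L)),
               "at least 2")
  expect_error(simulationConfig(groups = c(a = 2.5, b = 4)),
               "integer")
  expect_error(simulationConfig(n_modules = 2, module_size = 600,
                                n_genes = 1000), "exceeds")
  expect_error(simulationConfig(module_cor = 1.2), "module_cor")
  expect_error(simulationConfig(dispersion = 0), "dispersion")
  expect_error(simulationConfig(de_fraction_per_stage = 1.5),
               "de_fraction")
})

test_that("null design plants no effect and yields ~5% nominal positives", {
  cfg <- simulationConfig(n_genes = 2000,
                          groups = c(control = 5L, trt = 5L),
                          de_fraction_per_stage = 0, n_modules = 0,
                          dispersion = 0.1, seed = 11)
  sim <- simulateCounts(cfg)
  expect_true(all(sim$truth$de_log2fc == 0))
  de <- runDE(sim$se, "trt", "control")
  frac <- mean(de$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("a planted log2FC of +2 yields a ~4x empirical mean ratio", {
  ## Monte-Carlo over 100 seeds; single-seed ratios are highly variable
  ## but the average concentrates near 2^2 = 4
  ratios <- vapply(1:100, function(s) {
    cfg <- simulationConfig(
      n_genes = 5, groups = c(control = 5L, dpl1 = 5L),
      baseline_log_mean = log(100), baseline_log_sd = 0,
      dispersion = 0.1, n_modules = 0, size_factor_range = c(1, 1),
      planted_de = list(dpl1 = c(g1 = "Up")),
      de_log2fc_magnitude = 2, gene_prefix = "g", gene_ids = paste0("g", 1:5),
      seed = s)
    sim <- simulateCounts(cfg)
    k <- SummarizedExperiment::assay(sim$se)
    cond <- SummarizedExperiment::colData(sim$se)$condition
    mean(k["g1", cond == "dpl1"]) / mean(k["g1", cond == "control"])
  }, numeric(1))
  expect_gt(mean(ratios), 3.2)
  expect_lt(mean(ratios), 5.0)
})

test_that("counts obey the NB mean/variance law var = mu + alpha mu^2", {
  cfg <- simulationConfig(n_genes = 400,
                          groups = c(a = 100L, b = 100L),
                          baseline_log_mean = log(200),
                          baseline_log_sd = 0, dispersion = 0.15,
                          de_fraction_per_stage = 0, n_modules = 0,
                          size_factor_range = c(1, 1), seed = 21)
  k <- SummarizedExperiment::assay(simulateCounts(cfg)$se)
  m <- rowMeans(k)
  v <- apply(k, 1, var)
  expected <- mean(m) + 0.15 * mean(m)^2
  expect_lt(abs(mean(v) - expected) / expected, 0.15)
})

test_that("planted modules reach the target correlation on the true scale", {
  ## measured on expression normalized by the generator's own size
  ## factors; estimated factors can absorb part of the shared signal
  cors <- unlist(lapply(1:5, function(s) {
    cfg <- simulationConfig(n_genes = 660, de_fraction_per_stage = 0,
                            n_modules = 3, module_size = 120,
                            module_cor = 0.7, seed = s)
    sim <- simulateCounts(cfg)
    expr <- transformCounts(SummarizedExperiment::assay(sim$se),
                            sim$truth$size_factors)
    vapply(1:3, function(m) {
      g <- names(which(sim$truth$module_labels == m))
      C <- abs(cor(t(expr[g, ])))
      mean(C[upper.tri(C)])
    }, numeric(1))
  }))
  expect_lt(abs(mean(cors) - 0.7), 0.1)
})

test_that("orthology generator covers its ambiguity classes", {
  o <- simulateOrthology(200, seed = 9)
  expect_true(all(table(paste(o$table$src_id, o$table$tgt_id)) == 1))
  expect_true(any(is.na(o$truth)))            # unresolvable class
  expect_true(any(table(o$table$src_id) > 1)) # one-to-many class
  shared_tgt <- names(which(table(
    o$table$tgt_id[o$table$high_confidence]) >= 2))
  expect_gt(length(shared_tgt), 0)            # many-to-one class
  expect_true(all(o$table$goc >= 0 & o$table$goc <= 100, na.rm = TRUE))

  empty <- simulateOrthology(0, seed = 1)
  expect_identical(nrow(empty$table), 0L)
  expect_length(empty$truth, 0)
})

test_that("orthology fraction validation rejects bad mixes", {
  expect_error(simulateOrthology(10, ambiguity_mix = c(unique_hc = -0.1)),
               "non-negative")
  expect_error(simulateOrthology(10, ambiguity_mix = c(unique_hc = 0.9,
                                                       name_match = 0.5)),
               "sum")
})

test_that("annotation generator validates inputs", {
  g <- sprintf("g%02d", 1:50)
  expect_error(simulateAnnotation(g, planted = list(TERM0001 = "zz")),
               "outside the universe")
  expect_error(simulateAnnotation(g, n_terms = 2,
                                  planted = setNames(list(g[1:5]),
                                                     "TERM0001")),
               "duplicate")
  ann <- simulateAnnotation(g, n_terms = 5,
                            planted = list(MY_TERM = g[1:10]), seed = 2)
  expect_identical(ann$MY_TERM, g[1:10])
  expect_true(all(unlist(ann) %in% g))
})
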