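.dirset <- function(ids, dirs, lfc = NULL, fdr = 0.01) {
  data.frame(gene_id = ids, direction = dirs,
             log2fc = if (is.null(lfc))
               ifelse(dirs == "Up", 2, -2) else lfc,
             fdr = fdr)
}

.map_from <- function(src, tgt, multi = character(0)) {
  new("OrthologyMap",
      entries = data.frame(src_id = src, tgt_id = tgt,
                           winning_rule = "sole_candidate"),
      multiSourceTargets = multi)
}

test_that("mapping to target space resolves direction collisions", {
  map <- .map_from(c("z1", "z2", "z3"), c("H1", "H1", "H3"),
                   multi = "H1")
  deg <- .dirset(c("z1", "z2", "z3"),
                 c("Up", "Down", "Up"),
                 lfc = c(2.0, -0.9, 1.5))
  out <- mapToTargetSpace(deg, map)
  expect_setequal(out$gene_id, c("H1", "H3"))
  h1 <- out[out$gene_id == "H1", ]
  expect_identical(h1$direction, "Up")      # larger |log2fc| wins
  expect_true(h1$collision)
  expect_false(out$collision[out$gene_id == "H3"])

  ## unmapped genes are dropped and counted
  deg2 <- .dirset(c("z1", "zz_unknown"), c("Up", "Up"))
  out2 <- mapToTargetSpace(deg2, map)
  expect_identical(out2$gene_id, "H1")
  expect_identical(attr(out2, "n_unmapped"), 1L)

  ## empty table maps to an empty set
  out3 <- mapToTargetSpace(deg[0, ], map)
  expect_identical(nrow(out3), 0L)
})

test_that("directional intersection counts and conserves", {
  a <- .dirset(c("g1", "g2"), c("Up", "Down"))
  b <- .dirset(c("g1", "g3"), c("Up", "Up"))
  cmp <- intersectDirectional(a, b)
  expect_identical(cmp$shared, 1L)
  expect_identical(cmp$same_direction, 1L)
  expect_identical(cmp$opposite, 0L)
  expect_identical(sum(cmp$unique_a), 1L)
  expect_identical(sum(cmp$unique_b), 1L)

  ## disjoint and identical sets
  d <- intersectDirectional(.dirset("g1", "Up"), .dirset("g2", "Up"))
  expect_identical(d$shared, 0L)
  expect_identical(d$similarity, 0)
  e <- intersectDirectional(a, a)
  expect_identical(e$shared, 2L)
  expect_identical(e$same_direction, 2L)
  expect_identical(e$similarity, 1)
})

test_that("set-algebra conservation holds on random directional sets", {
  set.seed(31)
  uni <- sprintf("g%03d", 1:120)
  for (i in 1:50) {
    a <- random_dirset(uni, sample(10:60, 1))
    b <- random_dirset(uni, sample(10:60, 1))
    cmp <- intersectDirectional(a, b)
    expect_identical(cmp$same_direction + cmp$opposite, cmp$shared)
    expect_identical(sum(cmp$unique_a) + cmp$shared, nrow(a))
    expect_identical(sum(cmp$unique_b) + cmp$shared, nrow(b))
    expect_gte(cmp$similarity, -1)
    expect_lte(cmp$similarity, 1)
    ## symmetry
    rev <- intersectDirectional(b, a)
    expect_identical(rev$similarity, cmp$similarity)
  }
})

test_that("UpSet regions stratify by direction and match the oracle", {
  ## direction stratification: shared id, opposite direction
  s <- list(A = .dirset("g1", "Up"), B = .dirset("g1", "Down"))
  r <- upsetExclusiveRegions(s)
  expect_identical(r$count[r$region == "A" & r$direction == "Up"], 1L)
  expect_identical(r$count[r$region == "B" & r$direction == "Down"], 1L)
  expect_false(any(r$degree > 1))

  ## one gene in all three sets
  s3 <- list(A = .dirset("g1", "Up"), B = .dirset("g1", "Up"),
             C = .dirset("g1", "Up"))
  r3 <- upsetExclusiveRegions(s3)
  expect_identical(r3$region, "A+B+C")
  expect_identical(r3$count, 1L)

  ## random sets: regions partition the per-direction union
  set.seed(41)
  uni <- sprintf("g%03d", 1:80)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    sets <- setNames(lapply(seq_len(k), function(j)
      random_dirset(uni, sample(5:40, 1))), LETTERS[seq_len(k)])
    got <- upsetExclusiveRegions(sets)
    want <- upset_brute(sets)
    for (dir in c("Up", "Down")) {
      g <- got[got$direction == dir, ]
      w <- want[want$direction == dir, ]
      expect_identical(sum(g$count), sum(w$count))
      expect_identical(
        setNames(g$count, g$region)[order(g$region)],
        setNames(w$count, w$region)[order(w$region)])
      union_n <- length(unique(unlist(lapply(sets, function(s)
        s$gene_id[s$direction == dir]))))
      expect_identical(sum(g$count), union_n)
    }
  }
})

test_that("the union matrix includes and masks the right cells", {
  stage <- list(
    dpl1 = data.frame(gene_id = c("H1", "H2", "H3"),
                      log2fc = c(2, 1.8, 0.2),
                      fdr = c(0.01, 0.01, 0.8),
                      direction = c("Up", "Up", "NS")),
    dpl3 = data.frame(gene_id = c("H1", "H2", "H3"),
                      log2fc = c(0.3, -2, 0.1),
                      fdr = c(0.5, 0.01, 0.9),
                      direction = c("NS", "Down", "NS")))
  cancer <- list(
    LGG = data.frame(gene_id = c("H1", "H4"),
                     log2fc = c(1.9, 2), fdr = c(0.01, 0.01),
                     direction = c("Up", "Up")))
  um <- buildUnionMatrix(stage, cancer)
  ## H1 is DE at dpl1 and present in LGG -> included;
  ## H2 is DE but absent from every cancer -> excluded;
  ## H3 is NS everywhere -> excluded
  expect_identical(rownames(um$log2fc), "H1")
  expect_equal(um$log2fc["H1", "dpl1"], 2)
  expect_true(um$masked["H1", "dpl3"])      # weak and unsupported
  expect_equal(um$log2fc["H1", "LGG"], 1.9)
})

test_that("stage similarity ranking recovers a planted ordering", {
  set.seed(51)
  uni <- sprintf("H%04d", 1:2000)
  cancer_ids <- sample(uni, 500)
  cancer_dir <- sample(c("Up", "Down"), 500, replace = TRUE)
  cancer <- list(LGG = .dirset(cancer_ids, cancer_dir))
  mk_stage <- function(frac_shared) {
    n_sh <- round(frac_shared * 500)
    idx <- sample(500, n_sh)
    own <- sample(setdiff(uni, cancer_ids), 500 - n_sh)
    .dirset(c(cancer_ids[idx], own),
            c(cancer_dir[idx],
              sample(c("Up", "Down"), 500 - n_sh, replace = TRUE)))
  }
  stages <- list(stage1 = mk_stage(0.6), stage2 = mk_stage(0.3),
                 stage3 = mk_stage(0.1))
  rk <- rankStageSimilarity(stages, cancer)
  expect_identical(rk$overall, c("stage1", "stage2", "stage3"))
  expect_identical(rk$per_cancer$LGG, c("stage1", "stage2", "stage3"))

  ## identical sets reach similarity 1; anti-concordant sets go negative
  idn <- rankStageSimilarity(
    list(s1 = cancer$LGG, s2 = .dirset("x", "Up")), cancer)
  expect_equal(idn$table$similarity[idn$table$stage == "s1"], 1)
  flip <- .dirset(cancer_ids, ifelse(cancer_dir == "Up", "Down", "Up"))
  anti <- rankStageSimilarity(list(s1 = flip, s2 = cancer$LGG), cancer)
  expect_lt(anti$table$similarity[anti$table$stage == "s1"], 0)
})

test_that("percent unique reproduces printed study percentages", {
  ## per-stage totals and exclusive DEG counts as printed for the three
  ## post-lesion stages
  pct <- percentUnique(c(6123, 4662, 1954), c(3983, 1796, 373))
  expect_equal(pct, c(65.0, 38.5, 19.1))
  expect_equal(percentUnique(10, 10), 100)
  expect_equal(percentUnique(10, 0), 0)
  expect_true(is.na(percentUnique(0, 0)))
  expect_error(percentUnique(5, 6), "exceed")
  ## half-up rounding at the requested precision
  expect_equal(percentUnique(1000, 125, digits = 0), 13)
  expect_equal(percentUnique(200, 1, digits = 1), 0.5)
})
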