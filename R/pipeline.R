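#' Configuration for the end-to-end synthetic pipeline run
#'
#' Collects every tunable parameter of the pipeline in one validated
#' list: the simulation scales, the DE thresholds (fold change 1.5,
#' FDR 0.05), the co-expression settings (soft power 9, minimum cluster
#' size, deep split 2, low-count filter of 10 counts in at least 10
#' percent of samples), the masking FDR for the union fold-change
#' matrix (0.1), the ortholog name rule, and the master seed from which
#' every stage's RNG seed is derived.
#'
#' @param seed master integer seed; each stage derives its own seed
#'   from it, so one seed reproduces the whole run.
#' @param n_genes number of simulated source-species genes.
#' @param regen_groups replicate counts for the regeneration design.
#' @param cancer_groups replicate counts for each tumor/normal cohort
#'   (first label is the normal reference).
#' @param cancer_overlap named fractions: which share of each stage's
#'   planted DE genes is also planted (same direction) in the cancers.
#' @param cancer_unique_n planted DE genes private to each cancer.
#' @param fc_up,fdr_max DE thresholds.
#' @param mask_fdr masking FDR for the union matrix.
#' @param beta,min_cluster_size,deep_split,merge_cor,z_threshold
#'   co-expression settings.
#' @param min_count,min_sample_frac low-count filter.
#' @param wgcna_max_genes cap on network size: the most variable genes
#'   after filtering enter the network.
#' @param name_rule ortholog name-similarity rule.
#' @param n_terms background annotation terms for the enrichment stage.
#' @param out_dir optional directory for TSV/JSON outputs.
#' @return a validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1L,
                           n_genes = 6000,
                           regen_groups = c(control = 5L, dpl1 = 4L,
                                            dpl3 = 4L, dpl14 = 5L),
                           cancer_groups = c(normal = 6L, tumor = 6L),
                           cancer_overlap = c(dpl1 = 0.6, dpl3 = 0.3,
                                              dpl14 = 0.1),
                           cancer_unique_n = 150L,
                           fc_up = 1.5, fdr_max = 0.05, mask_fdr = 0.1,
                           beta = 9, min_cluster_size = 100L,
                           deep_split = 2L, merge_cor = 0.85,
                           z_threshold = 0.8,
                           min_count = 10, min_sample_frac = 0.10,
                           wgcna_max_genes = 2000L,
                           name_rule = c("suffix", "strict"),
                           n_terms = 50L,
                           out_dir = NULL) {
  name_rule <- match.arg(name_rule)
  stopifnot(fc_up > 1, fdr_max > 0, fdr_max < 1, mask_fdr > 0,
            mask_fdr < 1, beta >= 1, deep_split %in% 0:4,
            all(cancer_overlap >= 0), all(cancer_overlap <= 1))
  if (!setequal(names(cancer_overlap), names(regen_groups)[-1]))
    stop("cancer_overlap must name exactly the non-reference stages")
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

.derivedSeed <- function(seed, k) (as.integer(seed) + 1000L * k) %% 2147483647L

#' Run the full comparative pipeline on synthetic data
#'
#' Executes, in dependency order: count simulation for the regeneration
#' time course and two tumor cohorts (with planted cross-species
#' overlap decreasing from the first to the last stage), sample QC
#' (PCA, distances), per-stage and per-cancer differential expression,
#' co-expression module detection with stage-specificity calls,
#' ortholog resolution, direction-stratified intersections, the UpSet
#' exclusive regions and percent-unique summary, the masked union
#' fold-change matrix, stage-versus-cancer similarity ranking, and
#' EASE enrichment against simulated annotations. Identical
#' configuration and seed give an identical summary.
#'
#' @param config a [pipelineConfig()].
#' @return a run summary list (invisible copies of all intermediate
#'   objects under \code{$objects}); written as JSON and TSVs under
#'   \code{config$out_dir} when set.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- proc.time()[["elapsed"]]
  stages <- names(config$regen_groups)[-1]
  cancers <- c("LGG", "GBM")
  timings <- c()
  tick <- function(label) {
    t <- proc.time()[["elapsed"]]
    timings[label] <<- round(t - t0, 2)
    message(sprintf("[%s] done at %.1fs", label, t - t0))
  }

  ## 1. simulate regeneration counts and the orthology table
  rc <- simulationConfig(n_genes = config$n_genes,
                         groups = config$regen_groups,
                         seed = .derivedSeed(config$seed, 1))
  regen <- simulateCounts(rc)
  counts <- SummarizedExperiment::assay(regen$se, "counts")
  condition <- SummarizedExperiment::colData(regen$se)$condition
  orth <- simulateOrthology(config$n_genes,
                            seed = .derivedSeed(config$seed, 2))
  tick("simulate")

  ## 2. QC
  sf <- sizeFactorsMedianRatios(counts)
  expr <- transformCounts(counts, sf)
  pca <- samplePCA(expr)
  dists <- sampleDistances(expr)
  tick("qc")

  ## 3. per-stage differential expression
  deg <- lapply(stages, function(s)
    runDE(counts, s, names(config$regen_groups)[1],
          condition = condition,
          fc_up = config$fc_up, fdr_max = config$fdr_max))
  names(deg) <- stages
  tick("de")

  ## 4. co-expression modules on the most variable filtered genes
  filt <- filterLowCounts(counts, config$min_count,
                          config$min_sample_frac)
  fexpr <- transformCounts(filt, sf)
  vr <- apply(fexpr, 1, var)
  fexpr <- fexpr[vr > 0, , drop = FALSE]
  vr <- vr[vr > 0]
  if (nrow(fexpr) > config$wgcna_max_genes)
    fexpr <- fexpr[order(-vr)[seq_len(config$wgcna_max_genes)], ,
                   drop = FALSE]
  net <- buildNetwork(fexpr, beta = config$beta)
  mods <- detectModules(net, fexpr,
                        min_cluster_size = config$min_cluster_size,
                        deep_split = config$deep_split)
  if (length(mods@sizes) >= 2)
    mods <- mergeSimilarModules(mods, fexpr,
                                merge_cor = config$merge_cor)
  mods <- stageSpecificity(mods, condition,
                           z_threshold = config$z_threshold)
  tick("modules")

  ## 5. resolve orthologs
  omap <- resolveOrthologs(orth$table, name_rule = config$name_rule)
  tick("orthomap")

  ## 6. simulate tumor cohorts in target id space with planted overlap
  src2tgt <- orth$truth[!is.na(orth$truth)]
  tgt_universe <- unique(unname(src2tgt))
  tumor_lab <- names(config$cancer_groups)[2]
  cancer_sims <- list()
  for (ci in seq_along(cancers)) {
    plan <- character(0)
    set.seed(.derivedSeed(config$seed, 10 + ci))
    for (s in stages) {
      de_src <- rownames(regen$truth$de_labels)[
        regen$truth$de_labels[, s] != "NS"]
      de_src <- de_src[de_src %in% names(src2tgt)]
      take <- sample(de_src,
                     floor(config$cancer_overlap[[s]] * length(de_src)))
      dirs <- regen$truth$de_labels[take, s]
      plan[src2tgt[take]] <- dirs
    }
    rest <- setdiff(tgt_universe, names(plan))
    uniq <- sample(rest, min(config$cancer_unique_n, length(rest)))
    plan[uniq] <- sample(c("Up", "Down"), length(uniq), replace = TRUE)
    cc <- simulationConfig(
      n_genes = length(tgt_universe), groups = config$cancer_groups,
      n_modules = 0, de_fraction_per_stage = 0,
      planted_de = setNames(list(plan), tumor_lab),
      gene_ids = tgt_universe,
      seed = .derivedSeed(config$seed, 20 + ci))
    cancer_sims[[cancers[ci]]] <- simulateCounts(cc)
  }
  cancer_deg <- lapply(cancer_sims, function(sim)
    runDE(sim$se, tumor_lab, names(config$cancer_groups)[1],
          fc_up = config$fc_up, fdr_max = config$fdr_max))
  tick("cancer_de")

  ## 7. cross-species comparison
  mapped_all <- lapply(deg, mapToTargetSpace, map = omap, keep = "all")
  mapped_de <- lapply(mapped_all, .directionalOnly)
  cmp <- list()
  for (s in stages)
    for (cn in cancers)
      cmp[[paste(s, cn, sep = "_vs_")]] <-
        intersectDirectional(mapped_de[[s]], cancer_deg[[cn]])
  upset <- upsetExclusiveRegions(deg)
  totals <- vapply(deg, function(d)
    sum(d$direction %in% c("Up", "Down")), numeric(1))
  excl <- vapply(stages, function(s) {
    r <- upset[upset$region == s, , drop = FALSE]
    sum(r$count)
  }, numeric(1))
  pct_unique <- percentUnique(totals, excl)
  umat <- buildUnionMatrix(mapped_all, cancer_deg,
                           mask_fdr = config$mask_fdr,
                           fc_up = config$fc_up)
  ranking <- rankStageSimilarity(mapped_de, cancer_deg)
  tick("compare")

  ## 8. enrichment of the first stage-cancer shared list
  shared1 <- cmp[[paste(stages[1], cancers[1], sep = "_vs_")]]
  planted_term <- list(SHARED_RESPONSE = shared1$same_direction_ids)
  if (!length(planted_term[[1]])) planted_term <- list()
  terms <- simulateAnnotation(tgt_universe, n_terms = config$n_terms,
                              planted = planted_term,
                              seed = .derivedSeed(config$seed, 30))
  enr <- enrichGeneSets(shared1$same_direction_ids, tgt_universe, terms)
  tick("enrich")

  summary <- list(
    config = config[setdiff(names(config), "out_dir")],
    deg_counts = lapply(c(deg, cancer_deg), function(d)
      list(total = sum(d$direction != "NS"),
           up = sum(d$direction == "Up"),
           down = sum(d$direction == "Down"))),
    modules = list(
      n = length(mods@sizes),
      sizes = unname(as.integer(mods@sizes)),
      stage_specific = sum(!is.na(mods@specificStage)),
      specific_stage = as.list(mods@specificStage)),
    comparisons = lapply(cmp, function(x)
      list(shared = x$shared, same_direction = x$same_direction,
           opposite = x$opposite, similarity = x$similarity)),
    percent_unique = as.list(setNames(pct_unique, stages)),
    union_matrix_rows = nrow(umat$log2fc),
    similarity_ranking = ranking$overall,
    top_enriched_term = if (nrow(enr)) enr$term[1] else NA,
    pca_explained = unname(pca$explained_variance),
    timings = as.list(timings))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    op <- function(f) file.path(config$out_dir, f)
    writeCountsTSV(counts, op("regen_counts.tsv"))
    writeDesignTSV(data.frame(sample_id = colnames(counts),
                              condition = as.character(condition)),
                   op("regen_design.tsv"))
    for (s in stages)
      writeDETableTSV(deg[[s]], op(paste0("de_", s, ".tsv")))
    for (cn in cancers)
      writeDETableTSV(cancer_deg[[cn]], op(paste0("de_", cn, ".tsv")))
    writeOrthologyMapTSV(omap, op("orthology_map.tsv"))
    write.table(data.frame(gene_id = names(mods@labels),
                           module = unname(mods@labels)),
                op("modules.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(upset, op("upset_regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ranking$table, op("similarity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, op("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  summary$objects <- list(regen = regen, deg = deg, modules = mods,
                          orthology = omap, cancer_deg = cancer_deg,
                          comparisons = cmp, union_matrix = umat,
                          ranking = ranking, enrichment = enr,
                          pca = pca, distances = dists)
  summary
}
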