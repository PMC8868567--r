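#' Simulation settings for a synthetic regeneration time course
#'
#' Builds and validates the configuration consumed by [simulateCounts()].
#' The defaults emulate the statistical shape of a stab-lesion
#' regeneration experiment: four groups (uninjured control plus three
#' post-lesion stages) with four or five biological replicates each
#' (n = 18 in total), negative-binomial counts with log-normal baseline
#' means, stage-specific planted differentially expressed genes in both
#' directions, and planted co-expressed gene blocks each peaking in one
#' stage.
#'
#' @param n_genes number of genes.
#' @param groups named integer vector of replicate counts per condition;
#'   the first condition is the reference (control). All counts must be
#'   >= 2.
#' @param baseline_log_mean,baseline_log_sd parameters of the log-normal
#'   distribution of baseline gene means (natural-log scale).
#' @param dispersion negative-binomial dispersion \eqn{\alpha}
#'   (\eqn{var = \mu + \alpha\mu^2}); a scalar or one value per gene.
#' @param de_fraction_per_stage fraction of genes planted as DE in each
#'   non-reference condition.
#' @param de_log2fc_magnitude absolute planted log2 fold change.
#' @param up_fraction fraction of planted DE genes that are upregulated.
#' @param n_modules,module_size,module_cor planted co-expression blocks:
#'   number, genes per block, and target within-block correlation of
#'   log-expression. \code{module_cor} must lie in (0, 1).
#' @param module_peak_shift shift (in latent-factor standard deviations)
#'   of the module latent factor in its peak condition.
#' @param module_log_mean,module_log_sd log-normal parameters for module
#'   gene baselines; kept tighter and higher than the global baseline so
#'   counting noise does not dominate the planted correlation.
#' @param size_factor_range range of the log-uniform per-sample library
#'   size factors, so normalization is non-trivially exercised.
#' @param planted_de optional explicit plan: a named list, one element
#'   per non-reference condition, each a named character vector
#'   (gene id -> "Up"/"Down") overriding random DE planting for that
#'   condition.
#' @param gene_prefix prefix for generated gene identifiers.
#' @param gene_ids optional explicit vector of \code{n_genes} gene
#'   identifiers, overriding \code{gene_prefix} (used when the
#'   simulated genes must live in a predefined id space).
#' @param seed integer RNG seed; identical configuration and seed give a
#'   bit-identical count matrix.
#'
#' @return a validated list of class \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(n_genes = 500, seed = 7)
#' sim <- simulateCounts(cfg)
#' dim(SummarizedExperiment::assay(sim$se))
#' @export
simulationConfig <- function(n_genes = 6000,
                             groups = c(control = 5L, dpl1 = 4L,
                                        dpl3 = 4L, dpl14 = 5L),
                             baseline_log_mean = 4,
                             baseline_log_sd = 1.5,
                             dispersion = 0.1,
                             de_fraction_per_stage = 0.05,
                             de_log2fc_magnitude = 2,
                             up_fraction = 0.6,
                             n_modules = 3,
                             module_size = 120,
                             module_cor = 0.7,
                             module_peak_shift = 3,
                             module_log_mean = 5,
                             module_log_sd = 0.5,
                             size_factor_range = c(0.5, 2),
                             planted_de = NULL,
                             gene_prefix = "zg",
                             gene_ids = NULL,
                             seed = 1L) {
  if (!is.null(gene_ids) && length(gene_ids) != n_genes)
    stop("gene_ids must have length n_genes")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be a named vector of replicate counts")
  if (any(groups != as.integer(groups)))
    stop("replicate counts must be integers")
  groups <- setNames(as.integer(groups), names(groups))
  if (any(groups < 2L))
    stop("every condition needs at least 2 replicates")
  if (n_modules > 0 && (module_cor <= 0 || module_cor >= 1))
    stop("module_cor must lie strictly inside (0, 1)")
  if (de_fraction_per_stage < 0 || de_fraction_per_stage > 1)
    stop("de_fraction_per_stage must lie in [0, 1]")
  if (any(dispersion <= 0))
    stop("dispersion must be > 0")
  if (n_modules * module_size > n_genes)
    stop("module_size * n_modules exceeds n_genes")
  cfg <- list(
    n_genes = as.integer(n_genes), groups = groups,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    dispersion = dispersion,
    de_fraction_per_stage = de_fraction_per_stage,
    de_log2fc_magnitude = de_log2fc_magnitude,
    up_fraction = up_fraction,
    n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    module_cor = module_cor,
    module_peak_shift = module_peak_shift,
    module_log_mean = module_log_mean,
    module_log_sd = module_log_sd,
    size_factor_range = size_factor_range,
    planted_de = planted_de,
    gene_prefix = gene_prefix,
    gene_ids = gene_ids,
    seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a negative-binomial count matrix with planted structure
#'
#' Counts are drawn as NB(mean = size factor x group mean, dispersion
#' \eqn{\alpha}) with \eqn{var = \mu + \alpha\mu^2}. Planted DE genes
#' have their group mean multiplied by \eqn{2^{\pm log2fc}} in their
#' stage. Module genes share a per-sample latent factor
#' (gene = baseline x exp(loading x factor)), with equal loadings chosen
#' so the expected pairwise log-expression correlation is approximately
#' \code{module_cor}, and the factor mean shifted in the module's peak
#' condition.
#'
#' @param config a [simulationConfig()].
#' @return list with components \code{se} (a
#'   \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{counts} assay and a \code{condition} column in its
#'   \code{colData}) and \code{truth} (planted DE labels and log2 fold
#'   changes per stage, module labels, module peak stages, and the true
#'   size factors).
#' @export
simulateCounts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  G <- config$n_genes
  groups <- config$groups
  conds <- names(groups)
  stages <- conds[-1L]
  n <- sum(groups)
  genes <- config$gene_ids %||%
    sprintf("%s%05d", config$gene_prefix, seq_len(G))
  condition <- factor(rep(conds, groups), levels = conds)
  samples <- paste(as.character(condition),
                   unlist(lapply(groups, seq_len)), sep = "_")

  mu <- rlnorm(G, config$baseline_log_mean, config$baseline_log_sd)
  alpha <- rep_len(config$dispersion, G)

  ## planted DE: per-stage direction labels and signed log2 fold changes
  de_dir <- matrix("NS", G, length(stages),
                   dimnames = list(genes, stages))
  de_lfc <- matrix(0, G, length(stages), dimnames = list(genes, stages))
  for (s in stages) {
    if (!is.null(config$planted_de) && !is.null(config$planted_de[[s]])) {
      plan <- config$planted_de[[s]]
      bad <- setdiff(names(plan), genes)
      if (length(bad))
        stop("planted_de names unknown: ", paste(head(bad), collapse = ", "))
      de_dir[names(plan), s] <- unname(plan)
    } else if (config$de_fraction_per_stage > 0) {
      idx <- sample.int(G, floor(config$de_fraction_per_stage * G))
      up <- runif(length(idx)) < config$up_fraction
      de_dir[idx, s] <- ifelse(up, "Up", "Down")
    }
    sel <- de_dir[, s] != "NS"
    de_lfc[sel, s] <- ifelse(de_dir[sel, s] == "Up", 1, -1) *
      config$de_log2fc_magnitude
  }

  ## planted modules: disjoint blocks, preferentially non-DE genes
  module <- integer(G)
  names(module) <- genes
  peak <- character(0)
  if (config$n_modules > 0) {
    free <- which(rowSums(de_dir != "NS") == 0)
    need <- config$n_modules * config$module_size
    pool <- if (length(free) >= need) free else seq_len(G)
    picked <- sample(pool, need)
    module[picked] <- rep(seq_len(config$n_modules),
                          each = config$module_size)
    peak <- stages[(seq_len(config$n_modules) - 1L) %% length(stages) + 1L]
    names(peak) <- paste0("M", seq_len(config$n_modules))
    ## module baselines re-drawn tight and high
    mu[picked] <- rlnorm(need, config$module_log_mean, config$module_log_sd)
  }

  ## expected mean per gene x sample
  M <- matrix(mu, G, n)
  for (s in stages) {
    j <- which(condition == s)
    M[, j] <- M[, j] * 2^de_lfc[, s]
  }
  if (config$n_modules > 0) {
    for (m in seq_len(config$n_modules)) {
      g <- which(module == m)
      shift <- config$module_peak_shift * (condition == peak[m])
      f <- rnorm(n, mean = as.numeric(shift), sd = 1)
      ## standardized to unit sample variance so the realized
      ## signal-to-noise ratio does not fluctuate with the factor draw
      f <- as.numeric(scale(f))
      ## loading chosen from the average counting-noise variance on the
      ## log scale, Var(log X) ~ 1/mu + alpha, to hit module_cor
      v_noise <- mean(1 / mu[g] + alpha[g])
      a <- sqrt(config$module_cor / (1 - config$module_cor) * v_noise)
      M[g, ] <- M[g, ] * rep(exp(a * f - a^2 / 2), each = length(g))
    }
  }

  sf <- exp(runif(n, log(config$size_factor_range[1]),
                  log(config$size_factor_range[2])))
  M <- sweep(M, 2, sf, "*")
  K <- matrix(rnbinom(G * n, mu = M, size = rep(1 / alpha, n)), G, n,
              dimnames = list(genes, samples))
  storage.mode(K) <- "integer"

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = K),
    colData = S4Vectors::DataFrame(condition = condition,
                                   row.names = samples))
  truth <- list(
    de_labels = de_dir,
    de_log2fc = de_lfc,
    module_labels = module,
    module_peak_stage = peak,
    size_factors = setNames(sf, samples),
    baseline_mean = setNames(mu, genes))
  list(se = se, truth = truth)
}

#' Simulate an orthology candidate table with known truth
#'
#' Produces candidate source-to-target pairs of five ambiguity classes
#' mixing the situations a cross-species annotation export contains:
#' \describe{
#'   \item{unique_hc}{a single high-confidence candidate.}
#'   \item{name_match}{a non-high-confidence candidate whose names match
#'     after paralog-suffix stripping, plus a high-confidence decoy with
#'     strictly better metrics - the resolver must still prefer the name
#'     match.}
#'   \item{one_to_many}{three high-confidence candidates; the intended
#'     winner strictly dominates the metric ranking (gene-order
#'     conservation first).}
#'   \item{many_to_one}{pairs of source genes sharing one target, both
#'     high confidence, so the target must be flagged as multi-source.}
#'   \item{lowconf_only}{a single low-confidence, name-dissimilar
#'     candidate; filtered out, so the gene is unresolvable (truth NA).}
#' }
#'
#' @param n_source number of source genes.
#' @param ambiguity_mix named non-negative fractions for the classes
#'   above, summing to at most 1; any remainder is assigned to
#'   \code{unique_hc}.
#' @param seed integer RNG seed.
#' @return list with \code{table} (the candidate data.frame with columns
#'   src_id, src_name, tgt_id, tgt_name, high_confidence, goc, wga,
#'   pid_src_tgt, pid_tgt_src) and \code{truth} (named character vector
#'   src_id -> intended tgt_id, NA where unresolvable).
#' @export
simulateOrthology <- function(n_source,
                              ambiguity_mix = c(unique_hc = 0.6,
                                                name_match = 0.15,
                                                one_to_many = 0.1,
                                                many_to_one = 0.1,
                                                lowconf_only = 0.05),
                              seed = 1L) {
  classes <- c("unique_hc", "name_match", "one_to_many", "many_to_one",
               "lowconf_only")
  mix <- setNames(numeric(length(classes)), classes)
  mix[names(ambiguity_mix)] <- ambiguity_mix
  if (any(mix < 0)) stop("ambiguity fractions must be non-negative")
  if (sum(mix) > 1 + 1e-9) stop("ambiguity fractions must sum to <= 1")
  set.seed(seed)
  if (n_source == 0) {
    return(list(table = emptyOrthologyTable(), truth = character(0)))
  }
  counts <- floor(mix * n_source)
  ## many-to-one genes come in pairs
  counts["many_to_one"] <- 2L * (counts["many_to_one"] %/% 2L)
  counts["unique_hc"] <- counts["unique_hc"] +
    (n_source - sum(counts))
  cls <- sample(rep(classes, counts))

  src_id <- sprintf("zg%05d", seq_len(n_source))
  base <- replicate(n_source,
                    paste(sample(letters, 5, replace = TRUE), collapse = ""))
  src_name <- paste0(base, "a")          # zebrafish paralog-style names
  rows <- vector("list", n_source)
  truth <- setNames(rep(NA_character_, n_source), src_id)
  tgt_counter <- 0L
  newTgt <- function(k = 1L) {
    ids <- sprintf("HG%05d", tgt_counter + seq_len(k))
    tgt_counter <<- tgt_counter + k
    ids
  }
  metr <- function(k) round(matrix(runif(4 * k, 0, 95), k, 4), 1)

  i <- 1L
  while (i <= n_source) {
    cl <- cls[i]
    if (cl == "many_to_one" && i < n_source && cls[i + 1L] == "many_to_one") {
      tgt <- newTgt()
      m <- metr(2)
      rows[[i]] <- data.frame(
        src_id = src_id[c(i, i + 1L)], src_name = src_name[c(i, i + 1L)],
        tgt_id = tgt, tgt_name = paste0("N", toupper(base[i])),
        high_confidence = TRUE,
        goc = m[, 1], wga = m[, 2], pid_src_tgt = m[, 3], pid_tgt_src = m[, 4])
      truth[c(i, i + 1L)] <- tgt
      i <- i + 2L
      next
    }
    if (cl == "many_to_one") cl <- "unique_hc"  # unpaired leftover
    if (cl == "unique_hc") {
      tgt <- newTgt()
      m <- metr(1)
      rows[[i]] <- data.frame(
        src_id = src_id[i], src_name = src_name[i],
        tgt_id = tgt, tgt_name = paste0("N", toupper(base[i])),
        high_confidence = TRUE,
        goc = m[, 1], wga = m[, 2], pid_src_tgt = m[, 3], pid_tgt_src = m[, 4])
      truth[i] <- tgt
    } else if (cl == "name_match") {
      tgt <- newTgt(2)
      m <- metr(2)
      m[1, ] <- m[2, ] / 2             # decoy strictly better on metrics
      rows[[i]] <- data.frame(
        src_id = src_id[i], src_name = src_name[i],
        tgt_id = tgt,
        tgt_name = c(toupper(base[i]), paste0("X", toupper(base[i]))),
        high_confidence = c(FALSE, TRUE),
        goc = m[, 1], wga = m[, 2], pid_src_tgt = m[, 3], pid_tgt_src = m[, 4])
      truth[i] <- tgt[1]
    } else if (cl == "one_to_many") {
      tgt <- newTgt(3)
      m <- metr(3)
      m[1, 1] <- runif(1, 50, 95)      # winner strictly dominates on goc
      m[2, 1] <- m[1, 1] - runif(1, 1, 20)
      m[3, 1] <- m[2, 1] - runif(1, 1, 20)
      rows[[i]] <- data.frame(
        src_id = src_id[i], src_name = src_name[i],
        tgt_id = tgt, tgt_name = paste0(c("P", "Q", "R"), toupper(base[i])),
        high_confidence = TRUE,
        goc = round(m[, 1], 1), wga = m[, 2],
        pid_src_tgt = m[, 3], pid_tgt_src = m[, 4])
      truth[i] <- tgt[1]
    } else {                            # lowconf_only
      tgt <- newTgt()
      m <- metr(1)
      rows[[i]] <- data.frame(
        src_id = src_id[i], src_name = src_name[i],
        tgt_id = tgt, tgt_name = paste0("Y", toupper(base[i])),
        high_confidence = FALSE,
        goc = m[, 1], wga = m[, 2], pid_src_tgt = m[, 3], pid_tgt_src = m[, 4])
    }
    i <- i + 1L
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(tab) <- NULL
  list(table = tab, truth = truth)
}

emptyOrthologyTable <- function() {
  data.frame(src_id = character(0), src_name = character(0),
             tgt_id = character(0), tgt_name = character(0),
             high_confidence = logical(0), goc = numeric(0),
             wga = numeric(0), pid_src_tgt = numeric(0),
             pid_tgt_src = numeric(0))
}

#' Simulate gene-set annotations with planted enriched terms
#'
#' Background terms draw members uniformly from the gene universe;
#' planted terms are supplied verbatim so a designated query list is
#' enriched by construction.
#'
#' @param genes character vector, the gene universe.
#' @param n_terms number of background terms.
#' @param planted named list of character vectors: term name ->
#'   member genes (must be a subset of \code{genes}).
#' @param term_size_range background term sizes drawn uniformly in this
#'   range.
#' @param seed integer RNG seed.
#' @return named list of character vectors (one element per term),
#'   suitable for [writeGMT()] / [enrichGeneSets()].
#' @export
simulateAnnotation <- function(genes, n_terms = 50, planted = list(),
                               term_size_range = c(10, 50), seed = 1L) {
  set.seed(seed)
  if (length(planted)) {
    if (is.null(names(planted)) || any(!nzchar(names(planted))))
      stop("planted terms must be named")
    extra <- setdiff(unique(unlist(planted)), genes)
    if (length(extra))
      stop("planted term genes outside the universe: ",
           paste(head(extra), collapse = ", "))
  }
  bg_names <- sprintf("TERM%04d", seq_len(n_terms))
  sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                  n_terms, replace = TRUE)
  sizes <- pmin(sizes, length(genes))
  bg <- lapply(sizes, function(k) sample(genes, k))
  names(bg) <- bg_names
  out <- c(planted, bg)
  if (anyDuplicated(names(out)))
    stop("duplicate term names")
  out
}
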