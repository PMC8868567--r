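#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes
#' expressed in every sample, of the ratio of the gene's count to its
#' geometric mean across samples, rescaled so the factors themselves
#' have geometric mean 1.
#'
#' @param counts integer matrix, genes x samples.
#' @return named numeric vector of positive size factors (geometric
#'   mean 1).
#' @examples
#' k <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' sizeFactorsMedianRatios(k)  # (1/sqrt(2), sqrt(2))
#' @export
sizeFactorsMedianRatios <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has nonzero counts in all samples; use a ",
         "pseudo-reference fallback such as sizeFactorsTotalCount()")
  loggeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  lf <- apply(log(counts[pos, , drop = FALSE]) - loggeo, 2, median)
  sf <- exp(lf - mean(lf))
  setNames(sf, colnames(counts))
}

#' Total-count fallback size factors
#'
#' Per-sample library-size ratios, rescaled to geometric mean 1; the
#' fallback when no gene is expressed in every sample.
#'
#' @inheritParams sizeFactorsMedianRatios
#' @return named numeric vector of positive size factors.
#' @export
sizeFactorsTotalCount <- function(counts) {
  tot <- colSums(as.matrix(counts))
  if (any(tot == 0)) stop("sample with zero total counts")
  sf <- tot / exp(mean(log(tot)))
  setNames(sf, colnames(counts))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-gene dispersion \eqn{\hat\alpha = max(\alpha_{min},
#' (s^2 - \bar m)/\bar m^2)} on normalized counts, pooled within
#' condition (weighted by residual degrees of freedom). With few
#' replicates the per-gene estimate is noisy; by default it is replaced
#' by the mean raw estimate within quantile bins of the log mean
#' (\code{trend = TRUE}), sharing information across genes the way
#' standard RNA-seq dispersion estimators do. Set \code{trend = FALSE}
#' for the raw per-gene values.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors per-sample size factors.
#' @param condition factor of sample conditions (length = ncol(counts)).
#' @param trend replace per-gene estimates by a mean-dispersion trend.
#' @param n_bins number of quantile bins for the trend.
#' @param alpha_min lower clamp for the dispersion.
#' @return named numeric vector of per-gene dispersions.
#' @export
estimateDispersions <- function(counts, size_factors, condition,
                                trend = TRUE, n_bins = 20,
                                alpha_min = 1e-8) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3) stop("at least 3 samples required")
  condition <- as.factor(condition)
  q <- sweep(counts, 2, size_factors, "/")
  num <- 0; den <- 0
  for (lev in levels(condition)) {
    j <- which(condition == lev)
    if (length(j) < 2) next
    m <- rowMeans(q[, j, drop = FALSE])
    v <- rowSums((q[, j, drop = FALSE] - m)^2) / (length(j) - 1)
    a_lev <- (v - m) / pmax(m, 1e-12)^2
    num <- num + (length(j) - 1) * a_lev
    den <- den + (length(j) - 1)
  }
  if (den == 0) stop("no condition has >= 2 replicates")
  a <- num / den
  if (trend) {
    m0 <- rowMeans(q)
    ok <- is.finite(a) & m0 > 0
    if (sum(ok) >= n_bins) {
      br <- unique(quantile(log(m0[ok]), probs = seq(0, 1,
                                                     length.out = n_bins + 1)))
      if (length(br) >= 2) {
        bin <- cut(log(m0[ok]), br, include.lowest = TRUE)
        fit <- tapply(a[ok], bin, mean, na.rm = TRUE)
        a[ok] <- fit[as.integer(bin)]
      }
    }
  }
  a[!is.finite(a)] <- alpha_min
  setNames(pmax(a, alpha_min), rownames(counts))
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Group means are fitted on the normalized scale as
#' \eqn{\hat\mu = \sum_j K_j / \sum_j s_j}; the log2 fold change is the
#' log ratio of the treatment over the reference mean (with a 0.5
#' pseudo-mean floor applied to both groups whenever either mean is
#' zero, so fold changes are never infinite). The standard error comes
#' from the delta-method variance of the log ratio under
#' \eqn{var(K) = s\mu + \alpha s^2 \mu^2}, and
#' \eqn{p = 2(1 - \Phi(|log2fc / se|))}. Genes with all-zero counts in
#' both groups get \code{log2fc = 0}, \code{p = 1}.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors per-sample size factors.
#' @param dispersions per-gene NB dispersion (recycled if scalar).
#' @param condition factor/character of sample conditions.
#' @param treatment,reference condition labels to contrast; both groups
#'   need >= 2 samples.
#' @return data.frame with columns \code{gene_id}, \code{base_mean}
#'   (mean normalized count across the contrasted samples),
#'   \code{log2fc}, \code{se}, \code{p}.
#' @export
nbWaldTest <- function(counts, size_factors, dispersions, condition,
                       treatment, reference) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  jt <- which(condition == treatment)
  jr <- which(condition == reference)
  if (length(jt) < 2 || length(jr) < 2)
    stop("both groups need at least 2 samples")
  a <- rep_len(dispersions, nrow(counts))
  s <- size_factors
  groupMean <- function(j)
    rowSums(counts[, j, drop = FALSE]) / sum(s[j])
  mut <- groupMean(jt)
  mur <- groupMean(jr)
  floored <- mut == 0 | mur == 0
  mut_f <- ifelse(floored, mut + 0.5, mut)
  mur_f <- ifelse(floored, mur + 0.5, mur)
  lfc <- log2(mut_f / mur_f)
  varLogMean <- function(mu, j) {
    S1 <- sum(s[j]); S2 <- sum(s[j]^2)
    (S1 * mu + a * S2 * mu^2) / (S1^2 * mu^2)
  }
  se2 <- varLogMean(mut_f, jt) + varLogMean(mur_f, jr)
  se <- sqrt(se2) / log(2)
  z <- lfc / se
  p <- 2 * pnorm(-abs(z))
  allzero <- mut == 0 & mur == 0
  lfc[allzero] <- 0
  p[allzero] <- 1
  se[allzero] <- NA_real_
  jj <- c(jr, jt)
  base_mean <- rowMeans(sweep(counts[, jj, drop = FALSE], 2, s[jj], "/"))
  data.frame(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             base_mean = base_mean, log2fc = lfc, se = se, p = p,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotone enforcement, via [stats::p.adjust()], after
#' validating the input range.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return vector of BH-adjusted p-values (FDR).
#' @export
adjustBH <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify genes as Up / Down / NS
#'
#' A gene is \code{Up} when its fold change exceeds \code{fc_up} and its
#' FDR is below \code{fdr_max}; \code{Down} when the fold change is
#' below the reciprocal \code{1/fc_up} (0.67 for the default 1.5) at the
#' same FDR cutoff; otherwise \code{NS}. The down cutoff is always
#' derived as the reciprocal of the up cutoff.
#'
#' @param table data.frame with columns \code{log2fc} and \code{fdr}.
#' @param fc_up fold-change threshold for upregulation (default 1.5).
#' @param fdr_max FDR threshold (default 0.05).
#' @return the table with a \code{direction} column added.
#' @export
classifyDirection <- function(table, fc_up = 1.5, fdr_max = 0.05) {
  stopifnot(all(c("log2fc", "fdr") %in% names(table)))
  fc <- 2^table$log2fc
  dir <- rep("NS", nrow(table))
  sig <- !is.na(table$fdr) & table$fdr < fdr_max
  dir[sig & fc > fc_up] <- "Up"
  dir[sig & fc < 1 / fc_up] <- "Down"
  table$direction <- dir
  table
}

#' Run a full two-group differential expression contrast
#'
#' Convenience wrapper chaining [sizeFactorsMedianRatios()],
#' [estimateDispersions()], [nbWaldTest()], [adjustBH()] and
#' [classifyDirection()] for one treatment-versus-reference comparison.
#'
#' @param se a \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{counts} assay and a \code{condition} column in
#'   \code{colData}, or a counts matrix (then supply \code{condition}).
#' @param treatment,reference condition labels to contrast.
#' @param condition sample conditions; ignored when \code{se} is a
#'   SummarizedExperiment.
#' @param fc_up,fdr_max thresholds for [classifyDirection()].
#' @param trend passed to [estimateDispersions()].
#' @param size_factors optional precomputed size factors.
#' @return a differential expression data.frame with columns
#'   \code{gene_id}, \code{base_mean}, \code{log2fc}, \code{se},
#'   \code{p}, \code{fdr}, \code{direction}. FDR is computed within the
#'   contrast's full gene universe.
#' @export
runDE <- function(se, treatment, reference, condition = NULL,
                  fc_up = 1.5, fdr_max = 0.05, trend = TRUE,
                  size_factors = NULL) {
  if (is(se, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(se, "counts")
    condition <- SummarizedExperiment::colData(se)$condition
  } else counts <- as.matrix(se)
  if (is.null(condition)) stop("'condition' required")
  keep <- condition %in% c(treatment, reference)
  counts <- counts[, keep, drop = FALSE]
  condition <- factor(as.character(condition[keep]),
                      levels = c(reference, treatment))
  if (is.null(size_factors)) size_factors <- sizeFactorsMedianRatios(counts)
  disp <- estimateDispersions(counts, size_factors, condition, trend = trend)
  tab <- nbWaldTest(counts, size_factors, disp, condition,
                    treatment, reference)
  tab$fdr <- adjustBH(tab$p)
  classifyDirection(tab, fc_up = fc_up, fdr_max = fdr_max)
}
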