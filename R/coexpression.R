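#' Filter weakly expressed genes before network construction
#'
#' Keeps genes with at least \code{min_count} counts in at least
#' \code{ceiling(min_sample_frac * n)} samples, i.e. removes genes with
#' fewer than 10 counts in more than 90 percent of the samples under the
#' defaults. Gene order is preserved.
#'
#' @param counts integer matrix, genes x samples.
#' @param min_count minimum count for a sample to support a gene.
#' @param min_sample_frac minimum fraction of supporting samples.
#' @return the filtered count matrix (warning and empty matrix when
#'   nothing survives).
#' @export
filterLowCounts <- function(counts, min_count = 10,
                            min_sample_frac = 0.10) {
  counts <- as.matrix(counts)
  need <- ceiling(min_sample_frac * ncol(counts))
  keep <- rowSums(counts >= min_count) >= need
  if (!any(keep)) warning("no gene passes the low-count filter")
  counts[keep, , drop = FALSE]
}

#' Log variance-stabilizing transform of normalized counts
#'
#' \code{log2(count / size_factor + 1)}: a simple variance-stabilizing
#' stand-in, monotone in counts within each sample.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors per-sample size factors.
#' @return numeric matrix of transformed expression.
#' @export
transformCounts <- function(counts, size_factors) {
  log2(sweep(as.matrix(counts), 2, size_factors, "/") + 1)
}

#' Build an unsigned weighted co-expression network
#'
#' Similarity is the absolute Pearson correlation of gene expression
#' profiles; adjacency is the similarity raised elementwise to the
#' soft-threshold power \code{beta}; the topological overlap is
#' \deqn{\omega_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}}
#' with connectivity \eqn{k_i = \sum_{u \ne i} a_{iu}} and
#' \eqn{\omega_{ii} = 1}.
#'
#' @param expr numeric matrix, genes x samples (>= 4 samples).
#' @param beta soft-threshold power (default 9, suited to small sample
#'   sizes).
#' @return a [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(expr, beta = 9) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 4) stop("at least 4 samples required")
  v <- apply(expr, 1, var)
  if (any(v == 0))
    stop("zero-variance genes present: ",
         paste(head(rownames(expr)[v == 0], 5), collapse = ", "))
  genes <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  s <- abs(cor(t(expr)))
  s[s > 1] <- 1                     # numerical guard
  dimnames(s) <- list(genes, genes)
  a <- s^beta
  diag(a) <- 1
  tom <- tomFromAdjacency(a)
  new("CoexpressionNetwork", genes = genes, similarity = s,
      adjacency = a, tom = tom, beta = beta)
}

#' Topological overlap of a network adjacency
#'
#' \eqn{\omega_{ij} = (\sum_{u} a_{iu} a_{uj} + a_{ij}) /
#' (\min(k_i, k_j) + 1 - a_{ij})} over \eqn{u \ne i, j}, with
#' \eqn{k_i = \sum_{u \ne i} a_{iu}} and unit diagonal.
#'
#' @param a symmetric adjacency matrix with entries in [0, 1] (the
#'   diagonal is ignored).
#' @return the topological overlap matrix, same dimensions as \code{a}.
#' @export
tomFromAdjacency <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-8)
    stop("adjacency must be a symmetric square matrix")
  a0 <- a
  diag(a0) <- 0
  L <- a0 %*% a0
  k <- rowSums(a0)
  tom <- (L + a0) / (outer(k, k, pmin) + 1 - a0)
  diag(tom) <- 1
  tom
}

## first principal component of the standardized module submatrix,
## oriented to correlate positively with member genes on average
.eigengene <- function(expr, genes) {
  x <- expr[genes, , drop = FALSE]
  x <- t(scale(t(x)))
  x[!is.finite(x)] <- 0
  sv <- svd(x, nu = 0, nv = 1)
  e <- sv$v[, 1]
  cors <- suppressWarnings(cor(e, t(expr[genes, , drop = FALSE])))
  if (mean(cors, na.rm = TRUE) < 0) e <- -e
  e / sqrt(sum(e^2))
}

.eigengeneMatrix <- function(expr, labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods))
    return(matrix(0, ncol(expr), 0,
                  dimnames = list(colnames(expr), character(0))))
  E <- vapply(mods, function(m) .eigengene(expr, names(labels)[labels == m]),
              numeric(ncol(expr)))
  dimnames(E) <- list(colnames(expr), paste0("M", mods))
  E
}

## relabel so module 1 is the largest; returns relabelled integer vector
.relabelBySize <- function(labels) {
  tab <- sort(table(labels[labels > 0]), decreasing = TRUE)
  map <- setNames(seq_along(tab), names(tab))
  out <- labels
  out[labels > 0] <- map[as.character(labels[labels > 0])]
  storage.mode(out) <- "integer"
  out
}

.newAssignment <- function(labels, expr) {
  labels <- .relabelBySize(labels)
  E <- .eigengeneMatrix(expr, labels)
  sizes <- as.integer(table(factor(labels[labels > 0],
                                   levels = seq_len(ncol(E)))))
  names(sizes) <- colnames(E)
  new("ModuleAssignment", labels = labels, eigengenes = E,
      sizes = sizes, stageZ = matrix(0, 0, 0),
      specificStage = character(0))
}

#' Detect co-expression modules by adaptive decomposition of the TOM
#' dendrogram
#'
#' Average-linkage hierarchical clustering of the topological overlap
#' dissimilarity \code{1 - TOM} is decomposed into branches adaptively
#' (the tree variant of dynamic tree cut). Candidate branches are the
#' clusters at 0.95 of the dendrogram's merge-height span; each branch
#' of sufficient size is then scanned downwards to the deep-split floor
#' (\code{deep_split} 0 -> 0.95, 1 -> 0.90, 2 -> 0.85, 3 -> 0.80,
#' 4 -> 0.75 of the span; deeper splits scan further and so decompose
#' more aggressively) and split at the first height where it separates
#' into two or more sub-branches of at least \code{min_cluster_size}
#' genes, recursively. Span-relative heights adapt to the strong
#' compression of TOM dissimilarities toward 1 at high soft-threshold
#' powers. At every split, leftover sub-branches below the size floor
#' join the resulting module whose eigengene correlates best with
#' theirs when that correlation exceeds \code{rescue_cor}, and are
#' otherwise unassigned (label 0). Finally, module membership is
#' pruned: genes correlating with their own module eigengene below
#' \code{kme_min} are released to label 0. Modules are ordered by
#' descending size.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param expr the expression matrix the network was built from
#'   (genes x samples), needed for eigengenes.
#' @param min_cluster_size minimum genes per module (default 100).
#' @param deep_split integer 0-4 (default 2).
#' @param rescue_cor eigengene correlation required to absorb a small
#'   sub-branch into a module at a split (default 0.5).
#' @param kme_min minimum module membership (correlation of a member
#'   gene with its module eigengene; default 0.5).
#' @param scan_steps number of cut heights scanned between the shallow
#'   level and the deep-split floor.
#' @return a [ModuleAssignment-class].
#' @export
detectModules <- function(network, expr, min_cluster_size = 100,
                          deep_split = 2, rescue_cor = 0.5,
                          kme_min = 0.5, scan_steps = 20) {
  stopifnot(is(network, "CoexpressionNetwork"))
  if (!deep_split %in% 0:4) stop("deep_split must be in 0..4")
  expr <- as.matrix(expr)
  genes <- network@genes
  stopifnot(all(genes %in% rownames(expr)))
  n <- length(genes)
  labels <- setNames(integer(n), genes)
  if (n < min_cluster_size) {
    return(.newAssignment(labels, expr))
  }
  floor_frac <- c(`0` = 0.95, `1` = 0.90, `2` = 0.85, `3` = 0.80,
                  `4` = 0.75)[as.character(deep_split)]
  h <- hclust(as.dist(1 - network@tom), method = "average")
  hh <- function(f) min(h$height) + f * diff(range(h$height))
  fracs <- seq(0.95, floor_frac, length.out = scan_steps + 1)[-1]
  cuts <- vapply(fracs, function(f) cutree(h, h = hh(f)),
                 integer(n))                       # genes x scan levels
  rownames(cuts) <- genes

  ## recursive adaptive branch decomposition: split a branch at the
  ## first scanned height where >= 2 size-qualified cores appear
  decompose <- function(gene_set, level) {
    lev <- level
    while (lev <= length(fracs)) {
      sub <- split(gene_set, cuts[gene_set, lev])
      cores <- sub[lengths(sub) >= min_cluster_size]
      if (length(cores) >= 2) {
        small <- sub[lengths(sub) < min_cluster_size]
        parts <- lapply(cores, function(g) decompose(g, lev + 1))
        if (length(small)) {
          egs <- lapply(parts, function(p) .eigengene(expr, unlist(p[[1]])))
          ## attach leftovers to the first (largest-height) piece of the
          ## best-correlated part
          for (b in small) {
            e <- .eigengene(expr, b)
            cors <- vapply(egs, function(x) cor(e, x), numeric(1))
            j <- which.max(cors)
            if (cors[j] > rescue_cor)
              parts[[j]][[1]] <- c(parts[[j]][[1]], b)
          }
        }
        return(do.call(c, lapply(parts, identity)))
      }
      lev <- lev + 1
    }
    list(gene_set)
  }

  cl_shallow <- cutree(h, h = hh(0.95))
  nxt <- 0L
  for (S in unique(cl_shallow)) {
    gS <- genes[cl_shallow == S]
    if (length(gS) < min_cluster_size) next
    for (mod_genes in decompose(gS, 1L)) {
      if (length(mod_genes) < min_cluster_size) next
      nxt <- nxt + 1L
      labels[mod_genes] <- nxt
    }
  }
  ## module-membership pruning
  if (nxt > 0 && kme_min > 0) {
    E <- .eigengeneMatrix(expr, labels)
    for (m in seq_len(ncol(E))) {
      g <- names(labels)[labels == m]
      kme <- as.numeric(cor(t(expr[g, , drop = FALSE]), E[, m]))
      labels[g[kme < kme_min]] <- 0L
    }
  }
  .newAssignment(labels, expr)
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the module pair whose eigengene correlation is
#' highest, as long as it exceeds \code{merge_cor}; eigengenes are
#' recomputed after every merge. Labels are re-ordered by descending
#' size on return.
#'
#' @param assignment a [ModuleAssignment-class].
#' @param expr the expression matrix (genes x samples).
#' @param merge_cor eigengene correlation above which two modules are
#'   considered the same pattern (default 0.85).
#' @return a [ModuleAssignment-class].
#' @export
mergeSimilarModules <- function(assignment, expr, merge_cor = 0.85) {
  stopifnot(is(assignment, "ModuleAssignment"))
  expr <- as.matrix(expr)
  labels <- assignment@labels
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    E <- .eigengeneMatrix(expr, labels)
    C <- cor(E)
    diag(C) <- -Inf
    ij <- arrayInd(which.max(C), dim(C))
    if (C[ij] <= merge_cor) break
    keep <- mods[min(ij)]
    drop <- mods[max(ij)]
    labels[labels == drop] <- keep
  }
  .newAssignment(labels, expr)
}

#' Call stage-specific modules from eigengene z-profiles
#'
#' Each eigengene is z-scored across samples; a module is specific to a
#' condition when its mean z in that condition reaches
#' \code{z_threshold} and stays below the threshold in every other
#' condition.
#'
#' @param assignment a [ModuleAssignment-class] with eigengenes.
#' @param condition factor of sample conditions, aligned with the
#'   eigengene rows; every condition needs >= 2 samples.
#' @param z_threshold mean-z cutoff for a peak (default 0.8).
#' @return the assignment with \code{stageZ} (modules x conditions) and
#'   \code{specificStage} filled in.
#' @export
stageSpecificity <- function(assignment, condition, z_threshold = 0.8) {
  stopifnot(is(assignment, "ModuleAssignment"))
  condition <- as.factor(condition)
  if (any(table(condition) < 2))
    stop("every condition needs at least 2 samples")
  E <- assignment@eigengenes
  if (nrow(E) != length(condition))
    stop("condition length must match eigengene rows")
  if (!ncol(E)) {
    assignment@stageZ <- matrix(0, 0, nlevels(condition),
                                dimnames = list(NULL, levels(condition)))
    assignment@specificStage <- character(0)
    return(assignment)
  }
  Z <- scale(E)
  zprof <- matrix(0, ncol(E), nlevels(condition),
                  dimnames = list(colnames(E), levels(condition)))
  for (lev in levels(condition))
    zprof[, lev] <- colMeans(Z[condition == lev, , drop = FALSE])
  spec <- apply(zprof, 1, function(z) {
    hit <- which(z >= z_threshold)
    if (length(hit) == 1) colnames(zprof)[hit] else NA_character_
  })
  assignment@stageZ <- zprof
  assignment@specificStage <- spec
  assignment
}
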