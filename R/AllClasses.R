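#' @import methods
#' @importFrom stats cor median quantile var sd prcomp dist hclust cutree
#'   as.dist phyper pnorm p.adjust rnbinom rlnorm rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

#' Unsigned weighted co-expression network
#'
#' Holds the three matrices of a weighted gene co-expression network built
#' from an expression matrix: the unsigned similarity \eqn{s_{ij} =
#' |cor(x_i, x_j)|}, the soft-thresholded adjacency \eqn{a_{ij} =
#' s_{ij}^\beta}, and the topological overlap matrix (TOM) used as the
#' clustering similarity.
#'
#' @slot genes character vector of gene identifiers (row/column names of
#'   the matrices).
#' @slot similarity numeric matrix, absolute Pearson correlation.
#' @slot adjacency numeric matrix, \code{similarity^beta}.
#' @slot tom numeric matrix, topological overlap.
#' @slot beta numeric(1), the soft-threshold power.
#'
#' @seealso [buildNetwork()], [detectModules()]
#' @export
setClass("CoexpressionNetwork",
  representation(
    genes      = "character",
    similarity = "matrix",
    adjacency  = "matrix",
    tom        = "matrix",
    beta       = "numeric"
  )
)

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  n <- length(object@genes)
  for (nm in c("similarity", "adjacency", "tom")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n)))
      msg <- c(msg, sprintf("%s must be %d x %d", nm, n, n))
    else {
      if (max(abs(m - t(m))) > 1e-8)
        msg <- c(msg, sprintf("%s must be symmetric", nm))
      if (min(m) < -1e-12 || max(m) > 1 + 1e-12)
        msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
      if (max(abs(diag(m) - 1)) > 1e-8)
        msg <- c(msg, sprintf("%s must have unit diagonal", nm))
    }
  }
  if (length(object@beta) != 1L || object@beta < 1)
    msg <- c(msg, "beta must be a single power >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork with", length(object@genes), "genes\n")
  cat("  soft-threshold power beta =", object@beta, "\n")
  off <- object@tom[upper.tri(object@tom)]
  if (length(off))
    cat(sprintf("  TOM off-diagonal range: [%.4f, %.4f]\n",
                min(off), max(off)))
})

#' Module assignment with eigengenes and stage-specificity calls
#'
#' Result of module detection on a [CoexpressionNetwork-class]. Genes not
#' assigned to any module carry label 0. Eigengenes are the first
#' principal component of each module's standardized expression
#' submatrix, oriented so that the average correlation with member genes
#' is non-negative. After [stageSpecificity()] the per-condition mean
#' eigengene z-scores and the stage-specificity call are filled in.
#'
#' @slot labels named integer vector, gene -> module label (0 = none).
#' @slot eigengenes numeric matrix, samples x modules.
#' @slot sizes named integer vector of module sizes.
#' @slot stageZ numeric matrix, modules x conditions, mean eigengene
#'   z-score per condition (0 x 0 until [stageSpecificity()] is run).
#' @slot specificStage named character vector, module -> condition label
#'   or \code{NA} when the module is not specific to a single condition.
#'
#' @export
setClass("ModuleAssignment",
  representation(
    labels        = "integer",
    eigengenes    = "matrix",
    sizes         = "integer",
    stageZ        = "matrix",
    specificStage = "character"
  )
)

setValidity("ModuleAssignment", function(object) {
  msg <- character()
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by gene")
  if (any(object@labels < 0))
    msg <- c(msg, "labels must be >= 0")
  k <- length(object@sizes)
  if (k > 0 && ncol(object@eigengenes) != k)
    msg <- c(msg, "one eigengene column per module required")
  tab <- table(object@labels[object@labels > 0])
  if (k > 0 && !identical(unname(as.integer(tab[as.character(seq_len(k))])),
                          unname(object@sizes)))
    msg <- c(msg, "sizes must match label counts")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModuleAssignment", function(object) {
  k <- length(object@sizes)
  cat("ModuleAssignment:", k, "modules over",
      length(object@labels), "genes\n")
  if (k) {
    cat("  sizes:", paste(object@sizes, collapse = ", "), "\n")
    cat("  unassigned:", sum(object@labels == 0), "\n")
  }
  if (length(object@specificStage)) {
    sp <- object@specificStage[!is.na(object@specificStage)]
    cat("  stage-specific modules:", length(sp), "\n")
  }
})

#' Resolved one-target-per-source orthology map
#'
#' Each source gene maps to at most one target gene, with the rule that
#' won the assignment (\code{name_match}, \code{metric_rank}, or
#' \code{sole_candidate}). Targets claimed by two or more source genes
#' after many-to-one reduction are recorded in
#' \code{multiSourceTargets}; downstream reporting marks them with an
#' asterisk.
#'
#' @slot entries data.frame with columns \code{src_id}, \code{tgt_id},
#'   \code{winning_rule}.
#' @slot multiSourceTargets character vector of target ids mapped from
#'   at least two sources.
#'
#' @seealso [resolveOrthologs()]
#' @export
setClass("OrthologyMap",
  representation(
    entries            = "data.frame",
    multiSourceTargets = "character"
  )
)

setValidity("OrthologyMap", function(object) {
  msg <- character()
  e <- object@entries
  need <- c("src_id", "tgt_id", "winning_rule")
  if (!all(need %in% names(e)))
    msg <- c(msg, paste("entries must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(e$src_id))
      msg <- c(msg, "each src_id may appear at most once")
    multi <- names(which(table(e$tgt_id) >= 2))
    if (!setequal(multi, object@multiSourceTargets))
      msg <- c(msg, "multiSourceTargets inconsistent with entries")
    if (!all(e$winning_rule %in%
             c("name_match", "metric_rank", "sole_candidate")))
      msg <- c(msg, "unknown winning_rule value")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "OrthologyMap", function(object) {
  cat("OrthologyMap:", nrow(object@entries), "source genes resolved\n")
  if (nrow(object@entries)) {
    tab <- table(object@entries$winning_rule)
    cat("  by rule:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  cat("  multi-source targets:", length(object@multiSourceTargets), "\n")
})

# ---- accessors -------------------------------------------------------------

#' @describeIn CoexpressionNetwork-class the topological overlap matrix.
#' @param object a \code{CoexpressionNetwork}.
#' @export
tomMatrix <- function(object) {
  stopifnot(is(object, "CoexpressionNetwork"))
  object@tom
}

#' @describeIn CoexpressionNetwork-class the soft-thresholded adjacency.
#' @export
adjacencyMatrix <- function(object) {
  stopifnot(is(object, "CoexpressionNetwork"))
  object@adjacency
}

#' @describeIn ModuleAssignment-class named per-gene module labels.
#' @param object a \code{ModuleAssignment}.
#' @export
moduleLabels <- function(object) {
  stopifnot(is(object, "ModuleAssignment"))
  object@labels
}

#' @describeIn ModuleAssignment-class samples x modules eigengene matrix.
#' @export
moduleEigengenes <- function(object) {
  stopifnot(is(object, "ModuleAssignment"))
  object@eigengenes
}

#' @describeIn ModuleAssignment-class per-module stage-specificity call
#'   (NA until [stageSpecificity()] has been run).
#' @export
specificStages <- function(object) {
  stopifnot(is(object, "ModuleAssignment"))
  object@specificStage
}

#' @describeIn OrthologyMap-class the resolved source-to-target table.
#' @param object an \code{OrthologyMap}.
#' @export
orthologEntries <- function(object) {
  stopifnot(is(object, "OrthologyMap"))
  object@entries
}

#' @describeIn OrthologyMap-class target ids mapped from several sources
#'   (asterisk flags).
#' @export
multiSourceTargets <- function(object) {
  stopifnot(is(object, "OrthologyMap"))
  object@multiSourceTargets
}
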