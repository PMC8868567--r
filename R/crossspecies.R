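#' Translate a differential expression table into target-species ids
#'
#' Gene ids are translated through a resolved [OrthologyMap-class].
#' Unmapped genes are dropped (their number is attached as attribute
#' \code{n_unmapped}). When two source genes map onto the same target
#' with conflicting information, the entry with the larger absolute
#' log2 fold change wins and the row is flagged in \code{collision}.
#' Rows whose target is claimed by several source genes carry
#' \code{multi_ortholog = TRUE} (the asterisk flag of the reports).
#'
#' @param deg_table data.frame with columns \code{gene_id},
#'   \code{log2fc}, \code{fdr}, \code{direction}.
#' @param map an [OrthologyMap-class].
#' @param keep \code{"de"} (default) keeps only Up/Down genes,
#'   \code{"all"} also carries NS genes through (needed for the masked
#'   union fold-change matrix).
#' @return data.frame in target id space with columns \code{gene_id},
#'   \code{log2fc}, \code{fdr}, \code{direction}, \code{collision},
#'   \code{multi_ortholog}.
#' @export
mapToTargetSpace <- function(deg_table, map, keep = c("de", "all")) {
  keep <- match.arg(keep)
  stopifnot(is(map, "OrthologyMap"))
  tab <- deg_table
  if (keep == "de")
    tab <- tab[tab$direction %in% c("Up", "Down"), , drop = FALSE]
  e <- map@entries
  idx <- match(tab$gene_id, e$src_id)
  n_unmapped <- sum(is.na(idx))
  tab <- tab[!is.na(idx), , drop = FALSE]
  tab$gene_id <- e$tgt_id[idx[!is.na(idx)]]
  tab$collision <- logical(nrow(tab))
  if (nrow(tab)) {
    ## per target keep the strongest entry
    ord <- order(tab$gene_id, -abs(tab$log2fc))
    tab <- tab[ord, , drop = FALSE]
    dup <- duplicated(tab$gene_id)
    dup_ids <- unique(tab$gene_id[dup])
    conflict <- vapply(dup_ids, function(g) {
      d <- tab$direction[tab$gene_id == g]
      d <- d[d %in% c("Up", "Down")]
      length(unique(d)) > 1
    }, logical(1))
    tab <- tab[!dup, , drop = FALSE]
    tab$collision[tab$gene_id %in% dup_ids[conflict]] <- TRUE
  }
  tab$multi_ortholog <- tab$gene_id %in% map@multiSourceTargets
  rownames(tab) <- NULL
  attr(tab, "n_unmapped") <- n_unmapped
  tab
}

.directionalOnly <- function(tab)
  tab[tab$direction %in% c("Up", "Down"), , drop = FALSE]

#' Direction-stratified intersection of two DEG sets
#'
#' Counts the genes present in both sets, splits the shared genes into
#' same-direction (both Up or both Down) and opposite, reports the
#' per-direction exclusive counts of each set, and quantifies the
#' agreement by the signed Jaccard index
#' \eqn{(same - opposite) / |union|}.
#'
#' @param a,b data.frames with columns \code{gene_id} and
#'   \code{direction} (only Up/Down rows are used), in the same id
#'   space.
#' @return list with counts \code{shared}, \code{same_direction},
#'   \code{opposite}, \code{unique_a}, \code{unique_b} (each a named
#'   Up/Down vector), \code{similarity}, and the member id lists
#'   (\code{shared_ids}, \code{same_direction_ids},
#'   \code{opposite_ids}).
#' @export
intersectDirectional <- function(a, b) {
  a <- .directionalOnly(a)
  b <- .directionalOnly(b)
  if (anyDuplicated(a$gene_id) || anyDuplicated(b$gene_id))
    stop("a gene may carry only one direction per set")
  da <- setNames(a$direction, a$gene_id)
  db <- setNames(b$direction, b$gene_id)
  shared_ids <- intersect(names(da), names(db))
  same_ids <- shared_ids[da[shared_ids] == db[shared_ids]]
  opp_ids <- setdiff(shared_ids, same_ids)
  cntByDir <- function(d, ids)
    c(Up = sum(d[ids] == "Up"), Down = sum(d[ids] == "Down"))
  ua <- setdiff(names(da), shared_ids)
  ub <- setdiff(names(db), shared_ids)
  union_n <- length(union(names(da), names(db)))
  sim <- if (union_n == 0) 0 else
    (length(same_ids) - length(opp_ids)) / union_n
  out <- list(shared = length(shared_ids),
              same_direction = length(same_ids),
              opposite = length(opp_ids),
              unique_a = cntByDir(da, ua),
              unique_b = cntByDir(db, ub),
              similarity = sim,
              shared_ids = shared_ids,
              same_direction_ids = same_ids,
              opposite_ids = opp_ids)
  stopifnot(out$same_direction + out$opposite == out$shared,
            sum(out$unique_a) + out$shared == length(da))
  out
}

#' Exclusive intersection regions of several directional DEG sets
#'
#' The regions of an UpSet plot: for every nonempty subset of set
#' labels and each direction, the number of genes carrying that
#' direction in exactly those sets. Stratification by direction means a
#' gene Up in one set and Down in another contributes to two
#' single-set regions rather than to a shared one. Regions of one
#' direction are disjoint and sum to that direction's union size.
#'
#' @param sets named list (>= 2) of data.frames with \code{gene_id} and
#'   \code{direction}.
#' @return data.frame with columns \code{region} (set labels joined by
#'   "+"), \code{direction}, \code{degree}, \code{count}.
#' @export
upsetExclusiveRegions <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)))
    stop("need >= 2 named sets")
  labs <- names(sets)
  out <- list()
  for (dir in c("Up", "Down")) {
    ids <- lapply(sets, function(s)
      s$gene_id[s$direction == dir])
    uni <- unique(unlist(ids))
    if (!length(uni)) next
    memb <- vapply(ids, function(g) uni %in% g, logical(length(uni)))
    if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1)
    profile <- apply(memb, 1, function(r)
      paste(labs[r], collapse = "+"))
    tab <- table(profile)
    out[[dir]] <- data.frame(region = names(tab), direction = dir,
                             degree = lengths(strsplit(names(tab),
                                                       "+", fixed = TRUE)),
                             count = as.integer(tab))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Masked union log2 fold-change matrix across stages and cancers
#'
#' Rows are the genes differentially expressed in at least one
#' regeneration stage and present (either direction) in at least one
#' cancer DEG set; columns are the ordered conditions. Cells hold the
#' log2 fold change, masked (NA) where the regulation is weak
#' (fold change below \code{fc_up} in both directions) or not supported
#' (\code{fdr > mask_fdr}). Rows whose target id aggregates several
#' source orthologs are flagged (the asterisk of the report).
#'
#' @param stage_tables named list of mapped stage tables
#'   (\code{keep = "all"} output of [mapToTargetSpace()]).
#' @param cancer_tables named list of cancer DE tables (target id
#'   space, full universe with \code{direction}).
#' @param mask_fdr FDR above which a cell is masked (default 0.1).
#' @param fc_up fold-change magnitude below which a cell is masked
#'   (default 1.5).
#' @return list with \code{log2fc} (genes x conditions matrix, masked
#'   cells NA), \code{masked} (logical matrix), and
#'   \code{multi_ortholog} (named logical per row).
#' @export
buildUnionMatrix <- function(stage_tables, cancer_tables,
                             mask_fdr = 0.1, fc_up = 1.5) {
  if (is.null(names(stage_tables)) || is.null(names(cancer_tables)))
    stop("stage_tables and cancer_tables must be named lists")
  all_tabs <- c(stage_tables, cancer_tables)
  de_stage <- unique(unlist(lapply(stage_tables, function(s)
    s$gene_id[s$direction %in% c("Up", "Down")])))
  in_cancer <- unique(unlist(lapply(cancer_tables, function(s)
    s$gene_id[s$direction %in% c("Up", "Down")])))
  rows <- intersect(de_stage, in_cancer)
  conds <- names(all_tabs)
  lfc <- matrix(NA_real_, length(rows), length(conds),
                dimnames = list(rows, conds))
  masked <- matrix(TRUE, length(rows), length(conds),
                   dimnames = list(rows, conds))
  for (cn in conds) {
    tab <- all_tabs[[cn]]
    idx <- match(rows, tab$gene_id)
    l <- tab$log2fc[idx]
    f <- tab$fdr[idx]
    weak <- is.na(l) | is.na(f) | f > mask_fdr | 2^abs(l) < fc_up
    lfc[, cn] <- ifelse(weak, NA_real_, l)
    masked[, cn] <- weak
  }
  multi <- setNames(rep(FALSE, length(rows)), rows)
  for (tab in stage_tables)
    if (!is.null(tab$multi_ortholog)) {
      hit <- tab$gene_id[tab$multi_ortholog]
      multi[rows %in% hit] <- TRUE
    }
  list(log2fc = lfc, masked = masked, multi_ortholog = multi)
}

#' Rank regeneration stages by similarity to each cancer
#'
#' Similarity of a stage to a cancer is the signed Jaccard index of the
#' two directional DEG sets: concordant minus discordant shared genes,
#' divided by the union size. Stages are ranked per cancer and overall
#' by the mean similarity across cancers.
#'
#' @param stage_sets named list (>= 2) of directional stage tables.
#' @param cancer_sets named list of directional cancer tables.
#' @return list with \code{table} (stage x cancer grid of similarity
#'   and counts), \code{per_cancer} (named list of stage orderings) and
#'   \code{overall} (stages ordered by decreasing mean similarity).
#' @export
rankStageSimilarity <- function(stage_sets, cancer_sets) {
  if (length(stage_sets) < 2) stop("need >= 2 stages")
  grid <- expand.grid(stage = names(stage_sets),
                      cancer = names(cancer_sets),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cmp <- intersectDirectional(stage_sets[[grid$stage[i]]],
                                cancer_sets[[grid$cancer[i]]])
    data.frame(stage = grid$stage[i], cancer = grid$cancer[i],
               shared = cmp$shared, same_direction = cmp$same_direction,
               opposite = cmp$opposite, similarity = cmp$similarity)
  }))
  per_cancer <- lapply(split(res, res$cancer), function(d)
    d$stage[order(-d$similarity)])
  mean_sim <- tapply(res$similarity, res$stage, mean)
  overall <- names(sort(mean_sim, decreasing = TRUE))
  list(table = res, per_cancer = per_cancer, overall = overall)
}

#' Percentage of DEGs unique to each set
#'
#' \code{100 * exclusive / total}, rounded half-up to \code{digits}
#' decimals. A zero total yields NA (not applicable).
#'
#' @param total,exclusive numeric vectors of per-set total and
#'   exclusive DEG counts (\code{exclusive <= total}).
#' @param digits decimals to round to (half-up; default 1).
#' @return numeric vector of percentages.
#' @examples
#' percentUnique(c(6123, 4662, 1954), c(3983, 1796, 373))
#' @export
percentUnique <- function(total, exclusive, digits = 1) {
  if (any(exclusive > total))
    stop("exclusive counts cannot exceed totals")
  pct <- 100 * exclusive / total
  pct[total == 0] <- NA_real_
  f <- 10^digits
  floor(pct * f + 0.5) / f
}
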