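#' Gene-name similarity between species
#'
#' Under the default \code{"suffix"} rule two names are similar when
#' they are equal case-insensitively, or become equal after stripping
#' one trailing paralog suffix from the source name (a single trailing
#' "a" or "b", or a trailing ".N" ohnolog index) - the common
#' relationship between zebrafish paralog names and their mammalian
#' counterparts (e.g. "wnt7ba" vs "WNT7B"). The \code{"strict"} rule is
#' case-insensitive equality only.
#'
#' @param src_name,tgt_name character vectors of gene symbols (recycled
#'   to a common length).
#' @param rule \code{"suffix"} (default) or \code{"strict"}.
#' @return logical vector.
#' @examples
#' nameSimilar("gfap", "GFAP")      # TRUE
#' nameSimilar("wnt7ba", "WNT7B")   # TRUE (suffix stripped)
#' nameSimilar("kita", "KITLG")     # FALSE
#' @export
nameSimilar <- function(src_name, tgt_name, rule = c("suffix", "strict")) {
  rule <- match.arg(rule)
  s <- tolower(as.character(src_name))
  t <- tolower(as.character(tgt_name))
  eq <- s == t
  if (rule == "strict") return(eq)
  stripped <- sub("(\\.[0-9]+|[ab])$", "", s)
  eq | (stripped != s & stripped == t)
}

.orthologyColumns <- c("src_id", "src_name", "tgt_id", "tgt_name",
                       "high_confidence", "goc", "wga",
                       "pid_src_tgt", "pid_tgt_src")

#' Filter orthology candidates to confident or name-matched pairs
#'
#' Keeps candidate pairs flagged high confidence or whose gene names are
#' similar (see [nameSimilar()]). Malformed rows (empty identifiers or
#' an uninterpretable confidence flag) are reported with their row
#' numbers and skipped.
#'
#' @param table candidate data.frame with the columns of
#'   [simulateOrthology()] output.
#' @param name_rule passed to [nameSimilar()].
#' @return the filtered table, with a logical \code{name_matched}
#'   column added.
#' @export
filterCandidates <- function(table, name_rule = c("suffix", "strict")) {
  name_rule <- match.arg(name_rule)
  miss <- setdiff(.orthologyColumns, names(table))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  hc <- as.logical(table$high_confidence)
  bad <- !nzchar(as.character(table$src_id)) |
    !nzchar(as.character(table$tgt_id)) |
    is.na(table$src_id) | is.na(table$tgt_id) | is.na(hc)
  if (any(bad)) {
    warning("skipping malformed rows: ",
            paste(which(bad), collapse = ", "))
    table <- table[!bad, , drop = FALSE]
    hc <- hc[!bad]
  }
  nm <- nameSimilar(table$src_name, table$tgt_name, rule = name_rule)
  out <- table[hc | nm, , drop = FALSE]
  out$name_matched <- nm[hc | nm]
  rownames(out) <- NULL
  out
}

## lexicographic argmax over (goc, wga, pid_src_tgt, pid_tgt_src);
## missing metrics rank lowest; remaining ties broken by ascending tgt_id
.bestCandidate <- function(cand) {
  m <- as.matrix(cand[, c("goc", "wga", "pid_src_tgt", "pid_tgt_src")])
  m[is.na(m)] <- -Inf
  ord <- order(-m[, 1], -m[, 2], -m[, 3], -m[, 4],
               as.character(cand$tgt_id))
  cand[ord[1], , drop = FALSE]
}

#' Resolve each source gene to a unique target ortholog
#'
#' For every source gene: if any candidate pair is name-matched, the
#' choice is made among the name-matched candidates only; otherwise
#' among all candidates. The winner is the lexicographic maximum of
#' (gene-order conservation, whole-genome-alignment coverage, percent
#' identity source-to-target, percent identity target-to-source), with
#' missing metrics ranking lowest and remaining ties broken by
#' ascending target id. The winning rule is recorded as
#' \code{sole_candidate} (only one candidate existed),
#' \code{name_match}, or \code{metric_rank}.
#'
#' @param filtered a table from [filterCandidates()] (must carry the
#'   \code{name_matched} column; it is recomputed if absent).
#' @param name_rule passed to [nameSimilar()] if recomputation is
#'   needed.
#' @return an [OrthologyMap-class] (before many-to-one reduction).
#' @export
resolveUnique <- function(filtered, name_rule = c("suffix", "strict")) {
  name_rule <- match.arg(name_rule)
  if (!nrow(filtered)) {
    return(new("OrthologyMap",
               entries = data.frame(src_id = character(0),
                                    tgt_id = character(0),
                                    winning_rule = character(0)),
               multiSourceTargets = character(0)))
  }
  if (is.null(filtered$name_matched))
    filtered$name_matched <- nameSimilar(filtered$src_name,
                                         filtered$tgt_name, rule = name_rule)
  pieces <- split(filtered, as.character(filtered$src_id))
  entries <- do.call(rbind, lapply(pieces, function(cand) {
    rule <- if (nrow(cand) == 1) "sole_candidate"
            else if (any(cand$name_matched)) "name_match"
            else "metric_rank"
    pool <- if (any(cand$name_matched))
      cand[cand$name_matched, , drop = FALSE] else cand
    win <- .bestCandidate(pool)
    data.frame(src_id = as.character(win$src_id),
               tgt_id = as.character(win$tgt_id),
               winning_rule = rule)
  }))
  rownames(entries) <- NULL
  multi <- as.character(names(which(table(entries$tgt_id) >= 2)))
  new("OrthologyMap", entries = entries, multiSourceTargets = multi)
}

#' Reduce targets claimed by multiple source genes
#'
#' For every target mapped from two or more source genes, entries whose
#' underlying candidate pair is not high confidence are removed (the
#' source gene is dropped from the map, with a message). Targets still
#' mapped from several sources afterwards are recorded in
#' \code{multiSourceTargets} - the asterisk flags of downstream
#' reports.
#'
#' @param map an [OrthologyMap-class] from [resolveUnique()].
#' @param filtered the filtered candidate table the map was resolved
#'   from (used to look up the confidence flag of each winning pair).
#' @return the reduced [OrthologyMap-class].
#' @export
reduceManyToOne <- function(map, filtered) {
  stopifnot(is(map, "OrthologyMap"))
  e <- map@entries
  if (!nrow(e)) return(map)
  key <- paste(filtered$src_id, filtered$tgt_id, sep = "\r")
  hc <- tapply(as.logical(filtered$high_confidence), key, any)
  pair_hc <- as.logical(hc[paste(e$src_id, e$tgt_id, sep = "\r")])
  pair_hc[is.na(pair_hc)] <- FALSE
  shared <- as.character(names(which(table(e$tgt_id) >= 2)))
  drop <- e$tgt_id %in% shared & !pair_hc
  if (any(drop))
    message("dropping ", sum(drop),
            " source gene(s) with non-high-confidence pairs to shared targets: ",
            paste(head(e$src_id[drop], 5), collapse = ", "))
  e <- e[!drop, , drop = FALSE]
  rownames(e) <- NULL
  multi <- as.character(names(which(table(e$tgt_id) >= 2)))
  new("OrthologyMap", entries = e, multiSourceTargets = multi)
}

#' Resolve an orthology candidate table end to end
#'
#' Chains [filterCandidates()], [resolveUnique()] and
#' [reduceManyToOne()].
#'
#' @inheritParams filterCandidates
#' @return an [OrthologyMap-class].
#' @export
resolveOrthologs <- function(table, name_rule = c("suffix", "strict")) {
  name_rule <- match.arg(name_rule)
  filtered <- filterCandidates(table, name_rule = name_rule)
  map <- resolveUnique(filtered, name_rule = name_rule)
  reduceManyToOne(map, filtered)
}
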