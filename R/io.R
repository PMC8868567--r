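#' Read / write tab-separated count matrices
#'
#' Counts are stored as TSV with a header row of sample ids and a first
#' column \code{gene_id}.
#'
#' @param path file path.
#' @return \code{readCountsTSV}: integer matrix with gene rownames.
#' @export
readCountsTSV <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "gene_id") stop("first column must be 'gene_id'")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname readCountsTSV
#' @param counts integer matrix, genes x samples.
#' @export
writeCountsTSV <- function(counts, path) {
  d <- data.frame(gene_id = rownames(counts), counts,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a two-column sample design table
#'
#' TSV with columns \code{sample_id} and \code{condition}.
#'
#' @param path file path.
#' @return \code{readDesignTSV}: data.frame(sample_id, condition).
#' @export
readDesignTSV <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(d)))
    stop("design needs columns sample_id, condition")
  d
}

#' @rdname readDesignTSV
#' @param design data.frame with \code{sample_id} and \code{condition}.
#' @export
writeDesignTSV <- function(design, path) {
  write.table(design[, c("sample_id", "condition")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an orthology candidate table
#'
#' Fixed TSV header: src_id, src_name, tgt_id, tgt_name,
#' high_confidence, goc, wga, pid_src_tgt, pid_tgt_src.
#'
#' @param path file path.
#' @return \code{readOrthologyTSV}: the candidate data.frame.
#' @export
readOrthologyTSV <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.orthologyColumns, names(d))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  d$high_confidence <- as.logical(d$high_confidence)
  d
}

#' @rdname readOrthologyTSV
#' @param table the candidate data.frame.
#' @export
writeOrthologyTSV <- function(table, path) {
  write.table(table[, .orthologyColumns], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a resolved orthology map as TSV
#'
#' Columns: src_id, tgt_id, winning_rule, multi_source_flag.
#'
#' @param map an [OrthologyMap-class].
#' @param path file path.
#' @export
writeOrthologyMapTSV <- function(map, path) {
  e <- orthologEntries(map)
  e$multi_source_flag <- e$tgt_id %in% multiSourceTargets(map)
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one term per line, tab-separated term name,
#' description, then member gene ids.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets in GMT format
#'
#' @param terms named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector of term descriptions
#'   (defaults to "na").
#' @export
writeGMT <- function(terms, path, descriptions = NULL) {
  if (is.null(names(terms))) stop("terms must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(terms))
  lines <- vapply(seq_along(terms), function(i)
    paste(c(names(terms)[i], descriptions[i], terms[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a differential expression table as TSV
#'
#' @param table DE data.frame from [runDE()].
#' @param path file path.
#' @export
writeDETableTSV <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
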