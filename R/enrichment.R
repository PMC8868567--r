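#' EASE score: jackknifed one-tailed Fisher exact test
#'
#' The upper-tail hypergeometric probability of the 2x2 enrichment
#' table, computed after removing one gene from the query hits
#' (\eqn{k \to max(k - 1, 0)}). This penalization makes single-gene
#' overlaps non-significant (EASE p = 1 for k = 0 and k = 1) and is
#' uniformly more conservative than the plain Fisher test.
#'
#' @param k query genes in the term.
#' @param n query size.
#' @param K universe genes in the term.
#' @param N universe size.
#' @return one-tailed EASE p-value (vectorized over its arguments).
#' @examples
#' easeScore(0, 10, 10, 100)  # 1
#' easeScore(1, 10, 10, 100)  # 1
#' @export
easeScore <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0 |
          k > n | k > K | n > N | K > N))
    stop("inconsistent contingency counts")
  phyper(pmax(k - 1, 0) - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-tailed Fisher (hypergeometric upper-tail) p-value
#'
#' @inheritParams easeScore
#' @return upper-tail probability \eqn{P(X \ge k)}.
#' @export
fisherUpperTail <- function(k, n, K, N) {
  if (any(k < 0 | k > n | k > K | n > N | K > N))
    stop("inconsistent contingency counts")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE-score enrichment of a gene list against term collections
#'
#' Each term is intersected with the universe; the query is intersected
#' with the universe as well, so genes absent from the universe never
#' affect any count. BH correction is applied within each term category
#' separately (the term lists of different ontology branches are
#' reported separately downstream). Results are sorted by ascending
#' EASE p within category; \code{top_n} keeps the best terms per
#' category.
#'
#' @param query character vector of genes of interest.
#' @param universe character vector, the background gene universe
#'   (typically all genes tested for differential expression).
#' @param terms named list of character vectors (e.g. from
#'   [readGMT()] or [simulateAnnotation()]).
#' @param categories optional named character vector term -> category;
#'   terms without an entry fall into category \code{"geneset"}.
#' @param top_n optional single number or named per-category vector of
#'   how many top terms to keep.
#' @return data.frame with columns \code{term}, \code{category},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{fold_enrichment},
#'   \code{ease_p}, \code{fisher_p}, \code{fdr}.
#' @export
enrichGeneSets <- function(query, universe, terms, categories = NULL,
                           top_n = NULL) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  if (!length(query)) {
    warning("empty query after intersection with the universe")
    return(data.frame(term = character(0), category = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), fold_enrichment = numeric(0),
                      ease_p = numeric(0), fisher_p = numeric(0),
                      fdr = numeric(0)))
  }
  N <- length(universe)
  n <- length(query)
  Kv <- vapply(terms, function(g) length(intersect(g, universe)),
               integer(1))
  kv <- vapply(terms, function(g) length(intersect(g, query)),
               integer(1))
  cat_of <- setNames(rep("geneset", length(terms)), names(terms))
  if (!is.null(categories))
    cat_of[names(categories)] <- categories
  res <- data.frame(term = names(terms), category = unname(cat_of),
                    k = unname(kv), K = unname(Kv), n = n, N = N,
                    fold_enrichment = ifelse(Kv > 0,
                                             (kv / n) / (Kv / N), NA),
                    ease_p = easeScore(unname(kv), n, unname(Kv), N),
                    fisher_p = fisherUpperTail(unname(kv), n,
                                               unname(Kv), N))
  res <- res[res$K > 0, , drop = FALSE]
  res$fdr <- NA_real_
  for (cc in unique(res$category)) {
    j <- res$category == cc
    res$fdr[j] <- adjustBH(res$ease_p[j])
  }
  res <- res[order(res$category, res$ease_p), , drop = FALSE]
  if (!is.null(top_n)) {
    res <- do.call(rbind, lapply(split(res, res$category), function(d) {
      keep <- if (!is.null(names(top_n)) &&
                  d$category[1] %in% names(top_n))
        top_n[[d$category[1]]] else top_n[[1]]
      head(d, keep)
    }))
  }
  rownames(res) <- NULL
  res
}
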