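# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# step-up BH from the definition: adj p_(i) = min_{j >= i} min(1, n p_(j) / j)
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    vals <- vapply(i:n, function(j) min(1, n * ps[j] / j), numeric(1))
    adj[i] <- min(vals)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact hypergeometric upper tail by summation of binomial coefficients
hyper_tail_brute <- function(k_from, n, K, N) {
  if (k_from <= 0) return(1)
  i <- k_from:min(n, K)
  if (!length(i)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}
ease_brute <- function(k, n, K, N) hyper_tail_brute(max(k - 1, 0), n, K, N)
fisher_brute <- function(k, n, K, N) hyper_tail_brute(k, n, K, N)

# name similarity re-implemented scalar-wise for the resolver oracle
name_sim_brute <- function(s, t, rule = "suffix") {
  s <- tolower(s); t <- tolower(t)
  if (s == t) return(TRUE)
  if (rule == "strict") return(FALSE)
  st <- sub("(\\.[0-9]+|[ab])$", "", s)
  st != s && st == t
}

# exhaustive resolver: filter, per-source argmax by explicit tuple
# comparison, then many-to-one reduction
ortho_brute <- function(tab, rule = "suffix") {
  keep <- vapply(seq_len(nrow(tab)), function(i)
    isTRUE(as.logical(tab$high_confidence[i])) ||
      name_sim_brute(tab$src_name[i], tab$tgt_name[i], rule), logical(1))
  tab <- tab[keep, , drop = FALSE]
  entries <- NULL
  for (src in unique(as.character(tab$src_id))) {
    cand <- tab[tab$src_id == src, , drop = FALSE]
    nm <- vapply(seq_len(nrow(cand)), function(i)
      name_sim_brute(cand$src_name[i], cand$tgt_name[i], rule), logical(1))
    pool <- if (any(nm)) cand[nm, , drop = FALSE] else cand
    metric <- function(r) {
      v <- c(pool$goc[r], pool$wga[r], pool$pid_src_tgt[r],
             pool$pid_tgt_src[r])
      v[is.na(v)] <- -Inf
      v
    }
    best <- 1
    if (nrow(pool) > 1) for (r in 2:nrow(pool)) {
      a <- metric(r); b <- metric(best)
      pick <- NA
      for (j in 1:4) {
        if (a[j] > b[j]) { pick <- TRUE; break }
        if (a[j] < b[j]) { pick <- FALSE; break }
      }
      if (is.na(pick))
        pick <- as.character(pool$tgt_id[r]) < as.character(pool$tgt_id[best])
      if (pick) best <- r
    }
    rule_w <- if (nrow(cand) == 1) "sole_candidate"
              else if (any(nm)) "name_match" else "metric_rank"
    entries <- rbind(entries,
                     data.frame(src_id = src,
                                tgt_id = as.character(pool$tgt_id[best]),
                                winning_rule = rule_w))
  }
  if (is.null(entries))
    return(data.frame(src_id = character(0), tgt_id = character(0),
                      winning_rule = character(0)))
  drop <- logical(nrow(entries))
  for (t in unique(entries$tgt_id)) {
    idx <- which(entries$tgt_id == t)
    if (length(idx) < 2) next
    for (i in idx) {
      hc <- any(as.logical(tab$high_confidence[
        tab$src_id == entries$src_id[i] & tab$tgt_id == t]))
      if (!hc) drop[i] <- TRUE
    }
  }
  entries <- entries[!drop, , drop = FALSE]
  rownames(entries) <- NULL
  entries
}

# random candidate table mixing shared sources/targets, NAs, name matches
random_ortho_table <- function(n_rows) {
  src <- sprintf("z%d", sample.int(8, n_rows, replace = TRUE))
  tgt <- sprintf("H%d", sample.int(8, n_rows, replace = TRUE))
  base <- c("wnt7b", "gfap", "kit", "sox2")
  src_name <- paste0(sample(base, n_rows, replace = TRUE),
                     sample(c("", "a", "b", ".1"), n_rows, replace = TRUE))
  tgt_name <- sample(c(toupper(base), "XYZ1", "XYZ2"), n_rows,
                     replace = TRUE)
  mk <- function() {
    v <- round(runif(n_rows, 0, 100), 1)
    v[runif(n_rows) < 0.15] <- NA
    v
  }
  data.frame(src_id = src, src_name = src_name, tgt_id = tgt,
             tgt_name = tgt_name,
             high_confidence = runif(n_rows) < 0.6,
             goc = mk(), wga = mk(), pid_src_tgt = mk(),
             pid_tgt_src = mk())
}

# membership-profile enumeration for UpSet regions
upset_brute <- function(sets) {
  out <- list()
  for (dir in c("Up", "Down")) {
    ids <- lapply(sets, function(s) s$gene_id[s$direction == dir])
    uni <- unique(unlist(ids))
    cnt <- list()
    for (g in uni) {
      inset <- names(sets)[vapply(ids, function(x) g %in% x, logical(1))]
      key <- paste(inset, collapse = "+")
      cnt[[key]] <- (if (is.null(cnt[[key]])) 0 else cnt[[key]]) + 1
    }
    for (key in names(cnt))
      out[[paste(dir, key)]] <- data.frame(region = key, direction = dir,
                                           count = as.integer(cnt[[key]]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# random directional gene set over a shared universe
random_dirset <- function(universe, n) {
  g <- sample(universe, n)
  data.frame(gene_id = g,
             direction = sample(c("Up", "Down"), n, replace = TRUE),
             log2fc = rnorm(n, 0, 2), fdr = runif(n, 0, 0.05))
}
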