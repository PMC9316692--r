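# One over-representation core serving three uses: GO/pathway ORA on DEG
# lists, miRNA-target enrichment to nominate regulator miRNAs, and
# category-level ORA on miRNA sets. The hypergeometric upper tail is
# computed by exact summation of combinatorial terms (in log space); the
# Benjamini-Hochberg step-up is implemented literally. Both are the
# statistical core of the workflow and are cross-checked in the test
# suite against independent references.

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n items from a
#' universe of N containing K marked items, the probability of seeing at
#' least k marked. Computed by exact summation of
#' C(K, i) C(N-K, n-i) / C(N, n) over the upper tail in log space. Equals
#' the one-sided Fisher exact p-value for the corresponding 2x2 table.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K category size.
#' @param n query size.
#' @param N universe size (K <= N, n <= N).
#' @return probability in (0, 1].
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop_fmt("invalid hypergeometric arguments: k=%s K=%s n=%s N=%s",
             k, K, n, N)
  }
  if (k == 0) return(1)
  i <- k:min(K, n)
  terms <- exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  min(1, sum(terms))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Literal step-up rule: with p-values sorted ascending,
#' q_(i) = min over j >= i of p_(j) * m / j, clipped at 1; results are
#' returned in the input order.
#'
#' @param pvalues numeric vector of p-values in [0, 1] (NA passed through).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop_fmt("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  p <- pvalues[ok]
  m <- length(p)
  if (m > 0) {
    o <- order(p)
    q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    adj <- numeric(m)
    adj[o] <- q
    out[ok] <- adj
  }
  out
}

#' Over-representation analysis of a query set against named categories
#'
#' One hypergeometric upper-tail test per category with at least one
#' query member (after intersecting query and categories with the
#' universe); BH adjustment is applied across the tested categories only.
#' Query members outside the universe are dropped and reported via the
#' `"dropped"` attribute.
#'
#' @param query character vector of query entities (e.g. DEGs).
#' @param categories named list of character vectors.
#' @param universe character vector of all testable entities (e.g. every
#'   gene entering the DE analysis).
#' @param cfg a [pipeline_config()]; uses `min_category_size`,
#'   `max_category_size`, `fdr_alpha`.
#' @return an `enrichment_result` data frame sorted by p-value, with
#'   columns category, k, K, n, N, pvalue, padj, members, significant,
#'   and attributes `"dropped"` (query members outside the universe) and
#'   `"skipped"` (categories not tested: zero overlap or size bounds).
#' @export
ora <- function(query, categories, universe, cfg = pipeline_config()) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop_fmt("empty universe")
  query <- unique(as.character(query))
  if (length(query) == 0) stop_fmt("empty query")
  dropped <- setdiff(query, universe)
  query <- intersect(query, universe)
  if (length(query) == 0) stop_fmt("no query member is in the universe")
  n <- length(query); N <- length(universe)
  skipped <- character()
  rows <- list()
  for (nm in names(categories)) {
    cat_u <- intersect(unique(categories[[nm]]), universe)
    K <- length(cat_u)
    if (K < cfg$min_category_size || K > cfg$max_category_size) {
      skipped <- c(skipped, nm); next
    }
    members <- intersect(query, cat_u)
    k <- length(members)
    if (k == 0) { skipped <- c(skipped, nm); next }
    rows[[nm]] <- data.frame(
      category = nm, k = k, K = K, n = n, N = N,
      pvalue = hypergeom_upper(k, K, n, N),
      members = paste(sort(members), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    out <- data.frame(category = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), pvalue = numeric(),
                      padj = numeric(), members = character(),
                      significant = logical(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out$padj <- bh_adjust(out$pvalue)
    out$significant <- out$padj <= cfg$fdr_alpha
    out <- out[order(out$pvalue, out$category),
               c("category", "k", "K", "n", "N", "pvalue", "padj",
                 "members", "significant")]
    rownames(out) <- NULL
  }
  attr(out, "dropped") <- dropped
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' miRNA-target enrichment against a DEG set
#'
#' For each miRNA in the regulatory database, its target-gene set
#' (intersected with the universe) is a category; the DEG list is the
#' query. miRNAs whose targets are over-represented among the DEGs at
#' `padj <= fdr_alpha` are returned as the enriched set. By default all
#' miRNA->gene edges are used regardless of evidence; set
#' `cfg$filter_mirna_evidence` to restrict to `cfg$evidence_required`.
#'
#' @param degs a `deg_set` or character vector of DEG IDs.
#' @param db a [regdb()].
#' @param universe character vector of testable genes.
#' @param cfg a [pipeline_config()].
#' @return list with `mirnas` (enriched miRNA IDs) and `table` (the full
#'   `enrichment_result`).
#' @export
enrich_mirnas <- function(degs, db, universe, cfg = pipeline_config()) {
  stopifnot(inherits(db, "regdb"))
  genes <- if (inherits(degs, "deg_set")) degs$gene else as.character(degs)
  edges <- db[db$source_type == "mirna" & db$target_type == "gene", ,
              drop = FALSE]
  if (cfg$filter_mirna_evidence) {
    edges <- edges[edges$evidence == cfg$evidence_required, , drop = FALSE]
  }
  targets <- lapply(split(edges$target, edges$source), unique)
  targets <- lapply(targets, intersect, y = universe)
  targets <- targets[lengths(targets) > 0]
  if (length(genes) == 0) stop_fmt("empty query")
  if (length(targets) == 0) {
    warning("no miRNA has any target in the universe; empty enrichment")
    empty <- ora(genes, list(), universe, cfg)
    return(list(mirnas = character(), table = empty))
  }
  tab <- ora(genes, targets, universe, cfg)
  list(mirnas = tab$category[tab$significant], table = tab)
}
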