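# Two-group differential expression: median-of-ratios normalization, a
# negative binomial Wald test with method-of-moments gene-wise
# dispersion, threshold-based DEG calling, ontology-driven functional
# exclusion, and Venn-style overlaps between DEG sets. The test is a
# deliberately transparent NB Wald statistic (no dispersion shrinkage,
# independent filtering or outlier replacement); externally computed DE
# tables in the same column layout can be substituted at import.

#' Median-of-ratios size factors
#'
#' For each sample j, the factor is the median over genes (positive in
#' every sample) of count_gj divided by the gene's geometric mean across
#' samples. Factors are then normalized to geometric mean 1 across
#' samples, so a matrix with identical columns yields all-1 factors.
#'
#' @param cm a [count_matrix()].
#' @return named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop_fmt(paste("no gene has positive counts in every sample;",
                   "cannot form the median-of-ratios reference",
                   "(pseudo-reference fallback is disabled)"))
  }
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo[use]))
  })
  sf / exp(mean(log(sf)))
}

#' Negative binomial Wald test for two-group differential expression
#'
#' Counts are normalized by `factors`; per gene, the log2 fold change is
#' `log2((mean_B + c) / (mean_A + c))` with pseudocount `c`. The Wald
#' standard error uses the NB variance mu + alpha * mu^2 with a
#' method-of-moments gene-wise dispersion estimate floored at zero, and
#' p-values are two-sided normal tail probabilities, BH-adjusted.
#' Genes with all-zero counts in both groups are reported with
#' log2FC = 0 and p = 1, not dropped.
#'
#' @param cm a [count_matrix()] with two group levels.
#' @param factors size factors from [size_factors()]; computed if NULL.
#' @param pseudocount added to group means before the log ratio.
#' @return a `de_result` data frame with columns gene, baseMeanA,
#'   baseMeanB, log2FC, pvalue, padj.
#' @export
nb_wald_test <- function(cm, factors = NULL, pseudocount = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$group)) stop_fmt("count matrix carries no group labels")
  factors <- factors %||% size_factors(cm)
  norm <- sweep(cm$counts, 2, factors, "/")
  lv <- levels(cm$group)
  a <- norm[, cm$group == lv[1], drop = FALSE]
  b <- norm[, cm$group == lv[2], drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  m_a <- rowMeans(a); m_b <- rowMeans(b)
  v_a <- apply(a, 1, stats::var)
  v_b <- apply(b, 1, stats::var)
  # Method-of-moments dispersion per gene, pooled over the two groups and
  # floored at 0 (Poisson) when the sample variance is sub-Poisson.
  disp_of <- function(m, v) ifelse(m > 0, (v - m) / m^2, NA_real_)
  disp <- pmax(0, rowMeans(cbind(disp_of(m_a, v_a), disp_of(m_b, v_b)),
                           na.rm = TRUE))
  disp[is.nan(disp)] <- 0
  c0 <- pseudocount
  lfc <- log2((m_b + c0) / (m_a + c0))
  nb_var <- function(m, alpha) m + alpha * m^2
  se2 <- (nb_var(m_a, disp) / na / (m_a + c0)^2 +
          nb_var(m_b, disp) / nb / (m_b + c0)^2) / log(2)^2
  se <- sqrt(se2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  zero <- m_a == 0 & m_b == 0
  lfc[zero] <- 0
  p[zero | se == 0] <- 1
  out <- data.frame(gene = rownames(cm$counts),
                    baseMeanA = m_a, baseMeanB = m_b,
                    log2FC = lfc, pvalue = p,
                    padj = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Read an externally computed differential-expression table
#'
#' Accepts any table in the `de_results.tsv` layout (gene, baseMeanA,
#' baseMeanB, log2FC, pvalue, padj), allowing an external DE engine's
#' output to drive the downstream stages.
#'
#' @param path TSV path.
#' @return a `de_result` data frame.
#' @export
read_de_results <- function(path) {
  df <- read_tsv_checked(path, c("gene", "log2FC", "pvalue", "padj"))
  df$gene <- as.character(df$gene)
  if (anyDuplicated(df$gene)) stop_fmt("%s: duplicate gene IDs", path)
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE)) {
    stop_fmt("%s: padj outside [0, 1]", path)
  }
  class(df) <- c("de_result", "data.frame")
  df
}

#' Call differentially expressed genes at the configured thresholds
#'
#' A gene is kept iff `padj <= fdr_alpha` and `|log2FC| >= lfc_threshold`
#' (both boundaries inclusive); direction is the sign of the fold change.
#'
#' @param table a `de_result` from [nb_wald_test()] or [read_de_results()].
#' @param cfg a [pipeline_config()].
#' @param provenance optional label (e.g. the contrast name).
#' @return a `deg_set` data frame with columns gene, direction, log2FC,
#'   padj, and attribute `"provenance"`.
#' @export
call_degs <- function(table, cfg = pipeline_config(), provenance = NULL) {
  stopifnot(is.data.frame(table))
  if (!"padj" %in% names(table)) stop_fmt("table has no padj column")
  keep <- !is.na(table$padj) & table$padj <= cfg$fdr_alpha &
    abs(table$log2FC) >= cfg$lfc_threshold
  out <- data.frame(gene = table$gene[keep],
                    direction = ifelse(table$log2FC[keep] >= 0, "up", "down"),
                    log2FC = table$log2FC[keep],
                    padj = table$padj[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("deg_set", "data.frame")
  out
}

#' Remove DEGs annotated to excluded functional terms
#'
#' Drops every gene annotated (directly) to an excluded term or to any
#' descendant of one, following both `is_a` and `part_of` edges — the
#' usual ontology true-path convention. Used to strip e.g. stress
#' response and metabolism signatures before relapse-focused analysis.
#'
#' @param degs a `deg_set`.
#' @param annot an [annotation_map()].
#' @param dag the matching [go_dag()].
#' @param excluded_terms term IDs to exclude (must exist in the DAG).
#' @return list with `degs` (the filtered `deg_set`) and `removed`
#'   (character vector of removed genes).
#' @export
filter_functional_terms <- function(degs, annot, dag, excluded_terms) {
  stopifnot(inherits(degs, "deg_set"), inherits(dag, "go_dag"))
  excluded_terms <- unique(as.character(excluded_terms))
  unknown <- setdiff(excluded_terms, dag$terms)
  if (length(unknown) > 0) {
    stop_fmt("excluded term(s) not in DAG: %s", paste(unknown, collapse = ", "))
  }
  if (length(excluded_terms) == 0) {
    return(list(degs = degs, removed = character()))
  }
  banned <- term_descendants(dag, excluded_terms)
  hit <- vapply(degs$gene, function(g) {
    length(intersect(annot[[g]] %||% character(), banned)) > 0
  }, logical(1))
  removed <- degs$gene[hit]
  out <- degs[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(degs, "provenance")
  class(out) <- c("deg_set", "data.frame")
  list(degs = out, removed = removed)
}

# All descendants of `terms` (inclusive), following is_a and part_of.
term_descendants <- function(dag, terms) {
  out <- character()
  frontier <- terms
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    kids <- unlist(lapply(frontier, function(t) {
      dag$edges$child[dag$child_edges[[t]] %||% integer()]
    }), use.names = FALSE)
    frontier <- setdiff(unique(kids), out)
  }
  unique(out)
}

#' Venn-style overlaps between named gene sets
#'
#' Enumerates every non-empty membership pattern over the input sets and
#' reports counts and members per region. Region counts sum to the size
#' of the union.
#'
#' @param sets named list (>= 2) of character vectors or `deg_set`s.
#' @return data frame with one row per region: `region` (set names
#'   joined by "&"), `pattern` (e.g. "110"), `count`, `genes`
#'   (";"-joined).
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2) stop_fmt("need >= 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_fmt("sets must be named")
  }
  sets <- lapply(sets, function(s) {
    if (inherits(s, "deg_set")) unique(s$gene) else unique(as.character(s))
  })
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  k <- length(sets)
  all_patterns <- vapply(seq_len(2^k - 1), function(i) {
    paste(as.integer(intToBits(i)[seq_len(k)] == 1), collapse = "")
  }, "")
  rows <- lapply(all_patterns, function(p) {
    in_region <- universe[pattern == p]
    flags <- as.logical(as.integer(strsplit(p, "")[[1]]))
    data.frame(region = paste(names(sets)[flags], collapse = "&"),
               pattern = p, count = length(in_region),
               genes = paste(sort(in_region), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$count, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}
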