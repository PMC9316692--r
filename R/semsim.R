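# Topology-based GO semantic similarity (Wang's measure) between terms,
# best-match-average combination between genes, and the functional
# homogeneity test of a network's gene set against size-matched random
# gene sets using a one-sided two-sample Kolmogorov-Smirnov test.
#
# Wang's measure is corpus-free: each ancestor t of a term A carries a
# semantic contribution S_A(t), defined by S_A(A) = 1 and
# S_A(t) = max over edges (c -> t) within A's ancestor closure of
# w_rel * S_A(c), with per-relation weights w (is_a 0.8, part_of 0.6 by
# default). The similarity of A and B is the summed contribution of
# their common ancestors relative to their total semantic values.

wang_weights_default <- c(is_a = 0.8, part_of = 0.6)

# Ancestor closure of a term (inclusive), following child -> parent edges.
ancestor_closure <- function(dag, term) {
  out <- character()
  frontier <- term
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    up <- unlist(lapply(frontier, function(t) {
      dag$edges$parent[dag$parent_edges[[t]] %||% integer()]
    }), use.names = FALSE)
    frontier <- setdiff(unique(up), out)
  }
  unique(out)
}

# S-values of every ancestor of `term` (named vector, includes the term
# itself with S = 1), by memoized maximization over downward edges that
# stay inside the ancestor closure.
term_svalues <- function(dag, term, weights = wang_weights_default) {
  if (!term %in% dag$terms) stop_fmt("unknown term: %s", term)
  anc <- ancestor_closure(dag, term)
  S <- new.env(parent = emptyenv())
  assign(term, 1, envir = S)
  getS <- function(x) {
    if (exists(x, envir = S, inherits = FALSE)) {
      return(get(x, envir = S, inherits = FALSE))
    }
    idx <- dag$child_edges[[x]] %||% integer()
    idx <- idx[dag$edges$child[idx] %in% anc]
    vals <- vapply(idx, function(i) {
      unname(weights[[dag$edges$relation[i]]]) * getS(dag$edges$child[i])
    }, numeric(1))
    v <- max(vals)
    assign(x, v, envir = S)
    v
  }
  vapply(stats::setNames(anc, anc), getS, numeric(1))
}

#' Wang semantic similarity between two ontology terms
#'
#' @param dag a [go_dag()].
#' @param t1,t2 term IDs.
#' @param weights named per-relation contribution weights.
#' @return similarity in [0, 1]; 1 iff the terms are identical (for
#'   weights < 1).
#' @export
wang_term_sim <- function(dag, t1, t2, weights = wang_weights_default) {
  s1 <- term_svalues(dag, t1, weights)
  s2 <- term_svalues(dag, t2, weights)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# Pairwise Wang similarity matrix over a set of terms; computes each
# term's S-values once.
term_sim_matrix <- function(dag, terms, weights = wang_weights_default) {
  terms <- unique(terms)
  sv <- lapply(stats::setNames(terms, terms), term_svalues,
               dag = dag, weights = weights)
  tot <- vapply(sv, sum, numeric(1))
  m <- matrix(0, length(terms), length(terms), dimnames = list(terms, terms))
  for (i in seq_along(terms)) {
    for (j in i:length(terms)) {
      common <- intersect(names(sv[[i]]), names(sv[[j]]))
      val <- if (length(common) == 0) 0 else {
        sum(sv[[i]][common] + sv[[j]][common]) / (tot[i] + tot[j])
      }
      m[i, j] <- m[j, i] <- val
    }
  }
  m
}

# Best-match average over a precomputed term-similarity matrix.
bma_from_matrix <- function(term_m, terms1, terms2) {
  sub <- term_m[terms1, terms2, drop = FALSE]
  mean(c(apply(sub, 1, max), apply(sub, 2, max)))
}

#' Gene-level functional similarity (best-match average)
#'
#' Builds the term-similarity matrix between the two genes' direct
#' annotation sets and averages the row-wise and column-wise maxima.
#'
#' @param annot an [annotation_map()].
#' @param dag a [go_dag()].
#' @param g1,g2 gene IDs; both must carry at least one annotation.
#' @param weights per-relation Wang weights.
#' @return similarity in [0, 1].
#' @export
gene_pair_sim <- function(annot, dag, g1, g2,
                          weights = wang_weights_default) {
  t1 <- annot[[g1]]; t2 <- annot[[g2]]
  if (length(t1) == 0 || length(t2) == 0) {
    stop_fmt("gene(s) without annotation: %s",
             paste(c(g1, g2)[c(length(t1) == 0, length(t2) == 0)],
                   collapse = ", "))
  }
  m <- term_sim_matrix(dag, unique(c(t1, t2)), weights)
  bma_from_matrix(m, t1, t2)
}

# All pairwise gene similarities within `genes` using a shared term
# matrix; returns the vector of upper-triangle values.
pairwise_gene_sims <- function(genes, annot, term_m) {
  n <- length(genes)
  if (n < 2) return(numeric())
  tsets <- annot[genes]
  out <- numeric(n * (n - 1) / 2)
  idx <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      idx <- idx + 1L
      out[idx] <- bma_from_matrix(term_m, tsets[[i]], tsets[[j]])
    }
  }
  out
}

#' Functional-homogeneity test of a gene set against random gene sets
#'
#' Computes all pairwise best-match-average Wang similarities among the
#' annotated genes of `gene_set`, pools the pairwise similarities of
#' `cfg$n_random_sets` same-size random draws (without replacement) from
#' the annotated universe, and applies a one-sided two-sample
#' Kolmogorov-Smirnov test of whether the gene-set similarities are
#' stochastically greater than the random-pair similarities. The exact
#' small-sample p-value is used when both samples hold at most 25
#' values; otherwise the asymptotic approximation.
#'
#' @param gene_set character vector (>= 2 annotated genes).
#' @param annot an [annotation_map()].
#' @param dag a [go_dag()].
#' @param universe candidate genes for the random draws; defaults to all
#'   annotated genes in `annot`.
#' @param cfg a [pipeline_config()].
#' @param seed integer seed for the random draws.
#' @param weights per-relation Wang weights.
#' @return a `homogeneity_report`: list with `grn_scores`, `null_scores`,
#'   `ks_statistic`, `pvalue`, `set_size`, `n_random_sets`, `seed`.
#' @export
homogeneity_test <- function(gene_set, annot, dag, universe = NULL,
                             cfg = pipeline_config(), seed = cfg$rng_seed,
                             weights = wang_weights_default) {
  stopifnot(inherits(dag, "go_dag"))
  annotated <- names(annot)[lengths(annot) > 0]
  genes <- intersect(unique(as.character(gene_set)), annotated)
  if (length(genes) < 2) {
    stop_fmt("need >= 2 annotated genes in the set (got %d)", length(genes))
  }
  universe <- if (is.null(universe)) {
    annotated
  } else if (cfg$semsim_universe == "annotated") {
    intersect(unique(as.character(universe)), annotated)
  } else {
    unique(as.character(universe))
  }
  if (length(universe) < length(genes)) {
    stop_fmt("universe (%d) smaller than the gene set (%d)",
             length(universe), length(genes))
  }
  draw_pool <- intersect(universe, annotated)
  all_terms <- unique(unlist(annot[unique(c(genes, draw_pool))],
                             use.names = FALSE))
  term_m <- term_sim_matrix(dag, all_terms, weights)
  grn_scores <- pairwise_gene_sims(genes, annot, term_m)
  null_scores <- with_seed(seed, {
    unlist(lapply(seq_len(cfg$n_random_sets), function(r) {
      draw <- sample(draw_pool, length(genes))
      pairwise_gene_sims(draw, annot, term_m)
    }), use.names = FALSE)
  })
  exact <- length(grn_scores) <= 25 && length(null_scores) <= 25
  ks <- suppressWarnings(
    stats::ks.test(grn_scores, null_scores, alternative = "less",
                   exact = exact))
  structure(list(grn_scores = grn_scores, null_scores = null_scores,
                 ks_statistic = unname(ks$statistic),
                 pvalue = ks$p.value,
                 set_size = length(genes),
                 n_random_sets = cfg$n_random_sets,
                 seed = seed),
            class = "homogeneity_report")
}

#' @export
print.homogeneity_report <- function(x, ...) {
  cat(sprintf(paste0("homogeneity_report: %d genes (%d pairs) vs %d random",
                     " sets; D = %.4f, p = %.4g\n"),
              x$set_size, length(x$grn_scores), x$n_random_sets,
              x$ks_statistic, x$pvalue))
  invisible(x)
}

#' Empirical CDF table for a homogeneity report
#'
#' Returns the data behind the cumulative-distribution comparison plot:
#' the pooled sorted score grid with the ECDF of the network pairs and of
#' the random pairs at each score.
#'
#' @param report a `homogeneity_report`.
#' @return data frame with columns score, ecdf_network, ecdf_random.
#' @export
homogeneity_ecdf <- function(report) {
  stopifnot(inherits(report, "homogeneity_report"))
  grid <- sort(unique(c(report$grn_scores, report$null_scores)))
  data.frame(score = grid,
             ecdf_network = stats::ecdf(report$grn_scores)(grid),
             ecdf_random = stats::ecdf(report$null_scores)(grid))
}
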