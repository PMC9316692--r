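# Seeded generators for every input the pipeline consumes, each planting
# recoverable ground truth: differentially expressed genes in the count
# matrix, miRNAs that preferentially target them in the regulatory
# database, a functionally homogeneous gene module in the ontology, and a
# disease-association list. All generators are pure functions of their
# arguments (including the seed) and never touch the caller's RNG state.

#' Simulate a two-group RNA-seq count matrix with planted DE genes
#'
#' Counts are negative binomial with gene-wise baseline means drawn
#' log-normal(log 100, 1) and a common dispersion `alpha`, so that
#' variance = mu + alpha * mu^2. A `de_fraction` subset of genes has its
#' group-B mean multiplied by `2^(+/- lfc_mean)` with random sign.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_per_group samples per group (>= 2).
#' @param de_fraction fraction of genes planted as differentially
#'   expressed (0 <= f < 1).
#' @param lfc_mean absolute log2 fold change planted on DE genes.
#' @param dispersion NB dispersion alpha (> 0).
#' @param seed integer seed.
#' @return list with `counts` (a [count_matrix()], groups "A"/"B") and
#'   `truth` (list with `de_genes` data frame of gene/true_lfc, and the
#'   seed).
#' @export
simulate_counts <- function(n_genes = 2000, n_per_group = 5,
                            de_fraction = 0.1, lfc_mean = 2,
                            dispersion = 0.1, seed = 1) {
  if (n_genes < 10) stop_fmt("n_genes must be >= 10")
  if (n_per_group < 2) stop_fmt("n_per_group must be >= 2")
  if (de_fraction < 0 || de_fraction >= 1) {
    stop_fmt("de_fraction must lie in [0, 1)")
  }
  if (dispersion <= 0) stop_fmt("dispersion must be > 0")
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- c(sprintf("A%d", seq_len(n_per_group)),
                 sprintf("B%d", seq_len(n_per_group)))
    group <- rep(c("A", "B"), each = n_per_group)
    mu <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1)
    n_de <- floor(de_fraction * n_genes)
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer()
    sign <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric()
    mu_b <- mu
    mu_b[de_idx] <- mu[de_idx] * 2^(sign * lfc_mean)
    size <- 1 / dispersion
    counts <- matrix(0L, n_genes, 2 * n_per_group,
                     dimnames = list(genes, samples))
    for (j in seq_len(n_per_group)) {
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = size)
    }
    for (j in seq_len(n_per_group)) {
      counts[, n_per_group + j] <- stats::rnbinom(n_genes, mu = mu_b, size = size)
    }
    truth <- list(
      de_genes = data.frame(gene = genes[de_idx],
                            true_lfc = sign * lfc_mean,
                            stringsAsFactors = FALSE),
      baseline_mu = stats::setNames(mu, genes),
      seed = seed)
    list(counts = count_matrix(counts, group), truth = truth)
  })
}

#' Simulate a typed, evidence-labelled regulatory interaction database
#'
#' Background regulators target uniformly random genes; planted miRNAs
#' instead draw `planted_fraction` of their gene targets from a supplied
#' pool (typically the planted DE genes), so that a hypergeometric
#' miRNA-target enrichment test can recover them. Transcription factors
#' are drawn from the gene universe (a TF is itself a gene), so TF edges
#' can participate in DEG-restricted networks. All four edge classes
#' (tf->gene, tf->mirna, mirna->gene, mirna->mirna) are represented, and
#' every edge carries evidence "experimental" (with probability
#' `evidence_mix`) or "predicted".
#'
#' @param n_tfs,n_mirnas number of TF and miRNA regulators.
#' @param n_genes size of the gene universe (genes g0001..).
#' @param targets_per_regulator targets drawn per regulator.
#' @param planted_targets character vector (one planted miRNA) or list of
#'   vectors (one planted miRNA per element) of genes the planted
#'   miRNA(s) preferentially target; NULL plants nothing.
#' @param planted_fraction fraction of a planted miRNA's gene targets
#'   drawn from its pool (default 0.8).
#' @param evidence_mix probability an edge is labelled "experimental".
#' @param mirna_target_share fraction of a regulator's targets that are
#'   miRNAs rather than genes (default 0.1).
#' @param seed integer seed.
#' @return list with `regdb` (a [regdb()]) and `truth` (list with
#'   `enriched_mirnas`, the planted miRNA IDs, and `planted_pools`).
#' @export
simulate_regdb <- function(n_tfs = 50, n_mirnas = 100, n_genes = 2000,
                           targets_per_regulator = 50,
                           planted_targets = NULL, planted_fraction = 0.8,
                           evidence_mix = 0.7, mirna_target_share = 0.1,
                           seed = 1) {
  if (n_tfs < 1 || n_mirnas < 1 || n_genes < 1 || targets_per_regulator < 1) {
    stop_fmt("counts must be positive")
  }
  if (planted_fraction < 0 || planted_fraction > 1 ||
      evidence_mix < 0 || evidence_mix > 1) {
    stop_fmt("proportions must lie in [0, 1]")
  }
  if (!is.null(planted_targets) && !is.list(planted_targets)) {
    planted_targets <- list(planted_targets)
  }
  n_planted <- length(planted_targets)
  if (n_planted > n_mirnas) {
    stop_fmt("planted miRNA count (%d) exceeds n_mirnas (%d)",
             n_planted, n_mirnas)
  }
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    mirnas <- sprintf("mir-%03d", seq_len(n_mirnas))
    tfs <- sample(genes, n_tfs)
    planted_ids <- if (n_planted > 0) mirnas[seq_len(n_planted)] else character()

    draw_targets <- function(regulator, pool_genes) {
      k <- targets_per_regulator
      n_mir <- stats::rbinom(1, k, mirna_target_share)
      tgt_mir <- sample(setdiff(mirnas, regulator), min(n_mir, n_mirnas - 1))
      tgt_gene <- sample(setdiff(pool_genes, regulator), k - length(tgt_mir))
      list(gene = tgt_gene, mirna = tgt_mir)
    }

    rows <- list()
    add_rows <- function(src, src_type, tgt, tgt_type) {
      if (length(tgt) == 0) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        source = src, target = tgt, source_type = src_type,
        target_type = tgt_type, stringsAsFactors = FALSE)
    }
    for (tf in tfs) {
      tg <- draw_targets(tf, genes)
      add_rows(tf, "tf", tg$gene, "gene")
      add_rows(tf, "tf", tg$mirna, "mirna")
    }
    for (i in seq_along(mirnas)) {
      m <- mirnas[i]
      if (i <= n_planted) {
        pool <- intersect(planted_targets[[i]], genes)
        k_gene <- targets_per_regulator
        n_pool <- min(round(planted_fraction * k_gene), length(pool))
        tgt_pool <- sample(pool, n_pool)
        tgt_bg <- sample(setdiff(genes, c(pool, m)), k_gene - n_pool)
        add_rows(m, "mirna", c(tgt_pool, tgt_bg), "gene")
      } else {
        tg <- draw_targets(m, genes)
        add_rows(m, "mirna", tg$gene, "gene")
        add_rows(m, "mirna", tg$mirna, "mirna")
      }
    }
    df <- do.call(rbind, rows)
    df$evidence <- ifelse(stats::runif(nrow(df)) < evidence_mix,
                          "experimental", "predicted")
    db <- regdb(df)
    truth <- list(enriched_mirnas = planted_ids,
                  planted_pools = planted_targets,
                  tfs = tfs, seed = seed)
    list(regdb = db, truth = truth)
  })
}

#' Simulate an ontology DAG with a planted homogeneous gene module
#'
#' Builds a complete rooted tree of the given branching factor and depth
#' (child->parent `is_a` edges, a fraction relabelled `part_of`), adds a
#' few shortcut edges from leaves to non-parent depth-1 terms (so the
#' graph is a DAG, not a tree), annotates background genes to uniformly
#' random leaves, and annotates each planted module's genes to leaves
#' under a single depth-1 branch — giving the module high pairwise Wang
#' similarity by construction.
#'
#' @param branching children per internal term.
#' @param depth tree depth (root = depth 0; depth >= 2).
#' @param n_genes number of background genes (IDs g0001..).
#' @param module_genes character vector or list of vectors of gene IDs to
#'   plant as homogeneous modules (each module gets its own branch);
#'   NULL/empty plants nothing.
#' @param part_of_fraction fraction of tree edges labelled part_of.
#' @param shortcut_fraction fraction of leaves given an extra cross edge.
#' @param annots_per_gene maximum direct annotations per background gene.
#' @param seed integer seed.
#' @return list with `dag` ([go_dag()]), `annot` (annotation map over all
#'   genes incl. module genes) and `truth` (module gene sets and their
#'   branch roots).
#' @export
simulate_go <- function(branching = 3, depth = 3, n_genes = 300,
                        module_genes = NULL, part_of_fraction = 0.2,
                        shortcut_fraction = 0.1, annots_per_gene = 2,
                        seed = 1) {
  if (depth < 2) stop_fmt("depth must be >= 2")
  if (branching < 2) stop_fmt("branching must be >= 2")
  if (!is.null(module_genes) && !is.list(module_genes)) {
    module_genes <- list(module_genes)
  }
  module_genes <- module_genes %||% list()
  if (length(module_genes) > branching) {
    stop_fmt("at most %d planted modules supported (one branch each)", branching)
  }
  with_seed(seed, {
    n_terms <- sum(branching^(0:depth))
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    # Complete tree in breadth-first order: children of node i are at
    # branching*(i-1)+2 .. branching*i+1.
    child <- parent <- character()
    level <- integer(n_terms)
    level[1] <- 0L
    for (i in seq_len(n_terms)) {
      kids <- branching * (i - 1) + 1 + seq_len(branching)
      kids <- kids[kids <= n_terms]
      for (k in kids) {
        child <- c(child, terms[k]); parent <- c(parent, terms[i])
        level[k] <- level[i] + 1L
      }
    }
    relation <- ifelse(stats::runif(length(child)) < part_of_fraction,
                       "part_of", "is_a")
    leaves <- terms[level == depth]
    depth1 <- terms[level == 1L]
    # Shortcut edges: leaf -> random depth-1 term outside its own branch.
    branch_of <- function(t) {
      i <- match(t, terms)
      while (level[i] > 1L) i <- (i - 2) %/% branching + 1
      terms[i]
    }
    n_short <- round(shortcut_fraction * length(leaves))
    if (n_short > 0 && length(depth1) > 1) {
      sel <- sample(leaves, n_short)
      for (lf in sel) {
        tgt <- sample(setdiff(depth1, branch_of(lf)), 1)
        child <- c(child, lf); parent <- c(parent, tgt)
        relation <- c(relation, "part_of")
      }
    }
    dag <- go_dag(data.frame(child = child, parent = parent,
                             relation = relation, stringsAsFactors = FALSE))
    genes <- sprintf("g%04d", seq_len(n_genes))
    annot <- lapply(genes, function(g) {
      sample(leaves, sample.int(annots_per_gene, 1))
    })
    names(annot) <- genes
    # Planted modules: all annotations drawn from the leaves below one
    # depth-1 branch per module.
    module_roots <- if (length(module_genes) > 0) {
      sample(depth1, length(module_genes))
    } else {
      character()
    }
    for (mi in seq_along(module_genes)) {
      br_leaves <- leaves[vapply(leaves, branch_of, "") == module_roots[mi]]
      for (g in module_genes[[mi]]) {
        annot[[g]] <- sample(br_leaves, min(sample.int(annots_per_gene, 1),
                                            length(br_leaves)))
      }
    }
    truth <- list(homogeneous_modules = module_genes,
                  module_roots = module_roots, seed = seed)
    list(dag = dag, annot = annotation_map(annot, dag), truth = truth)
  })
}

#' Simulate a disease-association entity set
#'
#' Flags a random `flag_fraction` subset of `entities` plus everything in
#' `must_include`.
#'
#' @param entities candidate entity IDs.
#' @param flag_fraction probability each entity is flagged.
#' @param must_include entities flagged regardless of the draw.
#' @param seed integer seed.
#' @return character vector of flagged entities.
#' @export
simulate_disease <- function(entities, flag_fraction = 0.3,
                             must_include = character(), seed = 1) {
  if (flag_fraction < 0 || flag_fraction > 1) {
    stop_fmt("flag_fraction must lie in [0, 1]")
  }
  with_seed(seed, {
    flagged <- entities[stats::runif(length(entities)) < flag_fraction]
    sort(unique(c(flagged, must_include)))
  })
}
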