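# End-to-end orchestration: per contrast, differential expression ->
# threshold + functional exclusion -> miRNA-target enrichment -> network
# construction -> disease contextualization -> centralities -> hotspots
# -> functional-homogeneity validation, with BH adjustment applied
# across the homogeneity p-values of all contrasts in the run. The run
# manifest records the configuration snapshot, seeds and output digests,
# so deterministic stages re-run bit-identically.

#' Default synthetic study preset
#'
#' Generates every input the pipeline consumes, with planted ground
#' truth, for `n_contrasts` two-group contrasts sharing one gene
#' universe, one regulatory database, one ontology and one
#' disease-association list. Per contrast: a 2000-gene count matrix with
#' 5 samples per group, 10% planted DE genes at |log2FC| = 2 and NB
#' dispersion 0.1; one planted miRNA drawing 80% of its 50 targets from
#' that contrast's DE genes against a background of 99 miRNAs and 50 TFs
#' (70% of edges labelled experimental); an ontology module planting
#' each planted miRNA's DE targets under a single branch; and a disease
#' list flagging 30% of genes plus all planted miRNAs.
#'
#' @param seed master seed; per-generator streams are derived from it.
#' @param n_contrasts number of contrasts to simulate.
#' @param n_genes,n_per_group,de_fraction,lfc_mean,dispersion passed to
#'   [simulate_counts()].
#' @param out_dir optional directory: when given, all inputs are also
#'   written as TSV/GMT files (plus truth.tsv).
#' @return list with `inputs` (contrasts, regdb, disease, go) ready for
#'   [run_pipeline()] and `truth` (per-contrast planted DE genes,
#'   planted miRNAs, module genes).
#' @export
simulate_preset <- function(seed = 1, n_contrasts = 2, n_genes = 2000,
                            n_per_group = 5, de_fraction = 0.1,
                            lfc_mean = 2, dispersion = 0.1,
                            out_dir = NULL) {
  contrasts <- list()
  truth <- list(contrasts = list(), seed = seed)
  de_sets <- list()
  for (i in seq_len(n_contrasts)) {
    sim <- simulate_counts(n_genes = n_genes, n_per_group = n_per_group,
                           de_fraction = de_fraction, lfc_mean = lfc_mean,
                           dispersion = dispersion,
                           seed = derive_seed(seed, i))
    nm <- sprintf("contrast%d", i)
    contrasts[[nm]] <- sim$counts
    de_sets[[nm]] <- sim$truth$de_genes$gene
    truth$contrasts[[nm]] <- list(de_genes = sim$truth$de_genes)
  }
  reg <- simulate_regdb(n_tfs = 50, n_mirnas = 100, n_genes = n_genes,
                        targets_per_regulator = 50,
                        planted_targets = de_sets, planted_fraction = 0.8,
                        evidence_mix = 0.7,
                        seed = derive_seed(seed, 101))
  # Each contrast's homogeneous ontology module: the planted miRNA's
  # pool genes that it actually targets are a superset guess; use the
  # planted DE genes targeted by that contrast's planted miRNA.
  module_genes <- lapply(seq_len(n_contrasts), function(i) {
    m <- reg$truth$enriched_mirnas[i]
    tgts <- reg$regdb$target[reg$regdb$source == m &
                               reg$regdb$target_type == "gene"]
    intersect(tgts, de_sets[[i]])
  })
  go <- simulate_go(branching = 3, depth = 3, n_genes = n_genes,
                    module_genes = module_genes,
                    seed = derive_seed(seed, 202))
  disease <- simulate_disease(
    entities = sprintf("g%04d", seq_len(n_genes)),
    flag_fraction = 0.3,
    must_include = reg$truth$enriched_mirnas,
    seed = derive_seed(seed, 303))
  for (i in seq_len(n_contrasts)) {
    nm <- sprintf("contrast%d", i)
    truth$contrasts[[nm]]$enriched_mirna <- reg$truth$enriched_mirnas[i]
    truth$contrasts[[nm]]$module_genes <- module_genes[[i]]
  }
  truth$tfs <- reg$truth$tfs
  inputs <- list(contrasts = contrasts, regdb = reg$regdb,
                 disease = disease,
                 go = list(dag = go$dag, annot = go$annot))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(contrasts)) {
      write_count_matrix(contrasts[[nm]],
                         file.path(out_dir, paste0(nm, "_counts.tsv")),
                         file.path(out_dir, paste0(nm, "_groups.tsv")))
    }
    write_regdb(inputs$regdb, file.path(out_dir, "regdb.tsv"))
    write_disease(disease, file.path(out_dir, "disease.tsv"))
    write_go(go$dag, go$annot, file.path(out_dir, "go_edges.tsv"),
             file.path(out_dir, "go_annot.tsv"))
    truth_df <- do.call(rbind, lapply(names(truth$contrasts), function(nm) {
      tc <- truth$contrasts[[nm]]
      rbind(data.frame(contrast = nm, kind = "de_gene",
                       id = tc$de_genes$gene,
                       value = tc$de_genes$true_lfc),
            data.frame(contrast = nm, kind = "enriched_mirna",
                       id = tc$enriched_mirna, value = NA_real_),
            data.frame(contrast = nm, kind = "module_gene",
                       id = tc$module_genes, value = NA_real_))
    }))
    write_table(truth_df, file.path(out_dir, "truth.tsv"))
  }
  list(inputs = inputs, truth = truth)
}

#' Run the full relapse-network workflow
#'
#' Executes, per contrast: size-factor normalization and the NB Wald
#' test; DEG calling at the configured thresholds; exclusion of genes
#' annotated to the configured functional terms; miRNA-target
#' enrichment; network construction restricted to
#' experimentally supported interactions among DEGs and enriched miRNAs;
#' disease contextualization; centrality computation and hotspot
#' detection; and the functional-homogeneity test of the network's gene
#' nodes. Across contrasts, DEG-set overlaps are tabulated and the
#' homogeneity p-values are BH-adjusted. All stage outputs are written
#' under `out_dir/<contrast>/`, with run-level tables and
#' `manifest.json` at the top level.
#'
#' @param inputs list with `contrasts` (named list of [count_matrix()]),
#'   `regdb` (a [regdb()]), `disease` (character vector of associated
#'   entities), `go` (list with `dag`, `annot`).
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with per-contrast `results` and the
#'   `manifest` (also written as JSON).
#' @export
run_pipeline <- function(inputs, cfg = pipeline_config(), out_dir) {
  stopifnot(is.list(inputs), inherits(cfg, "pipeline_config"))
  contrasts <- inputs$contrasts
  if (length(contrasts) == 0) stop_fmt("no contrasts supplied")
  if (is.null(names(contrasts))) stop_fmt("contrasts must be named")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dag <- inputs$go$dag
  annot <- inputs$go$annot
  results <- list()
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  run_stage <- function(contrast, stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_fmt("stage '%s' failed for contrast '%s': %s",
               stage, contrast, conditionMessage(e))
    })
  }
  for (nm in names(contrasts)) {
    cdir <- file.path(out_dir, nm)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    cm <- contrasts[[nm]]
    de <- run_stage(nm, "diffexpr", {
      nb_wald_test(cm, size_factors(cm), pseudocount = cfg$pseudocount)
    })
    write_table(de, file.path(cdir, "de_results.tsv"))
    degs <- run_stage(nm, "call_degs", call_degs(de, cfg, provenance = nm))
    note("%s: %d DEGs at padj <= %g, |lfc| >= %g", nm, nrow(degs),
         cfg$fdr_alpha, cfg$lfc_threshold)
    removed <- character()
    if (length(cfg$excluded_go_terms) > 0) {
      filt <- run_stage(nm, "functional_filter", {
        filter_functional_terms(degs, annot, dag, cfg$excluded_go_terms)
      })
      degs <- filt$degs
      removed <- filt$removed
      note("%s: %d DEGs removed by functional-term exclusion, %d kept",
           nm, length(removed), nrow(degs))
    }
    write_table(degs, file.path(cdir, "degs.tsv"))
    universe <- de$gene
    enr <- run_stage(nm, "mirna_enrichment", {
      enrich_mirnas(degs, inputs$regdb, universe, cfg)
    })
    write_table(enr$table[names(enr$table) != "members"],
                file.path(cdir, "enrichment.tsv"))
    note("%s: %d miRNAs enriched of %d tested", nm, length(enr$mirnas),
         nrow(enr$table))
    grn <- run_stage(nm, "build_grn", {
      build_grn(degs, enr$mirnas, inputs$regdb, cfg)
    })
    note("%s: network %d nodes / %d edges before disease filter",
         nm, igraph::vcount(grn), igraph::ecount(grn))
    grn <- run_stage(nm, "contextualize", {
      contextualize_disease(grn, inputs$disease)
    })
    note("%s: network %d nodes / %d edges after disease filter",
         nm, igraph::vcount(grn), igraph::ecount(grn))
    write_network(grn, file.path(cdir, "network.sif"))
    hot <- character(); cent <- NULL; hom <- NULL
    if (igraph::vcount(grn) > 0) {
      cent <- run_stage(nm, "centralities", centralities(grn))
      write_table(cent, file.path(cdir, "centrality.tsv"))
      hot <- run_stage(nm, "hotspots", hotspots(cent, cfg))
      grn <- flag_hotspots(grn, hot)
      write_table(data.frame(node = hot,
                             kind = cent$kind[match(hot, cent$node)]),
                  file.path(cdir, "hotspots.tsv"))
      note("%s: %d hotspots (%d genes, %d miRNAs)", nm, length(hot),
           sum(cent$kind[match(hot, cent$node)] == "gene"),
           sum(cent$kind[match(hot, cent$node)] == "mirna"))
      gene_nodes <- cent$node[cent$kind == "gene"]
      annotated <- intersect(gene_nodes, names(annot)[lengths(annot) > 0])
      if (length(annotated) >= 2) {
        hom <- run_stage(nm, "homogeneity", {
          homogeneity_test(gene_nodes, annot, dag, cfg = cfg,
                           seed = derive_seed(cfg$rng_seed,
                                              match(nm, names(contrasts))))
        })
        write_table(homogeneity_ecdf(hom), file.path(cdir, "ecdf.tsv"))
      } else {
        note("%s: homogeneity test skipped (<2 annotated gene nodes)", nm)
      }
    }
    results[[nm]] <- list(de = de, degs = degs, removed = removed,
                          enrichment = enr, grn = grn,
                          centrality = cent, hotspots = hot,
                          homogeneity = hom)
  }
  # Cross-contrast accounting.
  if (length(contrasts) >= 2) {
    venn <- overlap_sets(lapply(results, function(r) r$degs))
    write_table(venn, file.path(out_dir, "venn.tsv"))
  } else {
    venn <- NULL
  }
  hom_p <- vapply(results, function(r) {
    if (is.null(r$homogeneity)) NA_real_ else r$homogeneity$pvalue
  }, numeric(1))
  hom_df <- data.frame(contrast = names(results),
                       n_genes = vapply(results, function(r) {
                         if (is.null(r$homogeneity)) NA_integer_
                         else r$homogeneity$set_size
                       }, integer(1)),
                       ks_statistic = vapply(results, function(r) {
                         if (is.null(r$homogeneity)) NA_real_
                         else r$homogeneity$ks_statistic
                       }, numeric(1)),
                       pvalue = hom_p,
                       padj = bh_adjust(hom_p),
                       row.names = NULL, stringsAsFactors = FALSE)
  write_table(hom_df, file.path(out_dir, "homogeneity.tsv"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  out_files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                            "manifest.json"))
  cfg_snapshot <- lapply(unclass(cfg), function(x) {
    if (is.numeric(x) && any(!is.finite(x))) as.character(x) else x
  })
  manifest <- list(
    contrasts = names(contrasts),
    config = cfg_snapshot,
    seed = cfg$rng_seed,
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(file.path(out_dir, out_files)))),
      out_files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, venn = venn, homogeneity = hom_df,
                 manifest = manifest))
}
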