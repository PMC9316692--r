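#' Pipeline configuration
#'
#' Bundles every tunable parameter of the workflow. The defaults are the
#' study's fixed analysis settings: differentially expressed genes are
#' called at an FDR of 5% with an absolute log2 fold change of at least
#' 1.5; hotspots are the top 10% of nodes per centrality measure;
#' functional-homogeneity p-values are computed against 100 random gene
#' sets; and only regulatory interactions backed by experimental evidence
#' enter the network.
#'
#' @param fdr_alpha significance cutoff applied to BH-adjusted p-values
#'   (probability, default 0.05).
#' @param lfc_threshold minimum absolute log2 fold change for a DEG call
#'   (log2 units, default 1.5; boundary inclusive).
#' @param hotspot_fraction fraction of nodes selected per centrality
#'   measure (default 0.10).
#' @param n_random_sets number of random gene sets drawn for the
#'   functional-homogeneity null (default 100).
#' @param evidence_required evidence label an interaction must carry to be
#'   kept at network construction (default "experimental").
#' @param disease_context name of the disease used when contextualizing
#'   networks (default "leukemia").
#' @param excluded_go_terms character vector of ontology term IDs whose
#'   annotated genes (terms plus all descendants) are removed from DEG
#'   sets before downstream analysis.
#' @param rng_seed master seed for all stochastic stages.
#' @param pseudocount added to group means before fold-change computation
#'   so zero-mean groups yield finite log ratios (default 0.5).
#' @param min_category_size,max_category_size category-size bounds for
#'   over-representation tests (defaults 2 and Inf).
#' @param filter_mirna_evidence if TRUE, miRNA-target edges are filtered
#'   to `evidence_required` before enrichment as well; by default the
#'   evidence filter applies only at network construction.
#' @param hotspot_per_kind if TRUE the top-fraction rule is applied
#'   separately to genes and miRNAs; default ranks all nodes jointly.
#' @param semsim_universe "annotated" (default) draws random gene sets
#'   from annotated genes only; "all" draws from the full universe and
#'   keeps the annotated members of each draw.
#' @return an object of class `pipeline_config` (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$fdr_alpha
#' @export
pipeline_config <- function(fdr_alpha = 0.05,
                            lfc_threshold = 1.5,
                            hotspot_fraction = 0.10,
                            n_random_sets = 100L,
                            evidence_required = "experimental",
                            disease_context = "leukemia",
                            excluded_go_terms = character(),
                            rng_seed = 1L,
                            pseudocount = 0.5,
                            min_category_size = 2L,
                            max_category_size = Inf,
                            filter_mirna_evidence = FALSE,
                            hotspot_per_kind = FALSE,
                            semsim_universe = c("annotated", "all")) {
  semsim_universe <- match.arg(semsim_universe)
  if (!is.numeric(fdr_alpha) || length(fdr_alpha) != 1 ||
      fdr_alpha <= 0 || fdr_alpha >= 1) {
    stop_fmt("fdr_alpha must be a probability strictly between 0 and 1, got %s",
             format(fdr_alpha))
  }
  if (!is.numeric(lfc_threshold) || lfc_threshold < 0) {
    stop_fmt("lfc_threshold must be >= 0, got %s", format(lfc_threshold))
  }
  if (!is.numeric(hotspot_fraction) || hotspot_fraction <= 0 ||
      hotspot_fraction > 1) {
    stop_fmt("hotspot_fraction must lie in (0, 1], got %s",
             format(hotspot_fraction))
  }
  n_random_sets <- as.integer(n_random_sets)
  if (is.na(n_random_sets) || n_random_sets < 1) {
    stop_fmt("n_random_sets must be a positive integer")
  }
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    stop_fmt("pseudocount must be >= 0")
  }
  if (min_category_size < 1) stop_fmt("min_category_size must be >= 1")
  cfg <- list(
    fdr_alpha = fdr_alpha,
    lfc_threshold = lfc_threshold,
    hotspot_fraction = hotspot_fraction,
    n_random_sets = n_random_sets,
    evidence_required = as.character(evidence_required),
    disease_context = as.character(disease_context),
    excluded_go_terms = as.character(excluded_go_terms),
    rng_seed = as.integer(rng_seed),
    pseudocount = pseudocount,
    min_category_size = as.integer(min_category_size),
    max_category_size = max_category_size,
    filter_mirna_evidence = isTRUE(filter_mirna_evidence),
    hotspot_per_kind = isTRUE(hotspot_per_kind),
    semsim_universe = semsim_universe
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    if (length(val) == 0) val <- "(none)"
    cat(sprintf("  %-22s %s\n", nm, paste(val, collapse = ", ")))
  }
  invisible(x)
}

#' Read and write flat key-value configuration files
#'
#' The on-disk format is one `key = value` pair per line, `#` comments
#' allowed; list-valued keys (e.g. `excluded_go_terms`) are
#' comma-separated. Unknown keys are rejected so typos fail loudly.
#'
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad) > 0) {
    stop_fmt("malformed config line(s): %s", paste(bad, collapse = "; "))
  }
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  defaults <- pipeline_config()
  known <- names(unclass(defaults))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    stop_fmt("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  args <- list()
  for (i in seq_along(keys)) {
    key <- keys[i]
    raw <- trimws(vals[i])
    args[[key]] <- switch(key,
      excluded_go_terms = {
        parts <- trimws(strsplit(raw, ",")[[1]])
        parts[nzchar(parts)]
      },
      evidence_required = ,
      disease_context = ,
      semsim_universe = raw,
      filter_mirna_evidence = ,
      hotspot_per_kind = as.logical(raw),
      as.numeric(raw)
    )
  }
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- unclass(cfg)
  lines <- vapply(names(x), function(nm) {
    sprintf("%s = %s", nm, paste(x[[nm]], collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
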