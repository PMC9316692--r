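# Construction of the drug-specific co-regulatory network and hotspot
# detection. The candidate node set is DEGs plus enriched miRNAs; an
# interaction enters the network only when both endpoints are candidates
# and its evidence label matches the configured requirement. The network
# is then contextualized to the disease of interest by keeping only
# edges with at least one disease-associated endpoint. Hotspots are the
# union, over degree, betweenness, closeness and eigenvector centrality,
# of the top-fraction nodes per measure.

#' Build the co-regulatory network over DEGs and enriched miRNAs
#'
#' Candidate nodes are the DEG genes plus the enriched miRNAs. An
#' interaction from the regulatory database is included iff both
#' endpoints are candidates and its evidence label equals
#' `cfg$evidence_required`. Candidates left without any edge are not
#' added as isolated vertices but are recorded in the `"isolated"` graph
#' attribute. Duplicate source-target pairs of different interaction
#' classes are kept as distinct typed edges.
#'
#' @param degs a `deg_set` or character vector of DEG IDs.
#' @param mirnas character vector of enriched miRNA IDs.
#' @param db a [regdb()].
#' @param cfg a [pipeline_config()].
#' @return a directed igraph with vertex attributes `kind`
#'   ("gene"/"mirna"), `is_deg`, `is_enriched_mirna`, and edge attributes
#'   `class` (e.g. "tf-gene") and `evidence`; graph attribute
#'   `isolated` lists candidates with no retained edge. Empty result
#'   yields a warning, not an error.
#' @export
build_grn <- function(degs, mirnas, db, cfg = pipeline_config()) {
  stopifnot(inherits(db, "regdb"))
  deg_genes <- if (inherits(degs, "deg_set")) degs$gene else as.character(degs)
  mirnas <- as.character(mirnas)
  candidates <- unique(c(deg_genes, mirnas))
  if (length(candidates) == 0) stop_fmt("no candidate nodes (DEGs + miRNAs)")
  keep <- db$source %in% candidates & db$target %in% candidates &
    db$evidence == cfg$evidence_required
  edges <- db[keep, , drop = FALSE]
  used <- unique(c(edges$source, edges$target))
  isolated <- setdiff(candidates, used)
  if (nrow(edges) == 0) {
    warning("no interaction satisfies the membership and evidence filters; ",
            "returning an empty network")
    g <- igraph::make_empty_graph(directed = TRUE)
    g <- igraph::set_graph_attr(g, "isolated", isolated)
    return(g)
  }
  # A node is a miRNA if the database types it as one anywhere or it is
  # in the enriched miRNA set; TFs are genes.
  mirna_ids <- unique(c(mirnas,
                        edges$source[edges$source_type == "mirna"],
                        edges$target[edges$target_type == "mirna"]))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$source, to = edges$target,
               class = paste(edges$source_type, edges$target_type, sep = "-"),
               evidence = edges$evidence, stringsAsFactors = FALSE),
    directed = TRUE)
  nodes <- igraph::V(g)$name
  g <- igraph::set_vertex_attr(g, "kind",
    value = ifelse(nodes %in% mirna_ids, "mirna", "gene"))
  g <- igraph::set_vertex_attr(g, "is_deg", value = nodes %in% deg_genes)
  g <- igraph::set_vertex_attr(g, "is_enriched_mirna",
                               value = nodes %in% mirnas)
  igraph::set_graph_attr(g, "isolated", isolated)
}

#' Contextualize a network to a disease
#'
#' Keeps only the edges with at least one endpoint in the
#' disease-association set, then drops nodes left isolated; vertex
#' attribute `is_disease` marks associated nodes. Idempotent.
#'
#' @param grn an igraph from [build_grn()].
#' @param assoc character vector of disease-associated entity IDs.
#' @return the filtered igraph.
#' @export
contextualize_disease <- function(grn, assoc) {
  stopifnot(inherits(grn, "igraph"))
  assoc <- unique(as.character(assoc))
  if (igraph::ecount(grn) == 0) {
    return(igraph::set_vertex_attr(grn, "is_disease",
                                   value = igraph::V(grn)$name %in% assoc))
  }
  el <- igraph::as_edgelist(grn)
  keep <- el[, 1] %in% assoc | el[, 2] %in% assoc
  g <- igraph::subgraph_from_edges(grn, which(keep), delete.vertices = TRUE)
  igraph::set_vertex_attr(g, "is_disease",
                          value = igraph::V(g)$name %in% assoc)
}

#' Node centralities
#'
#' Four measures per node: total degree (in + out, one count per typed
#' edge), shortest-path betweenness on the directed graph, harmonic
#' closeness on the undirected skeleton (well-defined on disconnected
#' graphs), and eigenvector centrality of the undirected skeleton's
#' principal eigenvector.
#'
#' @param grn a non-empty igraph.
#' @return a `centrality_table` data frame with columns node, kind,
#'   degree, betweenness, closeness, eigenvector.
#' @export
centralities <- function(grn) {
  stopifnot(inherits(grn, "igraph"))
  if (igraph::vcount(grn) == 0) stop_fmt("network is empty")
  und <- igraph::as_undirected(igraph::simplify(grn, remove.multiple = TRUE,
                                                remove.loops = FALSE),
                               mode = "collapse")
  ev <- eigenvector_power(und)
  out <- data.frame(
    node = igraph::V(grn)$name,
    kind = igraph::vertex_attr(grn, "kind") %||%
      rep(NA_character_, igraph::vcount(grn)),
    degree = igraph::degree(grn, mode = "all"),
    betweenness = igraph::betweenness(grn, directed = TRUE),
    closeness = igraph::harmonic_centrality(und, mode = "all"),
    eigenvector = ev,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  out
}

# Eigenvector centrality of an undirected graph by power iteration on
# the adjacency matrix: deterministic uniform start, tolerance 1e-10,
# scaled so the maximum entry is 1. Deterministic by construction, which
# keeps pipeline re-runs byte-identical.
eigenvector_power <- function(und, tol = 1e-10, max_iter = 10000L) {
  n <- igraph::vcount(und)
  adj <- igraph::as_adjacency_matrix(und, sparse = FALSE)
  x <- rep(1, n)
  if (sum(adj) == 0) return(stats::setNames(x, igraph::V(und)$name))
  for (i in seq_len(max_iter)) {
    # shifted iteration (A + I): same eigenvectors, but avoids the
    # sign-oscillation of bipartite graphs (paired +/- eigenvalues)
    x_new <- as.numeric(adj %*% x) + x
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) break
    x_new <- x_new / nrm
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      return(stats::setNames(x / max(x), igraph::V(und)$name))
    }
    x <- x_new
  }
  stop_fmt(paste("eigenvector power iteration did not converge in %d steps",
                 "(already computed on the undirected skeleton)"), max_iter)
}

#' Hotspot nodes: union of top-ranked nodes across centrality measures
#'
#' Per measure, the cutoff rank is `ceiling(hotspot_fraction * n)`; every
#' node scoring at least the cutoff-rank score is selected (ties at the
#' boundary are included). The hotspot set is the union of the four
#' per-measure selections. With `cfg$hotspot_per_kind = TRUE` the rule is
#' applied separately within genes and within miRNAs.
#'
#' @param table a `centrality_table` from [centralities()].
#' @param cfg a [pipeline_config()].
#' @return character vector of hotspot node IDs with attribute
#'   `"per_measure"` (named list of per-measure selections).
#' @export
hotspots <- function(table, cfg = pipeline_config()) {
  stopifnot(inherits(table, "centrality_table"))
  if (nrow(table) == 0) stop_fmt("empty centrality table")
  measures <- c("degree", "betweenness", "closeness", "eigenvector")
  select_top <- function(tab) {
    n <- nrow(tab)
    r <- ceiling(cfg$hotspot_fraction * n)
    sel <- lapply(measures, function(m) {
      cutoff <- sort(tab[[m]], decreasing = TRUE)[r]
      tab$node[tab[[m]] >= cutoff]
    })
    stats::setNames(sel, measures)
  }
  if (isTRUE(cfg$hotspot_per_kind) && !all(is.na(table$kind))) {
    parts <- split(table, table$kind)
    sels <- lapply(parts, select_top)
    per_measure <- stats::setNames(lapply(measures, function(m) {
      unique(unlist(lapply(sels, `[[`, m), use.names = FALSE))
    }), measures)
  } else {
    per_measure <- select_top(table)
  }
  out <- unique(unlist(per_measure, use.names = FALSE))
  out <- table$node[table$node %in% out]  # stable order
  attr(out, "per_measure") <- per_measure
  out
}

#' Flag hotspot nodes on a network
#'
#' @param grn an igraph.
#' @param hot character vector from [hotspots()].
#' @return the igraph with logical vertex attribute `is_hotspot`.
#' @export
flag_hotspots <- function(grn, hot) {
  igraph::set_vertex_attr(grn, "is_hotspot",
                          value = igraph::V(grn)$name %in% hot)
}
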