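# Readers and writers for the plain-text formats the pipeline consumes:
# count matrices, sample groupings, regulatory interaction tables, disease
# association lists, GMT gene sets, ontology DAGs (edge-list TSV or a
# minimal OBO subset) and SIF network exports. All tabular files are
# UTF-8 TSV with '#' comment lines and no quoting.

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE, quote = ""),
    error = function(e) stop_fmt("no data rows in %s", path)
  )
  if (nrow(df) == 0) stop_fmt("no data rows in %s", path)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop_fmt("%s: missing required column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  df
}

#' Construct a two-group count matrix
#'
#' @param counts integer matrix, genes in rows, samples in columns, with
#'   row and column names.
#' @param group optional factor/character of per-sample group labels
#'   (exactly two levels, each with at least two samples, matching the
#'   replicate design of a two-condition RNA-seq contrast).
#' @return a `count_matrix` object: a list with elements `counts`
#'   (integer matrix) and `group` (factor or NULL).
#' @export
count_matrix <- function(counts, group = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_fmt("counts must carry gene (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_fmt("duplicate gene ID(s): %s",
             paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                   collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) stop_fmt("duplicate sample IDs")
  if (!is.numeric(counts) || any(is.na(counts)) ||
      any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, , drop = TRUE]
    stop_fmt("non-integer or negative count at gene %s, sample %s",
             rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  storage.mode(counts) <- "integer"
  if (!is.null(group)) {
    if (length(group) != ncol(counts)) {
      stop_fmt("group has %d labels for %d samples", length(group), ncol(counts))
    }
    group <- factor(as.character(group))
    if (nlevels(group) != 2) {
      stop_fmt("exactly two group levels required, got: %s",
               paste(levels(group), collapse = ", "))
    }
    if (any(table(group) < 2)) {
      stop_fmt("each group needs >= 2 samples (biological replicates)")
    }
    names(group) <- colnames(counts)
  }
  structure(list(counts = counts, group = group), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$group)) {
    tab <- table(x$group)
    cat(sprintf("groups: %s\n",
                paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample IDs, a first column of gene IDs and
#' integer cells. An optional companion groups file (`sample`, `group`
#' columns) attaches the two-condition design.
#'
#' @param path path to the counts TSV.
#' @param groups optional: path to a groups TSV, a data frame with
#'   `sample`/`group` columns, or a named character vector.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, groups = NULL) {
  df <- read_tsv_checked(path, character())
  if (ncol(df) < 2) stop_fmt("%s: need a gene ID column plus >= 1 sample", path)
  gene_ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "numeric")
  if (any(is.na(mat))) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, , drop = TRUE]
    stop_fmt("%s: non-numeric cell at gene %s, sample %s", path,
             gene_ids[bad[1]], colnames(mat)[bad[2]])
  }
  if (any(mat != round(mat)) || any(mat < 0)) {
    bad <- which(mat != round(mat) | mat < 0, arr.ind = TRUE)[1, , drop = TRUE]
    stop_fmt("%s: non-integer or negative count at gene %s, sample %s", path,
             gene_ids[bad[1]], colnames(mat)[bad[2]])
  }
  rownames(mat) <- gene_ids
  group <- NULL
  if (!is.null(groups)) {
    gdf <- if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
      read_tsv_checked(groups, c("sample", "group"))
    } else if (is.data.frame(groups)) {
      groups
    } else {
      data.frame(sample = names(groups), group = unname(groups),
                 stringsAsFactors = FALSE)
    }
    missing <- setdiff(colnames(mat), gdf$sample)
    if (length(missing) > 0) {
      stop_fmt("no group label for sample(s): %s", paste(missing, collapse = ", "))
    }
    group <- gdf$group[match(colnames(mat), gdf$sample)]
  }
  count_matrix(mat, group)
}

#' Write a count matrix (and optional groups file) to TSV
#'
#' @param cm a [count_matrix()].
#' @param path output counts TSV.
#' @param groups_path optional output path for the sample-group table.
#' @export
write_count_matrix <- function(cm, path, groups_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, path)
  if (!is.null(groups_path)) {
    if (is.null(cm$group)) stop_fmt("count matrix has no group labels to write")
    write_table(data.frame(sample = names(cm$group),
                           group = as.character(cm$group)), groups_path)
  }
  invisible(path)
}

reg_source_types <- c("tf", "mirna", "gene")
reg_target_types <- c("gene", "mirna")

#' Construct a regulatory interaction table
#'
#' Directed, typed, evidence-labelled interactions among transcription
#' factors, miRNAs and genes. Self-loops are rejected unless
#' `allow_self_loops = TRUE`; exact duplicates on
#' (source, target, source_type, target_type) are collapsed to the first
#' occurrence, and the number collapsed is recorded in the
#' `"n_deduplicated"` attribute so no row disappears silently.
#'
#' @param interactions data frame with columns `source`, `target`,
#'   `source_type` (tf/mirna/gene), `target_type` (gene/mirna),
#'   `evidence`.
#' @param allow_self_loops keep edges with source == target.
#' @return a `regdb` data frame.
#' @export
regdb <- function(interactions, allow_self_loops = FALSE) {
  req <- c("source", "target", "source_type", "target_type", "evidence")
  missing <- setdiff(req, names(interactions))
  if (length(missing) > 0) {
    stop_fmt("regdb: missing column(s): %s", paste(missing, collapse = ", "))
  }
  df <- interactions[req]
  for (col in req) df[[col]] <- as.character(df[[col]])
  bad_src <- setdiff(unique(df$source_type), reg_source_types)
  if (length(bad_src) > 0) {
    stop_fmt("unknown source_type value(s): %s (allowed: %s)",
             paste(bad_src, collapse = ", "),
             paste(reg_source_types, collapse = ", "))
  }
  bad_tgt <- setdiff(unique(df$target_type), reg_target_types)
  if (length(bad_tgt) > 0) {
    stop_fmt("unknown target_type value(s): %s (allowed: %s)",
             paste(bad_tgt, collapse = ", "),
             paste(reg_target_types, collapse = ", "))
  }
  if (!allow_self_loops && any(df$source == df$target)) {
    stop_fmt("self-loop interaction(s) not allowed: %s",
             paste(unique(df$source[df$source == df$target]), collapse = ", "))
  }
  key <- paste(df$source, df$target, df$source_type, df$target_type, sep = "\r")
  dup <- duplicated(key)
  out <- df[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_deduplicated") <- sum(dup)
  class(out) <- c("regdb", "data.frame")
  out
}

#' Read a regulatory interaction table from TSV
#'
#' @param path TSV with columns source, target, source_type, target_type,
#'   evidence.
#' @param allow_self_loops passed to [regdb()].
#' @return a `regdb` data frame.
#' @export
read_regdb <- function(path, allow_self_loops = FALSE) {
  df <- read_tsv_checked(path,
    c("source", "target", "source_type", "target_type", "evidence"))
  regdb(df, allow_self_loops = allow_self_loops)
}

#' @rdname read_regdb
#' @param db a `regdb`.
#' @export
write_regdb <- function(db, path) {
  write_table(as.data.frame(db), path)
}

#' Read a disease-association table
#'
#' @param path TSV with columns `entity`, `entity_type`, `disease`.
#' @param disease optional disease name to filter on; default keeps all.
#' @return character vector of associated entity IDs, with the full table
#'   attached as attribute `"table"`.
#' @export
read_disease <- function(path, disease = NULL) {
  df <- read_tsv_checked(path, c("entity", "entity_type", "disease"))
  for (col in names(df)) df[[col]] <- as.character(df[[col]])
  if (!is.null(disease)) df <- df[df$disease == disease, , drop = FALSE]
  out <- unique(df$entity)
  attr(out, "table") <- df
  out
}

#' @rdname read_disease
#' @param entities character vector of entity IDs.
#' @param entity_type per-entity type labels (recycled).
#' @export
write_disease <- function(entities, path, disease = "leukemia",
                          entity_type = "gene") {
  df <- data.frame(entity = entities,
                   entity_type = rep_len(entity_type, length(entities)),
                   disease = disease, stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member IDs, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) stop_fmt("no data rows in %s", path)
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop_fmt("%s: GMT line needs name, description and >= 1 member: %s",
               path, substr(ln, 1, 40))
    }
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_fmt("gene sets must be named")
  }
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct an ontology DAG
#'
#' The DAG is stored as typed child-to-parent edges (`is_a`, `part_of`).
#' Construction verifies acyclicity (topological sort) and that every
#' non-root term reaches a root.
#'
#' @param edges data frame with columns `child`, `parent`, `relation`.
#' @return a `go_dag`: list with `terms`, `edges`, `roots`, and
#'   parent/child adjacency lists.
#' @export
go_dag <- function(edges) {
  req <- c("child", "parent", "relation")
  missing <- setdiff(req, names(edges))
  if (length(missing) > 0) {
    stop_fmt("go_dag edges: missing column(s): %s", paste(missing, collapse = ", "))
  }
  edges <- edges[req]
  for (col in req) edges[[col]] <- as.character(edges[[col]])
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel) > 0) {
    stop_fmt("unknown relation(s): %s (allowed: is_a, part_of)",
             paste(bad_rel, collapse = ", "))
  }
  terms <- sort(unique(c(edges$child, edges$parent)))
  # Kahn topological sort on child -> parent arrows; leftovers mean a cycle.
  indeg <- table(factor(edges$parent, levels = terms))
  outgoing <- split(seq_len(nrow(edges)), edges$child)
  seen <- 0L
  indeg <- stats::setNames(as.integer(indeg), terms)
  q <- terms[indeg == 0]
  while (length(q) > 0) {
    v <- q[[1]]; q <- q[-1]; seen <- seen + 1L
    for (i in outgoing[[v]] %||% integer()) {
      p <- edges$parent[i]
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) q <- c(q, p)
    }
  }
  if (seen < length(terms)) {
    cyc <- names(indeg)[indeg > 0]
    stop_fmt("DAG violation: cycle involving term(s) %s",
             paste(utils::head(cyc, 5), collapse = ", "))
  }
  parents <- split(seq_len(nrow(edges)), edges$child)
  children <- split(seq_len(nrow(edges)), edges$parent)
  roots <- setdiff(terms, edges$child)
  if (length(roots) == 0) stop_fmt("DAG has no root term")
  structure(list(terms = terms, edges = edges, roots = roots,
                 parent_edges = parents, child_edges = children),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d edges (%d is_a, %d part_of), root(s): %s\n",
              length(x$terms), nrow(x$edges),
              sum(x$edges$relation == "is_a"),
              sum(x$edges$relation == "part_of"),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' Construct a gene-to-term annotation map
#'
#' @param annotations data frame with columns `gene`, `term`, or a named
#'   list of term-ID vectors.
#' @param dag the [go_dag()] the terms must belong to.
#' @return named list mapping gene ID to a character vector of directly
#'   annotated term IDs.
#' @export
annotation_map <- function(annotations, dag) {
  stopifnot(inherits(dag, "go_dag"))
  if (is.data.frame(annotations)) {
    missing <- setdiff(c("gene", "term"), names(annotations))
    if (length(missing) > 0) {
      stop_fmt("annotations: missing column(s): %s", paste(missing, collapse = ", "))
    }
    annot <- lapply(split(as.character(annotations$term),
                          as.character(annotations$gene)), unique)
  } else {
    annot <- lapply(annotations, function(x) unique(as.character(x)))
  }
  unknown <- setdiff(unique(unlist(annot, use.names = FALSE)), dag$terms)
  if (length(unknown) > 0) {
    stop_fmt("annotation to unknown term(s): %s",
             paste(utils::head(unknown, 5), collapse = ", "))
  }
  annot
}

#' Read an ontology DAG and its annotations
#'
#' @param path_edges TSV with columns child, parent, relation.
#' @param path_annot TSV with columns gene, term.
#' @return list with elements `dag` (a [go_dag()]) and `annot`
#'   (an [annotation_map()]).
#' @export
read_go <- function(path_edges, path_annot) {
  edges <- read_tsv_checked(path_edges, c("child", "parent", "relation"))
  dag <- go_dag(edges)
  annot_df <- read_tsv_checked(path_annot, c("gene", "term"))
  list(dag = dag, annot = annotation_map(annot_df, dag))
}

#' @rdname read_go
#' @param dag a `go_dag`; `annot` an annotation map.
#' @export
write_go <- function(dag, annot, path_edges, path_annot) {
  write_table(dag$edges, path_edges)
  df <- data.frame(
    gene = rep(names(annot), lengths(annot)),
    term = unlist(annot, use.names = FALSE), stringsAsFactors = FALSE)
  write_table(df, path_annot)
  invisible(path_edges)
}

#' Read a minimal OBO subset into an ontology DAG
#'
#' Recognizes `[Term]` stanzas with `id:`, `is_a:` and
#' `relationship: part_of` lines; everything else is ignored. The result
#' is normalized to the same edge-list model as [read_go()].
#'
#' @param path OBO file.
#' @return a [go_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  child <- parent <- relation <- character()
  current <- NA_character_
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; current <- NA_character_; next }
    if (startsWith(ln, "[")) { in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      current <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      child <- c(child, current); parent <- c(parent, tgt)
      relation <- c(relation, "is_a")
    } else if (grepl("^relationship:\\s*part_of", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^relationship:\\s*part_of", "", ln)))
      child <- c(child, current); parent <- c(parent, tgt)
      relation <- c(relation, "part_of")
    }
  }
  if (length(child) == 0) stop_fmt("no is_a/part_of relationships found in %s", path)
  if (anyNA(child)) stop_fmt("%s: relationship line before any id:", path)
  go_dag(data.frame(child = child, parent = parent, relation = relation,
                    stringsAsFactors = FALSE))
}

#' Write a network as a SIF-style edge list
#'
#' One line per edge: source, interaction class, target, tab-separated.
#'
#' @param grn an igraph network as built by [build_grn()].
#' @param path output file.
#' @export
write_network <- function(grn, path) {
  stopifnot(inherits(grn, "igraph"))
  el <- igraph::as_edgelist(grn)
  cls <- igraph::edge_attr(grn, "class") %||% rep("regulates", nrow(el))
  lines <- sprintf("%s\t%s\t%s", el[, 1], cls, el[, 2])
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table to TSV
#'
#' @param df data frame.
#' @param path output file.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
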