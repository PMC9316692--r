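# Network construction, disease contextualization, centralities and
# hotspot detection.

test_that("network includes only candidate-to-candidate experimental edges", {
  db <- fixture_regdb()
  cfg <- pipeline_config()
  g <- build_grn(c("g1", "g2", "g3"), "m1", db, cfg)
  # m1->g3 is predicted (evidence filter); tf9->g1 has tf9 outside the
  # candidate set (both-endpoint rule); the three experimental
  # within-candidate edges remain.
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  el <- igraph::as_edgelist(g)
  expect_false(any(el == "tf9"))
  expect_false(any(el[, 2] == "g3"))
  expect_setequal(igraph::V(g)$kind[igraph::V(g)$name == "m1"], "mirna")
  expect_true(all(igraph::E(g)$evidence == "experimental"))
  # isolated candidates are dropped but reported
  g2 <- build_grn(c("g1", "g2", "lonely"), "m1", db, cfg)
  expect_false("lonely" %in% igraph::V(g2)$name)
  expect_true("lonely" %in% igraph::graph_attr(g2, "isolated"))
  expect_warning(build_grn("nobody", character(), db, cfg), "empty network")
})

test_that("disease contextualization keeps edges touching associated nodes", {
  db <- fixture_regdb()
  g <- build_grn(c("g1", "g2", "g3"), "m1", db, pipeline_config())
  # g2 is the only disease node; it is incident to m1->g2 and g1->g2,
  # so m1->g1 must be removed.
  ctx <- contextualize_disease(g, "g2")
  expect_equal(igraph::ecount(ctx), 2)
  el <- igraph::as_edgelist(ctx)
  expect_true(all(el[, 1] == "g2" | el[, 2] == "g2"))
  # vacuous filter empties the network; full association is the identity
  expect_equal(igraph::ecount(contextualize_disease(g, character())), 0)
  all_nodes <- contextualize_disease(g, igraph::V(g)$name)
  expect_equal(igraph::ecount(all_nodes), igraph::ecount(g))
  # idempotence
  twice <- contextualize_disease(ctx, "g2")
  expect_equal(igraph::as_edgelist(twice), igraph::as_edgelist(ctx))
})

test_that("path and star centralities take their analytic values", {
  path <- igraph::graph_from_literal(A - B - C)
  pathd <- igraph::as_directed(path, mode = "mutual")
  cent <- centralities(pathd)
  expect_equal(cent$betweenness[cent$node == "B"], 2)  # (A,C) and (C,A)
  expect_equal(cent$betweenness[cent$node %in% c("A", "C")], c(0, 0))

  star <- igraph::graph_from_data_frame(
    data.frame(from = "c", to = paste0("l", 1:4)), directed = TRUE)
  cs <- centralities(star)
  expect_equal(cs$degree[cs$node == "c"], 4)
  expect_equal(which.max(cs$eigenvector), which(cs$node == "c"))
  expect_equal(max(cs$eigenvector), 1)
})

test_that("betweenness matches exhaustive shortest-path counting", {
  set.seed(55)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    m <- sample(n:(n * (n - 1) / 2), 1)
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    sel <- pairs[sample(nrow(pairs), m), , drop = FALSE]
    flip <- runif(m) < 0.5
    edges <- cbind(ifelse(flip, sel[, 2], sel[, 1]),
                   ifelse(flip, sel[, 1], sel[, 2]))
    g <- igraph::graph_from_edgelist(
      matrix(as.character(edges), ncol = 2), directed = TRUE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    ids <- as.integer(igraph::V(g)$name)
    ids[is.na(ids)] <- setdiff(seq_len(n), ids)
    cent <- centralities(g)
    oracle <- brute_betweenness(n, edges)
    expect_equal(cent$betweenness, oracle[ids], tolerance = 1e-9)
  }
})

test_that("hotspot selection implements rank cutoff, ties and union", {
  mk <- function(deg, btw, clo, eig) {
    out <- data.frame(node = sprintf("n%02d", seq_along(deg)),
                      kind = "gene", degree = deg, betweenness = btw,
                      closeness = clo, eigenvector = eig,
                      stringsAsFactors = FALSE)
    class(out) <- c("centrality_table", "data.frame")
    out
  }
  cfg <- pipeline_config()
  # n = 10 distinct scores -> exactly ceil(1) node per measure
  tab <- mk(10:1, 1:10, seq(0.1, 1, 0.1), seq(1, 0.1, -0.1))
  hot <- hotspots(tab, cfg)
  per <- attr(hot, "per_measure")
  expect_true(all(lengths(per) == 1))
  expect_equal(per$degree, "n01")
  expect_equal(per$betweenness, "n10")
  # all-equal scores on one measure select every node (inclusive ties)
  tab2 <- mk(rep(5, 10), 1:10, 1:10, 1:10)
  per2 <- attr(hotspots(tab2, cfg), "per_measure")
  expect_length(per2$degree, 10)
  # union semantics: top on exactly one measure is still a hotspot
  tab3 <- mk(c(10, 9:1), c(1:9, 10), c(10, 9:1), c(10, 9:1))
  hot3 <- hotspots(tab3, cfg)
  expect_true("n10" %in% hot3)
  expect_setequal(hot3, c("n01", "n10"))
  # union size bounds
  expect_gte(length(hot3), max(lengths(attr(hot3, "per_measure"))))
  expect_lte(length(hot3), sum(lengths(attr(hot3, "per_measure"))))
})

test_that("per-kind hotspot switch ranks genes and miRNAs separately", {
  tab <- data.frame(node = c(paste0("g", 1:9), "m1"),
                    kind = c(rep("gene", 9), "mirna"),
                    degree = c(9:1, 0.5), betweenness = c(9:1, 0.5),
                    closeness = c(9:1, 0.5), eigenvector = c(9:1, 0.5),
                    stringsAsFactors = FALSE)
  class(tab) <- c("centrality_table", "data.frame")
  joint <- hotspots(tab, pipeline_config())
  expect_false("m1" %in% joint)
  per_kind <- hotspots(tab, pipeline_config(hotspot_per_kind = TRUE))
  expect_true("m1" %in% per_kind)
})

test_that("a densely wired planted hub is a hotspot under every measure", {
  set.seed(66)
  n <- 40
  genes <- sprintf("g%02d", 1:n)
  hub <- "g01"
  # hub wired to 30% of the other nodes (mixed in/out so directed paths
  # route through it); sparse background edges
  hub_targets <- sample(genes[-1], ceiling(0.3 * n))
  half <- seq_along(hub_targets) %% 2 == 0
  bg <- t(replicate(30, sample(genes[-1], 2)))
  df <- data.frame(source = c(rep(hub, sum(!half)), hub_targets[half], bg[, 1]),
                   target = c(hub_targets[!half], rep(hub, sum(half)), bg[, 2]),
                   source_type = "tf", target_type = "gene",
                   evidence = "experimental", stringsAsFactors = FALSE)
  df <- df[df$source != df$target, ]
  g <- build_grn(genes, character(), regdb(df), pipeline_config())
  cent <- centralities(g)
  hot <- hotspots(cent, pipeline_config())
  per <- attr(hot, "per_measure")
  for (m in names(per)) expect_true(hub %in% per[[m]])
})
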