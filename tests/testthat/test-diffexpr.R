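# Differential expression: normalization, the NB Wald test, DEG calling,
# functional exclusion and set overlaps.

test_that("size factors: symmetry, scale equivariance, brute-force oracle", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(size_factors(count_matrix(m)), c(s1 = 1, s2 = 1))

  m2 <- cbind(s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
  rownames(m2) <- paste0("g", 1:3)
  sf <- size_factors(count_matrix(m2))
  # proportional to (1, 2), normalized to geometric mean 1
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  set.seed(88)
  # odd gene count so the linear-scale and log-scale medians coincide
  m3 <- matrix(rpois(204, 50) + 1L, 51, 4,
               dimnames = list(sprintf("g%02d", 1:51), paste0("s", 1:4)))
  sf3 <- size_factors(count_matrix(m3))
  # direct re-computation per definition
  geo <- exp(rowMeans(log(m3)))
  raw <- apply(m3, 2, function(col) median(col / geo))
  expect_equal(unname(sf3), unname(raw / exp(mean(log(raw)))), tolerance = 1e-12)

  zero_row <- matrix(c(0L, 1L, 1L, 0L), 2,
                     dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(count_matrix(zero_row)), "pseudo-reference")
})

test_that("size factors agree with the reference median-of-ratios engine", {
  set.seed(99)
  m <- matrix(rnbinom(600, mu = 80, size = 5) + 1L, 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  ours <- size_factors(count_matrix(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # same up to the geometric-mean-1 convention
  expect_equal(unname(ours), unname(ref / exp(mean(log(ref)))),
               tolerance = 1e-10)
})

test_that("NB Wald test handles degenerate genes and basic arithmetic", {
  m <- rbind(gz = c(0L, 0L, 0L, 0L),
             gx = c(100L, 100L, 400L, 400L),
             gc = c(50L, 50L, 50L, 50L))
  colnames(m) <- paste0("s", 1:4)
  cm <- count_matrix(m, group = c("A", "A", "B", "B"))
  de <- nb_wald_test(cm, factors = setNames(rep(1, 4), colnames(m)))
  expect_equal(de$log2FC[de$gene == "gz"], 0)
  expect_equal(de$pvalue[de$gene == "gz"], 1)
  expect_equal(de$log2FC[de$gene == "gx"], log2(400.5 / 100.5))
  expect_equal(de$log2FC[de$gene == "gc"], 0)
  expect_true(all(de$padj >= de$pvalue - 1e-15))
  expect_true(all(de$padj >= 0 & de$padj <= 1))
})

test_that("DEG calling applies inclusive thresholds and is monotone", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    log2FC = c(2.0, 1.5, 3.0, -1.6),
                    pvalue = c(0.001, 0.001, 0.02, 0.001),
                    padj = c(0.04, 0.04, 0.06, 0.03))
  cfg <- pipeline_config()
  degs <- call_degs(tab, cfg)
  expect_setequal(degs$gene, c("a", "b", "d"))
  expect_equal(degs$direction[degs$gene == "a"], "up")
  expect_equal(degs$direction[degs$gene == "d"], "down")
  # boundary inclusive
  expect_true("b" %in% degs$gene)
  # tightening either threshold never adds genes
  for (alpha in c(0.05, 0.035, 0.01)) {
    for (lfc in c(1.5, 2, 2.5)) {
      sub <- call_degs(tab, pipeline_config(fdr_alpha = alpha,
                                            lfc_threshold = lfc))
      expect_true(all(sub$gene %in% degs$gene))
    }
  }
})

test_that("functional-term exclusion propagates to descendants and is idempotent", {
  dag <- sibling_dag()
  annot <- list(gd = "P1",   # directly annotated to the excluded term
                gc = "L1",   # annotated to a child of it
                go_ = "L3")  # other branch, must survive
  degs <- call_degs(data.frame(gene = c("gd", "gc", "go_"),
                               log2FC = 2, pvalue = 0.001, padj = 0.001),
                    pipeline_config())
  res <- filter_functional_terms(degs, annot, dag, "P1")
  expect_setequal(res$removed, c("gd", "gc"))
  expect_equal(res$degs$gene, "go_")
  twice <- filter_functional_terms(res$degs, annot, dag, "P1")
  expect_identical(twice$degs$gene, res$degs$gene)
  # empty exclusion list is the identity
  same <- filter_functional_terms(degs, annot, dag, character())
  expect_identical(same$degs$gene, degs$gene)
  expect_error(filter_functional_terms(degs, annot, dag, "NOPE"),
               "not in DAG")
})

test_that("overlap regions match brute-force membership enumeration", {
  simple <- overlap_sets(list(x = c("a", "b"), y = c("b", "c")))
  expect_equal(simple$count[simple$region == "x&y"], 1)
  expect_equal(simple$genes[simple$region == "x&y"], "b")
  expect_equal(simple$count[simple$region == "x"], 1)
  expect_equal(simple$count[simple$region == "y"], 1)

  ident <- overlap_sets(list(x = c("a", "b"), y = c("a", "b")))
  expect_equal(ident$count[ident$region == "x&y"], 2)
  expect_equal(sum(ident$count), 2)

  set.seed(4)
  sets <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
  names(sets) <- paste0("S", 1:4)
  out <- overlap_sets(sets)
  expect_equal(sum(out$count), length(unique(unlist(sets))))
  # brute force: for each element, its membership pattern defines its region
  for (el in unique(unlist(sets))) {
    pattern <- paste(as.integer(vapply(sets, function(s) el %in% s,
                                       logical(1))), collapse = "")
    row <- out[out$pattern == pattern, ]
    expect_true(el %in% strsplit(row$genes, ";")[[1]])
  }
})

test_that("ranking by p-value recovers planted DE genes", {
  sim <- simulate_counts(n_genes = 1000, n_per_group = 5, de_fraction = 0.1,
                         lfc_mean = 2, dispersion = 0.1, seed = 31)
  de <- nb_wald_test(sim$counts)
  auc <- auroc_from_pvalues(de$pvalue, de$gene %in% sim$truth$de_genes$gene)
  expect_gt(auc, 0.95)
})
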