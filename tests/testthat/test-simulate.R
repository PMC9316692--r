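# Synthetic-data generators: determinism, planted structure, and
# consistency with the stated generative models.

test_that("count simulation is seed-deterministic and respects de_fraction", {
  a <- simulate_counts(n_genes = 100, n_per_group = 3, seed = 42)
  b <- simulate_counts(n_genes = 100, n_per_group = 3, seed = 42)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$de_genes, b$truth$de_genes)
  c2 <- simulate_counts(n_genes = 100, n_per_group = 3, seed = 43)
  expect_false(identical(a$counts$counts, c2$counts$counts))

  none <- simulate_counts(n_genes = 50, n_per_group = 2, de_fraction = 0,
                          seed = 1)
  expect_equal(nrow(none$truth$de_genes), 0)
  expect_error(simulate_counts(dispersion = 0), "dispersion")
  expect_error(simulate_counts(n_genes = 5), "n_genes")
})

test_that("non-DE gene moments match NB(mu, mu + alpha mu^2)", {
  # Moment check against the stated generative model: for each non-DE
  # gene, pooled counts across 2 * 30 samples should have mean ~ mu and
  # variance ~ mu + alpha mu^2. Aggregate over genes to beat sampling
  # error: regress sample variance on mu + alpha*mu^2.
  alpha <- 0.1
  sim <- simulate_counts(n_genes = 2000, n_per_group = 30, de_fraction = 0,
                         lfc_mean = 2, dispersion = alpha, seed = 7)
  x <- sim$counts$counts
  mu_hat <- rowMeans(x)
  v_hat <- apply(x, 1, var)
  mu_true <- sim$truth$baseline_mu
  # Means unbiased: average ratio of empirical to true mean near 1.
  expect_equal(mean(mu_hat / mu_true), 1, tolerance = 0.05)
  # Variance function: per-gene method-of-moments alpha against the true
  # mean is unbiased for the dispersion; averaging over genes beats the
  # sampling noise of individual variances.
  use <- mu_true > 5
  a_fit <- mean((v_hat[use] - mu_true[use]) / mu_true[use]^2)
  expect_equal(a_fit, alpha, tolerance = 0.25 * alpha)
})

test_that("planted miRNAs over-target the DE pool at the stated rates", {
  de <- sprintf("g%04d", 1:200)  # 200 of 2000 genes
  sim <- simulate_regdb(n_tfs = 20, n_mirnas = 50, n_genes = 2000,
                        targets_per_regulator = 50, planted_targets = de,
                        planted_fraction = 0.8, evidence_mix = 0.5,
                        seed = 9)
  db <- sim$regdb
  planted <- sim$truth$enriched_mirnas
  expect_length(planted, 1)
  overlap_rate <- function(m) {
    tg <- db$target[db$source == m & db$target_type == "gene"]
    mean(tg %in% de)
  }
  expect_equal(overlap_rate(planted), 0.8, tolerance = 0.05)
  background <- setdiff(unique(db$source[db$source_type == "mirna"]), planted)
  bg_rate <- mean(vapply(background, overlap_rate, numeric(1)))
  expect_equal(bg_rate, 0.1, tolerance = 0.05)
  # all four edge classes present
  classes <- unique(paste(db$source_type, db$target_type))
  expect_setequal(classes, c("tf gene", "tf mirna", "mirna gene", "mirna mirna"))
})

test_that("regdb generator honours the evidence mix and determinism", {
  all_exp <- simulate_regdb(n_tfs = 5, n_mirnas = 10, n_genes = 100,
                            targets_per_regulator = 10, evidence_mix = 1,
                            seed = 2)
  expect_true(all(all_exp$regdb$evidence == "experimental"))
  again <- simulate_regdb(n_tfs = 5, n_mirnas = 10, n_genes = 100,
                          targets_per_regulator = 10, evidence_mix = 1,
                          seed = 2)
  expect_identical(as.data.frame(all_exp$regdb), as.data.frame(again$regdb))
  expect_error(simulate_regdb(n_mirnas = 2,
                              planted_targets = list("g1", "g2", "g3")),
               "planted")
})

test_that("depth-2 binary ontology is the forced 7-term tree", {
  sim <- simulate_go(branching = 2, depth = 2, n_genes = 20,
                     shortcut_fraction = 0, seed = 5)
  expect_length(sim$dag$terms, 7)
  expect_length(sim$dag$roots, 1)
  # root has no outgoing child->parent edge; leaves have none incoming
  expect_false(sim$dag$roots %in% sim$dag$edges$child)
})

test_that("planted ontology module is more self-similar than background", {
  module <- sprintf("g%04d", 1:10)
  sim <- simulate_go(branching = 3, depth = 3, n_genes = 60,
                     module_genes = module, seed = 11)
  dag <- sim$dag; annot <- sim$annot
  mean_pairwise <- function(genes) {
    pairs <- combn(genes, 2)
    mean(vapply(seq_len(ncol(pairs)), function(i) {
      gene_pair_sim(annot, dag, pairs[1, i], pairs[2, i])
    }, numeric(1)))
  }
  background <- setdiff(names(annot), module)[1:10]
  expect_gt(mean_pairwise(module), mean_pairwise(background))
  again <- simulate_go(branching = 3, depth = 3, n_genes = 60,
                       module_genes = module, seed = 11)
  expect_identical(again$dag$edges, sim$dag$edges)
  expect_identical(again$annot, sim$annot)
})

test_that("disease flags cover must_include and track the flag fraction", {
  expect_length(simulate_disease(letters, 0, seed = 1), 0)
  expect_true("g1" %in% simulate_disease(paste0("g", 1:100), 0,
                                         must_include = "g1", seed = 1))
  entities <- sprintf("e%04d", 1:1000)
  flagged <- simulate_disease(entities, 0.2, seed = 3)
  # binomial 99% interval around 200 of 1000
  expect_gt(length(flagged), qbinom(0.005, 1000, 0.2))
  expect_lt(length(flagged), qbinom(0.995, 1000, 0.2))
})

test_that("generator output files pass every reader without rejected rows", {
  out <- withr::local_tempdir()
  p <- simulate_preset(seed = 21, n_contrasts = 1, n_genes = 200,
                       n_per_group = 2, out_dir = out)
  cm <- read_count_matrix(file.path(out, "contrast1_counts.tsv"),
                          file.path(out, "contrast1_groups.tsv"))
  expect_identical(cm$counts, p$inputs$contrasts$contrast1$counts)
  db <- read_regdb(file.path(out, "regdb.tsv"))
  expect_equal(nrow(db), nrow(p$inputs$regdb))
  dis <- read_disease(file.path(out, "disease.tsv"), disease = "leukemia")
  expect_setequal(as.character(dis), p$inputs$disease)
  go <- read_go(file.path(out, "go_edges.tsv"), file.path(out, "go_annot.tsv"))
  expect_identical(go$dag$edges, p$inputs$go$dag$edges)
  expect_identical(go$annot[names(p$inputs$go$annot)], p$inputs$go$annot)
})
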