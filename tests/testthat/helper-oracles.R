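# Independent oracles used across tests. Each re-derives the quantity it
# checks from first principles, by a different route than the package.

# Upper-tail hypergeometric probability by direct combinatorial summation.
brute_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Literal BH step-up definition: q_i = min over j with rank >= rank(i) of
# p_(j) * m / j, computed by explicit double loop.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (pos in seq_len(m)) {
    cand <- vapply(pos:m, function(j) p[o[j]] * m / j, numeric(1))
    q[o[pos]] <- min(1, min(cand))
  }
  q
}

# Betweenness by explicit shortest-path counting on a directed, unweighted
# edge list over nodes 1..n: BFS from every source gives distances and
# path counts; dependency of v on pair (s, t) is
# sigma_sv * sigma_vt / sigma_st when dist(s,v) + dist(v,t) = dist(s,t).
brute_betweenness <- function(n, edges) {
  adj <- lapply(seq_len(n), function(v) edges[edges[, 1] == v, 2])
  bfs <- function(s) {
    dist <- rep(Inf, n); np <- numeric(n)
    dist[s] <- 0; np[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) np[w] <- np[w] + np[v]
        }
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, np = np)
  }
  res <- lapply(seq_len(n), bfs)
  btw <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t || is.infinite(res[[s]]$dist[t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (res[[s]]$dist[v] + res[[v]]$dist[t] == res[[s]]$dist[t]) {
          btw[v] <- btw[v] +
            res[[s]]$np[v] * res[[v]]$np[t] / res[[s]]$np[t]
        }
      }
    }
  }
  btw
}

# Wang S-values by exhaustive enumeration of upward paths: the semantic
# contribution of an ancestor is the maximum over all child->parent paths
# of the product of edge weights along the path.
brute_svalues <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  best <- list()
  rec <- function(t, w) {
    if (is.null(best[[t]]) || w > best[[t]]) best[[t]] <<- w
    idx <- dag$parent_edges[[t]]
    for (i in idx) {
      rec(dag$edges$parent[i], w * unname(weights[[dag$edges$relation[i]]]))
    }
  }
  rec(term, 1)
  unlist(best)
}

brute_wang_sim <- function(dag, t1, t2, weights = c(is_a = 0.8, part_of = 0.6)) {
  s1 <- brute_svalues(dag, t1, weights)
  s2 <- brute_svalues(dag, t2, weights)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# Rank-based AUROC for ranking positives by ascending p-value.
auroc_from_pvalues <- function(p, is_positive) {
  r <- rank(p)
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  1 - (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Tiny two-term DAG: B is_a A.
parent_child_dag <- function() {
  go_dag(data.frame(child = "B", parent = "A", relation = "is_a",
                    stringsAsFactors = FALSE))
}

# Small fixture DAG: root R with children P1, P2; leaves L1, L2 under P1,
# L3 under P2. All is_a.
sibling_dag <- function() {
  go_dag(data.frame(
    child = c("P1", "P2", "L1", "L2", "L3"),
    parent = c("R", "R", "P1", "P1", "P2"),
    relation = "is_a", stringsAsFactors = FALSE))
}

# Random DAG on `n` terms: each non-root term gets 1-2 parents among
# lower-index terms, random relations. Indexing guarantees acyclicity.
random_dag <- function(n, seed) {
  set.seed(seed)
  terms <- sprintf("T%02d", seq_len(n))
  child <- parent <- relation <- character()
  for (i in 2:n) {
    np <- sample(1:min(2, i - 1), 1)
    ps <- sample(seq_len(i - 1), np)
    child <- c(child, rep(terms[i], np))
    parent <- c(parent, terms[ps])
    relation <- c(relation, sample(c("is_a", "part_of"), np, replace = TRUE))
  }
  go_dag(data.frame(child = child, parent = parent, relation = relation,
                    stringsAsFactors = FALSE))
}

# Small hand-built regulatory database used by grn tests.
fixture_regdb <- function() {
  regdb(data.frame(
    source      = c("m1", "m1", "g1", "m1", "tf9"),
    target      = c("g1", "g2", "g2", "g3", "g1"),
    source_type = c("mirna", "mirna", "tf", "mirna", "tf"),
    target_type = c("gene", "gene", "gene", "gene", "gene"),
    evidence    = c("experimental", "experimental", "experimental",
                    "predicted", "experimental"),
    stringsAsFactors = FALSE))
}
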