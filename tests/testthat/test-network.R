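path_graph <- function() {
  build_graph(data.frame(source = c("a", "b"), target = c("b", "c")))
}

test_that("betweenness closed forms: path, star, complete", {
  bt <- betweenness_table(path_graph())
  expect_equal(bt$betweenness[bt$node == "b"], 1)
  expect_equal(sum(bt$betweenness), 1)
  star <- build_graph(data.frame(source = "hub", target = c("l1", "l2", "l3")))
  bs <- betweenness_table(star)
  expect_equal(bs$betweenness[bs$node == "hub"], 3)
  expect_true(all(bs$betweenness[bs$node != "hub"] == 0))
  expect_equal(bs$normalized[bs$node == "hub"], 1)
  k4 <- build_graph(data.frame(source = rep(c("a", "a", "a", "b", "b", "c"), 1),
                               target = c("b", "c", "d", "c", "d", "d")))
  expect_true(all(betweenness_table(k4)$betweenness == 0))
})

test_that("betweenness matches exhaustive enumeration on random graphs", {
  for (seed in 1:30) {
    g <- random_graph(n = sample(4:7, 1), p_edge = runif(1, 0.2, 0.8),
                      seed = seed)
    if (nrow(g$edges) == 0) next
    gr <- build_graph(g$edges)
    bt <- betweenness_table(gr)
    want <- oracle_betweenness(g$adj)
    names(want) <- g$nodes
    got <- setNames(bt$betweenness, bt$node)
    expect_equal(got[names(got)], want[names(got)], tolerance = 1e-10)
  }
})

test_that("tree conservation: total betweenness equals internal pair counts", {
  # on a tree each pair has a unique path; sum of betweenness = number of
  # (pair, interior-node) incidences
  set.seed(40)
  for (rep in 1:5) {
    n <- 8
    parent <- c(NA, sapply(2:n, function(i) sample(i - 1, 1)))
    edges <- data.frame(source = paste0("v", parent[-1]),
                        target = paste0("v", 2:n))
    gr <- build_graph(edges)
    bt <- betweenness_table(gr)
    d <- igraph::distances(gr)
    expect_equal(sum(bt$betweenness),
                 sum(d[upper.tri(d)] - 1), tolerance = 1e-10)
  }
})

test_that("self-loops are dropped and graphs are simple", {
  expect_warning(g <- build_graph(data.frame(source = c("a", "a", "a"),
                                             target = c("a", "b", "b"))),
                 "self-loop")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
})

test_that("topological attack: worked path example and exhaustion", {
  atk <- topological_attack(path_graph(), "betweenness")
  expect_equal(atk$removed[2], "b")     # first removal
  expect_equal(atk$lcc_size[1:2], c(3, 1))
  expect_equal(atk$lcc_size[nrow(atk)], 0)
  expect_true(all(diff(atk$lcc_size) <= 0))
  # edgeless graph: LCC stays 1 until exhaustion
  g0 <- igraph::make_empty_graph(n = 4, directed = FALSE)
  igraph::V(g0)$name <- letters[1:4]
  a0 <- topological_attack(g0, "degree")
  expect_true(all(a0$lcc_size[-nrow(a0)] == 1))
})

test_that("attack curves are monotone and respect strategy/ties", {
  for (seed in 31:45) {
    g <- random_graph(n = 7, p_edge = 0.4, seed = seed)
    if (nrow(g$edges) == 0) next
    gr <- build_graph(g$edges)
    for (rec in c(TRUE, FALSE)) {
      atk <- topological_attack(gr, "betweenness", recompute = rec)
      expect_true(all(diff(atk$lcc_size) <= 0))
      expect_equal(atk$lcc_size[nrow(atk)], 0)
    }
  }
  # given-order strategy follows the order verbatim
  atk <- topological_attack(path_graph(), "given-order",
                            order = c("a", "c", "b"))
  expect_equal(atk$removed[-1], c("a", "c", "b"))
  expect_error(topological_attack(path_graph(), "given-order"), "order")
})

test_that("understudied ranking follows rank-percentile arithmetic", {
  cent <- data.frame(node = c("a", "b", "c", "d", "e"),
                     betweenness = c(10, 8, 6, 4, 2),
                     normalized = c(1, 0.8, 0.6, 0.4, 0.2))
  lit <- data.frame(node = c("a", "b", "c", "d"), count = c(100, 0, 50, 10))
  rk <- rank_understudied(cent, lit)
  # hand-ranked percentiles: centrality ranks 5..1 -> 1.0,0.8,0.6,0.4,0.2
  # counts: a=100,b=0,c=50,d=10,e=0(missing) -> ranks 5,1.5,4,3,1.5 -> /5
  hand <- c(a = 1.0 - 1.0, b = 0.8 - 0.3, c = 0.6 - 0.8,
            d = 0.4 - 0.6, e = 0.2 - 0.3)
  expect_equal(setNames(rk$score, rk$node)[names(hand)], hand)
  expect_equal(rk$node[1], "b")
  expect_true(rk$missing_count[rk$node == "e"])
  # max centrality with zero citations ranks first
  lit2 <- data.frame(node = c("a", "b", "c", "d", "e"),
                     count = c(0, 5, 5, 5, 5))
  expect_equal(rank_understudied(cent, lit2)$node[1], "a")
  # all-ties: every score 0
  cent0 <- data.frame(node = letters[1:4], betweenness = rep(1, 4),
                      normalized = rep(0.1, 4))
  lit0 <- data.frame(node = letters[1:4], count = rep(7, 4))
  expect_true(all(rank_understudied(cent0, lit0)$score == 0))
})

test_that("ORA matches the exact combinatorial tail sum", {
  universe <- paste0("g", 1:20)
  sets <- list(setA = paste0("g", 1:5))
  query <- paste0("g", c(1:4, 10))
  res <- ora_enrichment(query, sets, universe)
  expect_equal(res$p_hyper, 76 / 15504, tolerance = 1e-12)  # hand-computed
  # overlap 0 and query = universe give p = 1
  expect_equal(ora_enrichment(paste0("g", 10:14),
                              list(s = paste0("g", 1:5)), universe)$p_hyper, 1)
  expect_equal(ora_enrichment(universe, list(s = paste0("g", 1:5)),
                              universe)$p_hyper, 1)
  # random parameter sweep against the oracle
  set.seed(50)
  for (rep in 1:50) {
    N <- sample(10:50, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    uni <- paste0("u", 1:N)
    set <- sample(uni, K)
    qry <- sample(uni, n)
    k <- length(intersect(set, qry))
    p <- ora_enrichment(qry, list(s = set), uni)$p_hyper
    expect_equal(p, oracle_hyper_tail(k, K, N, n), tolerance = 1e-12)
  }
  expect_error(ora_enrichment(c("zz"), list(s = "g1"), universe), "outside")
  expect_error(ora_enrichment(character(0), list(s = "g1"), universe), "query")
})
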