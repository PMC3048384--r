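test_that("series and parallel circuits give textbook currents", {
  # series: tg - a - c, unit conductances -> current 1 everywhere, V = 2,1,0
  mk <- function(edges, cand, tg = "tg") {
    edges$directed <- edges$type != "ppi"
    structure(list(nodes = unique(c(edges$u, edges$v)), edges = edges,
                   tg = tg, tag_id = NA, candidates = cand,
                   solvable = TRUE, reason = NULL),
              class = "circuit_instance")
  }
  series <- mk(data.frame(u = c("x", "tg", "a"), v = c("tg", "a", "c"),
                          type = c("protein_dna", "ppi", "ppi"), w = 1),
               cand = "c")
  # the x -> tg TF edge is a stub; all current still runs tg -> a -> c
  sol <- solve_circuit(series)
  expect_equal(unname(sol$V[c("tg", "a", "c")]), c(2, 1, 0),
               tolerance = 1e-12)
  expect_equal(unname(sol$X["c"]), 1, tolerance = 1e-12)

  # parallel divider: conductances 1 and 3 -> branch currents 0.25 / 0.75
  par <- mk(data.frame(u = c("tg", "tg"), v = c("c", "c"), type = "ppi",
                       w = c(1, 3)), cand = "c")
  # two parallel edges collapse in the constructor, so build two 2-hop arms
  par <- mk(data.frame(u = c("tg", "a1", "tg", "a2"),
                       v = c("a1", "c", "a2", "c"),
                       type = "ppi", w = c(2, 2, 6, 6)), cand = "c")
  sol <- solve_circuit(par)   # arm conductances: series(2,2)=1, series(6,6)=3
  expect_equal(unname(sol$I[1]), 0.25, tolerance = 1e-12)
  expect_equal(unname(sol$I[3]), 0.75, tolerance = 1e-12)
})

test_that("sparse solution matches the dense block-system oracle", {
  set.seed(31)
  for (i in 1:25) {
    inst <- random_circuit_instance(25)
    sol <- solve_circuit(inst)
    oracle <- dense_circuit_solve(inst)
    expect_equal(sol$V, oracle$V, tolerance = 1e-10)
    expect_equal(sol$I, oracle$I, tolerance = 1e-10)
    expect_equal(sol$X, oracle$X, tolerance = 1e-10)
    expect_equal(sum(sol$X), 1, tolerance = 1e-8)
    expect_true(all(sol$X >= -1e-8))
    # Kirchhoff residual at free interior nodes
    for (n in setdiff(inst$nodes, c(inst$tg, inst$candidates))) {
      res <- sum(sol$I[inst$edges$u == n]) - sum(sol$I[inst$edges$v == n])
      expect_lt(abs(res), 1e-8)
    }
  }
})

test_that("unit-conductance currents equal random-walk absorption probabilities", {
  set.seed(17)
  inst <- random_circuit_instance(15, unit = TRUE)
  sol <- solve_circuit(inst)
  rw <- random_walk_absorption(inst, n_walks = 2e5)
  se <- sqrt(pmax(sol$X * (1 - sol$X), 1e-12) / 2e5)
  expect_true(all(abs(sol$X - rw) <= 3 * se + 1e-9))
})

test_that("currents are invariant under uniform conductance scaling", {
  set.seed(12)
  inst <- random_circuit_instance(20)
  sol <- solve_circuit(inst)
  inst2 <- inst; inst2$edges$w <- inst$edges$w * 7.3
  sol2 <- solve_circuit(inst2)
  expect_equal(sol$X, sol2$X, tolerance = 1e-10)
  expect_equal(sol$I, sol2$I, tolerance = 1e-10)
})

test_that("removing a zero-current edge leaves the solution unchanged", {
  # symmetric diamond: the rung between the two arms carries no current
  edges <- data.frame(u = c("s", "tg", "tg", "a", "b", "a"),
                      v = c("tg", "a", "b", "c", "c", "b"),
                      type = c("protein_dna", rep("ppi", 5)),
                      w = c(1, 1, 1, 1, 1, 1))
  edges$directed <- edges$type != "ppi"
  inst <- structure(list(nodes = c("s", "tg", "a", "b", "c"),
                         edges = edges, tg = "tg", tag_id = NA,
                         candidates = "c", solvable = TRUE, reason = NULL),
                    class = "circuit_instance")
  sol <- solve_circuit(inst)
  rung <- which(edges$u == "a" & edges$v == "b")
  expect_equal(sol$I[rung], 0, tolerance = 1e-12)
  inst2 <- inst; inst2$edges <- edges[-rung, ]
  sol2 <- solve_circuit(inst2)
  expect_equal(sol2$X, sol$X, tolerance = 1e-10)
  expect_equal(sol2$V, sol$V, tolerance = 1e-10)
})

test_that("conductances average absolute correlations with an epsilon floor", {
  toy <- worked_toy()
  # tf1 and a share the target's tumor signature exactly -> |corr| = 1
  expect_equal(edge_conductance("tf1", "a", "tg", toy$expr), 1,
               tolerance = 1e-12)
  # a gene missing from the expression matrix contributes eps
  w <- edge_conductance("tf1", "not_measured", "tg", toy$expr)
  expect_equal(w, (1 + 1e-3) / 2, tolerance = 1e-9)
  # hand-computed Pearson mean for a weakly correlated pair
  tum <- tumor_values(toy$expr)
  expected <- mean(c(abs(cor(tum["b", ], tum["tg", ])),
                     abs(cor(tum["c2", ], tum["tg", ]))))
  expect_equal(edge_conductance("b", "c2", "tg", toy$expr), expected,
               tolerance = 1e-12)
})

test_that("the TF constraint prunes the toy instance to the hand enumeration", {
  toy <- worked_toy()
  inst <- build_instance(toy$network, toy$tg,
                         region_genes = toy$region_genes, expr = NULL)
  expect_true(inst$solvable)
  expect_setequal(inst$nodes, c("tg", "tf1", "a", "b", "c1", "c2"))
  expect_equal(nrow(inst$edges), 5)       # ppi distractors at tg removed
  expect_equal(inst$candidates, c("c1", "c2"))
  sol <- solve_circuit(inst)
  expect_equal(unname(sol$V[c("tg", "tf1", "a", "b", "c1", "c2")]),
               c(2, 1, 0.5, 0.5, 0, 0), tolerance = 1e-12)
  expect_equal(unname(sol$X), c(0.5, 0.5), tolerance = 1e-12)

  # no protein-DNA in-edge at the target -> unsolvable
  net2 <- toy$network
  net2$edges <- net2$edges[net2$edges$type != "protein_dna", ]
  inst2 <- build_instance(net2, toy$tg, region_genes = toy$region_genes)
  expect_false(inst2$solvable)
  expect_match(inst2$reason, "TF")
})

test_that("direction heuristic removes reverse-used directed edges", {
  # tg -> a -> c with a directed phosphorylation a -> b -> c shortcut whose
  # admissible direction (regulated -> regulator) opposes the actual flow
  edges <- data.frame(u = c("s", "tg", "a", "a", "b"),
                      v = c("tg", "a", "c", "b", "c"),
                      type = c("protein_dna", "ppi", "ppi",
                               "phosphorylation", "ppi"),
                      w = 1)
  edges$directed <- edges$type != "ppi"
  inst <- structure(list(nodes = c("s", "tg", "a", "b", "c"),
                         edges = edges, tg = "tg", tag_id = NA,
                         candidates = "c", solvable = TRUE, reason = NULL),
                    class = "circuit_instance")
  sol0 <- solve_circuit(inst)
  expect_equal(sol0$wrong_direction_count, 1)  # current runs a -> b
  sol <- solve_directed(inst, wrong_dir_max = 0)
  expect_equal(sol$wrong_direction_count, 0)
  expect_equal(nrow(sol$instance$edges), 4)    # shortcut removed
  expect_gt(sol$iterations, 1)

  # with no directed edges the first solve already terminates
  edges2 <- edges; edges2$type <- "ppi"; edges2$directed <- FALSE
  inst2 <- inst; inst2$edges <- edges2
  sol2 <- solve_directed(inst2, wrong_dir_max = 0)
  expect_equal(sol2$iterations, 1)
  expect_equal(sol2$X, solve_circuit(inst2)$X)
})

test_that("wrong-direction count never increases across heuristic iterations", {
  set.seed(77)
  for (i in 1:20) {
    inst <- random_circuit_instance(20)
    # randomly mark a third of the edges as directed phosphorylations
    k <- sample(nrow(inst$edges), ceiling(nrow(inst$edges) / 3))
    inst$edges$type[k] <- "phosphorylation"
    inst$edges$directed <- inst$edges$type != "ppi"
    counts <- c()
    cur <- inst
    repeat {
      sol <- solve_circuit(cur)
      counts <- c(counts, sol$wrong_direction_count)
      if (sol$wrong_direction_count == 0) break
      edges <- cur$edges[!sol$wrong_direction, , drop = FALSE]
      pruned <- tryCatch(causalflow:::prune_to_component(edges, cur$tg),
                         error = function(e) NULL)
      if (is.null(pruned)) break
      cand <- intersect(cur$candidates, pruned$nodes)
      if (length(cand) == 0) break
      cur$nodes <- pruned$nodes; cur$edges <- pruned$edges
      cur$candidates <- cand
    }
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("rewiring preserves degrees, is seed-reproducible and moves far", {
  sim <- simulate_cohort(simulation_config(n_genes = 60, n_loci = 20,
                                           n_tumor = 30, n_control = 5,
                                           seed = 4))
  net <- sim$network
  deg <- function(n) {
    d <- table(c(n$edges$u, n$edges$v))
    d[order(names(d))]
  }
  set.seed(1); r1 <- rewire_network(net)
  set.seed(1); r2 <- rewire_network(net)
  set.seed(2); r3 <- rewire_network(net)
  expect_identical(r1$edges, r2$edges)
  expect_false(identical(r1$edges, r3$edges))
  expect_equal(deg(r1), deg(net))
  expect_equal(table(r1$edges$type), table(net$edges$type))
  key <- function(n) paste(pmin(n$edges$u, n$edges$v),
                           pmax(n$edges$u, n$edges$v), n$edges$type)
  jac <- length(intersect(key(net), key(r1))) /
    length(union(key(net), key(r1)))
  expect_lt(jac, 0.5)
})

test_that("empirical p-values follow the fitted-normal upper tail", {
  sol <- list(X = c(a = 0.5, b = 0.9, c = 0.1))
  null <- matrix(c(0.5, 0.5, 0.5 + 0.2 * c(-1, 1),
                   0.5, 0.5, 0.5 + 0.2 * c(-1, 1),
                   0.1, 0.1, 0.1 + 0.0 * c(-1, 1)),
                 nrow = 4)
  null <- cbind(a = c(0.3, 0.5, 0.7, 0.5), b = c(0.3, 0.5, 0.7, 0.5),
                c = c(0.1, 0.1, 0.1, 0.1))
  pv <- empirical_pvalues(sol, null)
  expect_equal(pv$p_value[pv$gene == "a"], 0.5, tolerance = 1e-12)
  sd_b <- sd(null[, "b"])
  expect_equal(pv$p_value[pv$gene == "b"],
               pnorm((0.9 - 0.5) / sd_b, lower.tail = FALSE),
               tolerance = 1e-12)
  # observed two sd above the mean ~ 0.02275
  sol2 <- list(X = c(a = 0.5 + 2 * sd(null[, "a"])))
  expect_equal(empirical_pvalues(sol2, null)$p_value, 0.0227501,
               tolerance = 1e-4)
  # degenerate null: p = 0 above the mean, 1 otherwise
  expect_equal(pv$p_value[pv$gene == "c"], 1)
  sol3 <- list(X = c(c = 0.2))
  expect_equal(empirical_pvalues(sol3, null)$p_value, 0)
  # below the null mean the tail exceeds one half
  sol4 <- list(X = c(a = 0.3))
  expect_gt(empirical_pvalues(sol4, null)$p_value, 0.5)
})

test_that("candidate selection applies the 70%-of-max and p filters", {
  res <- data.frame(target = "t", tag = "L",
                    gene = c("a", "b", "c"),
                    current = c(1.0, 0.8, 0.6),
                    p_value = c(0.01, 0.02, 0.001))
  kept <- select_candidates(res)
  expect_setequal(kept$gene, c("a", "b"))
  single <- data.frame(target = "t", tag = "L2", gene = "z",
                       current = 0.4, p_value = 0.04)
  expect_equal(select_candidates(single)$gene, "z")
  # p filter applies on top of the current filter
  res$p_value <- c(0.2, 0.02, 0.001)
  expect_equal(select_candidates(res)$gene, "b")
})
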