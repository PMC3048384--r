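# minimal solved-instance stand-in: only the fields path extraction reads
fake_solution <- function(edges, node_current, tg) {
  edges$type <- "ppi"; edges$directed <- FALSE; edges$w <- 1
  structure(list(instance = list(nodes = unique(c(edges$u, edges$v)),
                                 edges = edges, tg = tg),
                 node_current = node_current),
            class = "circuit_solution")
}

test_that("a unique path is returned regardless of currents", {
  edges <- data.frame(u = c("tg", "m", "n"), v = c("m", "n", "cg"))
  curr <- c(tg = 2, m = 0.01, n = 0.02, cg = 1)
  p <- max_current_path(fake_solution(edges, curr, "tg"),
                        node_p = setNames(rep(0, 4), names(curr)),
                        "tg", "cg")
  expect_equal(p$nodes, c("tg", "m", "n", "cg"))
  expect_equal(p$objective, 0.01)
})

test_that("bottleneck objective prefers the wider branch", {
  # branch 1 interior {a: 0.9}; branch 2 interior {b: 0.5, c: 0.8}
  edges <- data.frame(u = c("tg", "a", "tg", "b", "c"),
                      v = c("a", "cg", "b", "c", "cg"))
  curr <- c(tg = 2, a = 0.9, b = 0.5, c = 0.8, cg = 1)
  p <- max_current_path(fake_solution(edges, curr, "tg"),
                        node_p = setNames(rep(0, 5), names(curr)),
                        "tg", "cg")
  expect_equal(p$nodes, c("tg", "a", "cg"))
  expect_equal(p$objective, 0.9)
})

test_that("node filter removes high-p interior nodes but keeps endpoints", {
  edges <- data.frame(u = c("tg", "a", "tg", "b"),
                      v = c("a", "cg", "b", "cg"))
  curr <- c(tg = 2, a = 0.9, b = 0.3, cg = 1)
  node_p <- c(tg = 1, a = 0.2, b = 0.01, cg = 1)  # endpoint p ignored
  p <- max_current_path(fake_solution(edges, curr, "tg"), node_p,
                        "tg", "cg")
  expect_equal(p$nodes, c("tg", "b", "cg"))  # a filtered out despite width
  # filtering everything leaves no path
  node_p2 <- c(tg = 1, a = 0.2, b = 0.2, cg = 1)
  expect_null(max_current_path(fake_solution(edges, curr, "tg"), node_p2,
                               "tg", "cg"))
})

test_that("widest path equals the exhaustive optimum on random graphs", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(6:15, 1)
    g <- igraph::sample_gnp(n, 0.35)
    el <- igraph::as_edgelist(g)
    if (nrow(el) < 2) next
    genes <- sprintf("v%02d", seq_len(n))
    edges <- data.frame(u = genes[el[, 1]], v = genes[el[, 2]],
                        stringsAsFactors = FALSE)
    curr <- setNames(runif(n, 0.01, 1), genes)
    tg <- genes[1]; cg <- genes[n]
    sol <- fake_solution(edges, curr, tg)
    p <- max_current_path(sol, setNames(rep(0, n), genes), tg, cg)
    opt <- brute_force_widest(edges, curr, tg, cg)
    if (is.null(opt)) {
      expect_null(p)
    } else {
      expect_equal(p$objective, opt, tolerance = 1e-12)
    }
  }
})

test_that("raising the p filter threshold never shrinks the optimum", {
  set.seed(29)
  for (i in 1:10) {
    n <- 10
    g <- igraph::sample_gnp(n, 0.4)
    el <- igraph::as_edgelist(g)
    if (nrow(el) < 2) next
    genes <- sprintf("v%02d", seq_len(n))
    edges <- data.frame(u = genes[el[, 1]], v = genes[el[, 2]],
                        stringsAsFactors = FALSE)
    curr <- setNames(runif(n, 0.01, 1), genes)
    node_p <- setNames(runif(n), genes)
    sol <- fake_solution(edges, curr, genes[1])
    objs <- vapply(c(0.2, 0.5, 1), function(th) {
      p <- max_current_path(sol, node_p, genes[1], genes[n], p_max = th)
      if (is.null(p)) -1 else min(p$objective, 2)  # cap Inf (no interior)
    }, numeric(1))
    expect_true(all(diff(objs) >= 0))
  }
})

test_that("product objective agrees with enumeration and differs when it should", {
  # product favors the short strong branch; bottleneck the long flat one
  edges <- data.frame(u = c("tg", "a", "tg", "b", "c"),
                      v = c("a", "cg", "b", "c", "cg"))
  curr <- c(tg = 2, a = 0.6, b = 0.55, c = 0.55, cg = 1)
  sol <- fake_solution(edges, curr, "tg")
  np <- setNames(rep(0, 5), names(curr))
  pb <- max_current_path(sol, np, "tg", "cg", objective = "bottleneck")
  pp <- max_current_path(sol, np, "tg", "cg", objective = "product")
  expect_equal(pb$objective, 0.6)
  expect_equal(pp$nodes, c("tg", "a", "cg"))   # 0.6 > 0.55 * 0.55
  expect_equal(pp$objective, 0.6)
})

test_that("hub counting uses a strict interior-occurrence threshold", {
  mk <- function(nodes) structure(list(target = nodes[1],
                                       causal = nodes[length(nodes)],
                                       nodes = nodes),
                                  class = "causal_path")
  paths <- c(replicate(11, mk(c("t", "hub", "c")), simplify = FALSE),
             replicate(10, mk(c("t", "almost", "c")), simplify = FALSE))
  hubs <- count_hubs(paths, min_occurrences = 10)
  expect_equal(hubs$gene, "hub")
  expect_equal(hubs$n_paths, 11)
  expect_equal(nrow(count_hubs(list())), 0)
  # endpoints never count as hub occurrences
  many <- replicate(20, mk(c("t", "x", "c")), simplify = FALSE)
  expect_false("t" %in% count_hubs(many)$gene)
})

test_that("subnetworks are exact path unions without duplicates", {
  mk <- function(cgl, nodes) structure(list(target = nodes[1], causal = cgl,
                                            nodes = nodes),
                                       class = "causal_path")
  paths <- list(mk("cg1", c("t1", "m", "cg1")),
                mk("cg1", c("t2", "m", "cg1")),
                mk("cg2", c("t1", "n", "cg2")))
  subs <- assemble_subnetworks(paths)
  expect_setequal(names(subs), c("cg1", "cg2"))
  expect_setequal(subs$cg1$nodes, c("t1", "t2", "m", "cg1"))
  expect_equal(nrow(subs$cg1$edges), 3)  # m-cg1 shared edge deduplicated
  expect_false(any(duplicated(subs$cg1$nodes)))
  set.seed(5)
  for (i in 1:20) {
    ps <- replicate(sample(2:5, 1),
                    mk("cgX", c("t", sample(letters, 3), "cgX")),
                    simplify = FALSE)
    sub <- assemble_subnetworks(ps)$cgX
    expect_setequal(sub$nodes, unique(unlist(lapply(ps, `[[`, "nodes"))))
  }
})
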