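# Independent oracles used across the suite.  These deliberately avoid the
# package's production code paths: the circuit oracle assembles the full
# dense block system (Ohm rows, Kirchhoff rows, ground rows) and solves it
# with base::solve; the cover/path oracles enumerate exhaustively.

# Dense solve of the full circuit system.
# Unknowns stacked as [I (|E|), V (|N|), X (|C|)]:
#   per edge   e=(u,v):  I_e - w V_u + w V_v = 0
#   per node   n:        sum_{u=n} I_e - sum_{v=n} I_e + [n in C] X_n = [n == tg]
#   per ground c:        V_c = 0
dense_circuit_solve <- function(instance) {
  nodes <- instance$nodes; edges <- instance$edges
  cand <- instance$candidates; tg <- instance$tg
  nE <- nrow(edges); nN <- length(nodes); nC <- length(cand)
  ni <- stats::setNames(seq_len(nN), nodes)
  ci <- stats::setNames(seq_len(nC), cand)
  A <- matrix(0, nE + nN + nC, nE + nN + nC)
  b <- rep(0, nE + nN + nC)
  for (e in seq_len(nE)) {
    u <- ni[[edges$u[e]]]; v <- ni[[edges$v[e]]]; w <- edges$w[e]
    A[e, e] <- 1
    A[e, nE + u] <- -w
    A[e, nE + v] <- w
  }
  for (n in seq_len(nN)) {
    row <- nE + n
    out_e <- which(edges$u == nodes[n]); in_e <- which(edges$v == nodes[n])
    A[row, out_e] <- A[row, out_e] + 1
    A[row, in_e] <- A[row, in_e] - 1
    if (nodes[n] %in% cand) A[row, nE + nN + ci[[nodes[n]]]] <- 1
    if (nodes[n] == tg) b[row] <- 1
  }
  for (cc in seq_len(nC))
    A[nE + nN + cc, nE + ni[[cand[cc]]]] <- 1
  sol <- solve(A, b)
  list(I = sol[seq_len(nE)],
       V = stats::setNames(sol[nE + seq_len(nN)], nodes),
       X = stats::setNames(sol[nE + nN + seq_len(nC)], cand))
}

# Monte-Carlo absorption probabilities of the unit-conductance random walk
# (walker starts at tg, moves to a uniform neighbor, is absorbed at the
# grounded candidates).  Grouped sampling keeps it vectorized.
random_walk_absorption <- function(instance, n_walks = 1e6,
                                   max_steps = 100000) {
  nodes <- instance$nodes; edges <- instance$edges
  cand <- instance$candidates; tg <- instance$tg
  idx <- stats::setNames(seq_along(nodes), nodes)
  nbrs <- vector("list", length(nodes))
  for (e in seq_len(nrow(edges))) {
    u <- idx[[edges$u[e]]]; v <- idx[[edges$v[e]]]
    nbrs[[u]] <- c(nbrs[[u]], v); nbrs[[v]] <- c(nbrs[[v]], u)
  }
  absorbing <- idx[cand]
  pos <- rep(idx[[tg]], n_walks)
  absorbed <- integer(0)
  for (step in seq_len(max_steps)) {
    done <- pos %in% absorbing
    if (any(done)) {
      absorbed <- c(absorbed, pos[done])
      pos <- pos[!done]
    }
    if (length(pos) == 0) break
    newpos <- pos
    for (n in unique(pos)) {
      at <- pos == n
      nb <- nbrs[[n]]
      newpos[at] <- nb[sample.int(length(nb), sum(at), replace = TRUE)]
    }
    pos <- newpos
  }
  counts <- tabulate(absorbed, nbins = length(nodes))
  stats::setNames(counts[idx[cand]] / n_walks, cand)
}

# Exhaustive minimum multi-set cover (unweighted, alpha/beta), subsets by
# bitmask.  Returns the optimal size, or Inf when infeasible.
brute_force_cover_size <- function(incidence, alpha, beta = 0) {
  genes <- rownames(incidence)
  n <- length(genes)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    pick <- genes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(pick) >= best) next
    cov <- colSums(incidence[pick, , drop = FALSE])
    if (sum(cov < alpha) <= beta) best <- length(pick)
  }
  best
}

# Exhaustive minimum weighted multi-set cover.
brute_force_weighted_cover_size <- function(weights, gamma, delta = 0) {
  genes <- rownames(weights)
  n <- length(genes)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    pick <- genes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(pick) >= best) next
    acc <- colSums(weights[pick, , drop = FALSE])
    if (sum(acc < gamma) <= delta) best <- length(pick)
  }
  best
}

# Exhaustive bottleneck objective over all simple tg -> cg paths.
brute_force_widest <- function(edges, curr, tg, cg) {
  g <- igraph::graph_from_data_frame(edges[, c("u", "v")], directed = FALSE)
  if (!(tg %in% igraph::V(g)$name) || !(cg %in% igraph::V(g)$name))
    return(NULL)
  paths <- igraph::all_simple_paths(g, from = tg, to = cg)
  if (length(paths) == 0) return(NULL)
  scores <- vapply(paths, function(p) {
    nm <- igraph::V(g)$name[p]
    interior <- nm[-c(1, length(nm))]
    if (length(interior) == 0) Inf else min(curr[interior])
  }, numeric(1))
  max(scores)
}

# Random solvable circuit instance on <= n_max nodes: a random connected
# graph, one TF wired into the target, random positive conductances and a
# random candidate subset.
random_circuit_instance <- function(n_max = 30, unit = FALSE) {
  n <- sample(6:n_max, 1)
  g <- igraph::sample_gnm(n, min(2 * n, n * (n - 1) / 2))
  while (igraph::components(g)$no > 1)
    g <- igraph::sample_gnm(n, min(2 * n, n * (n - 1) / 2))
  el <- igraph::as_edgelist(g)
  genes <- sprintf("n%02d", seq_len(n))
  edges <- data.frame(u = genes[el[, 1]], v = genes[el[, 2]],
                      type = "ppi", directed = FALSE,
                      stringsAsFactors = FALSE)
  tg <- genes[1]
  # replace one edge at tg by a protein-DNA in-edge so the TF rule holds
  at <- which(edges$u == tg | edges$v == tg)[1]
  other <- setdiff(c(edges$u[at], edges$v[at]), tg)
  edges$u[at] <- other; edges$v[at] <- tg
  edges$type[at] <- "protein_dna"; edges$directed[at] <- TRUE
  edges$w <- if (unit) 1 else stats::runif(nrow(edges), 0.05, 1)
  cand <- sample(setdiff(genes, c(tg, other)),
                 sample(1:min(4, n - 2), 1))
  structure(list(nodes = genes, edges = edges, tg = tg, tag_id = NA,
                 candidates = sort(cand), solvable = TRUE, reason = NULL),
            class = "circuit_instance")
}

# Small random cover instances.
random_cover_instance <- function(n_genes = 8, n_cases = 6,
                                  p_edge = 0.45) {
  m <- matrix(stats::runif(n_genes * n_cases) < p_edge, n_genes, n_cases,
              dimnames = list(sprintf("g%d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_cases))))
  m
}
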