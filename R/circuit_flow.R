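## Circuit-flow scoring of candidate causal genes.
##
## The target gene injects one unit of current into the interaction
## network; all candidate genes of a tag-locus region are grounded at
## voltage 0.  Edge conductances encode expression correlation with the
## target, so current preferentially follows paths whose genes co-vary
## with the target.  The current exiting into each candidate measures how
## well the network supports that gene as the cause of the target's
## dysregulation.

#' Edge conductance from expression correlation with the target
#'
#' The conductance of an edge (u, v) is the mean of the absolute Pearson
#' correlations of u and v with the target gene over tumor samples, floored
#' at `eps`.  A gene absent from the expression matrix (or with undefined
#' correlation) contributes `eps` in place of its absolute correlation, so
#' a single non-correlated node damps but never interrupts the flow.
#'
#' @param u,v Gene identifiers (vectorized, equal length).
#' @param tg Target gene (must be in `expr`).
#' @param expr An [expression_matrix()].
#' @param eps Conductance floor (default 1e-3).
#' @return Numeric vector of conductances.
#' @export
edge_conductance <- function(u, v, tg, expr, eps = 1e-3) {
  ac <- abs_target_correlation(expr, tg, eps)
  cu <- ifelse(u %in% names(ac), ac[u], eps)
  cv <- ifelse(v %in% names(ac), ac[v], eps)
  pmax((cu + cv) / 2, eps)
}

# |Pearson corr with tg| over tumor samples for every expression gene;
# undefined correlations (zero variance) fall back to eps
abs_target_correlation <- function(expr, tg, eps = 1e-3) {
  stopifnot(tg %in% expr$genes)
  tum <- tumor_values(expr)
  r <- suppressWarnings(as.vector(stats::cor(t(tum), tum[tg, ])))
  r <- abs(r)
  r[is.na(r)] <- eps
  names(r) <- expr$genes
  r
}

#' Build a circuit instance for one (target gene, tag locus) pair
#'
#' Enforces the biological constraints before solving: only transcription
#' factors directly change a target's expression, so every edge incident to
#' the target is dropped except protein-DNA edges from a TF into the
#' target.  Candidates are the region's genes present in the network
#' (minus the target), all grounded.  Nodes disconnected from the target
#' are pruned.
#'
#' @param network An [interaction_network()].
#' @param tg Target gene.
#' @param tag One row of a [select_tag_loci()] table (or its `tag_id`) with
#'   the tag table passed as `tags`; alternatively pass `region_genes`
#'   directly.
#' @param expr An [expression_matrix()] for correlation conductances, or
#'   `NULL` for unit conductances (used by the permutation null).
#' @param tags Tag table from [select_tag_loci()] when `tag` is an id.
#' @param region_genes Optional explicit candidate gene pool overriding
#'   `tag`/`tags`.
#' @param eps Conductance floor.
#' @return An object of class `circuit_instance` with fields `nodes`,
#'   `edges` (with conductance column `w`), `tg`, `candidates`, `solvable`
#'   and (when unsolvable) `reason`.
#' @export
build_instance <- function(network, tg, tag = NULL, expr = NULL,
                           tags = NULL, region_genes = NULL, eps = 1e-3) {
  stopifnot(inherits(network, "interaction_network"))
  if (is.null(region_genes)) {
    if (is.null(tags) || is.null(tag))
      stop("either region_genes or (tag, tags) must be given")
    region_genes <- attr(tags, "region_genes")[[as.character(tag)]]
  }
  tag_id <- if (!is.null(tag)) as.character(tag) else NA_character_
  if (!tg %in% network$nodes$gene)
    return(unsolvable_instance(tg, tag_id, "target gene not in network"))
  edges <- network$edges
  tf <- stats::setNames(network$nodes$is_tf, network$nodes$gene)
  at_tg <- edges$u == tg | edges$v == tg
  keep_tf <- edges$type == "protein_dna" & edges$v == tg & tf[edges$u]
  edges <- edges[!at_tg | keep_tf, , drop = FALSE]
  if (!any(edges$u == tg | edges$v == tg))
    return(unsolvable_instance(tg, tag_id,
                               "no TF protein-DNA edge into target"))
  # conductances
  if (is.null(expr)) {
    edges$w <- 1
  } else {
    ac <- abs_target_correlation(expr, tg, eps)
    cu <- ifelse(edges$u %in% names(ac), ac[edges$u], eps)
    cv <- ifelse(edges$v %in% names(ac), ac[edges$v], eps)
    edges$w <- pmax((cu + cv) / 2, eps)
  }
  inst <- prune_to_component(edges, tg)
  candidates <- setdiff(intersect(region_genes, inst$nodes), tg)
  if (length(candidates) == 0)
    return(unsolvable_instance(tg, tag_id,
                               "no candidate gene reachable from target"))
  structure(list(nodes = inst$nodes, edges = inst$edges, tg = tg,
                 tag_id = tag_id, candidates = sort(candidates),
                 solvable = TRUE, reason = NULL),
            class = "circuit_instance")
}

unsolvable_instance <- function(tg, tag_id, reason) {
  structure(list(nodes = character(0),
                 edges = data.frame(u = character(0), v = character(0),
                                    type = character(0),
                                    directed = logical(0), w = numeric(0)),
                 tg = tg, tag_id = tag_id, candidates = character(0),
                 solvable = FALSE, reason = reason),
            class = "circuit_instance")
}

# restrict an edge table to the connected component containing tg
prune_to_component <- function(edges, tg) {
  g <- igraph::graph_from_data_frame(edges[, c("u", "v")], directed = FALSE)
  comp <- igraph::components(g)
  keep_nodes <- names(comp$membership)[
    comp$membership == comp$membership[[tg]]]
  edges <- edges[edges$u %in% keep_nodes & edges$v %in% keep_nodes, ,
                 drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = keep_nodes, edges = edges)
}

#' Solve the circuit linear system
#'
#' Ohm's law on every edge, current conservation at every node except the
#' target (net injection 1) and the grounded candidates (voltage 0).  The
#' production path solves the reduced sparse weighted-Laplacian system for
#' the free voltages; edge currents and candidate exit currents follow.
#'
#' @param instance A solvable `circuit_instance`.
#' @param frame Admissible-direction convention for directed edges (see
#'   [solve_directed()]); only affects the reported wrong-direction count.
#' @return An object of class `circuit_solution` with fields `V` (named
#'   voltages, candidates at 0), `I` (signed current per edge row of
#'   `instance$edges`, positive u -> v), `X` (named exit current per
#'   candidate, summing to 1), `node_current` (throughflow per node: half
#'   the sum of absolute incident currents), `wrong_direction_count`
#'   (directed edges whose current opposes the admissible orientation,
#'   see [solve_directed()]), plus `instance`.
#' @export
solve_circuit <- function(instance,
                          frame = c("regulated_to_regulator",
                                    "regulator_to_regulated")) {
  frame <- match.arg(frame)
  stopifnot(inherits(instance, "circuit_instance"))
  if (!instance$solvable) stop("instance is not solvable: ", instance$reason)
  nodes <- instance$nodes
  edges <- instance$edges
  cand <- instance$candidates
  tg <- instance$tg
  free <- setdiff(nodes, cand)
  if (!tg %in% free) stop("target gene must not be grounded")
  fi <- stats::setNames(seq_along(free), free)
  ui <- fi[edges$u]; vi <- fi[edges$v]  # NA when endpoint grounded
  w <- edges$w
  # weighted Laplacian over free nodes (grounded neighbors contribute only
  # to the diagonal)
  both <- !is.na(ui) & !is.na(vi)
  ii <- c(ui[both], vi[both], ui[!is.na(ui)], vi[!is.na(vi)])
  jj <- c(vi[both], ui[both], ui[!is.na(ui)], vi[!is.na(vi)])
  xx <- c(-w[both], -w[both], w[!is.na(ui)], w[!is.na(vi)])
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(free), length(free)))
  b <- rep(0, length(free)); b[fi[[tg]]] <- 1
  Vfree <- tryCatch(as.vector(Matrix::solve(L, b)),
                    error = function(e)
                      stop("singular circuit system (floating component ",
                           "without a grounded candidate): ",
                           conditionMessage(e)))
  V <- stats::setNames(rep(0, length(nodes)), nodes)
  V[free] <- Vfree
  I <- w * (V[edges$u] - V[edges$v])  # positive = current u -> v
  names(I) <- NULL
  # exit current per candidate: net inflow from its incident edges
  X <- vapply(cand, function(cc) {
    sum(I[edges$v == cc]) - sum(I[edges$u == cc])
  }, numeric(1))
  flow_in <- vapply(nodes, function(n)
    sum(abs(I)[edges$u == n | edges$v == n]) / 2, numeric(1))
  wrong <- wrong_direction(edges, I, frame)
  structure(list(V = V, I = I, X = X, node_current = flow_in,
                 wrong_direction_count = sum(wrong),
                 wrong_direction = wrong,
                 frame = frame, instance = instance),
            class = "circuit_solution")
}

# Directed edges are stored regulator/kinase (u) -> regulated/substrate (v).
# Current is injected at the target and exits at the candidate causes, i.e.
# it travels against the direction of regulatory information flow, so in
# the default frame the admissible current direction is v -> u (I < 0) and
# an edge is used in the wrong direction when I > 0.
wrong_direction <- function(edges, I, frame, tol = 1e-12) {
  if (frame == "regulated_to_regulator") edges$directed & I > tol
  else edges$directed & I < -tol
}

#' @export
print.circuit_solution <- function(x, ...) {
  cat(sprintf("circuit_solution: %d nodes, %d edges, %d candidates; sum(X)=%.6f; %d wrong-direction edges\n",
              length(x$V), length(x$I), length(x$X), sum(x$X),
              x$wrong_direction_count))
  invisible(x)
}

#' Solve the circuit while enforcing edge directions heuristically
#'
#' Protein-DNA and phosphorylation edges are directed; an exact directed
#' formulation is a linear program, so a simple heuristic is used instead:
#' solve the undirected system, delete every directed edge whose current
#' opposes its admissible orientation, and repeat until at most
#' `wrong_dir_max` such edges remain or no edge is removed.
#'
#' @param instance A solvable `circuit_instance`.
#' @param wrong_dir_max Tolerated wrong-direction edges; the default is
#'   0.1% of the instance's edge count (at least 1).
#' @param frame Which current direction counts as admissible for a
#'   directed edge; the default treats current flowing regulated ->
#'   regulator as admissible (the source is the target, sinks are causes).
#' @return A `circuit_solution` (see [solve_circuit()]) with an extra field
#'   `iterations`; if deletions disconnect every candidate the result is a
#'   list with `solvable = FALSE` and a `reason`.
#' @export
solve_directed <- function(instance, wrong_dir_max = NULL,
                           frame = c("regulated_to_regulator",
                                     "regulator_to_regulated")) {
  frame <- match.arg(frame)
  stopifnot(inherits(instance, "circuit_instance"))
  if (!instance$solvable) stop("instance is not solvable: ", instance$reason)
  if (is.null(wrong_dir_max))
    wrong_dir_max <- max(1, round(0.001 * nrow(instance$edges)))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sol <- solve_circuit(instance, frame = frame)
    if (sol$wrong_direction_count <= wrong_dir_max) break
    keep <- !sol$wrong_direction
    edges <- instance$edges[keep, , drop = FALSE]
    pruned <- tryCatch(prune_to_component(edges, instance$tg),
                       error = function(e) NULL)
    cand <- if (is.null(pruned)) character(0)
      else intersect(instance$candidates, pruned$nodes)
    if (length(cand) == 0)
      return(structure(list(solvable = FALSE,
                            reason = "direction filtering disconnected all candidates",
                            instance = instance, iterations = iter),
                       class = "circuit_solution"))
    instance$nodes <- pruned$nodes
    instance$edges <- pruned$edges
    instance$candidates <- cand
  }
  sol$iterations <- iter
  sol$solvable <- TRUE
  sol
}

#' Degree-preserving rewiring of an interaction network
#'
#' Randomizes the topology by repeated double-edge swaps within each edge
#' type: two edges (a, b) and (c, d) of the same type become (a, d) and
#' (c, b).  Every node therefore keeps its degree per edge type — and, for
#' the directed types, its regulator/regulated (kinase/substrate) role
#' counts — so a target gene keeps as many TF protein-DNA in-edges as it
#' had and null circuit instances remain structurally comparable to the
#' observed one.  Swaps creating self-loops or duplicating an existing
#' (pair, type) edge are rejected.
#'
#' @param network An [interaction_network()].
#' @param swaps_per_edge Accepted swaps per edge within each type class
#'   (default 10).
#' @return A rewired `interaction_network` with the same nodes and
#'   per-type degree sequences.
#' @export
rewire_network <- function(network, swaps_per_edge = 10) {
  edges <- network$edges
  key <- function(u, v, type) paste(pmin(u, v), pmax(u, v), type)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(edges$u, edges$v, edges$type)) assign(k, TRUE, envir = seen)
  for (ty in unique(edges$type)) {
    rows <- which(edges$type == ty)
    m <- length(rows)
    if (m < 2) next
    n_swaps <- swaps_per_edge * m
    accepted <- 0L; attempts <- 0L
    max_attempts <- 100L * m * max(1L, swaps_per_edge)
    while (accepted < n_swaps && attempts < max_attempts) {
      attempts <- attempts + 1L
      ij <- rows[sample.int(m, 2)]
      i <- ij[1]; j <- ij[2]
      a <- edges$u[i]; b <- edges$v[i]; c <- edges$u[j]; d <- edges$v[j]
      if (length(unique(c(a, b, c, d))) < 4) next
      k1 <- key(a, d, ty); k2 <- key(c, b, ty)
      if (exists(k1, envir = seen) || exists(k2, envir = seen) || k1 == k2)
        next
      rm(list = c(key(a, b, ty), key(c, d, ty)), envir = seen)
      assign(k1, TRUE, envir = seen); assign(k2, TRUE, envir = seen)
      edges$v[i] <- d; edges$v[j] <- b
      accepted <- accepted + 1L
    }
    if (accepted < m && attempts >= max_attempts)
      stop("edge-swap acceptance stagnated for type '", ty,
           "'; the network is too sparse or constrained to rewire")
  }
  network$edges <- edges
  network
}

#' Null distribution of candidate currents on rewired networks
#'
#' Generates `n_perm` degree-preserving rewirings of the full network,
#' rebuilds the instance for the same target gene and candidate set on
#' each (the TF constraint at the target is re-applied on the rewired
#' topology), solves with unit conductances, and records each candidate's
#' exit current.  Candidates unreachable in a rewiring (or unsolvable
#' instances) contribute zero current.
#'
#' @param network The original [interaction_network()].
#' @param instance The observed `circuit_instance` (defines target and
#'   candidates).
#' @param n_perm Number of random networks (default 30).
#' @param seed Integer seed; the null is reproducible from it.
#' @param rewired Optional pre-generated list of rewired networks (reused
#'   across instances by the pipeline); overrides `n_perm`/`seed`.
#' @param wrong_dir_max Passed to [solve_directed()].
#' @return Matrix of null currents, `n_perm` rows x candidates columns.
#' @export
permutation_null <- function(network, instance, n_perm = 30, seed = NULL,
                             rewired = NULL, wrong_dir_max = NULL) {
  stopifnot(inherits(instance, "circuit_instance"))
  if (is.null(rewired)) {
    stopifnot(n_perm >= 2)
    if (!is.null(seed)) set.seed(seed)
    rewired <- replicate(n_perm, rewire_network(network), simplify = FALSE)
  }
  cand <- instance$candidates
  out <- matrix(0, nrow = length(rewired), ncol = length(cand),
                dimnames = list(NULL, cand))
  node_out <- matrix(0, nrow = length(rewired),
                     ncol = length(instance$nodes),
                     dimnames = list(NULL, instance$nodes))
  for (r in seq_along(rewired)) {
    inst <- build_instance(rewired[[r]], instance$tg, expr = NULL,
                           region_genes = cand)
    if (!inst$solvable) next
    sol <- solve_directed(inst, wrong_dir_max = wrong_dir_max)
    if (!isTRUE(sol$solvable)) next
    got <- intersect(names(sol$X), cand)
    out[r, got] <- sol$X[got]
    gn <- intersect(names(sol$node_current), instance$nodes)
    node_out[r, gn] <- sol$node_current[gn]
  }
  attr(out, "node_current") <- node_out
  out
}

#' Node-level empirical p-values from the permutation null
#'
#' Same normal-fit upper-tail test as [empirical_pvalues()], applied to
#' every node's throughflow current; used to filter intermediate pathway
#' nodes before path extraction.
#'
#' @param solution A solved `circuit_solution`.
#' @param null_currents Matrix from [permutation_null()] (its
#'   `node_current` attribute supplies the node-level null).
#' @return Named numeric vector of p-values over the solution's nodes.
#' @export
node_pvalues <- function(solution, null_currents) {
  nn <- attr(null_currents, "node_current")
  if (is.null(nn)) stop("null_currents lacks node-level records")
  nodes <- intersect(names(solution$node_current), colnames(nn))
  mu <- colMeans(nn[, nodes, drop = FALSE])
  sd0 <- apply(nn[, nodes, drop = FALSE], 2, stats::sd)
  x <- solution$node_current[nodes]
  p <- ifelse(sd0 > 0, stats::pnorm((x - mu) / sd0, lower.tail = FALSE),
              ifelse(x > mu, 0, 1))
  stats::setNames(p, nodes)
}

#' Empirical p-values from the permutation null
#'
#' Fits a normal distribution to each candidate's null currents and
#' reports the upper-tail probability of the observed current under it
#' (one-sided Z-test).  A degenerate null (zero spread) yields p = 0 when
#' the observed current exceeds the null mean and p = 1 otherwise.
#'
#' @param solution A solved `circuit_solution` for the observed network.
#' @param null_currents Matrix from [permutation_null()].
#' @return Data frame: `gene`, `observed`, `null_mean`, `null_sd`,
#'   `p_value`.
#' @export
empirical_pvalues <- function(solution, null_currents) {
  cand <- names(solution$X)
  stopifnot(all(cand %in% colnames(null_currents)),
            nrow(null_currents) >= 2)
  mu <- colMeans(null_currents[, cand, drop = FALSE])
  sd0 <- apply(null_currents[, cand, drop = FALSE], 2, stats::sd)
  p <- ifelse(sd0 > 0,
              stats::pnorm((solution$X - mu) / sd0, lower.tail = FALSE),
              ifelse(solution$X > mu, 0, 1))
  data.frame(gene = cand, observed = unname(solution$X),
             null_mean = unname(mu), null_sd = unname(sd0),
             p_value = unname(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select candidate causal genes per target
#'
#' Within each (target, tag locus) region only genes receiving at least
#' `current_frac` of the region's maximum current are considered; among
#' those, genes with empirical p-value below `emp_p` become candidate
#' causal genes.  The union over a target's regions gives its candidate
#' set.
#'
#' @param results Data frame with columns `target`, `tag`, `gene`,
#'   `current`, `p_value` (one row per candidate per solved instance).
#' @param current_frac Fraction of the region maximum (default 0.7).
#' @param emp_p Empirical p-value threshold (default 0.05).
#' @return The subset of `results` rows that pass, with a `kept` column
#'   dropped; one row per retained (target, tag, gene).
#' @export
select_candidates <- function(results, current_frac = 0.7, emp_p = 0.05) {
  stopifnot(all(c("target", "tag", "gene", "current", "p_value")
                %in% names(results)))
  if (nrow(results) == 0) return(results)
  grp <- interaction(results$target, results$tag, drop = TRUE)
  maxc <- stats::ave(results$current, grp, FUN = max)
  keep <- results$current >= current_frac * maxc & results$p_value < emp_p
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
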