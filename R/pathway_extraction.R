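#' Maximum-current (bottleneck) path from target to causal gene
#'
#' After removing every node whose empirical p-value exceeds `p_max`
#' (endpoints are kept), finds a simple path from the target to the causal
#' gene maximizing the minimum total current through its interior nodes
#' (the widest / bottleneck path, solved by a maximin Dijkstra sweep).
#' An alternative objective maximizes the product of interior node
#' currents by exhaustive enumeration of simple paths.
#'
#' @param solution A `circuit_solution` (from [solve_circuit()] or
#'   [solve_directed()]); supplies the graph and node throughflow
#'   currents.
#' @param node_p Named numeric vector of per-node empirical p-values;
#'   nodes absent from it are treated as failing the filter (endpoints
#'   always pass).
#' @param tg,cg Target and causal gene (endpoints).
#' @param p_max Node filter threshold (default 0.05; nodes with p above it
#'   are removed, p equal to it is retained).
#' @param objective `"bottleneck"` (default) or `"product"`.
#' @return An object of class `causal_path` (`target`, `causal`, `nodes`
#'   in target -> causal order, `objective`, `node_current`), or `NULL`
#'   when the causal gene is unreachable after filtering.
#' @export
max_current_path <- function(solution, node_p, tg, cg, p_max = 0.05,
                             objective = c("bottleneck", "product")) {
  objective <- match.arg(objective)
  edges <- solution$instance$edges
  curr <- solution$node_current
  keep <- names(node_p)[node_p <= p_max]
  keep <- union(keep, c(tg, cg))
  edges <- edges[edges$u %in% keep & edges$v %in% keep, , drop = FALSE]
  if (nrow(edges) == 0) return(NULL)
  g <- igraph::graph_from_data_frame(edges[, c("u", "v")],
                                     directed = FALSE)
  if (!cg %in% igraph::V(g)$name || !tg %in% igraph::V(g)$name)
    return(NULL)
  if (objective == "bottleneck") {
    path <- widest_path(g, curr, tg, cg)
  } else {
    path <- product_path(g, curr, tg, cg)
  }
  if (is.null(path)) return(NULL)
  interior <- path[-c(1, length(path))]
  obj <- if (length(interior) == 0) Inf
    else if (objective == "bottleneck") min(curr[interior])
    else prod(curr[interior])
  structure(list(target = tg, causal = cg, nodes = path, objective = obj,
                 node_current = curr[path]),
            class = "causal_path")
}

# Maximin Dijkstra on node capacities: the width of a path is the minimum
# throughflow current over its interior nodes (endpoints uncapacitated).
# Deterministic: nodes are processed by (width desc, name asc) and a
# predecessor is replaced only on a strict width improvement.
widest_path <- function(g, curr, tg, cg) {
  nodes <- sort(igraph::V(g)$name)
  cap <- stats::setNames(curr[nodes], nodes)
  cap[c(tg, cg)] <- Inf
  width <- stats::setNames(rep(-Inf, length(nodes)), nodes)
  pred <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  width[tg] <- Inf
  done <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  adj <- igraph::adjacent_vertices(g, nodes)
  adj <- lapply(adj, function(vs) sort(vs$name))
  names(adj) <- nodes
  repeat {
    open <- !done & width > -Inf
    if (!any(open)) break
    u <- nodes[open][which.max(width[open])]  # first max = name asc
    if (u == cg) break
    done[u] <- TRUE
    for (v in adj[[u]]) {
      if (done[v]) next
      w_new <- min(width[u], cap[v])
      if (w_new > width[v]) {
        width[v] <- w_new
        pred[v] <- u
      }
    }
  }
  if (width[cg] == -Inf) return(NULL)
  path <- cg
  while (path[1] != tg) path <- c(pred[[path[1]]], path)
  path
}

# Exhaustive product-objective path (small filtered graphs only).
product_path <- function(g, curr, tg, cg, max_paths = 20000) {
  paths <- igraph::all_simple_paths(g, from = tg, to = cg)
  if (length(paths) == 0) return(NULL)
  if (length(paths) > max_paths)
    stop("too many simple paths for the product objective; ",
         "use the bottleneck objective")
  score <- vapply(paths, function(p) {
    nm <- igraph::V(g)$name[p]
    interior <- nm[-c(1, length(nm))]
    if (length(interior) == 0) Inf else prod(curr[interior])
  }, numeric(1))
  keys <- vapply(paths, function(p)
    paste(igraph::V(g)$name[p], collapse = "|"), character(1))
  best <- order(-score, keys)[1]
  igraph::V(g)$name[paths[[best]]]
}

#' Count pathway hub genes
#'
#' Hubs are genes appearing as interior nodes in strictly more than
#' `min_occurrences` causal paths.
#'
#' @param paths List of `causal_path` objects.
#' @param min_occurrences Strict occurrence threshold (default 10).
#' @return Data frame `gene`, `n_paths` for hubs, sorted by decreasing
#'   count then gene id.
#' @export
count_hubs <- function(paths, min_occurrences = 10) {
  interior <- unlist(lapply(paths, function(p)
    p$nodes[-c(1, length(p$nodes))]), use.names = FALSE)
  if (length(interior) == 0)
    return(data.frame(gene = character(0), n_paths = integer(0)))
  tab <- table(interior)
  hubs <- tab[tab > min_occurrences]
  out <- data.frame(gene = names(hubs), n_paths = as.integer(hubs),
                    stringsAsFactors = FALSE)
  out[order(-out$n_paths, out$gene), , drop = FALSE]
}

#' Assemble per-causal-gene subnetworks from causal paths
#'
#' One subnetwork per causal gene: the union of the nodes and edges of
#' all its paths (across targets).
#'
#' @param paths List of `causal_path` objects.
#' @return Named list (by causal gene) of lists with `nodes` (character)
#'   and `edges` (two-column data frame, unordered pairs, deduplicated).
#' @export
assemble_subnetworks <- function(paths) {
  by_cg <- split(paths, vapply(paths, function(p) p$causal, character(1)))
  lapply(by_cg, function(ps) {
    nodes <- sort(unique(unlist(lapply(ps, function(p) p$nodes))))
    edges <- do.call(rbind, lapply(ps, function(p) {
      n <- length(p$nodes)
      data.frame(u = pmin(p$nodes[-n], p$nodes[-1]),
                 v = pmax(p$nodes[-n], p$nodes[-1]),
                 stringsAsFactors = FALSE)
    }))
    edges <- unique(edges)
    rownames(edges) <- NULL
    list(nodes = nodes, edges = edges)
  })
}
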