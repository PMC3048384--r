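#' Run the full causal-gene discovery pipeline
#'
#' Chains all stages: per-case differential expression and greedy
#' multi-set cover target selection; tag-locus compression and eQTL
#' association; circuit-flow scoring of every associated (target, tag)
#' instance with the transcription-factor constraint, the directed-edge
#' heuristic and a shared degree-preserving permutation null; candidate
#' filtering by region-maximum current and empirical p-value; the
#' explanation graph and greedy weighted cover for the final causal set;
#' and bottleneck causal-path extraction for every final (causal, target)
#' pair.
#'
#' @param expr An [expression_matrix()].
#' @param cnv A [copy_number_profile()].
#' @param network An [interaction_network()].
#' @param alpha,beta Target-selection cover parameters (defaults 55, 3).
#' @param de_p Per-case differential expression level (default 0.01).
#' @param theta Tag-locus correlation threshold (default 0.9).
#' @param assoc_p Association p threshold (default 0.01).
#' @param n_perm Random networks for the permutation null (default 30).
#' @param current_frac Region-maximum current fraction (default 0.7).
#' @param emp_p Empirical p threshold for candidates (default 0.05).
#' @param gamma Required explanation weight per case (default 50).
#' @param delta `"auto"` or an integer outlier allowance.
#' @param wrong_dir_max Passed to [solve_directed()].
#' @param hub_min Strict path-occurrence threshold for hubs (default 10).
#' @param extract_paths Extract bottleneck paths (default TRUE).
#' @param seed Integer seed driving the permutation null.
#' @return A list of class `causalflow_result`: `targets`, `tags`,
#'   `associations`, `currents` (per-candidate circuit results),
#'   `candidates`, `explanation`, `final_causal` (with `exempt`
#'   attribute), `paths`, `hubs`, `subnetworks`, `unsolved` (skipped
#'   instances with reasons) and the solved `solutions`/`node_p` needed to
#'   reproduce path extraction.
#' @export
run_pipeline <- function(expr, cnv, network, alpha = 55, beta = 3,
                         de_p = 0.01, theta = 0.9, assoc_p = 0.01,
                         n_perm = 30, current_frac = 0.7, emp_p = 0.05,
                         gamma = 50, delta = "auto", wrong_dir_max = NULL,
                         hub_min = 10, extract_paths = TRUE, seed = 1) {
  targets <- select_targets(expr, alpha = alpha, beta = beta, de_p = de_p)
  de <- attr(targets, "calls")
  tags <- select_tag_loci(cnv, theta = theta)
  assoc <- associate(expr, cnv, tags, targets$gene, assoc_p = assoc_p)
  sig <- assoc[assoc$significant, , drop = FALSE]

  set.seed(seed)
  rewired <- replicate(n_perm, rewire_network(network), simplify = FALSE)

  currents <- list(); solutions <- list(); node_p <- list()
  unsolved <- list()
  for (i in seq_len(nrow(sig))) {
    tg <- sig$target[i]; tag <- sig$tag[i]
    key <- paste(tg, tag, sep = "|")
    inst <- build_instance(network, tg, tag = tag, expr = expr,
                           tags = tags)
    if (!inst$solvable) {
      unsolved[[key]] <- inst$reason
      next
    }
    sol <- solve_directed(inst, wrong_dir_max = wrong_dir_max)
    if (!isTRUE(sol$solvable)) {
      unsolved[[key]] <- sol$reason
      next
    }
    nullc <- permutation_null(network, inst, rewired = rewired,
                              wrong_dir_max = wrong_dir_max)
    pv <- empirical_pvalues(sol, nullc)
    currents[[key]] <- data.frame(target = tg, tag = tag, gene = pv$gene,
                                  current = pv$observed,
                                  p_value = pv$p_value,
                                  stringsAsFactors = FALSE)
    solutions[[key]] <- sol
    node_p[[key]] <- node_pvalues(sol, nullc)
  }
  currents <- if (length(currents)) do.call(rbind, c(currents,
                                                     make.row.names = FALSE))
    else data.frame(target = character(0), tag = character(0),
                    gene = character(0), current = numeric(0),
                    p_value = numeric(0))
  candidates <- select_candidates(currents, current_frac = current_frac,
                                  emp_p = emp_p)

  if (nrow(candidates) > 0) {
    graph <- build_explanation_graph(candidates, cnv, de)
    final <- greedy_weighted_cover(graph, gamma = gamma, delta = delta)
  } else {
    graph <- NULL
    final <- structure(character(0), exempt = character(0))
  }

  paths <- list()
  if (extract_paths && length(final) > 0) {
    for (cg in final) {
      for (tg in graph$targets_of[[cg]]) {
        rows <- candidates[candidates$gene == cg &
                             candidates$target == tg, , drop = FALSE]
        if (nrow(rows) == 0) next
        rows <- rows[order(rows$p_value, rows$tag), , drop = FALSE]
        key <- paste(tg, rows$tag[1], sep = "|")
        p <- max_current_path(solutions[[key]], node_p[[key]], tg, cg)
        if (!is.null(p)) paths[[paste(cg, tg, sep = "|")]] <- p
      }
    }
  }
  structure(list(targets = targets, tags = tags, associations = assoc,
                 currents = currents, candidates = candidates,
                 explanation = graph, final_causal = final,
                 paths = paths, hubs = count_hubs(paths, hub_min),
                 subnetworks = assemble_subnetworks(paths),
                 solutions = solutions, node_p = node_p,
                 unsolved = unsolved),
            class = "causalflow_result")
}

#' @export
print.causalflow_result <- function(x, ...) {
  cat("causalflow pipeline result\n")
  cat(sprintf("  targets selected:       %d\n", nrow(x$targets)))
  cat(sprintf("  tag loci:               %d\n", nrow(x$tags)))
  cat(sprintf("  associated pairs:       %d\n",
              sum(x$associations$significant)))
  cat(sprintf("  candidate causal genes: %d (%d pairs)\n",
              length(unique(x$candidates$gene)), nrow(x$candidates)))
  cat(sprintf("  final causal genes:     %d\n", length(x$final_causal)))
  cat(sprintf("  causal paths:           %d (hubs: %d)\n",
              length(x$paths), nrow(x$hubs)))
  invisible(x)
}
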