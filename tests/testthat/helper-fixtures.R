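# Shared fixture builders for calibration-style experiments.

# Well-connected typed network: `n` nodes at mean ppi degree ~`deg`,
# `n_tf` TFs with a swappable protein-DNA layer, a few protein-DNA edges
# into the designated target gene (node 1).
dense_typed_network <- function(n = 100, deg = 10, n_tf = 10,
                                n_pd = 40, pd_into_tg = 3) {
  g <- igraph::sample_gnp(n, deg / n)
  while (igraph::components(g)$no > 1)
    g <- igraph::sample_gnp(n, deg / n)
  el <- igraph::as_edgelist(g)
  genes <- sprintf("n%03d", seq_len(n))
  edges <- data.frame(u = genes[el[, 1]], v = genes[el[, 2]],
                      type = "ppi", stringsAsFactors = FALSE)
  tfs <- sample(genes[-1], n_tf)
  pd <- data.frame(u = sample(tfs, n_pd, replace = TRUE),
                   v = sample(genes, n_pd, replace = TRUE),
                   type = "protein_dna", stringsAsFactors = FALSE)
  pd <- rbind(pd, data.frame(u = tfs[seq_len(pd_into_tg)], v = genes[1],
                             type = "protein_dna"))
  pd <- pd[pd$u != pd$v, , drop = FALSE]
  net <- interaction_network(
    data.frame(gene = genes, is_tf = genes %in% tfs,
               stringsAsFactors = FALSE),
    rbind(edges, pd))
  list(network = net, tg = genes[1], tfs = tfs, genes = genes)
}

# Planted-instance bookkeeping used by the recovery experiments: which tag
# regions contain each planted causal gene, and whether the planted gene
# tops the current ranking of its own (target, region) instances.
planted_instance_stats <- function(sim, res) {
  tr <- sim$truth
  rg <- attr(res$tags, "region_genes")
  top <- logical(0)
  for (k in seq_along(tr$causal_genes)) {
    cg <- tr$causal_genes[k]; tg <- tr$target_genes[k]
    tags_with <- names(rg)[vapply(rg, function(g) cg %in% g, logical(1))]
    cur <- res$currents[res$currents$target == tg &
                          res$currents$tag %in% tags_with, , drop = FALSE]
    if (nrow(cur) == 0) next
    for (tag in unique(cur$tag)) {
      cc <- cur[cur$tag == tag, , drop = FALSE]
      top <- c(top, cc$gene[which.max(cc$current)] == cg)
    }
  }
  list(recovery = mean(tr$causal_genes %in% res$final_causal),
       precision = if (length(res$final_causal))
         mean(res$final_causal %in% tr$causal_genes) else NA_real_,
       top = top)
}
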