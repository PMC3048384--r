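#' Build the causal-gene x disease-case explanation graph
#'
#' A causal gene explains a case when (i) its tag locus carries a
#' copy-number alteration in that case and (ii) at least one of its
#' affected target genes (targets whose circuit instance retained the gene
#' with empirical p below the candidate threshold) is differentially
#' expressed in the case.  The edge weight is the number of such targets.
#' When a candidate was retained in several regions, the alteration test
#' uses the tag locus of its most significant instance.
#'
#' @param candidates Retained candidate table from [select_candidates()]
#'   (columns `target`, `tag`, `gene`, `current`, `p_value`).
#' @param cnv A [copy_number_profile()].
#' @param de A `de_calls` object from [compute_de_calls()].
#' @return An object of class `explanation_graph`: `weights` (causal genes
#'   x cases numeric matrix, 0 = no edge), `targets_of` (affected targets
#'   per causal gene), `tl_max` (deciding tag locus per causal gene) and
#'   `edge_targets` (per-edge target lists, named `gene|case`).
#' @export
build_explanation_graph <- function(candidates, cnv, de) {
  stopifnot(inherits(cnv, "copy_number_profile"), inherits(de, "de_calls"))
  cases <- cnv$samples
  cg <- sort(unique(candidates$gene))
  # tl_max: the candidate's most significant instance decides alterations
  tl_max <- vapply(cg, function(g) {
    rows <- candidates[candidates$gene == g, , drop = FALSE]
    rows <- rows[order(rows$p_value, rows$tag), , drop = FALSE]
    rows$tag[1]
  }, character(1))
  targets_of <- lapply(cg, function(g)
    sort(unique(candidates$target[candidates$gene == g])))
  names(targets_of) <- cg
  state <- matrix(call_alteration(cnv$log2_ratios[tl_max, cases]),
                  nrow = length(cg),
                  dimnames = list(cg, cases))
  weights <- matrix(0, nrow = length(cg), ncol = length(cases),
                    dimnames = list(cg, cases))
  edge_targets <- list()
  for (g in cg) {
    tgts <- intersect(targets_of[[g]], rownames(de$called))
    if (length(tgts) == 0) next
    de_sub <- de$called[tgts, cases, drop = FALSE]
    altered <- state[g, ] != "neutral"
    w <- colSums(de_sub) * altered
    weights[g, ] <- w
    for (s in cases[w > 0])
      edge_targets[[paste(g, s, sep = "|")]] <- tgts[de_sub[, s]]
  }
  structure(list(weights = weights, targets_of = targets_of,
                 tl_max = tl_max, edge_targets = edge_targets),
            class = "explanation_graph")
}

#' @export
print.explanation_graph <- function(x, ...) {
  cat(sprintf("explanation_graph: %d causal genes x %d cases, %d edges\n",
              nrow(x$weights), ncol(x$weights), sum(x$weights > 0)))
  invisible(x)
}

#' Greedy weighted multi-set cover of disease cases
#'
#' Selects causal genes so that the accumulated explanation weight of
#' every case except at most `delta` outliers reaches `gamma`.  Each
#' greedy step picks the gene with the maximum additional total weight,
#' where a case contributes at most its remaining demand
#' (`max(0, gamma - accumulated)`); ties break lexicographically.  With
#' `delta = "auto"` the outliers are exactly the cases whose total
#' achievable weight falls short of `gamma` (the data-derived rule).
#'
#' @param graph An `explanation_graph` (or a bare weight matrix).
#' @param gamma Required weight per case (default 50).
#' @param delta `"auto"` or a non-negative integer.
#' @return Character vector of selected genes in selection order, with
#'   attribute `exempt` naming the outlier cases.
#' @export
greedy_weighted_cover <- function(graph, gamma = 50, delta = "auto") {
  w <- if (inherits(graph, "explanation_graph")) graph$weights else graph
  stopifnot(is.matrix(w), gamma >= 0)
  if (gamma == 0) return(structure(character(0), exempt = character(0)))
  genes <- rownames(w); cases <- colnames(w)
  achievable <- colSums(w)
  deficient <- cases[achievable < gamma]
  if (identical(delta, "auto")) {
    exempt <- deficient
  } else {
    stopifnot(is.numeric(delta), delta >= 0)
    if (length(deficient) > delta)
      stop("infeasible cover: ", length(deficient),
           " case(s) cannot reach weight ", gamma,
           " (allowed outliers: ", delta, "): ",
           paste(utils::head(deficient, 10), collapse = ", "))
    ord <- order(achievable, cases)
    exempt <- cases[ord[seq_len(delta)]]
  }
  demand <- rep(gamma, length(cases)); names(demand) <- cases
  demand[exempt] <- 0
  ordg <- order(genes)
  wo <- w[ordg, , drop = FALSE]; genes_sorted <- genes[ordg]
  chosen <- character(0)
  available <- rep(TRUE, length(genes_sorted))
  while (any(demand > 0)) {
    gain <- as.vector(pmin(wo, rep(demand, each = nrow(wo))) %*%
                        rep(1, length(demand)))
    gain[!available] <- -1
    best <- which.max(gain)
    if (gain[best] <= 0)
      stop("infeasible cover: residual demand cannot be met")
    chosen <- c(chosen, genes_sorted[best])
    available[best] <- FALSE
    demand <- pmax(0, demand - wo[best, ])
  }
  structure(chosen, exempt = exempt)
}

#' Certify a weighted cover solution
#'
#' @param weights Causal genes x cases weight matrix.
#' @param selected Selected gene set.
#' @param gamma Required weight per case.
#' @param delta Allowed outlier cases.
#' @return `TRUE` when all but at most `delta` cases accumulate weight
#'   >= `gamma` from `selected`.
#' @export
check_weighted_cover <- function(weights, selected, gamma, delta) {
  acc <- colSums(weights[selected, , drop = FALSE])
  sum(acc < gamma) <= delta
}

#' Hypergeometric significance of a gene-set overlap
#'
#' Upper-tail probability of drawing an overlap at least as large as
#' observed when `length(selected)` genes are sampled from the universe
#' without replacement.
#'
#' @param selected,reference Character vectors, both subsets of
#'   `universe`.
#' @param universe Character vector of all eligible genes.
#' @return List with `overlap`, `expected` and `p_value`.
#' @export
overlap_significance <- function(selected, reference, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  selected <- unique(selected); reference <- unique(reference)
  if (!all(selected %in% universe) || !all(reference %in% universe))
    stop("selected and reference sets must be subsets of the universe")
  k <- length(intersect(selected, reference))
  p <- stats::phyper(k - 1, length(reference),
                     length(universe) - length(reference),
                     length(selected), lower.tail = FALSE)
  list(overlap = k,
       expected = length(selected) * length(reference) / length(universe),
       p_value = p)
}

#' Permutation significance of the final cover size
#'
#' Estimates how often a uniformly random candidate subset of the selected
#' size satisfies the (gamma, delta) constraint; a small fraction means
#' the greedy solution is far smaller than chance would allow.
#'
#' @param graph An `explanation_graph` (or weight matrix).
#' @param selected_size Size of the selected causal set.
#' @param gamma,delta Cover constraint (numeric `delta`).
#' @param n_perm Number of random subsets (default 1000, >= 100).
#' @param seed Integer seed.
#' @return Fraction of feasible random subsets.
#' @export
cover_significance <- function(graph, selected_size, gamma, delta,
                               n_perm = 1000, seed = NULL) {
  w <- if (inherits(graph, "explanation_graph")) graph$weights else graph
  stopifnot(n_perm >= 100, selected_size >= 1,
            selected_size <= nrow(w))
  if (!is.null(seed)) set.seed(seed)
  genes <- rownames(w)
  hits <- vapply(seq_len(n_perm), function(i) {
    pick <- sample(genes, selected_size)
    check_weighted_cover(w, pick, gamma, delta)
  }, logical(1))
  mean(hits)
}
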