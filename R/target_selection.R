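#' Per-case differential expression calls by Z-test against controls
#'
#' Each gene's tumor values are normalized as Z-scores using the control
#' mean and control standard deviation of that gene; a gene is called
#' differentially expressed in a case when the two-sided normal-tail
#' p-value of its Z-score falls below `de_p`.
#'
#' @param expr An [expression_matrix()].
#' @param de_p Per-case significance level (default 0.01).
#' @return An object of class `de_calls` with fields `z` (genes x tumor
#'   cases Z-score matrix), `called` (logical matrix of the same shape) and
#'   `de_p`.  Genes with zero control standard deviation are dropped with a
#'   warning.
#' @export
compute_de_calls <- function(expr, de_p = 0.01) {
  stopifnot(inherits(expr, "expression_matrix"), de_p > 0, de_p <= 1)
  ctrl <- expr$values[, expr$is_control, drop = FALSE]
  tum <- tumor_values(expr)
  mu <- rowMeans(ctrl)
  sd0 <- apply(ctrl, 1, stats::sd)
  keep <- sd0 > 0
  if (any(!keep))
    warning(sum(!keep), " gene(s) with zero control sd excluded: ",
            paste(utils::head(expr$genes[!keep], 5), collapse = ", "))
  z <- (tum[keep, , drop = FALSE] - mu[keep]) / sd0[keep]
  called <- 2 * stats::pnorm(-abs(z)) < de_p
  structure(list(z = z, called = called, de_p = de_p),
            class = "de_calls")
}

#' Greedy minimum multi-set cover with outliers
#'
#' Chooses genes so that every case except at most `beta` outliers is
#' covered at least `alpha` times, where a gene covers a case once if the
#' incidence matrix is `TRUE` there.  The `beta` cases with the smallest
#' maximum achievable coverage are exempted up front; each greedy step then
#' picks the gene with the largest residual coverage gain (cases count only
#' while their demand is unmet), breaking ties lexicographically by gene
#' identifier.
#'
#' @param incidence Logical matrix, genes x cases (`TRUE` = gene covers
#'   case), with dimnames.
#' @param alpha Required coverage per case (>= 0).
#' @param beta Maximum number of outlier cases (0..n cases).
#' @return Character vector of selected genes in selection order, with
#'   attribute `exempt` naming the outlier cases.
#' @export
greedy_multiset_cover <- function(incidence, alpha, beta = 0) {
  stopifnot(is.matrix(incidence), is.logical(incidence),
            alpha >= 0, beta >= 0, beta <= ncol(incidence))
  if (alpha == 0)
    return(structure(character(0), exempt = character(0)))
  genes <- rownames(incidence); cases <- colnames(incidence)
  if (is.null(genes) || is.null(cases))
    stop("incidence matrix needs gene and case dimnames")
  achievable <- colSums(incidence)
  deficient <- cases[achievable < alpha]
  if (length(deficient) > beta)
    stop("infeasible cover: cases ",
         paste(utils::head(deficient, 10), collapse = ", "),
         " cannot reach coverage ", alpha, " (allowed outliers: ", beta, ")")
  # exempt the beta least-coverable cases a priori; ties by case id
  ord <- order(achievable, cases)
  exempt <- cases[ord[seq_len(beta)]]
  demand <- rep(alpha, length(cases)); names(demand) <- cases
  demand[exempt] <- 0
  ordg <- order(genes)  # lexicographic tie-break via ordered scan
  inc <- incidence[ordg, , drop = FALSE]
  genes_sorted <- genes[ordg]
  chosen <- character(0)
  available <- rep(TRUE, length(genes_sorted))
  while (any(demand > 0)) {
    gain <- as.vector(inc[, demand > 0, drop = FALSE] %*%
                        rep(1L, sum(demand > 0)))
    gain[!available] <- -1L
    best <- which.max(gain)  # first max = lexicographically smallest gene
    if (gain[best] <= 0)
      stop("infeasible cover: residual demand cannot be met")
    chosen <- c(chosen, genes_sorted[best])
    available[best] <- FALSE
    covered <- inc[best, ]
    demand[covered] <- pmax(0L, demand[covered] - 1L)
  }
  structure(chosen, exempt = exempt)
}

#' Select representative target genes
#'
#' Composition of [compute_de_calls()] and [greedy_multiset_cover()]: per
#' -case differential expression calls define a bipartite gene/case
#' incidence, and the greedy multi-set cover picks a minimal representative
#' gene set covering every case at least `alpha` times with at most `beta`
#' outlier cases.
#'
#' @param expr An [expression_matrix()].
#' @param alpha Required coverage per case (default 55).
#' @param beta Maximum outlier cases (default 3).
#' @param de_p Per-case differential expression level (default 0.01).
#' @return A data frame with one row per selected gene: `gene`, selection
#'   `order`, `n_cases_covered`, and `direction` (`up`, `down` or `mixed`,
#'   the sign of its significant Z-scores).  The `de_calls` object is
#'   attached as attribute `calls`.
#' @export
select_targets <- function(expr, alpha = 55, beta = 3, de_p = 0.01) {
  calls <- compute_de_calls(expr, de_p)
  sel <- greedy_multiset_cover(calls$called, alpha = alpha, beta = beta)
  direction <- vapply(sel, function(g) {
    zs <- calls$z[g, calls$called[g, ]]
    if (all(zs > 0)) "up" else if (all(zs < 0)) "down" else "mixed"
  }, character(1))
  out <- data.frame(gene = as.character(sel),
                    order = seq_along(sel),
                    n_cases_covered = rowSums(calls$called)[as.character(sel)],
                    direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "calls") <- calls
  attr(out, "exempt") <- attr(sel, "exempt")
  out
}

#' Certify a multi-set cover solution
#'
#' Independent re-check that a gene set satisfies the (alpha, beta)
#' constraint: counts per-case coverage directly from the incidence matrix.
#'
#' @param incidence Logical genes x cases matrix.
#' @param selected Character vector of selected genes.
#' @inheritParams greedy_multiset_cover
#' @return `TRUE` if all but at most `beta` cases reach coverage `alpha`.
#' @export
check_cover <- function(incidence, selected, alpha, beta = 0) {
  cov <- colSums(incidence[selected, , drop = FALSE])
  sum(cov < alpha) <= beta
}
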