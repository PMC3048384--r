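#' Compress loci into tag loci by local correlation clustering
#'
#' Copy numbers of neighboring loci are highly correlated, so a single
#' representative (tag) locus can stand in for a run of consecutive loci.
#' The default scan walks each chromosome left to right: the first
#' uncovered locus opens a region and becomes its tag, the region extends
#' rightward while every new locus correlates above `theta` with the tag,
#' then the scan restarts at the next uncovered locus.  In `"bidirectional"`
#' mode each tag's region also extends leftward, so adjacent regions may
#' overlap and a gene may belong to more than one region.
#'
#' @param cnv A [copy_number_profile()].
#' @param theta Pearson correlation threshold in (0, 1); default 0.9.
#' @param mode `"scan"` (left-to-right, default) or `"bidirectional"`.
#' @return A data frame of tag loci: `tag_id`, `chromosome`, `start_index`,
#'   `end_index` (inclusive, 0-based over the genome-ordered locus list),
#'   `n_loci`, `n_genes`; attribute `region_genes` holds the per-tag gene
#'   union and attribute `region_loci` the per-tag locus ids.
#' @export
select_tag_loci <- function(cnv, theta = 0.9,
                            mode = c("scan", "bidirectional")) {
  stopifnot(inherits(cnv, "copy_number_profile"), theta > 0, theta < 1)
  mode <- match.arg(mode)
  cn <- cnv$log2_ratios
  m <- nrow(cn)
  sds <- apply(cn, 1, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0),
            " zero-variance locus/loci become singleton tags")
  chrom <- cnv$loci$chromosome
  corr_ok <- function(i, j) {
    # does locus j correlate with tag i above theta?
    if (sds[i] == 0 || sds[j] == 0) return(FALSE)
    stats::cor(cn[i, ], cn[j, ]) > theta
  }
  tags <- integer(0); starts <- integer(0); ends <- integer(0)
  if (mode == "scan") {
    i <- 1L
    while (i <= m) {
      j <- i
      while (j < m && chrom[j + 1L] == chrom[i] && corr_ok(i, j + 1L))
        j <- j + 1L
      tags <- c(tags, i); starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    }
  } else {
    covered <- rep(FALSE, m)
    i <- 1L
    while (i <= m) {
      if (!covered[i]) {
        j <- i
        while (j < m && chrom[j + 1L] == chrom[i] && corr_ok(i, j + 1L))
          j <- j + 1L
        k <- i
        while (k > 1L && chrom[k - 1L] == chrom[i] && corr_ok(i, k - 1L))
          k <- k - 1L
        tags <- c(tags, i); starts <- c(starts, k); ends <- c(ends, j)
        covered[k:j] <- TRUE
      }
      i <- i + 1L
    }
  }
  region_loci <- Map(function(s, e) cnv$loci$locus_id[s:e], starts, ends)
  region_genes <- lapply(region_loci, function(ids)
    unique(unlist(cnv$locus_genes[ids], use.names = FALSE)))
  out <- data.frame(tag_id = cnv$loci$locus_id[tags],
                    chromosome = chrom[tags],
                    start_index = starts - 1L, end_index = ends - 1L,
                    n_loci = ends - starts + 1L,
                    n_genes = lengths(region_genes),
                    stringsAsFactors = FALSE)
  names(region_genes) <- names(region_loci) <- out$tag_id
  attr(out, "region_genes") <- region_genes
  attr(out, "region_loci") <- region_loci
  out
}

#' Associate target-gene expression with tag-locus copy number
#'
#' Ordinary least-squares regression of each target gene's tumor-sample
#' expression on each tag locus' copy number, with a two-sided t-test on
#' the slope.  Pairs below `assoc_p` form the associated tag-locus set of
#' each target.
#'
#' @param expr An [expression_matrix()]; tumor samples must match the
#'   copy-number samples.
#' @param cnv A [copy_number_profile()].
#' @param tags Tag-locus table from [select_tag_loci()].
#' @param targets Character vector of target genes (subset of `expr$genes`).
#' @param assoc_p Association significance threshold (default 0.01).
#' @return A data frame of all tested pairs: `target`, `tag`, `slope`,
#'   `p_value`, `significant` (p < `assoc_p`).  Zero-variance tags are
#'   skipped with a warning.
#' @export
associate <- function(expr, cnv, tags, targets, assoc_p = 0.01) {
  stopifnot(all(targets %in% expr$genes))
  tum <- tumor_values(expr)
  shared <- intersect(colnames(tum), cnv$samples)
  if (length(shared) < 3)
    stop("need >=3 shared tumor samples between expression and copy number")
  tum <- tum[, shared, drop = FALSE]
  cn <- cnv$log2_ratios[, shared, drop = FALSE]
  n <- length(shared)
  keep <- apply(cn[tags$tag_id, , drop = FALSE], 1, stats::sd) > 0
  if (any(!keep))
    warning(sum(!keep), " zero-variance tag locus/loci skipped")
  tag_ids <- tags$tag_id[keep]
  res <- lapply(tag_ids, function(tl) {
    x <- cn[tl, ]
    sx <- stats::sd(x)
    vapply(targets, function(tg) {
      y <- tum[tg, ]
      r <- stats::cor(x, y)
      slope <- r * stats::sd(y) / sx
      if (is.na(r)) return(c(slope = NA_real_, p = 1))
      # exact OLS slope t-test, df = n - 2
      r2 <- min(r^2, 1)
      tstat <- if (r2 >= 1) Inf else r * sqrt((n - 2) / (1 - r2))
      c(slope = slope, p = 2 * stats::pt(-abs(tstat), df = n - 2))
    }, c(slope = 0, p = 0))
  })
  out <- data.frame(
    target = rep(targets, times = length(tag_ids)),
    tag = rep(tag_ids, each = length(targets)),
    slope = unlist(lapply(res, function(m) m["slope", ])),
    p_value = unlist(lapply(res, function(m) m["p", ])),
    row.names = NULL, stringsAsFactors = FALSE)
  out$significant <- out$p_value < assoc_p
  attr(out, "assoc_p") <- assoc_p
  out
}

#' Nominal significance bounds of the association + circuit pipeline
#'
#' For a scan of `n_tags` tag loci against `n_targets` target genes, every
#' retained (target, causal gene) pair passed both the association filter
#' (p < `assoc_p`) and the circuit-flow empirical filter (p < `emp_p`), so
#' its combined nominal p-value is bounded by their product.  The
#' Bonferroni threshold is the family-wise level `assoc_p` divided by the
#' number of tested pairs.
#'
#' @param n_tags Number of tag loci.
#' @param n_targets Number of target genes.
#' @param assoc_p Association threshold (default 0.01).
#' @param emp_p Circuit empirical threshold (default 0.05).
#' @return List with `n_tested_pairs`, `pair_p_bound`,
#'   `bonferroni_threshold`.
#' @export
analysis_bounds <- function(n_tags, n_targets, assoc_p = 0.01,
                            emp_p = 0.05) {
  n_pairs <- n_tags * n_targets
  list(n_tested_pairs = n_pairs,
       pair_p_bound = assoc_p * emp_p,
       bonferroni_threshold = assoc_p / n_pairs)
}
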