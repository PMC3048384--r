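#' Construct an expression matrix with a tumor/control partition
#'
#' Container for log-scale expression values of `genes x samples` together
#' with a per-sample control flag.  Control samples provide the mean and
#' standard deviation used for per-case Z-score normalization downstream.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.  Row and
#'   column names are taken as gene and sample identifiers when `genes` /
#'   `samples` are not supplied.
#' @param is_control Logical vector, one flag per sample (`TRUE` = non-tumor
#'   control).
#' @param genes,samples Optional identifier vectors overriding dimnames.
#' @return An object of class `expression_matrix` with fields `genes`,
#'   `samples`, `values`, `is_control`.
#' @export
expression_matrix <- function(values, is_control, genes = rownames(values),
                              samples = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(genes) || is.null(samples))
    stop("gene and sample identifiers are required")
  genes <- as.character(genes); samples <- as.character(samples)
  if (length(genes) != nrow(values) || length(samples) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(genes))
    stop("duplicated gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicated sample identifiers")
  is_control <- as.logical(is_control)
  if (length(is_control) != length(samples) || anyNA(is_control))
    stop("is_control must be one non-missing flag per sample")
  if (sum(is_control) < 2)
    stop("at least 2 control samples are required")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  dimnames(values) <- list(genes, samples)
  structure(list(genes = genes, samples = samples, values = values,
                 is_control = is_control),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d tumor, %d control)\n",
              length(x$genes), length(x$samples),
              sum(!x$is_control), sum(x$is_control)))
  invisible(x)
}

#' Tumor-only view of an expression matrix
#'
#' @param expr An `expression_matrix`.
#' @return Numeric matrix restricted to tumor (non-control) samples.
#' @export
tumor_values <- function(expr) {
  expr$values[, !expr$is_control, drop = FALSE]
}

#' Construct a copy-number profile
#'
#' Genome-ordered loci by tumor samples, values on the log2 copy-number
#' scale on which diploid sits near 1 (so the alteration statistic is
#' `log2_ratio - 1`).
#'
#' @param loci Data frame with columns `locus_id`, `chromosome`, `position`.
#' @param log2_ratios Numeric matrix, loci x tumor samples.
#' @param locus_genes Named list mapping `locus_id` to character vectors of
#'   gene identifiers (may be empty per locus).
#' @param samples Optional sample identifiers (default: column names).
#' @return An object of class `copy_number_profile`.
#' @export
copy_number_profile <- function(loci, log2_ratios, locus_genes,
                                samples = colnames(log2_ratios)) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  stopifnot(all(c("locus_id", "chromosome", "position") %in% names(loci)))
  loci$locus_id <- as.character(loci$locus_id)
  loci$chromosome <- as.character(loci$chromosome)
  if (anyDuplicated(loci$locus_id)) stop("duplicated locus identifiers")
  ord <- order(loci$chromosome, loci$position)
  if (!identical(ord, seq_len(nrow(loci))))
    stop("loci must be sorted by (chromosome, position)")
  log2_ratios <- as.matrix(log2_ratios)
  if (nrow(log2_ratios) != nrow(loci))
    stop("log2_ratios rows do not match loci")
  if (is.null(samples)) stop("sample identifiers are required")
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicated sample identifiers")
  if (length(samples) != ncol(log2_ratios))
    stop("sample identifiers do not match matrix columns")
  if (anyNA(log2_ratios) || any(!is.finite(log2_ratios)))
    stop("log2 ratios must be finite")
  if (!all(names(locus_genes) %in% loci$locus_id))
    stop("locus_genes names must be declared locus ids")
  lg <- stats::setNames(vector("list", nrow(loci)), loci$locus_id)
  lg[names(locus_genes)] <- lapply(locus_genes, as.character)
  lg[vapply(lg, is.null, logical(1))] <- list(character(0))
  dimnames(log2_ratios) <- list(loci$locus_id, samples)
  structure(list(loci = loci, samples = samples, log2_ratios = log2_ratios,
                 locus_genes = lg),
            class = "copy_number_profile")
}

#' @export
print.copy_number_profile <- function(x, ...) {
  cat(sprintf("copy_number_profile: %d loci (%d chromosomes) x %d tumor samples\n",
              nrow(x$loci), length(unique(x$loci$chromosome)),
              length(x$samples)))
  invisible(x)
}

#' Construct a typed molecular interaction network
#'
#' Protein-protein edges are undirected; protein-DNA edges are directed
#' regulator -> regulated gene; phosphorylation edges are directed
#' kinase -> substrate.  Each node carries a transcription-factor flag.
#'
#' @param nodes Data frame with columns `gene` and logical `is_tf`.
#' @param edges Data frame with columns `u`, `v`, `type`; `type` must be one
#'   of `"ppi"`, `"protein_dna"`, `"phosphorylation"`.  Duplicate edges
#'   (same unordered pair and type) are merged; self-loops are rejected.
#' @return An object of class `interaction_network` whose `edges` field
#'   gains a logical `directed` column derived from `type`.
#' @export
interaction_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "is_tf") %in% names(nodes)),
            all(c("u", "v", "type") %in% names(edges)))
  nodes$gene <- as.character(nodes$gene)
  nodes$is_tf <- as.logical(nodes$is_tf)
  if (anyDuplicated(nodes$gene)) stop("duplicated node identifiers")
  if (anyNA(nodes$is_tf)) stop("is_tf flags must be non-missing")
  edges$u <- as.character(edges$u); edges$v <- as.character(edges$v)
  edges$type <- as.character(edges$type)
  bad <- setdiff(edges$type, edge_types())
  if (length(bad))
    stop("unknown edge type(s): ", paste(unique(bad), collapse = ", "))
  if (any(edges$u == edges$v)) stop("self-loops are not allowed")
  missing_nodes <- setdiff(c(edges$u, edges$v), nodes$gene)
  if (length(missing_nodes))
    stop("edge endpoints not declared as nodes: ",
         paste(utils::head(missing_nodes, 5), collapse = ", "))
  # one edge per unordered pair per type; directed types keep first-seen
  # orientation
  key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v), edges$type)
  edges <- edges[!duplicated(key), c("u", "v", "type"), drop = FALSE]
  edges$directed <- edges$type != "ppi"
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_network")
}

edge_types <- function() c("ppi", "protein_dna", "phosphorylation")

#' @export
print.interaction_network <- function(x, ...) {
  tab <- table(factor(x$edges$type, levels = edge_types()))
  cat(sprintf("interaction_network: %d nodes (%d TFs), %d edges (ppi %d, protein_dna %d, phosphorylation %d)\n",
              nrow(x$nodes), sum(x$nodes$is_tf), nrow(x$edges),
              tab[["ppi"]], tab[["protein_dna"]], tab[["phosphorylation"]]))
  invisible(x)
}

#' Convert an interaction network to an igraph object
#'
#' The igraph view is undirected (the circuit solver treats all edges as
#' conductors); direction and type survive as edge attributes.
#'
#' @param network An `interaction_network`.
#' @return An undirected `igraph` graph with `type` and `directed` edge
#'   attributes and an `is_tf` vertex attribute.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = data.frame(name = network$nodes$gene,
                          is_tf = network$nodes$is_tf,
                          stringsAsFactors = FALSE))
  g
}

#' Call a copy-number alteration state
#'
#' The log2 copy-number value is centered so diploid sits near 1; a locus is
#' amplified when `log2_ratio - 1 > 0.1`, deleted when `log2_ratio - 1 <
#' -0.1`, and neutral otherwise (boundaries are neutral because the
#' inequalities are strict).
#'
#' @param log2_ratio Numeric vector of log2 copy-number values.
#' @return Character vector in `c("amplified", "deleted", "neutral")`.
#' @export
call_alteration <- function(log2_ratio) {
  if (anyNA(log2_ratio) || any(!is.finite(log2_ratio)))
    stop("log2 ratios must be finite")
  # compare on the raw scale (1.1 / 0.9 cutoffs) so the boundary values
  # themselves are classified neutral without floating-point surprises
  out <- rep("neutral", length(log2_ratio))
  out[log2_ratio > 1.1] <- "amplified"
  out[log2_ratio < 0.9] <- "deleted"
  out
}

## ---- readers / writers ----------------------------------------------------

#' Read an expression table with its control sidecar
#'
#' Expects a tab-separated table whose first column holds gene identifiers
#' and whose header names the samples, plus a two-column sidecar
#' `sample<TAB>{tumor|control}` declaring the partition.
#'
#' @param path Path to the expression table.
#' @param groups_path Path to the sidecar; defaults to `<path>.groups`.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, groups_path = paste0(path, ".groups")) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs >=1 sample column")
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("duplicated gene identifiers in ", path)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (anyNA(vals)) stop("missing expression values in ", path)
  grp <- utils::read.delim(groups_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "group"))
  if (!all(grp$group %in% c("tumor", "control")))
    stop("sample groups must be 'tumor' or 'control'")
  idx <- match(colnames(vals), grp$sample)
  if (anyNA(idx)) stop("samples missing from group sidecar")
  expression_matrix(vals, is_control = grp$group[idx] == "control",
                    genes = genes, samples = colnames(vals))
}

#' Write an expression table with its control sidecar
#'
#' Inverse of [read_expression()]; rows keep input order so a write/read
#' round-trip is the identity.
#'
#' @param expr An `expression_matrix`.
#' @param path Output table path.
#' @param groups_path Sidecar path; defaults to `<path>.groups`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path,
                             groups_path = paste0(path, ".groups")) {
  tab <- data.frame(gene = expr$genes, expr$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  grp <- data.frame(sample = expr$samples,
                    group = ifelse(expr$is_control, "control", "tumor"))
  utils::write.table(grp, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a copy-number profile
#'
#' The table is tab-separated with columns `locus_id`, `chromosome`,
#' `position`, then one column per tumor sample.  The locus-to-gene map is a
#' two-column table `locus_id<TAB>gene` (one row per pair).
#'
#' @param path Path to the copy-number table.
#' @param genes_path Path to the locus-gene map; defaults to
#'   `<path>.genes`.
#' @return A `copy_number_profile`.
#' @export
read_copy_number <- function(path, genes_path = paste0(path, ".genes")) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("locus_id", "chromosome", "position") %in% names(tab)))
  loci <- tab[, c("locus_id", "chromosome", "position")]
  vals <- as.matrix(tab[, setdiff(names(tab), names(loci)), drop = FALSE])
  map <- utils::read.delim(genes_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("locus_id", "gene"))
  locus_genes <- split(map$gene, factor(map$locus_id,
                                        levels = unique(loci$locus_id)))
  locus_genes <- locus_genes[lengths(locus_genes) > 0]
  copy_number_profile(loci, vals, locus_genes)
}

#' Write a copy-number profile
#'
#' @param cnv A `copy_number_profile`.
#' @param path Output table path.
#' @param genes_path Locus-gene map path; defaults to `<path>.genes`.
#' @return `path`, invisibly.
#' @export
write_copy_number <- function(cnv, path,
                              genes_path = paste0(path, ".genes")) {
  tab <- data.frame(cnv$loci, cnv$log2_ratios, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  n <- lengths(cnv$locus_genes)
  map <- data.frame(locus_id = rep(names(cnv$locus_genes), n),
                    gene = unlist(cnv$locus_genes, use.names = FALSE))
  utils::write.table(map, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an interaction network from SIF-style files
#'
#' The edge list is `u<TAB>type<TAB>v` with type in `ppi`, `protein_dna`,
#' `phosphorylation`; the node attribute table is `gene<TAB>{tf|non_tf}` and
#' must declare every endpoint.
#'
#' @param path Path to the SIF edge list.
#' @param nodes_path Path to the node attribute table; defaults to
#'   `<path>.nodes`.
#' @return An `interaction_network`.
#' @export
read_network <- function(path, nodes_path = paste0(path, ".nodes")) {
  sif <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("u", "type", "v"))
  bad <- setdiff(sif$type, edge_types())
  if (length(bad))
    stop("unknown edge type(s) in ", path, ": ",
         paste(unique(bad), collapse = ", "))
  nod <- utils::read.delim(nodes_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("gene", "tf_flag"))
  if (!all(nod$tf_flag %in% c("tf", "non_tf")))
    stop("node flags must be 'tf' or 'non_tf'")
  interaction_network(
    nodes = data.frame(gene = nod$gene, is_tf = nod$tf_flag == "tf",
                       stringsAsFactors = FALSE),
    edges = sif[, c("u", "v", "type")])
}

#' Write an interaction network to SIF-style files
#'
#' @param network An `interaction_network`.
#' @param path Output SIF path.
#' @param nodes_path Node attribute table path; defaults to `<path>.nodes`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path,
                          nodes_path = paste0(path, ".nodes")) {
  sif <- data.frame(u = network$edges$u, type = network$edges$type,
                    v = network$edges$v)
  utils::write.table(sif, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  nod <- data.frame(gene = network$nodes$gene,
                    tf_flag = ifelse(network$nodes$is_tf, "tf", "non_tf"))
  utils::write.table(nod, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path Path to a GMT file (`name<TAB>description<TAB>gene...`).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}
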