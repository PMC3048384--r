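#' Configuration for a synthetic cohort with planted causal structure
#'
#' The generator emulates the statistical structure the pipeline exploits:
#' copy numbers of neighboring loci are autocorrelated; a few planted
#' causal loci are amplified in a fraction of tumors; each planted causal
#' gene perturbs the expression of one target gene proportionally to its
#' copy-number dosage through a short interaction-network path whose
#' intermediate genes are co-expressed with the target and whose last hop
#' is a protein-DNA edge from a transcription factor into the target.
#'
#' @param n_tumor,n_control Sample counts (defaults 158 / 32, a GBM-sized
#'   cohort).
#' @param n_genes,n_loci Numbers of genes and genomic loci.
#' @param genes_per_locus Mean genes mapped to each locus.
#' @param n_planted_causal Number of planted causal genes (one target each).
#' @param path_length Planted causal-path length in edges (>= 2; the last
#'   edge is TF -> target).
#' @param effect_size Regression slope of target expression on the causal
#'   gene's copy-number dosage (log2 units).
#' @param noise_sd Residual standard deviation of target expression.
#' @param cna_fraction Fraction of tumors carrying each planted
#'   amplification.
#' @param neighbor_corr Target Pearson correlation of adjacent loci.
#' @param n_chromosomes Chromosomes the loci are spread over.
#' @param tf_fraction Fraction of genes flagged as transcription factors.
#' @param cna_gain Log2 copy-number gain of a planted amplification
#'   (added to the diploid level 1 in carriers; must exceed 0.1 to be
#'   called amplified).
#' @param seed Integer random seed; the whole cohort is reproducible from
#'   it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_tumor = 158, n_control = 32,
                              n_genes = 160, n_loci = 40,
                              genes_per_locus = 4, n_planted_causal = 4,
                              path_length = 3, effect_size = 2,
                              noise_sd = 0.5, cna_fraction = 0.5,
                              neighbor_corr = 0.9, n_chromosomes = 4,
                              tf_fraction = 0.15, cna_gain = 0.6,
                              seed = 1) {
  cfg <- list(n_tumor = n_tumor, n_control = n_control, n_genes = n_genes,
              n_loci = n_loci, genes_per_locus = genes_per_locus,
              n_planted_causal = n_planted_causal,
              path_length = path_length, effect_size = effect_size,
              noise_sd = noise_sd, cna_fraction = cna_fraction,
              neighbor_corr = neighbor_corr,
              n_chromosomes = n_chromosomes, tf_fraction = tf_fraction,
              cna_gain = cna_gain, seed = seed)
  counts <- c("n_tumor", "n_control", "n_genes", "n_loci",
              "genes_per_locus", "path_length", "n_chromosomes")
  if (any(unlist(cfg[counts]) <= 0)) stop("all counts must be positive")
  if (cfg$n_planted_causal < 0) stop("n_planted_causal must be >= 0")
  if (cfg$cna_fraction < 0 || cfg$cna_fraction > 1)
    stop("cna_fraction must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$path_length < 2)
    stop("path_length must be >= 2 (the last hop is a TF -> target edge)")
  if (cfg$n_control < 2) stop("need >= 2 control samples")
  if (abs(cfg$neighbor_corr) >= 1) stop("neighbor_corr must be in (-1, 1)")
  structure(cfg, class = "simulation_config")
}

#' Simulate a cohort, copy-number profile and network with planted truth
#'
#' @param config A [simulation_config()].
#' @return List with components `expr` ([expression_matrix()]), `cnv`
#'   ([copy_number_profile()]), `network` ([interaction_network()]) and
#'   `truth` (class `planted_truth`: `causal_genes`, `target_genes`,
#'   `causal_paths` ordered causal -> ... -> TF -> target,
#'   `locus_of_causal`, `carriers` per causal locus).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cf <- config
  genes <- sprintf("g%03d", seq_len(cf$n_genes))
  tumors <- sprintf("t%03d", seq_len(cf$n_tumor))
  controls <- sprintf("c%03d", seq_len(cf$n_control))

  ## ---- roles: causal genes, their decoy locus mates, paths, targets ----
  n_interm <- cf$path_length - 2L        # nodes strictly between causal and TF
  need <- cf$n_planted_causal * (2L + n_interm + 1L)  # causal+target+interm+TF
  if (need > cf$n_genes)
    stop("generation error: n_genes too small for ", cf$n_planted_causal,
         " planted paths of length ", cf$path_length)
  pool <- sample(genes)
  take <- function(k) {
    out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out
  }
  causal <- take(cf$n_planted_causal)
  targets <- take(cf$n_planted_causal)
  tfs_planted <- take(cf$n_planted_causal)
  interm <- if (n_interm > 0)
    matrix(take(cf$n_planted_causal * n_interm), ncol = n_interm)
  else matrix(character(0), nrow = cf$n_planted_causal, ncol = 0)
  causal_paths <- lapply(seq_len(cf$n_planted_causal), function(k)
    c(causal[k], interm[k, ], tfs_planted[k], targets[k]))

  ## ---- copy number: AR(1) along each chromosome, planted amplifications ----
  chrom <- rep(sprintf("chr%d", seq_len(cf$n_chromosomes)),
               length.out = cf$n_loci)
  chrom <- sort(chrom)
  pos <- unlist(lapply(table(chrom), seq_len), use.names = FALSE) * 1e5
  loci <- data.frame(locus_id = sprintf("L%03d", seq_len(cf$n_loci)),
                     chromosome = chrom, position = pos,
                     stringsAsFactors = FALSE)
  rho <- cf$neighbor_corr
  cn_sd <- 0.05   # background wobble on the log2 scale, well inside neutral
  cn <- matrix(0, nrow = cf$n_loci, ncol = cf$n_tumor)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    z <- matrix(stats::rnorm(length(idx) * cf$n_tumor), nrow = length(idx))
    for (i in seq_along(idx)[-1])
      z[i, ] <- rho * z[i - 1L, ] + sqrt(1 - rho^2) * z[i, ]
    cn[idx, ] <- 1 + cn_sd * z
  }
  # map genes to loci: planted causal genes get one locus each (with decoy
  # mates), remaining genes spread over the remaining loci
  locus_of_causal <- stats::setNames(
    sample(loci$locus_id, cf$n_planted_causal), causal)
  locus_genes <- stats::setNames(
    vector("list", cf$n_loci), loci$locus_id)
  for (k in seq_along(causal))
    locus_genes[[locus_of_causal[k]]] <- causal[k]
  assignable <- setdiff(genes, c(causal, targets, tfs_planted,
                                 as.vector(interm)))
  n_assign <- min(length(assignable),
                  max(0L, round(cf$genes_per_locus * cf$n_loci) -
                        cf$n_planted_causal))
  assignable <- assignable[seq_len(n_assign)]
  li <- sample(loci$locus_id, length(assignable), replace = TRUE)
  for (k in seq_along(assignable))
    locus_genes[[li[k]]] <- c(locus_genes[[li[k]]], assignable[k])
  # carriers of each planted amplification
  n_carrier <- max(1L, round(cf$cna_fraction * cf$n_tumor))
  carriers <- lapply(seq_along(causal), function(k)
    sort(sample(cf$n_tumor, n_carrier)))
  names(carriers) <- causal
  for (k in seq_along(causal)) {
    row <- match(locus_of_causal[k], loci$locus_id)
    cn[row, carriers[[k]]] <- cn[row, carriers[[k]]] + cf$cna_gain
  }
  cnv <- copy_number_profile(loci, cn, locus_genes, samples = tumors)

  ## ---- network: scale-free background + planted conductive paths ----
  bg <- igraph::sample_pa(cf$n_genes, power = 1, m = 2, directed = FALSE)
  el <- igraph::as_edgelist(bg, names = FALSE)
  perm <- sample(cf$n_genes)  # decouple hub identity from gene index
  edges <- data.frame(u = genes[perm[el[, 1]]], v = genes[perm[el[, 2]]],
                      type = "ppi", stringsAsFactors = FALSE)
  is_tf <- stats::setNames(rep(FALSE, cf$n_genes), genes)
  is_tf[sample(genes, max(1, round(cf$tf_fraction * cf$n_genes)))] <- TRUE
  is_tf[tfs_planted] <- TRUE
  # sprinkle directed background edges of both directed types
  n_dir <- max(2L, round(0.15 * nrow(edges)))
  tf_pool <- names(is_tf)[is_tf]
  pd <- data.frame(u = sample(tf_pool, n_dir, replace = TRUE),
                   v = sample(genes, n_dir, replace = TRUE),
                   type = "protein_dna", stringsAsFactors = FALSE)
  ph <- data.frame(u = sample(genes, n_dir, replace = TRUE),
                   v = sample(genes, n_dir, replace = TRUE),
                   type = "phosphorylation", stringsAsFactors = FALSE)
  extra <- rbind(pd, ph)
  extra <- extra[extra$u != extra$v, , drop = FALSE]
  # planted path edges, oriented causal -> target (regulatory direction);
  # the final hop is protein-DNA from the planted TF into the target
  planted <- do.call(rbind, lapply(causal_paths, function(p) {
    n <- length(p)
    data.frame(u = p[-n], v = p[-1],
               type = c(rep("ppi", n - 2L), "protein_dna"),
               stringsAsFactors = FALSE)
  }))
  nodes <- data.frame(gene = genes, is_tf = unname(is_tf),
                      stringsAsFactors = FALSE)
  network <- interaction_network(nodes, rbind(edges, extra, planted))

  ## ---- expression: gene-specific control distributions ----
  mu <- stats::setNames(stats::rnorm(cf$n_genes, mean = 7, sd = 1), genes)
  sdg <- stats::setNames(stats::runif(cf$n_genes, 0.2, 0.4), genes)
  n_all <- cf$n_tumor + cf$n_control
  vals <- matrix(stats::rnorm(cf$n_genes * n_all, mean = mu, sd = sdg),
                 nrow = cf$n_genes,
                 dimnames = list(genes, c(tumors, controls)))
  # targets: dosage effect of the causal gene's copy number in tumors; the
  # causal gene's own transcript also tracks its copy number (cis dosage)
  dose_signal <- matrix(0, nrow = cf$n_planted_causal, ncol = cf$n_tumor)
  for (k in seq_along(causal)) {
    dose <- cn[match(locus_of_causal[k], loci$locus_id), ] - 1
    sig <- cf$effect_size * dose +
      stats::rnorm(cf$n_tumor, sd = cf$noise_sd)
    vals[targets[k], seq_len(cf$n_tumor)] <-
      stats::rnorm(cf$n_tumor, mean = mu[targets[k]], sd = sdg[targets[k]]) +
      sig
    vals[causal[k], seq_len(cf$n_tumor)] <-
      stats::rnorm(cf$n_tumor, mean = mu[causal[k]], sd = sdg[causal[k]]) +
      0.5 * cf$effect_size * dose +
      stats::rnorm(cf$n_tumor, sd = 0.5 * cf$noise_sd)
    dose_signal[k, ] <- sig
  }
  # intermediate path genes (and the planted TF): attenuated copy of the
  # target signal with little private noise, so the planted path is highly
  # conductive under correlation conductances while the intermediates
  # themselves are mostly below the per-case differential-expression cut
  # (signal relay is largely post-translational)
  for (k in seq_along(causal)) {
    for (g in c(interm[k, ], tfs_planted[k])) {
      vals[g, seq_len(cf$n_tumor)] <-
        stats::rnorm(cf$n_tumor, mean = mu[g], sd = 0.1 * sdg[g]) +
        0.5 * dose_signal[k, ]
    }
  }
  expr <- expression_matrix(vals,
                            is_control = c(rep(FALSE, cf$n_tumor),
                                           rep(TRUE, cf$n_control)))

  truth <- structure(list(causal_genes = causal, target_genes = targets,
                          causal_paths = causal_paths,
                          locus_of_causal = locus_of_causal,
                          carriers = carriers),
                     class = "planted_truth")
  list(expr = expr, cnv = cnv, network = network, truth = truth,
       config = config)
}

#' Write a simulated cohort to disk in the package's text formats
#'
#' Emits the expression table (+ groups sidecar), copy-number table
#' (+ gene map), SIF network (+ node attributes) and a `truth.tsv` table
#' (gene, role, locus, path).
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  write_copy_number(sim$cnv, file.path(dir, "copy_number.tsv"))
  write_network(sim$network, file.path(dir, "network.sif"))
  tr <- sim$truth
  truth <- data.frame(
    gene = c(tr$causal_genes, tr$target_genes),
    role = rep(c("causal", "target"), each = length(tr$causal_genes)),
    locus = c(unname(tr$locus_of_causal),
              rep(NA_character_, length(tr$target_genes))),
    path = rep(vapply(tr$causal_paths, paste, character(1),
                      collapse = "|"), 2),
    stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' A fixed, hand-checkable toy fixture
#'
#' A 20-node network and an 8-sample cohort (6 tumor, 2 control) small
#' enough to verify every pipeline stage by hand.  The network around the
#' target `tg` is a textbook circuit: the only edge kept at `tg` is the
#' protein-DNA edge from TF `tf1`; from `tf1` two series branches of two
#' unit-conductance edges each lead to the grounded candidates `c1` and
#' `c2`, so each branch carries current 1/2 and the voltages are
#' V(tg) = 2, V(tf1) = 1, V(a) = V(b) = 1/2.
#'
#' @return List with `network`, `expr`, `cnv`, `region_genes` (the toy
#'   candidate pool `c("c1", "c2")`) and `tg` (`"tg"`).
#' @export
worked_toy <- function() {
  genes <- c("tg", "tf1", "a", "b", "c1", "c2",
             sprintf("x%02d", 1:14))
  nodes <- data.frame(gene = genes, is_tf = genes == "tf1",
                      stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(u = "tf1", v = "tg", type = "protein_dna"),
    data.frame(u = c("tf1", "a", "tf1", "b"),
               v = c("a", "c1", "b", "c2"), type = "ppi"),
    # distractor edges at tg that the TF constraint must remove
    data.frame(u = c("tg", "tg"), v = c("x01", "x02"), type = "ppi"),
    # a background chain among the padding nodes
    data.frame(u = sprintf("x%02d", 1:13), v = sprintf("x%02d", 2:14),
               type = "ppi"))
  network <- interaction_network(nodes, edges)
  samples <- c(sprintf("t%d", 1:6), "ctl1", "ctl2")
  # deterministic expression: controls at 5.0/5.2; tg and path genes share
  # a tumor signature; everything else flat with a small gene-specific tilt
  vals <- matrix(5.0, nrow = length(genes), ncol = 8,
                 dimnames = list(genes, samples))
  vals[, "ctl2"] <- 5.2
  sig <- c(2, 2, 0, 2, 1, 0)          # tumor signature, cases t1..t6
  for (g in c("tg", "tf1", "a", "c1")) vals[g, 1:6] <- 5.1 + sig
  vals["b", 1:6] <- 5.1 + c(0.2, -0.1, 0.1, 0, -0.2, 0.15)
  vals["c2", 1:6] <- 5.1 + c(-0.1, 0.2, 0, 0.15, 0.1, -0.2)
  vals[sprintf("x%02d", 1:14), 1:6] <- 5.1 +
    0.05 * outer(1:14 %% 3, c(1, -1, 0, 1, -1, 0))
  expr <- expression_matrix(vals, is_control = samples %in%
                              c("ctl1", "ctl2"))
  loci <- data.frame(locus_id = sprintf("L%d", 1:6),
                     chromosome = rep(c("chr1", "chr2"), each = 3),
                     position = rep(c(1e5, 2e5, 3e5), 2),
                     stringsAsFactors = FALSE)
  cn <- matrix(1, nrow = 6, ncol = 6,
               dimnames = list(loci$locus_id, sprintf("t%d", 1:6)))
  cn["L2", ] <- c(1.6, 1.6, 1, 1.6, 1.3, 1)   # amplified in the signature
  cn["L5", ] <- c(1, 0.85, 1, 1, 0.85, 1)     # an unrelated deletion
  locus_genes <- list(L1 = "x01", L2 = c("c1", "c2"), L3 = "x03",
                      L4 = "x04", L5 = c("x05", "x06"), L6 = "x07")
  cnv <- copy_number_profile(loci, cn, locus_genes)
  list(network = network, expr = expr, cnv = cnv,
       region_genes = c("c1", "c2"), tg = "tg")
}
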