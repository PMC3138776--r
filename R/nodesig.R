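#' Per-node counts of sample members among descendant tips
#'
#' Single post-order pass: for every node of the tree, the number of
#' sampled taxa among the tips distal to it.
#'
#' @param tree A `"phylo"` object.
#' @param sample Character vector of tip labels (may be empty).
#' @return Named integer vector over all nodes (tips and internal, ape
#'   numbering as names).
#' @export
node_counts <- function(tree, sample) {
  sample <- unique(normalize_labels(sample))
  missing <- setdiff(sample, tree$tip.label)
  if (length(missing))
    stop("sample tips not in tree: ", paste(missing, collapse = ", "))
  desc <- descendant_matrix(tree)
  x <- as.integer(desc %*% (tree$tip.label %in% sample))
  names(x) <- seq_along(x)
  x
}

#' Upper-tail hypergeometric probability for node enrichment
#'
#' Under a null that draws n tips uniformly without replacement from the N
#' tips of the pool, the number X of drawn tips descending from a node
#' with D descendant tips is Hypergeometric(N, D, n). Returns
#' `P(X >= x)`, the exact counterpart of the randomization tail.
#'
#' @param N Pool tip count.
#' @param D Descendant tip count of the node.
#' @param n Sample size.
#' @param x Observed number of sample members descending from the node.
#' @return `P(X >= x)` in (0, 1].
#' @examples
#' hypergeom_node_p(10, 4, 4, 4)  # 1/210
#' @export
hypergeom_node_p <- function(N, D, n, x) {
  if (any(c(N, D, n, x) < 0) || D > N || n > N || x > min(D, n))
    stop("inconsistent hypergeometric arguments (need 0 <= x <= min(D, n), ",
         "D <= N, n <= N)")
  stats::phyper(x - 1, D, N - D, n, lower.tail = FALSE)
}

#' Node enrichment ("nodesig") test per community sample
#'
#' Tests every internal node with `2 <= D <= N - 1` descendant tips (the
#' root, which always contains the whole sample, is excluded) for
#' overabundance of sample members among the tips distal to it.
#'
#' In `"exact"` mode `p_more` is the hypergeometric upper tail and a node
#' is flagged `MORE` when `p_more <= 1 - flag_threshold` (0.025 by
#' default). In `"permutation"` mode the observed count is compared
#' against `cfg$runs` random draws of n tips from the pool: `p_more =
#' (#\{X_null >= x\} + 1) / (R + 1)` and the node is flagged when the
#' observed count strictly exceeds the null count in at least
#' `flag_threshold` of the runs (the 975/1000 convention). Underabundance
#' (`LESS`) is reported symmetrically but is not highlighted downstream.
#'
#' @param cm A `community_matrix`; samples with at least 1 taxon are
#'   tested, empty samples skipped with a warning.
#' @param tree A `"phylo"` object.
#' @param cfg A [null_model_config()] (runs and seed used in permutation
#'   mode).
#' @param mode `"exact"` (hypergeometric) or `"permutation"`.
#' @param flag_threshold Fraction of null runs the observed count must
#'   strictly exceed for a `MORE` flag (default 0.975; the exact-mode
#'   cutoff is `1 - flag_threshold`).
#' @return Data.frame with one row per (sample, tested node): `sample`,
#'   `node` (ape node number), `node_label` (`"MRCA(x,y)"`), `D`, `n`,
#'   `x_obs`, `null_mean` (= nD/N), `p_more`, `p_less`, `flag`.
#' @export
nodesig_test <- function(cm, tree, cfg = null_model_config(),
                         mode = c("exact", "permutation"),
                         flag_threshold = 0.975) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"), flag_threshold > 0, flag_threshold < 1)
  taxa <- normalize_labels(colnames(cm))
  missing <- setdiff(taxa[colSums(cm) > 0], tree$tip.label)
  if (length(missing))
    stop("taxa with no matching tree tip: ", paste(missing, collapse = ", "))
  N <- ape::Ntip(tree)
  desc <- descendant_matrix(tree)
  internal <- (N + 1L):(N + tree$Nnode)
  D <- rowSums(desc[internal, , drop = FALSE])
  test_nodes <- internal[D >= 2L & D <= N - 1L]
  Dv <- rowSums(desc[test_nodes, , drop = FALSE])
  labels <- vapply(test_nodes, node_report_label, "", tree = tree, .desc = desc)
  sizes <- rowSums(cm > 0)
  empty <- rownames(cm)[sizes == 0L]
  if (length(empty))
    warning("skipping empty sample(s): ", paste(empty, collapse = ", "))
  res <- list()
  for (s in which(sizes >= 1L)) {
    members <- taxa[cm[s, ] > 0]
    n <- length(members)
    x <- as.integer(desc[test_nodes, , drop = FALSE] %*%
                      (tree$tip.label %in% members))
    if (mode == "exact") {
      p_more <- mapply(hypergeom_node_p, D = Dv, x = x,
                       MoreArgs = list(N = N, n = n))
      p_less <- stats::phyper(x, Dv, N - Dv, n)  # P(X <= x)
      flag <- ifelse(p_more <= 1 - flag_threshold, "MORE",
                     ifelse(p_less <= 1 - flag_threshold, "LESS", ""))
    } else {
      if (!is.null(cfg$seed)) set.seed(.derive_seed(cfg$seed, rownames(cm)[s]))
      draws <- matrix(0L, N, cfg$runs)
      for (r in seq_len(cfg$runs)) draws[sample.int(N, n), r] <- 1L
      Xnull <- desc[test_nodes, , drop = FALSE] %*% draws
      ge <- rowSums(Xnull >= x)
      le <- rowSums(Xnull <= x)
      p_more <- (ge + 1) / (cfg$runs + 1)
      p_less <- (le + 1) / (cfg$runs + 1)
      frac_gt <- rowSums(Xnull < x) / cfg$runs   # runs the observed strictly beats
      frac_lt <- rowSums(Xnull > x) / cfg$runs
      flag <- ifelse(frac_gt >= flag_threshold, "MORE",
                     ifelse(frac_lt >= flag_threshold, "LESS", ""))
    }
    res[[length(res) + 1L]] <- data.frame(
      sample = rownames(cm)[s], node = test_nodes, node_label = labels,
      D = as.integer(Dv), n = n, x_obs = x, null_mean = n * Dv / N,
      p_more = as.numeric(p_more), p_less = as.numeric(p_less),
      flag = flag, stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no nonempty sample; nothing to test")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Annotated Newick with enriched nodes highlighted
#'
#' Nodes flagged `MORE` for at least one sample are labeled
#' `"MORE:<sample>"`, with multiple samples joined as a single sorted,
#' `|`-separated label; unflagged nodes are left unlabeled.
#'
#' @param tree A `"phylo"` object.
#' @param results Output of [nodesig_test()] (one or several samples).
#' @param file Optional output path.
#' @return The Newick string.
#' @export
annotate_tree <- function(tree, results, file = NULL) {
  hot <- results[results$flag == "MORE", , drop = FALSE]
  if (!nrow(hot)) return(write_newick(tree, file = file))
  labs <- vapply(split(hot$sample, hot$node), function(s)
    paste0("MORE:", paste(sort(unique(s)), collapse = "|")), "")
  write_newick(tree, node_labels = labs, file = file)
}
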