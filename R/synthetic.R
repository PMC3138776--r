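#' Configuration for the synthetic calibration experiments
#'
#' @param n_tips Tip count of each simulated tree (>= 2).
#' @param birth_rate Speciation rate lambda of the pure-birth process
#'   (default 1; only relative branch lengths matter to the scale-invariant
#'   tests).
#' @param n_sample Community size n (2 <= n <= n_tips).
#' @param clump_fraction Vector of clumping fractions f in [0, 1]: the
#'   fraction of community members drawn from one focal clade (f = 0 is a
#'   uniform draw, f = 1 fully clade-restricted).
#' @param replicates Number of (tree, community) replicates per f.
#' @param seed Base seed; every replicate derives its own substream.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_tips, birth_rate = 1, n_sample,
                             clump_fraction = 0, replicates = 100,
                             seed = 1) {
  stopifnot(n_tips >= 2, birth_rate > 0,
            n_sample >= 2, n_sample <= n_tips,
            all(clump_fraction >= 0), all(clump_fraction <= 1),
            replicates >= 0)
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 n_sample = as.integer(n_sample),
                 clump_fraction = clump_fraction,
                 replicates = as.integer(replicates), seed = seed),
            class = "synthetic_config")
}

#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Grows a tree by exponential waiting times (rate k * lambda with k
#' extant lineages), splitting a uniformly chosen lineage at each event,
#' until `n_tips` lineages exist; a final `Exp(n_tips * lambda)` waiting
#' time is then added so pendant branches are positive. All tips end at
#' the same time (ultrametric by construction) and are labeled
#' `t1..tN` in cladewise order.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate lambda (> 0).
#' @param seed Optional integer seed (bit-reproducible output).
#' @return A binary ultrametric `"phylo"` object.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  n_tips <- as.integer(n_tips)
  stopifnot(n_tips >= 2L, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  nlin <- 2L * n_tips - 1L              # total lineages ever created
  start <- numeric(nlin)
  split_time <- rep(NA_real_, nlin)
  child1 <- rep(NA_integer_, nlin)
  child2 <- rep(NA_integer_, nlin)
  active <- 1L
  t <- 0
  nextid <- 2L
  while (length(active) < n_tips) {
    k <- length(active)
    t <- t + stats::rexp(1L, k * birth_rate)
    pick <- active[sample.int(k, 1L)]
    split_time[pick] <- t
    child1[pick] <- nextid
    child2[pick] <- nextid + 1L
    start[nextid] <- t
    start[nextid + 1L] <- t
    active <- c(active[active != pick], nextid, nextid + 1L)
    nextid <- nextid + 2L
  }
  t_end <- t + stats::rexp(1L, n_tips * birth_rate)
  # convert lineage table to an ape phylo (root lineage's stem dropped)
  edge_from <- integer(2L * n_tips - 2L)
  edge_to <- integer(2L * n_tips - 2L)
  elen <- numeric(2L * n_tips - 2L)
  tip_count <- 0L
  node_count <- n_tips
  ei <- 0L
  visit <- function(lin) {
    if (is.na(child1[lin])) {
      tip_count <<- tip_count + 1L
      return(tip_count)
    }
    node_count <<- node_count + 1L
    me <- node_count
    for (ch in c(child1[lin], child2[lin])) {
      num <- visit(ch)
      ei <<- ei + 1L
      edge_from[ei] <<- me
      edge_to[ei] <<- num
      end <- if (is.na(split_time[ch])) t_end else split_time[ch]
      elen[ei] <<- end - start[ch]
    }
    me
  }
  visit(1L)
  tree <- structure(list(edge = cbind(edge_from, edge_to),
                         edge.length = elen,
                         tip.label = paste0("t", seq_len(n_tips)),
                         Nnode = n_tips - 1L),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate a presence community with known clumping structure
#'
#' Draws `ceiling(f * n_sample)` community members from inside one focal
#' clade (chosen uniformly among internal nodes whose descendant count D
#' satisfies `ceiling(f*n) <= D <= N - (n - ceiling(f*n))`, so both the
#' inside and outside draws are feasible) and the remainder uniformly from
#' outside it. With `f = 0` the community is a uniform draw from all tips
#' and no focal clade is chosen.
#'
#' @param tree A `"phylo"` object.
#' @param n_sample Community size n (2 <= n <= Ntip).
#' @param f Clumping fraction in [0, 1].
#' @param seed Optional integer seed.
#' @return List with `tips` (character vector of n tip labels) and
#'   `focal` (internal node number, or `NA` when f = 0).
#' @export
simulate_community <- function(tree, n_sample, f, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), f >= 0, f <= 1)
  N <- ape::Ntip(tree)
  n <- as.integer(n_sample)
  stopifnot(n >= 2L, n <= N)
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(ceiling(f * n))
  if (m == 0L)
    return(list(tips = tree$tip.label[sample.int(N, n)], focal = NA_integer_))
  desc <- descendant_matrix(tree)
  internal <- (N + 1L):(N + tree$Nnode)
  D <- rowSums(desc[internal, , drop = FALSE])
  eligible <- internal[D >= m & D <= N - (n - m)]
  if (!length(eligible))
    stop("no eligible focal clade for n = ", n, ", f = ", f,
         " on this tree (need an internal node with between ", m, " and ",
         N - (n - m), " descendant tips)")
  focal <- eligible[sample.int(length(eligible), 1L)]
  inside <- tree$tip.label[desc[focal, ]]
  outside <- setdiff(tree$tip.label, inside)
  tips <- c(inside[sample.int(length(inside), m)],
            if (n > m) outside[sample.int(length(outside), n - m)])
  list(tips = tips, focal = focal)
}

#' Type-I error / power calibration of the clumping test
#'
#' For each clumping fraction f and each replicate: simulates a fresh Yule
#' tree and community, runs [signal_test()] on it, and records whether the
#' one-tailed clumping p falls at or below alpha. At f = 0 the rejection
#' rate estimates the size of the test; at f > 0, its power.
#'
#' @param cfg A [synthetic_config()].
#' @param null_cfg A [null_model_config()] (its `runs` and `model` are
#'   used; per-replicate seeds derive from `cfg$seed`).
#' @return Data.frame with one row per (f, metric): `clump_fraction`,
#'   `metric`, `alpha`, `replicates`, `rejections`, `rate`, and an exact
#'   (Clopper-Pearson) 95% binomial interval `ci_lower`, `ci_upper`.
#' @export
calibration_experiment <- function(cfg, null_cfg = null_model_config()) {
  empty <- data.frame(clump_fraction = numeric(0), metric = character(0),
                      alpha = numeric(0), replicates = integer(0),
                      rejections = integer(0), rate = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      stringsAsFactors = FALSE)
  if (cfg$replicates == 0L) return(empty)
  rows <- list()
  for (f in cfg$clump_fraction) {
    rej <- c(mpd = 0L, mntd = 0L)
    for (i in seq_len(cfg$replicates)) {
      key <- sprintf("f%g_rep%d", f, i)
      tree <- simulate_yule_tree(cfg$n_tips, cfg$birth_rate,
                                 seed = .derive_seed(cfg$seed, paste0("tree_", key)))
      comm <- simulate_community(tree, cfg$n_sample, f,
                                 seed = .derive_seed(cfg$seed, paste0("comm_", key)))
      cm <- .new_community_matrix(matrix(
        as.integer(tree$tip.label %in% comm$tips), 1L, cfg$n_tips,
        dimnames = list(key, tree$tip.label)))
      res <- signal_test(cm, tree,
                         null_model_config(runs = null_cfg$runs,
                                           seed = cfg$seed,
                                           model = null_cfg$model,
                                           alpha = null_cfg$alpha))
      rej["mpd"] <- rej["mpd"] + (res$p_mpd <= null_cfg$alpha)
      rej["mntd"] <- rej["mntd"] + (res$p_mntd <= null_cfg$alpha)
    }
    for (metric in c("mpd", "mntd")) {
      ci <- stats::binom.test(rej[[metric]], cfg$replicates)$conf.int
      rows[[length(rows) + 1L]] <- data.frame(
        clump_fraction = f, metric = metric, alpha = null_cfg$alpha,
        replicates = cfg$replicates, rejections = rej[[metric]],
        rate = rej[[metric]] / cfg$replicates,
        ci_lower = ci[1L], ci_upper = ci[2L], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
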