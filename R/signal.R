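#' Null-model configuration for the permutation tests
#'
#' @param runs Number of randomizations R (default 999).
#' @param seed Integer seed; per-sample substreams are derived
#'   deterministically from `(seed, sample name)` so adding a sample does
#'   not perturb the others.
#' @param model `"pool_draw"` (uniform draws of n distinct tips from the
#'   full tip pool; the default, matching randomly generated samples) or
#'   `"label_shuffle"` (tip labels permuted on the tree). For presence data
#'   the two coincide in distribution.
#' @param alpha Significance level for downstream flagging.
#' @return A list of class `"null_model_config"`.
#' @export
null_model_config <- function(runs = 999, seed = NULL,
                              model = c("pool_draw", "label_shuffle"),
                              alpha = 0.05) {
  model <- match.arg(model)
  runs <- as.integer(runs)
  stopifnot(runs >= 1L, alpha > 0, alpha < 1)
  structure(list(runs = runs, seed = seed, model = model, alpha = alpha),
            class = "null_model_config")
}

# deterministic 31-bit substream seed from a base seed and a character key
.derive_seed <- function(seed, key) {
  h <- 0
  for (v in utf8ToInt(as.character(key))) h <- (h * 31 + v) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

.check_sample_tips <- function(tips, dmat) {
  missing <- setdiff(tips, rownames(dmat))
  if (length(missing))
    stop("sample tips not in distance matrix: ", paste(missing, collapse = ", "))
}

#' Mean pairwise phylogenetic distance (MPD)
#'
#' Mean of the n(n-1)/2 pairwise patristic distances among the sampled
#' tips; sensitive to clumping at deep nodes.
#'
#' @param sample Character vector of tip labels (n >= 2).
#' @param dmat Patristic distance matrix from [patristic_matrix()].
#' @return The MPD, in the tree's branch-length units.
#' @export
mpd <- function(sample, dmat) {
  sample <- unique(normalize_labels(sample))
  if (length(sample) < 2L)
    stop("MPD is undefined for samples of fewer than 2 taxa")
  .check_sample_tips(sample, dmat)
  sub <- dmat[sample, sample]
  mean(sub[upper.tri(sub)])
}

#' Mean nearest taxon distance (MNTD)
#'
#' Mean over sampled tips of the patristic distance to the nearest other
#' sampled tip; sensitive to clumping near the tips of the tree.
#'
#' @inheritParams mpd
#' @return The MNTD; always `<=` MPD for the same sample.
#' @export
mntd <- function(sample, dmat) {
  sample <- unique(normalize_labels(sample))
  if (length(sample) < 2L)
    stop("MNTD is undefined for samples of fewer than 2 taxa")
  .check_sample_tips(sample, dmat)
  sub <- dmat[sample, sample]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

# both metrics for a set of row/col indices into d (no validation)
.metrics_idx <- function(d, idx) {
  sub <- d[idx, idx]
  m1 <- mean(sub[upper.tri(sub)])
  diag(sub) <- Inf
  c(mpd = m1, mntd = mean(apply(sub, 1L, min)))
}

# R x 2 matrix of null MPD/MNTD values for samples of size n
.null_metrics <- function(dmat, n, runs, model = "pool_draw") {
  N <- nrow(dmat)
  out <- matrix(NA_real_, runs, 2L, dimnames = list(NULL, c("mpd", "mntd")))
  for (r in seq_len(runs)) {
    idx <- if (model == "label_shuffle") sample.int(N)[seq_len(n)]
           else sample.int(N, n)
    out[r, ] <- .metrics_idx(dmat, idx)
  }
  out
}

#' Null distribution of a clumping metric
#'
#' Draws `cfg$runs` random samples of `n` distinct tips from the full tip
#' pool and returns the metric value of each; reproducible for a fixed
#' `cfg$seed`.
#'
#' @param metric `"mpd"` or `"mntd"`.
#' @param n Sample size (2 <= n <= number of tips).
#' @param dmat Patristic distance matrix.
#' @param cfg A [null_model_config()].
#' @return Numeric vector of length `cfg$runs`.
#' @export
null_distribution <- function(metric = c("mpd", "mntd"), n, dmat,
                              cfg = null_model_config()) {
  metric <- match.arg(metric)
  N <- nrow(dmat)
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  if (n > N) stop("n (", n, ") exceeds the tip pool size (", N, ")")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  .null_metrics(dmat, n, cfg$runs, cfg$model)[, metric]
}

#' Permutation test of phylogenetic clumping per community sample
#'
#' For every sample (row) of the community matrix with n >= 2 member taxa,
#' computes observed MPD and MNTD, a permutation null of `cfg$runs` random
#' equal-sized tip draws, standardized effect sizes
#' `SES = (null mean - observed) / null sd` (positive = clumped; the
#' NRI/NTI sign convention), and one-tailed clumping p-values
#' `(k + 1) / (R + 1)` with `k` the number of null values less than or
#' equal to the observed (ties counted as more clumped). Samples with
#' fewer than 2 taxa are skipped with a warning.
#'
#' @param cm A `community_matrix` (samples x taxa; taxa must match tree
#'   tips after normalization).
#' @param tree A `"phylo"` object, or a precomputed patristic matrix.
#' @param cfg A [null_model_config()].
#' @param p_adjust Optional multiple-testing method (e.g. `"BH"`) applied
#'   across samples per metric; off (`"none"`) by default.
#' @return Data.frame with one row per tested sample: `sample`, `n`,
#'   `mpd_obs`, `mpd_null_mean`, `mpd_null_sd`, `ses_mpd`, `p_mpd`, and the
#'   same for MNTD (plus `p_mpd_adj`/`p_mntd_adj` when `p_adjust != "none"`).
#' @export
signal_test <- function(cm, tree, cfg = null_model_config(),
                        p_adjust = "none") {
  dmat <- if (inherits(tree, "phylo")) patristic_matrix(tree) else tree
  taxa <- normalize_labels(colnames(cm))
  .check_sample_tips(taxa[colSums(cm) > 0], dmat)
  sizes <- rowSums(cm > 0)
  skipped <- rownames(cm)[sizes < 2L]
  if (length(skipped))
    warning("skipping sample(s) with fewer than 2 taxa: ",
            paste(skipped, collapse = ", "))
  keep <- which(sizes >= 2L)
  if (!length(keep)) stop("no sample with at least 2 taxa; nothing to test")
  res <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    s <- keep[i]
    members <- taxa[cm[s, ] > 0]
    idx <- match(members, rownames(dmat))
    obs <- .metrics_idx(dmat, idx)
    if (!is.null(cfg$seed)) set.seed(.derive_seed(cfg$seed, rownames(cm)[s]))
    nulls <- .null_metrics(dmat, length(idx), cfg$runs, cfg$model)
    mu <- colMeans(nulls)
    sd_ <- apply(nulls, 2L, stats::sd)
    ses <- ifelse(sd_ > 0, (mu - obs) / sd_, 0)
    p <- (colSums(nulls <= rep(obs, each = cfg$runs)) + 1) / (cfg$runs + 1)
    res[[i]] <- data.frame(
      sample = rownames(cm)[s], n = length(idx),
      mpd_obs = obs[["mpd"]], mpd_null_mean = mu[["mpd"]],
      mpd_null_sd = sd_[["mpd"]], ses_mpd = ses[["mpd"]], p_mpd = p[["mpd"]],
      mntd_obs = obs[["mntd"]], mntd_null_mean = mu[["mntd"]],
      mntd_null_sd = sd_[["mntd"]], ses_mntd = ses[["mntd"]],
      p_mntd = p[["mntd"]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (!identical(p_adjust, "none")) {
    out$p_mpd_adj <- stats::p.adjust(out$p_mpd, method = p_adjust)
    out$p_mntd_adj <- stats::p.adjust(out$p_mntd, method = p_adjust)
  }
  out
}

#' Exact clumping p-value by full enumeration
#'
#' Enumerates every size-n subset of the tip pool and returns the exact
#' one-tailed p: the fraction of subsets whose metric is less than or
#' equal to the observed sample's (ties counted as more clumped). Serves
#' as the independent oracle for the permutation test when `choose(N, n)`
#' is small.
#'
#' @inheritParams mpd
#' @param metric `"mpd"` or `"mntd"`.
#' @param cap Enumeration cap on `choose(N, n)` (default 1e6).
#' @return The exact p-value in (0, 1].
#' @export
exact_signal_p <- function(sample, dmat, metric = c("mpd", "mntd"),
                           cap = 1e6) {
  metric <- match.arg(metric)
  sample <- unique(normalize_labels(sample))
  .check_sample_tips(sample, dmat)
  N <- nrow(dmat)
  n <- length(sample)
  if (n < 2L) stop("metric undefined for samples of fewer than 2 taxa")
  if (choose(N, n) > cap)
    stop("choose(", N, ",", n, ") exceeds the enumeration cap (", cap,
         "); use the permutation test instead")
  obs <- .metrics_idx(dmat, match(sample, rownames(dmat)))[[metric]]
  subsets <- utils::combn(N, n)
  vals <- apply(subsets, 2L, function(idx) .metrics_idx(dmat, idx)[[metric]])
  # tolerance absorbs float noise in tie detection
  tol <- 1e-12 * max(1, abs(obs))
  sum(vals <= obs + tol) / ncol(subsets)
}
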