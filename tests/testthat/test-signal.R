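test_that("MPD and MNTD match hand-computed toy values and error on singletons", {
  d <- patristic_matrix(tree3())
  expect_equal(mpd(c("A", "B"), d), 2)
  expect_equal(mntd(c("A", "B"), d), 2)
  expect_equal(mpd(c("A", "B", "C"), d), 10 / 3)
  expect_equal(mntd(c("A", "B", "C"), d), 8 / 3)
  expect_error(mpd("A", d), "fewer than 2")
  expect_error(mntd("A", d), "fewer than 2")
  expect_error(mpd(c("A", "Q"), d), "Q")
})

test_that("MNTD never exceeds MPD and both agree with picante", {
  for (seed in 1:5) {
    tr <- simulate_yule_tree(15, seed = 200 + seed)
    d <- patristic_matrix(tr)
    set.seed(seed)
    samp <- sample(tr$tip.label, 6)
    expect_lte(mntd(samp, d), mpd(samp, d) + 1e-12)
    comm <- matrix(as.integer(tr$tip.label %in% samp), 1,
                   dimnames = list("s", tr$tip.label))
    expect_equal(mpd(samp, d), unname(picante::mpd(comm, d)))
    expect_equal(mntd(samp, d), unname(picante::mntd(comm, d)))
  }
})

test_that("null distributions are reproducible and centred correctly", {
  d <- patristic_matrix(simulate_yule_tree(12, seed = 7))
  cfg <- null_model_config(runs = 50, seed = 11)
  expect_identical(null_distribution("mpd", 4, d, cfg),
                   null_distribution("mpd", 4, d, cfg))
  # degenerate null: n = N gives the full-pool value in every run
  full <- mpd(rownames(d), d)
  expect_equal(null_distribution("mpd", nrow(d), d, cfg), rep(full, 50))
  expect_error(null_distribution("mpd", nrow(d) + 1, d, cfg), "exceeds")
  # E[null MPD] is the mean pairwise distance of the pool (uniform pairs)
  nulls <- null_distribution("mpd", 5, d, null_model_config(runs = 4000, seed = 3))
  pool_mean <- mean(d[upper.tri(d)])
  expect_lt(abs(mean(nulls) - pool_mean), 4 * stats::sd(nulls) / sqrt(4000))
  # label-shuffle model draws from the same null for presence data
  nulls_ls <- null_distribution("mpd", 5, d,
                                null_model_config(runs = 4000, seed = 3,
                                                  model = "label_shuffle"))
  expect_lt(abs(mean(nulls_ls) - pool_mean), 4 * stats::sd(nulls_ls) / sqrt(4000))
})

test_that("signal_test reports per-sample results and skips tiny samples", {
  tr <- simulate_yule_tree(12, seed = 9)
  cm <- build_community_matrix(data.frame(
    taxon = c("t1", "t2", "t3", "t5"), region = NA,
    category = c("Skin", "Skin", "Skin", "Pain"),
    condition = NA, source = NA))
  expect_warning(res <- signal_test(cm, tr, null_model_config(runs = 99, seed = 1)),
                 "Pain")
  expect_setequal(res$sample, c("Skin", "Medicinal uses overall"))
  expect_true(all(res$p_mpd > 0 & res$p_mpd <= 1))
  expect_true(all(res$p_mntd > 0 & res$p_mntd <= 1))
  expect_true(all(res$mntd_obs <= res$mpd_obs + 1e-12))
  lone <- cm["Pain", , drop = FALSE]
  expect_error(suppressWarnings(signal_test(lone, tr)), "no sample")
})

test_that("p-values and SES are invariant to relabeling and branch-length scale", {
  tr <- simulate_yule_tree(14, seed = 21)
  samp <- c("t2", "t3", "t4", "t9")
  cm <- matrix(as.integer(tr$tip.label %in% samp), 1,
               dimnames = list("use", tr$tip.label))
  cfg <- null_model_config(runs = 199, seed = 5)
  base <- signal_test(cm, tr, cfg)
  # consistent relabeling: rename every taxon in tree and matrix
  tr2 <- tr
  tr2$tip.label <- paste0("sp_", seq_along(tr$tip.label))
  cm2 <- cm
  colnames(cm2) <- tr2$tip.label
  ren <- signal_test(cm2, tr2, cfg)
  expect_equal(ren$p_mpd, base$p_mpd)
  expect_equal(ren$p_mntd, base$p_mntd)
  expect_equal(ren$ses_mntd, base$ses_mntd)
  # branch-length rescaling: SES and p unchanged
  tr3 <- tr
  tr3$edge.length <- tr$edge.length * 3.7
  sc <- signal_test(cm, tr3, cfg)
  expect_equal(sc$p_mpd, base$p_mpd)
  expect_equal(sc$p_mntd, base$p_mntd)
  expect_equal(sc$ses_mpd, base$ses_mpd, tolerance = 1e-10)
  expect_equal(sc$ses_mntd, base$ses_mntd, tolerance = 1e-10)
})

test_that("exact enumeration oracle handles the caterpillar and edge cases", {
  d <- patristic_matrix(caterpillar5())
  expect_equal(exact_signal_p(c("A", "B"), d, "mpd"), 1 / 10)
  expect_equal(exact_signal_p(rownames(d), d, "mpd"), 1)  # full pool
  expect_error(exact_signal_p(c("A", "B"), d, "mpd", cap = 5), "cap")
})
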