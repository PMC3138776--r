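#' Run configuration for the end-to-end pipeline
#'
#' Collects paths and options for the pipeline stages. All tabular outputs
#' carry `#`-prefixed provenance lines (seed, runs, null model, package
#' version, input checksums) and are byte-identical across runs for a
#' fixed seed and fixed inputs.
#'
#' @param tree Path to the Newick tree.
#' @param samples Path to a community file, or `NULL` when `records` is
#'   given.
#' @param samples_format `"phylocom"` (3-column sample file) or `"wide"`
#'   (taxon-by-sample 0/1 TSV).
#' @param records Path to a long-form use-record TSV/CSV.
#' @param condition_samples Condition names added as extra samples when
#'   building from records.
#' @param out_dir Output directory (created if absent).
#' @param runs,seed,null_model,alpha See [null_model_config()].
#' @param mode Node-enrichment mode, `"exact"` or `"permutation"`.
#' @param flag_threshold See [nodesig_test()].
#' @param prune Tip labels (e.g. outgroups) dropped from the tree before
#'   any analysis.
#' @param mapping Optional species-to-tip mapping file (see
#'   [match_taxa_to_tips()]).
#' @param prune_unmatched Drop matrix taxa absent from the tree instead of
#'   erroring.
#' @param unit_lengths Substitute unit branch lengths when missing.
#' @param n_tips,n_sample,clump_fraction,replicates,birth_rate Synthetic
#'   settings used by [run_simulate()].
#' @return List of class `"run_config"`.
#' @export
run_config <- function(tree = NULL, samples = NULL,
                       samples_format = c("phylocom", "wide"),
                       records = NULL, condition_samples = NULL,
                       out_dir = ".", runs = 999, seed = 1,
                       null_model = "pool_draw", alpha = 0.05,
                       mode = "exact", flag_threshold = 0.975,
                       prune = NULL, mapping = NULL,
                       prune_unmatched = FALSE, unit_lengths = FALSE,
                       n_tips = 100, n_sample = 10, clump_fraction = c(0, 1),
                       replicates = 100, birth_rate = 1) {
  structure(list(tree = tree, samples = samples,
                 samples_format = match.arg(samples_format),
                 records = records, condition_samples = condition_samples,
                 out_dir = out_dir, runs = as.integer(runs), seed = seed,
                 null_model = null_model, alpha = alpha, mode = mode,
                 flag_threshold = flag_threshold, prune = prune,
                 mapping = mapping, prune_unmatched = prune_unmatched,
                 unit_lengths = unit_lengths, n_tips = n_tips,
                 n_sample = n_sample, clump_fraction = clump_fraction,
                 replicates = replicates, birth_rate = birth_rate),
            class = "run_config")
}

.pipeline_tree <- function(cfg) {
  tree <- read_phylogeny(file = cfg$tree, unit_lengths = cfg$unit_lengths)
  if (!is.null(cfg$prune)) {
    drop <- normalize_labels(cfg$prune)
    missing <- setdiff(drop, tree$tip.label)
    if (length(missing))
      warning("prune list names tips absent from the tree: ",
              paste(missing, collapse = ", "))
    tree <- ape::drop.tip(tree, intersect(drop, tree$tip.label))
    tree <- validate_phylogeny(tree)
  }
  tree
}

.pipeline_matrix <- function(cfg, tree) {
  cm <- if (!is.null(cfg$samples)) {
    if (cfg$samples_format == "phylocom") read_phylocom_samples(cfg$samples)
    else build_community_matrix(wide = cfg$samples)
  } else if (!is.null(cfg$records)) {
    recs <- assign_categories(read_use_records(cfg$records))
    build_community_matrix(recs, condition_samples = cfg$condition_samples)
  } else stop("run_config needs either 'samples' or 'records'")
  match_taxa_to_tips(cm, tree, mapping = cfg$mapping,
                     prune_unmatched = cfg$prune_unmatched)
}

.provenance <- function(cfg, extra = character(0)) {
  files <- c(tree = cfg$tree, samples = cfg$samples, records = cfg$records)
  files <- files[!vapply(files, is.null, TRUE)]
  sums <- if (length(files))
    sprintf("# input %s=%s md5=%s", names(files), unlist(files),
            unname(tools::md5sum(unlist(files)))) else character(0)
  c(sprintf("# ethnophylo %s",
            as.character(utils::packageVersion("ethnophylo"))),
    sprintf("# seed=%s runs=%d null_model=%s alpha=%g",
            format(cfg$seed), cfg$runs, cfg$null_model, cfg$alpha),
    sums, extra)
}

.write_tsv <- function(df, file, header) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

#' Run the clumping-signal stage and write its report
#'
#' @param cfg A [run_config()].
#' @return The [signal_test()] data.frame, invisibly; `signal.tsv` is
#'   written under `cfg$out_dir`.
#' @export
run_signal <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- .pipeline_tree(cfg)
  cm <- .pipeline_matrix(cfg, tree)
  res <- signal_test(cm, tree,
                     null_model_config(runs = cfg$runs, seed = cfg$seed,
                                       model = cfg$null_model,
                                       alpha = cfg$alpha))
  .write_tsv(res, file.path(cfg$out_dir, "signal.tsv"), .provenance(cfg))
  invisible(res)
}

#' Run the node-enrichment stage and write its reports
#'
#' @param cfg A [run_config()].
#' @return The [nodesig_test()] data.frame, invisibly; `nodesig.tsv` and
#'   the annotated `nodesig_annotated.nwk` are written under
#'   `cfg$out_dir`.
#' @export
run_nodesig <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- .pipeline_tree(cfg)
  cm <- .pipeline_matrix(cfg, tree)
  res <- nodesig_test(cm, tree,
                      null_model_config(runs = cfg$runs, seed = cfg$seed,
                                        model = cfg$null_model,
                                        alpha = cfg$alpha),
                      mode = cfg$mode, flag_threshold = cfg$flag_threshold)
  .write_tsv(res, file.path(cfg$out_dir, "nodesig.tsv"),
             .provenance(cfg, sprintf("# mode=%s flag_threshold=%g",
                                      cfg$mode, cfg$flag_threshold)))
  annotate_tree(tree, res, file = file.path(cfg$out_dir, "nodesig_annotated.nwk"))
  invisible(res)
}

#' Run the synthetic calibration stage and write its report
#'
#' @param cfg A [run_config()] (the synthetic fields are used).
#' @return The [calibration_experiment()] data.frame, invisibly;
#'   `calibration.tsv` is written under `cfg$out_dir`.
#' @export
run_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- synthetic_config(n_tips = cfg$n_tips, birth_rate = cfg$birth_rate,
                           n_sample = cfg$n_sample,
                           clump_fraction = cfg$clump_fraction,
                           replicates = cfg$replicates, seed = cfg$seed)
  res <- calibration_experiment(
    scfg, null_model_config(runs = cfg$runs, seed = cfg$seed,
                            model = cfg$null_model, alpha = cfg$alpha))
  .write_tsv(res, file.path(cfg$out_dir, "calibration.tsv"),
             .provenance(cfg, sprintf("# n_tips=%d n_sample=%d replicates=%d",
                                      scfg$n_tips, scfg$n_sample,
                                      scfg$replicates)))
  invisible(res)
}

#' Run the descriptive-summary stage and write the use tallies
#'
#' @param cfg A [run_config()] with `records` set.
#' @return List of the three tables, invisibly; `uses_by_taxon.tsv`,
#'   `uses_by_category.tsv` and `region_proportions.tsv` are written under
#'   `cfg$out_dir`.
#' @export
run_summary <- function(cfg) {
  if (is.null(cfg$records)) stop("run_summary needs 'records' in the config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- assign_categories(read_use_records(cfg$records))
  by_taxon <- tally_uses(recs, "taxon")
  by_cat <- tally_uses(recs, "category")
  prop <- relative_usage_by_region(recs)
  header <- .provenance(cfg)
  .write_tsv(by_taxon, file.path(cfg$out_dir, "uses_by_taxon.tsv"), header)
  .write_tsv(by_cat, file.path(cfg$out_dir, "uses_by_category.tsv"), header)
  propdf <- data.frame(region = rownames(prop), as.data.frame(prop),
                       check.names = FALSE)
  .write_tsv(propdf, file.path(cfg$out_dir, "region_proportions.tsv"), header)
  invisible(list(by_taxon = by_taxon, by_category = by_cat,
                 region_proportions = prop))
}
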