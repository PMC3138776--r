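#' Canonical medicinal-use category vocabulary
#'
#' The 13 canonical use categories (Circulatory/Blood ... Unspecific) with a
#' case-insensitive synonym table. The synonym table ships as an editable
#' TSV (`system.file("extdata", "category_synonyms.tsv", package =
#' "ethnophylo")`, columns `synonym`, `canonical`); the canonical names are
#' fixed by default.
#'
#' @param synonyms_file Optional path to a replacement synonym TSV.
#' @return List with elements `canonical` (character(13)) and `synonyms`
#'   (named character: lowercase synonym -> canonical name).
#' @export
use_category_vocabulary <- function(synonyms_file = NULL) {
  canonical <- c(
    "Circulatory/Blood", "Gastro-intestinal", "Genito-urinary/Fertility",
    "Infections/Fever", "Inflammation", "Musculo-Skeletal", "Nervous",
    "Pain", "Poisons treatment", "Respiratory", "Sensory", "Skin",
    "Unspecific")
  if (is.null(synonyms_file))
    synonyms_file <- system.file("extdata", "category_synonyms.tsv",
                                 package = "ethnophylo")
  syn <- stats::setNames(character(0), character(0))
  if (nzchar(synonyms_file) && file.exists(synonyms_file)) {
    tab <- utils::read.delim(synonyms_file, stringsAsFactors = FALSE)
    bad <- setdiff(tab$canonical, canonical)
    if (length(bad))
      stop("synonym table maps to unknown categories: ", paste(bad, collapse = ", "))
    syn <- stats::setNames(tab$canonical, tolower(trimws(tab$synonym)))
  }
  # every canonical name is its own (case-insensitive) synonym
  syn <- c(stats::setNames(canonical, tolower(canonical)), syn)
  list(canonical = canonical, synonyms = syn)
}

#' Read long-form ethnomedicinal use records
#'
#' Expects a delimited text file with a header naming at least `taxon` and
#' `category` columns (case-insensitive); `region`, `condition` and
#' `source` columns are kept when present. Unknown regions are stored
#' verbatim.
#'
#' @param file Path to a TSV (default) or CSV file.
#' @param sep Field separator; inferred from the file extension by default.
#' @return A data.frame with columns taxon, region, category, condition,
#'   source (one row per use record).
#' @export
read_use_records <- function(file, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "#")
  names(tab) <- tolower(names(tab))
  need <- c("taxon", "category")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("use-record table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("region", "condition", "source"))
    if (is.null(tab[[col]])) tab[[col]] <- NA_character_
  out <- tab[, c("taxon", "region", "category", "condition", "source")]
  if (!nrow(out)) warning("no use records found in ", file)
  bad <- !nzchar(trimws(out$taxon))
  if (any(bad)) stop("empty taxon name in record row(s): ",
                     paste(which(bad), collapse = ", "))
  out
}

#' Map record categories onto the canonical vocabulary
#'
#' @param records Data.frame of use records (see [read_use_records()]).
#' @param vocab Vocabulary from [use_category_vocabulary()].
#' @param strict If `TRUE`, a category with no canonical match is an error;
#'   otherwise it is kept verbatim with a warning.
#' @return The records with `category` replaced by its canonical form;
#'   unmatched originals are attached as `attr(, "unmatched")`.
#' @export
assign_categories <- function(records, vocab = use_category_vocabulary(),
                              strict = FALSE) {
  key <- tolower(trimws(records$category))
  hit <- vocab$synonyms[key]
  unmatched <- sort(unique(records$category[is.na(hit)]))
  if (length(unmatched)) {
    msg <- paste("categories with no canonical match:",
                 paste(unmatched, collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; kept verbatim")
  }
  records$category <- ifelse(is.na(hit), records$category, unname(hit))
  attr(records, "unmatched") <- unmatched
  records
}

.new_community_matrix <- function(m) {
  storage.mode(m) <- "integer"
  class(m) <- c("community_matrix", "matrix", "array")
  m
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community matrix:", nrow(x), "sample(s) x", ncol(x), "taxa\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Build the samples-by-taxa presence matrix
#'
#' Each medicinal-use category becomes one "community" sample containing
#' the taxa reported for it; optional condition-level samples (e.g.
#' malaria) are matched against the `condition` field; an overall sample
#' (union of all medicinal taxa) is appended. Alternatively a wide 0/1
#' matrix (first column taxon, remaining columns samples) is accepted.
#'
#' @param records Categorized use records, or `NULL` when `wide` is given.
#' @param wide Wide presence table: data.frame whose first column is the
#'   taxon name and remaining columns are 0/1 sample memberships, or a path
#'   to such a TSV.
#' @param condition_samples Character vector of condition names to add as
#'   extra samples (case-insensitive match on the condition field).
#' @param overall_name Name for the union sample.
#' @return A `community_matrix`: integer 0/1 matrix, samples in rows,
#'   taxa (normalized labels, sorted) in columns.
#' @export
build_community_matrix <- function(records = NULL, wide = NULL,
                                   condition_samples = NULL,
                                   overall_name = "Medicinal uses overall") {
  if (!is.null(wide)) {
    if (is.character(wide))
      wide <- utils::read.delim(wide, stringsAsFactors = FALSE, check.names = FALSE)
    taxa <- normalize_labels(wide[[1L]])
    vals <- as.matrix(wide[, -1L, drop = FALSE])
    bad <- which(!(vals %in% c(0, 1)), arr.ind = FALSE)
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(vals))
      stop("non-binary cell in wide matrix at taxon row ", rc[1L],
           ", sample column '", colnames(vals)[rc[2L]], "'")
    }
    m <- t(vals)
    colnames(m) <- taxa
    m <- m[, order(colnames(m)), drop = FALSE]
    if (!overall_name %in% rownames(m)) {
      m <- rbind(m, as.integer(colSums(m) > 0))
      rownames(m)[nrow(m)] <- overall_name
    }
    return(.new_community_matrix(m))
  }
  stopifnot(is.data.frame(records), nrow(records) > 0)
  records$taxon <- normalize_labels(records$taxon)
  taxa <- sort(unique(records$taxon))
  vocab <- use_category_vocabulary()
  cats <- unique(records$category)
  cats <- c(intersect(vocab$canonical, cats),
            sort(setdiff(cats, vocab$canonical)))
  rows <- lapply(cats, function(cc)
    as.integer(taxa %in% records$taxon[records$category == cc]))
  samples <- cats
  for (cond in condition_samples) {
    hit <- !is.na(records$condition) &
      tolower(trimws(records$condition)) == tolower(trimws(cond))
    rows <- c(rows, list(as.integer(taxa %in% records$taxon[hit])))
    samples <- c(samples, cond)
  }
  m <- do.call(rbind, rows)
  overall <- as.integer(taxa %in% records$taxon)
  m <- rbind(m, overall)
  dimnames(m) <- list(c(samples, overall_name), taxa)
  .new_community_matrix(m)
}

#' Read a Phylocom-style sample file
#'
#' Three tab-separated columns (sample name, abundance, taxon), no header.
#' Abundances are collapsed to presence; duplicate sample/taxon lines give
#' a single presence.
#'
#' @param file Path to the sample file.
#' @return A `community_matrix`.
#' @export
read_phylocom_samples <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty Phylocom sample file: ", file)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop("malformed Phylocom sample line ", which(nf != 3L)[1L],
         ": expected 3 tab-separated fields, got ", nf[nf != 3L][1L])
  sample <- vapply(parts, `[[`, "", 1L)
  taxon <- normalize_labels(vapply(parts, `[[`, "", 3L))
  samples <- unique(sample)
  taxa <- sort(unique(taxon))
  m <- matrix(0L, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  m[cbind(match(sample, samples), match(taxon, taxa))] <- 1L
  .new_community_matrix(m)
}

#' Write a community matrix in Phylocom sample format
#'
#' @param cm A `community_matrix`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_phylocom_samples <- function(cm, file) {
  idx <- which(cm == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  lines <- sprintf("%s\t1\t%s", rownames(cm)[idx[, 1L]], colnames(cm)[idx[, 2L]])
  writeLines(lines, file)
  invisible(file)
}

#' Tally use records
#'
#' @param records Use records.
#' @param by Grouping key: `"taxon"`, `"category"` or `"region"`.
#' @return Data.frame with the key and `uses` (record count), sorted by
#'   decreasing count then key.
#' @export
tally_uses <- function(records, by = c("taxon", "category", "region")) {
  by <- match.arg(by)
  stopifnot(nrow(records) > 0)
  tab <- table(records[[by]], useNA = "no")
  out <- data.frame(key = names(tab), uses = as.integer(tab),
                    stringsAsFactors = FALSE)
  names(out)[1L] <- by
  out[order(-out$uses, out[[by]]), , drop = FALSE]
}

#' Relative usage per category within each region
#'
#' @param records Use records carrying a `region` field.
#' @return Numeric matrix (region x category) of within-region proportions;
#'   each row sums to 1. Regions with zero records are omitted with a
#'   warning (as are records lacking a region).
#' @export
relative_usage_by_region <- function(records) {
  keep <- !is.na(records$region) & nzchar(trimws(records$region))
  if (!all(keep))
    warning(sum(!keep), " record(s) without a region omitted")
  records <- records[keep, , drop = FALSE]
  if (!nrow(records)) stop("no records with a region")
  tab <- table(records$region, records$category)
  prop <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  prop[order(rownames(prop)), order(colnames(prop)), drop = FALSE]
}

#' Match community-matrix taxa to tree tips
#'
#' Taxa match tips exactly after label normalization; an optional
#' species-to-tip mapping expands one taxon column to all of its accession
#' tips (presences propagated to every mapped tip).
#'
#' @param cm A `community_matrix`.
#' @param tree A `"phylo"` object.
#' @param mapping Optional data.frame (columns `taxon`, `tip`) or path to a
#'   two-column TSV mapping species names to tree tips.
#' @param prune_unmatched Drop taxa with no matching tip (with a warning)
#'   instead of raising an error.
#' @return A `community_matrix` whose columns are all tree tips.
#' @export
match_taxa_to_tips <- function(cm, tree, mapping = NULL,
                               prune_unmatched = FALSE) {
  tips <- tree$tip.label
  taxa <- normalize_labels(colnames(cm))
  if (!is.null(mapping)) {
    if (is.character(mapping))
      mapping <- utils::read.delim(mapping, stringsAsFactors = FALSE)
    names(mapping) <- tolower(names(mapping))
    stopifnot(all(c("taxon", "tip") %in% names(mapping)))
    mapping$taxon <- normalize_labels(mapping$taxon)
    mapping$tip <- normalize_labels(mapping$tip)
    badtip <- setdiff(mapping$tip, tips)
    if (length(badtip))
      stop("mapping refers to tips absent from the tree: ",
           paste(badtip, collapse = ", "))
    out <- matrix(0L, nrow(cm), length(tips),
                  dimnames = list(rownames(cm), tips))
    resolved <- logical(length(taxa))
    for (j in seq_along(taxa)) {
      to <- mapping$tip[mapping$taxon == taxa[j]]
      if (!length(to) && taxa[j] %in% tips) to <- taxa[j]
      if (length(to)) {
        out[, to] <- pmax(out[, to, drop = FALSE], cm[, j])
        resolved[j] <- TRUE
      }
    }
    unmatched <- taxa[!resolved]
    if (length(unmatched)) {
      if (!prune_unmatched)
        stop("taxa with no matching tree tip: ", paste(unmatched, collapse = ", "))
      warning("dropped ", length(unmatched), " unmatched taxa: ",
              paste(unmatched, collapse = ", "))
    }
    return(.new_community_matrix(out))
  }
  unmatched <- setdiff(taxa, tips)
  if (length(unmatched)) {
    if (!prune_unmatched)
      stop("taxa with no matching tree tip: ", paste(unmatched, collapse = ", "))
    warning("dropped ", length(unmatched), " unmatched taxa: ",
            paste(unmatched, collapse = ", "))
  }
  keep <- taxa %in% tips
  out <- matrix(0L, nrow(cm), length(tips),
                dimnames = list(rownames(cm), tips))
  out[, taxa[keep]] <- cm[, keep, drop = FALSE]
  .new_community_matrix(out)
}
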