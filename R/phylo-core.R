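#' Normalize taxon / tip labels
#'
#' Strips leading and trailing whitespace and converts internal runs of
#' whitespace to underscores, so that matrix taxon names written as
#' "P. angolensis 2" match tree tips written as "P.angolensis2"-style
#' underscore labels.
#'
#' @param x Character vector of labels.
#' @return Character vector of normalized labels.
#' @export
normalize_labels <- function(x) {
  gsub("[[:space:]]+", "_", trimws(as.character(x)))
}

.check_newick_text <- function(text) {
  if (!nzchar(trimws(text))) stop("empty Newick string")
  # strip square-bracket comments and quoted labels before bracket counting
  bare <- gsub("\\[[^]]*\\]", "", text)
  bare <- gsub("'[^']*'", "x", bare)
  chars <- strsplit(bare, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced parentheses in Newick string: unmatched ')' at position ", i)
    }
  }
  if (depth > 0L)
    stop("unbalanced parentheses in Newick string: ", depth, " '(' left open")
  if (!grepl(";[[:space:]]*$", text))
    stop("Newick string must end with ';' (position ", nchar(text), ")")
  invisible(TRUE)
}

#' Read and validate a rooted phylogeny
#'
#' Reads a Newick tree (from file or text), normalizes tip labels, and
#' enforces the invariants the downstream analyses rely on: at least two
#' tips, unique tip labels, and nonnegative resolved branch lengths. The
#' tree is treated as rooted as written; no rerooting is performed.
#'
#' @param file Path to a Newick file (ignored when `text` is given).
#' @param text Newick string.
#' @param unit_lengths If `TRUE`, missing branch lengths are replaced by
#'   unit length (this changes every patristic distance and is off by
#'   default; missing lengths are otherwise an error).
#' @return An object of class `"phylo"` (see [ape::read.tree()]).
#' @examples
#' tr <- read_phylogeny(text = "((A:1,B:1):1,C:2);")
#' @export
read_phylogeny <- function(file = NULL, text = NULL, unit_lengths = FALSE) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply either 'file' or 'text'")
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  .check_newick_text(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_phylogeny(tree, unit_lengths = unit_lengths)
}

#' Validate a phylo object for use in the clumping analyses
#'
#' @param tree A `"phylo"` object.
#' @param unit_lengths Replace missing branch lengths by 1 instead of
#'   raising an error.
#' @return The (possibly repaired) tree, invisibly classed `"phylo"`.
#' @export
validate_phylogeny <- function(tree, unit_lengths = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips")
  tree$tip.label <- normalize_labels(tree$tip.label)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels after normalization: ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (!unit_lengths)
      stop("tree has no branch lengths; set unit_lengths = TRUE to assume unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (!unit_lengths)
      stop("tree has unresolved (missing) branch lengths; set unit_lengths = TRUE ",
           "to substitute unit length for every branch")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (any(tree$edge.length == 0))
    warning("tree contains zero-length branches; tied zero distances are possible ",
            "(MNTD ties between distinct tips)")
  tree
}

#' Write a tree as Newick, optionally with internal-node labels
#'
#' Labels containing Newick metacharacters (parentheses, commas, colons,
#' semicolons, whitespace) are single-quoted rather than rejected.
#'
#' @param tree A `"phylo"` object.
#' @param node_labels Optional character vector of labels, named by internal
#'   node number (ape numbering, `Ntip+1 .. Ntip+Nnode`). Unnamed nodes are
#'   left unlabeled.
#' @param digits Number of significant digits for branch lengths.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, node_labels = NULL, digits = 10, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  nt <- ape::Ntip(tree)
  lab <- rep("", nt + tree$Nnode)
  if (!is.null(tree$node.label))
    lab[nt + seq_len(tree$Nnode)] <- tree$node.label
  if (!is.null(node_labels)) {
    idx <- as.integer(names(node_labels))
    if (anyNA(idx) || any(idx <= nt) || any(idx > nt + tree$Nnode))
      stop("node_labels names must be internal node numbers")
    lab[idx] <- unname(node_labels)
  }
  lab <- .quote_label(lab)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- rep(NA_real_, nt + tree$Nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  fmt <- function(x) sprintf("%.*g", digits, x)
  render <- function(node) {
    piece <- if (node <= nt) {
      paste0(.quote_label(tree$tip.label[node]), lab[node])
    } else {
      kids <- children[[as.character(node)]]
      paste0("(", paste(vapply(kids, render, ""), collapse = ","), ")", lab[node])
    }
    if (!is.na(elen[node])) piece <- paste0(piece, ":", fmt(elen[node]))
    piece
  }
  out <- paste0(render(nt + 1L), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

.quote_label <- function(x) {
  needs <- grepl("[](),:;[[:space:]'\\[]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Patristic distance matrix between all tips
#'
#' Sum of branch lengths along the tree path between every pair of tips,
#' computed without per-pair re-traversal.
#'
#' @param tree A `"phylo"` object with resolved branch lengths.
#' @return Symmetric numeric matrix with tip labels as dimnames and zero
#'   diagonal.
#' @examples
#' d <- patristic_matrix(read_phylogeny(text = "((A:1,B:1):1,C:2);"))
#' d["A", "C"]  # 4
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("branch lengths must be resolved before computing patristic distances")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A `"phylo"` object.
#' @param tips Character vector of tip labels (normalized before matching).
#' @return Node number (for a single tip, the tip's own number).
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  tips <- normalize_labels(tips)
  if (!length(tips)) stop("'tips' must be nonempty")
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("tip labels not in tree: ", paste(missing, collapse = ", "))
  idx <- match(unique(tips), tree$tip.label)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Descendant-tip incidence matrix
#'
#' One post-order pass over the edge matrix; row `v` is the logical
#' indicator over tips of "tip descends from node v" (a tip descends from
#' itself).
#'
#' @param tree A `"phylo"` object.
#' @return Logical matrix `(Ntip + Nnode) x Ntip`, columns named by tip.
#' @keywords internal
descendant_matrix <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  m <- matrix(FALSE, nt + nn, nt, dimnames = list(NULL, tree$tip.label))
  m[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge)))
    m[edge[i, 1L], ] <- m[edge[i, 1L], ] | m[edge[i, 2L], ]
  m
}

#' Tips descending from a node
#'
#' @param tree A `"phylo"` object.
#' @param node Node number (tip or internal).
#' @return Character vector of tip labels; for a tip node, the tip itself.
#' @export
descendant_tips <- function(tree, node) {
  stopifnot(inherits(tree, "phylo"))
  node <- as.integer(node)
  nt <- ape::Ntip(tree)
  if (node < 1L || node > nt + tree$Nnode) stop("node ", node, " not in tree")
  if (node <= nt) return(tree$tip.label[node])
  tree$tip.label[descendant_matrix(tree)[node, ]]
}

#' Report label for an internal node
#'
#' Names a node by the MRCA convention used for clade reports:
#' `"MRCA(x,y)"` where `x` and `y` are the first and last descendant tips
#' in the tree's stored tip order. Deterministic for a fixed input tree.
#'
#' @param tree A `"phylo"` object.
#' @param node Internal node number.
#' @param .desc Optional precomputed [descendant_matrix()] (avoids repeated
#'   traversals in per-node loops).
#' @return A string `"MRCA(first_tip,last_tip)"`.
#' @export
node_report_label <- function(tree, node, .desc = NULL) {
  stopifnot(inherits(tree, "phylo"))
  node <- as.integer(node)
  if (node <= ape::Ntip(tree))
    stop("node ", node, " is a tip; report labels are defined for internal nodes")
  if (is.null(.desc)) .desc <- descendant_matrix(tree)
  tips <- which(.desc[node, ])
  sprintf("MRCA(%s,%s)", tree$tip.label[tips[1L]], tree$tip.label[tips[length(tips)]])
}
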