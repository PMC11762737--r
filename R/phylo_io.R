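# Tree input/output and phylogenetic covariance structures.
#
# Trees are plain "phylo" objects (ape); this module adds strict validation
# on top of ape's permissive reader, the Brownian-motion variance-covariance
# matrix, the Pagel lambda rescaling of its off-diagonals, and pruning.

#' Parse a Newick string into a validated phylogeny
#'
#' Wraps [ape::read.tree()] with strict validation: the tree must have at
#' least two uniquely labelled tips and a branch length on every edge.
#' Square-bracket comments are stripped before parsing and quoted labels are
#' accepted; internal node labels, if present, are preserved.
#'
#' @param text A Newick string (trailing semicolon required).
#' @return An object of class `"phylo"`.
#' @seealso [write_newick()], [vcv_matrix()]
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE)) {
    stop("Newick parse error: no terminating semicolon in input", call. = FALSE)
  }
  # strip [...] comments (BEAST/TreeAnnotator annotations); non-greedy
  text <- gsub("\\[[^][]*\\]", "", text)
  tr <- withCallingHandlers(
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("Newick parse error: ", conditionMessage(e),
                                      call. = FALSE)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("Newick parse error: input did not yield a tree", call. = FALSE)
  }
  validate_phylogeny(tr)
  tr
}

#' Read a Newick tree from a file
#'
#' @param path Path to a file containing a single Newick tree.
#' @return An object of class `"phylo"`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Serialize a phylogeny to Newick
#'
#' Round-trips with [parse_newick()]: `parse_newick(write_newick(tr))`
#' preserves topology, labels and branch lengths at stored precision.
#'
#' @param tree A `"phylo"` object.
#' @param path Optional file path; when given the string is also written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_phylogeny(tree)
  s <- ape::write.tree(tree, digits = 15)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

# Internal validation shared by parse/write and downstream consumers.
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("branch lengths missing on one or more edges", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  invisible(tree)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Entry (i, j) is the summed branch length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip distances.
#' Rows and columns are ordered and named by `tree$tip.label`.
#'
#' @param tree A `"phylo"` object.
#' @return A symmetric positive semi-definite numeric matrix with tip labels
#'   as dimnames.
#' @examples
#' vcv_matrix(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
vcv_matrix <- function(tree) {
  validate_phylogeny(tree)
  C <- ape::vcv.phylo(tree)
  # a root edge (e.g. left by pruning) is history shared by every tip
  if (!is.null(tree$root.edge)) C <- C + tree$root.edge
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Pagel lambda rescaling of a phylogenetic covariance matrix
#'
#' Multiplies off-diagonal entries by `lambda` while leaving the diagonal
#' (tip depths) untouched: `lambda = 1` is full Brownian dependence,
#' `lambda = 0` phylogenetic independence.
#'
#' @param C A phylogenetic covariance matrix (see [vcv_matrix()]).
#' @param lambda A scalar in `[0, 1]`.
#' @return The rescaled matrix.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a scalar in [0, 1]", call. = FALSE)
  }
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

#' Prune a phylogeny to a subset of taxa
#'
#' Returns the induced subtree on `keep`; path lengths between retained tips
#' are preserved (degree-two nodes created by pruning are suppressed and
#' their branch lengths summed).
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return A `"phylo"` object on `keep`.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2L) stop("need at least 2 taxa to keep", call. = FALSE)
  drop <- setdiff(tree$tip.label, keep)
  if (!length(drop)) return(tree)
  sub <- ape::keep.tip(tree, keep)
  # record the depth from the original root down to the new MRCA as a root
  # edge, so that vcv(prune(tree, S)) equals the S-submatrix of vcv(tree)
  d_full <- ape::node.depth.edgelength(tree)[match(keep[1], tree$tip.label)]
  d_sub <- ape::node.depth.edgelength(sub)[match(keep[1], sub$tip.label)]
  lost <- d_full - d_sub
  if (!is.null(tree$root.edge)) lost <- lost + tree$root.edge
  if (lost > 1e-12) sub$root.edge <- lost
  sub
}

#' Write a covariance matrix as CSV with a taxa header
#'
#' @param C Matrix from [vcv_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcv_csv <- function(C, path) {
  df <- data.frame(taxon = rownames(C), C, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Canonical taxon-name normalization used for all CSV/Newick joins:
# trim whitespace, spaces -> underscores.
normalize_taxon <- function(x) {
  gsub(" ", "_", trimws(as.character(x)), fixed = TRUE)
}

# TRUE when all root-to-tip distances agree within tol (relative).
is_ultrametric_tree <- function(tree, tol = 1e-8) {
  isTRUE(ape::is.ultrametric(tree, tol = tol))
}
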