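#' Read a phylogeny from Newick text or file
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree must be rooted
#' (a trifurcating root is accepted and treated as the root), carry branch
#' lengths on every edge, and have unique tip labels. Tip labels are
#' normalised with [normalize_taxa()] so that joins against trait tables are
#' deterministic.
#'
#' @param x A Newick string, or the path to a file containing one.
#' @return An object of class `phylo`.
#' @examples
#' tr <- read_tree("((A:1,B:1):1,C:2):0;")
#' ape::Ntip(tr)
#' @export
read_tree <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "") else x
  if (!grepl(";", txt, fixed = TRUE)) {
    stop("not a valid Newick string (no terminating ';'): ",
         substr(txt, 1, 60), call. = FALSE)
  }
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick string (", n_open, " '(' vs ",
         n_close, "')')", call. = FALSE)
  }
  tr <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tr)) stop("Newick parse error: ape could not parse the string", call. = FALSE)
  validate_tree(tr)
}

#' Write a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_tree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

validate_tree <- function(tr) {
  tr$tip.label <- normalize_taxa(tr$tip.label)
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (anyNA(tr$edge.length)) {
    bad <- which(is.na(tr$edge.length))
    stop("missing branch length on edge(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(tr$edge.length < 0)) {
    bad <- which(tr$edge.length < 0)
    stop("negative branch length on edge(s) ", paste(bad, collapse = ", "),
         " (", paste(signif(tr$edge.length[bad], 4), collapse = ", "), ")",
         call. = FALSE)
  }
  tr
}

#' Normalise species names
#'
#' Trims surrounding whitespace, collapses internal whitespace and converts
#' spaces to underscores, so `"Viburnum  tinus "` and `"Viburnum_tinus"`
#' compare equal. Applied to tip labels on read and to species columns on
#' join.
#'
#' @param x Character vector of names.
#' @return Character vector of the same length.
#' @export
normalize_taxa <- function(x) {
  x <- gsub("^\\s+|\\s+$", "", x)
  gsub("\\s+", "_", x)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Returns the n-by-n matrix `C` whose entry (i, j) is the shared path length
#' from the root to the most recent common ancestor of tips i and j; the
#' diagonal holds root-to-tip depths. Under Brownian motion this is the
#' expected trait covariance structure (up to the evolutionary rate).
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A numeric matrix with tip labels as dimnames.
#' @examples
#' phylo_vcv(read_tree("((A:1,B:1):1,C:2):0;"))
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree must have branch lengths on all edges", call. = FALSE)
  }
  ape::vcv.phylo(tree)
}

#' Prune a phylogeny to a set of taxa
#'
#' Drops all tips not in `keep`, suppressing the resulting degree-2 nodes so
#' that path lengths between the retained tips are unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return A `phylo` object with exactly the `keep` tips.
#' @export
prune_to_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- normalize_taxa(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2) stop("need at least 2 taxa to keep", call. = FALSE)
  ape::keep.tip(tree, keep)
}

# Invert a phylogenetic covariance matrix, lifting zero-length terminal
# branches with a small diagonal floor so GLS stays well-posed.
solve_vcv <- function(C, floor = 1e-8) {
  d <- diag(C)
  if (any(d <= 0) || kappa(C) > 1e12) C <- C + diag(floor * max(d, 1), nrow(C))
  out <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(out)) {
    C <- C + diag(floor * max(diag(C), 1), nrow(C))
    out <- tryCatch(solve(C), error = function(e)
      stop("phylogenetic covariance matrix is singular; ",
           "consider a larger branch-length floor", call. = FALSE))
  }
  out
}
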