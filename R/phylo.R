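#' Read a genus-level tree from Newick text
#'
#' Parses a Newick string or file into an `ape` `phylo` object. Any branch
#' lengths present are discarded: the analysis assigns Grafen branch lengths
#' itself, so only the topology is used. Polytomies are retained.
#'
#' @param newick Newick text (containing `"("`) or a path to a Newick file.
#' @return A rooted `phylo` object with unique tip labels and no branch
#'   lengths.
#' @export
read_tree <- function(newick) {
  tree <- if (grepl("(", newick, fixed = TRUE)) {
    ape::read.tree(text = newick)
  } else {
    ape::read.tree(file = newick)
  }
  if (is.null(tree)) stop("malformed Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree$edge.length <- NULL
  tree
}

#' Assign Grafen branch lengths
#'
#' Sets node heights to ((number of descendant tips - 1) /
#' (total tips - 1))^rho, giving tips height 0 and the root height 1; each
#' branch length is the height difference between parent and child. Every
#' root-to-tip path then has total length 1, so the resulting phylogenetic
#' covariance matrix has unit diagonal.
#'
#' @param tree A rooted `phylo` object (>= 2 tips).
#' @param rho Power applied to the relative node heights (default 1).
#' @return The tree with Grafen branch lengths assigned.
#' @export
grafen_lengths <- function(tree, rho = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2)
    stop("Grafen branch lengths require at least 2 tips")
  stopifnot(is.numeric(rho), rho > 0)
  ape::compute.brlen(tree, method = "Grafen", power = rho)
}

#' Phylogenetic variance-covariance matrix
#'
#' Builds the tip-by-tip covariance matrix whose entries are the shared
#' root-to-tip path lengths (the Brownian-motion expectation). After Grafen
#' scaling the diagonal is 1.
#'
#' @param tree A `phylo` object with branch lengths assigned.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("branch lengths must be assigned first (see grafen_lengths)")
  V <- ape::vcv(tree)
  V[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of V by lambda, leaving the diagonal
#' unchanged: lambda = 0 removes all phylogenetic covariance, lambda = 1
#' leaves the Brownian expectation intact. Positive semi-definiteness is
#' preserved for lambda in [0, 1].
#'
#' @param V Phylogenetic covariance matrix.
#' @param lambda Signal strength in [0, 1].
#' @return The transformed covariance matrix.
#' @export
lambda_transform <- function(V, lambda) {
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  if (!is.numeric(lambda) || length(lambda) != 1 ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  W <- lambda * V
  diag(W) <- diag(V)
  W
}

#' Intersect a genus table with the tips of a tree
#'
#' The trait table and the tree rarely cover identical genus sets; both are
#' restricted to the shared genera, with a message reporting what was
#' dropped on each side.
#'
#' @param genus_table A genus-mean table (one row per genus).
#' @param tree A `phylo` object with genus tip labels.
#' @return A list with the pruned `genus_table` (ordered as the tree tips)
#'   and `tree`.
#' @export
match_tree_table <- function(genus_table, tree) {
  shared <- intersect(tree$tip.label, genus_table$genus)
  if (length(shared) < 2) stop("fewer than 2 genera shared by tree and table")
  drop_tree <- setdiff(tree$tip.label, shared)
  drop_tab <- setdiff(genus_table$genus, shared)
  if (length(drop_tree) || length(drop_tab))
    message(length(drop_tree), " tip(s) and ", length(drop_tab),
            " table genus/genera dropped in tree-table intersection")
  if (length(drop_tree)) tree <- ape::drop.tip(tree, drop_tree)
  genus_table <- genus_table[match(tree$tip.label, genus_table$genus), ,
                             drop = FALSE]
  rownames(genus_table) <- NULL
  list(genus_table = genus_table, tree = tree)
}
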