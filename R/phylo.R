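#' Parse a Newick string into a phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]. Trees are expected to
#' be rooted, with branch lengths in time units (Myr); fossil tips simply end
#' before the present, so trees need not be ultrametric.
#'
#' @param text a Newick string (single tree, trailing semicolon).
#' @return an object of class `"phylo"`.
#' @details Errors on missing branch lengths and duplicated tip labels.
#'   Zero-length terminal branches are permitted but trigger a warning,
#'   because they make a tip's trait value deterministic given its parent.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick string: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick string", call. = FALSE)
  validate_phylogeny(tree)
}

#' Read a phylogeny from a Newick file
#'
#' @param file path to a Newick file containing a single tree.
#' @return an object of class `"phylo"`.
#' @export
read_phylogeny <- function(file) {
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""))
}

validate_phylogeny <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] == 0))
    warning("tree has zero-length terminal branches", call. = FALSE)
  tree
}

#' Tip ages before present
#'
#' Ages are measured backwards from the present, taken to be the maximum
#' root-to-tip path length; extant tips have age 0, fossil tips age > 0.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @return named numeric vector of tip ages (Myr).
#' @export
tip_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  ages <- max(depth[seq_len(ntip)]) - depth[seq_len(ntip)]
  names(ages) <- tree$tip.label
  ages
}

#' Prune a phylogeny to a set of taxa
#'
#' Degree-two internal nodes created by the pruning are suppressed with their
#' branch lengths summed, so patristic distances among the kept tips are
#' unchanged.
#'
#' @param tree a `"phylo"` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `"phylo"` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown tip labels: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(keep) < 2)
    stop("at least 2 tips must be kept", call. = FALSE)
  if (length(keep) == length(tree$tip.label)) return(tree)
  out <- ape::keep.tip(tree, keep)
  # when the kept taxa do not span the original root, record the basal path
  # to the new root as a root edge so depths from the original root (and
  # hence shared-path covariances) are preserved
  mrca <- ape::getMRCA(tree, keep)
  offset <- ape::node.depth.edgelength(tree)[mrca] +
    (if (is.null(tree$root.edge)) 0 else tree$root.edge)
  if (offset > 0) out$root.edge <- offset
  out
}

#' Graft a tip (e.g. a fossil) onto a dated phylogeny
#'
#' Attaches a new terminal branch at an explicit time point along an existing
#' edge, the standard way taxa of known affinity but unsampled in the tree
#' are added a posteriori. Attachment ages are never guessed: the caller must
#' supply both the age of the attachment point and the age of the new tip.
#'
#' @param tree a `"phylo"` object with branch lengths in time units.
#' @param new_label label of the grafted tip.
#' @param attach_edge label of the tip, or number of the internal node, at
#'   the *child* end of the edge to attach to.
#' @param attach_age age (time before present) of the attachment point; must
#'   lie within the age span of the chosen edge.
#' @param tip_age age of the new tip (0 for extant, > 0 for fossils); the new
#'   branch length is `attach_age - tip_age` and must be non-negative.
#' @return a `"phylo"` object with one extra tip. Patristic distances among
#'   pre-existing tips are unchanged.
#' @export
graft_tip <- function(tree, new_label, attach_edge, attach_age, tip_age = 0) {
  stopifnot(length(new_label) == 1L, length(attach_age) == 1L,
            length(tip_age) == 1L)
  if (new_label %in% tree$tip.label)
    stop("tip label already present: ", new_label, call. = FALSE)
  if (tip_age < 0) stop("tip_age must be >= 0", call. = FALSE)
  ntip <- length(tree$tip.label)
  if (is.character(attach_edge)) {
    node <- match(attach_edge, tree$tip.label)
    if (is.na(node)) stop("unknown attachment tip: ", attach_edge, call. = FALSE)
  } else {
    node <- as.integer(attach_edge)
    if (node < 1 || node > ntip + tree$Nnode)
      stop("attachment node out of range", call. = FALSE)
  }
  depth <- ape::node.depth.edgelength(tree)
  present <- max(depth[seq_len(ntip)])
  age <- present - depth
  edge_row <- which(tree$edge[, 2] == node)
  if (!length(edge_row)) stop("cannot attach to the root edge", call. = FALSE)
  parent <- tree$edge[edge_row, 1]
  if (attach_age < age[node] - 1e-9 || attach_age > age[parent] + 1e-9)
    stop(sprintf("attach_age %.4g outside the edge age span [%.4g, %.4g]",
                 attach_age, age[node], age[parent]), call. = FALSE)
  new_len <- attach_age - tip_age
  if (new_len < 0)
    stop("tip_age exceeds attach_age: implied negative branch length",
         call. = FALSE)
  position <- attach_age - age[node]  # distance rootward of the child node
  out <- phytools::bind.tip(tree, tip.label = new_label,
                            edge.length = new_len, where = node,
                            position = position)
  validate_phylogeny(out)
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry `C[i, j]` is the depth (shared path length from the root) of the
#' most recent common ancestor of tips `i` and `j`; the diagonal holds
#' root-to-tip path lengths, which differ among tips when fossils are
#' present. The result carries class `"phylo_cov"` with a `lambda` attribute
#' recording any Pagel's-lambda transformation applied.
#'
#' @param tree a `"phylo"` object with at least 2 tips.
#' @param order optional character vector giving the taxon order of the rows.
#' @return a symmetric positive semi-definite matrix of class `"phylo_cov"`.
#' @seealso [lambda_transform()]
#' @export
vcv_matrix <- function(tree, order = NULL) {
  if (length(tree$tip.label) < 2) stop("tree must have >= 2 tips", call. = FALSE)
  C <- ape::vcv(tree)
  # a retained root edge is ancestral path shared by every tip
  if (isTRUE(tree$root.edge > 0))
    C <- C + tree$root.edge
  if (!is.null(order)) {
    unknown <- setdiff(order, rownames(C))
    if (length(unknown))
      stop("unknown taxa in order: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    C <- C[order, order, drop = FALSE]
  }
  new_phylo_cov(C, lambda = "raw")
}

new_phylo_cov <- function(C, lambda) {
  structure(C, class = c("phylo_cov", "matrix", "array"), lambda = lambda)
}

#' Pagel's lambda transformation of a phylogenetic covariance
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 1` returns the Brownian-motion covariance intact,
#' `lambda = 0` an independence (diagonal) structure.
#'
#' @param C a `"phylo_cov"` (or plain square symmetric) matrix.
#' @param lambda value in `[0, 1]`.
#' @return the transformed matrix, class `"phylo_cov"`, with its `lambda`
#'   attribute set.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  d <- diag(C)
  out <- unclass(C) * lambda
  diag(out) <- d
  new_phylo_cov(out, lambda = lambda)
}

#' Write a covariance matrix with its taxon order
#'
#' Serialises a `"phylo_cov"` matrix as TSV with the taxon order as the
#' header row (and first column).
#'
#' @param C a `"phylo_cov"` matrix.
#' @param file output path.
#' @export
write_phylo_cov <- function(C, file) {
  df <- data.frame(taxon = rownames(C), unclass(C), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
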