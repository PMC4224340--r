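# Rooted-tree handling on top of ape's "phylo" structure. Node ids are ape's
# integer numbering (tips 1..Ntip, internals Ntip+1..); node_label() gives a
# stable display name for every node (tip label, internal label, or "node_i").

#' Read a rooted tree from newick text
#'
#' Parses a newick string with [ape::read.tree()], validating that the result
#' is a single rooted tree with unique tip names. Internal node labels and
#' branch lengths are preserved; polytomies are accepted.
#'
#' @param text A newick string (must end with `;`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("newick parse error: empty input", call. = FALSE)
  open_n <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  close_n <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (open_n != close_n) {
    stop("newick parse error: unbalanced parentheses (", open_n, " '(' vs ",
         close_n, "')') near character ",
         regexpr("[()]", text), call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e)
                     stop("newick parse error: ", conditionMessage(e),
                          call. = FALSE))
  if (is.null(tree))
    stop("newick parse error: input could not be parsed", call. = FALSE)
  if (inherits(tree, "multiPhylo"))
    stop("newick parse error: expected exactly one tree", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip name error: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("newick error: negative branch length", call. = FALSE)
  tree
}

#' Write a tree as newick text
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A newick string. Reading it back yields a tree isomorphic to the
#'   input (same tips, same clusters).
#' @export
write_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip names (nonempty). A single tip is its
#'   own MRCA.
#' @return Integer node id (ape numbering).
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"), length(tips) >= 1L)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx))
    stop("unknown tip name: ", paste(tips[is.na(idx)], collapse = ", "),
         call. = FALSE)
  if (length(unique(idx)) == 1L) return(unique(idx))
  ape::getMRCA(tree, unique(idx))
}

root_node <- function(tree) length(tree$tip.label) + 1L

# children of a node in input (edge matrix) order
node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1L] == node, 2L]
}

node_parent <- function(tree, node) {
  hit <- tree$edge[, 2L] == node
  if (!any(hit)) return(NA_integer_)
  tree$edge[hit, 1L]
}

#' Display labels for every node of a tree
#'
#' Tips keep their tip labels; internal nodes use their newick labels where
#' present, otherwise `"node_<id>"`.
#'
#' @param tree A `phylo` object.
#' @return Character vector indexed by node id.
#' @export
node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  lab <- c(tree$tip.label, paste0("node_", ntip + seq_len(nnode)))
  if (!is.null(tree$node.label)) {
    has <- nzchar(tree$node.label) & !is.na(tree$node.label)
    lab[ntip + which(has)] <- tree$node.label[has]
  }
  lab
}

# node ids in postorder (children before parents) and preorder
traverse_postorder <- function(tree) {
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  unique(c(edge[, 2L], root_node(tree)))
}

traverse_preorder <- function(tree) {
  rev_post <- rev(traverse_postorder(tree))
  rev_post
}

# branch length of the edge above `node`, NA if absent
branch_length_above <- function(tree, node) {
  if (is.null(tree$edge.length)) return(NA_real_)
  hit <- which(tree$edge[, 2L] == node)
  if (!length(hit)) return(NA_real_)
  tree$edge.length[[hit]]
}
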