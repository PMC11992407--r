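#' Cell-type trees
#'
#' A `cell_type_tree` is a rooted tree whose leaves are the cell types (or
#' cell states) of a simulated dataset. Branch weights are nonnegative
#' divergences: the larger the weight, the larger the variance of the
#' log-fold expression effects accumulated along that branch, hence the more
#' distinct the populations below it. Leaf `cell_fractions` give the
#' proportion of simulated cells per leaf and must sum to 1.
#'
#' @param edges a data frame with columns `parent`, `child`,
#'   `branch_weight` (nonnegative numeric).
#' @param cell_fractions named numeric vector, one entry per leaf, summing
#'   to 1. Defaults to uniform over the leaves.
#' @return an object of class `cell_type_tree` with elements `edges`
#'   (tibble), `root`, `leaves`, and `cell_fractions`.
#' @export
#' @examples
#' cell_type_tree(data.frame(
#'   parent = "root", child = c("A", "B"), branch_weight = 2
#' ))
cell_type_tree <- function(edges, cell_fractions = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("parent", "child", "branch_weight") %in% names(edges)))
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (any(edges$branch_weight < 0)) abort("branch weights must be >= 0")
  if (anyDuplicated(edges$child)) abort("each node may have only one parent")

  nodes <- union(edges$parent, edges$child)
  root <- setdiff(edges$parent, edges$child)
  if (length(root) != 1L) {
    abort(sprintf("tree must have exactly one root, found %d", length(root)))
  }
  leaves <- setdiff(edges$child, edges$parent)
  if (length(leaves) == 0L) abort("tree has no leaves")

  # reachability from root
  reached <- root
  repeat {
    nxt <- edges$child[edges$parent %in% reached & !(edges$child %in% reached)]
    if (length(nxt) == 0L) break
    reached <- c(reached, nxt)
  }
  if (!all(nodes %in% reached)) abort("not all nodes are reachable from the root")

  if (is.null(cell_fractions)) {
    cell_fractions <- stats::setNames(rep(1 / length(leaves), length(leaves)), leaves)
  }
  if (!setequal(names(cell_fractions), leaves)) {
    abort("cell_fractions must be named by the tree's leaves")
  }
  cell_fractions <- cell_fractions[leaves]
  if (abs(sum(cell_fractions) - 1) > 1e-9) {
    abort("cell_fractions must sum to 1 (tolerance 1e-9)")
  }

  structure(
    list(edges = edges, root = root, leaves = leaves,
         cell_fractions = cell_fractions),
    class = "cell_type_tree"
  )
}

#' @export
print.cell_type_tree <- function(x, ...) {
  cat(sprintf("<cell_type_tree> %d leaves, root '%s'\n",
              length(x$leaves), x$root))
  cat("leaves:", paste(x$leaves, collapse = ", "), "\n")
  invisible(x)
}

tree_parent <- function(tree, node) {
  p <- tree$edges$parent[tree$edges$child == node]
  if (length(p) == 0L) NULL else p
}

# root -> leaf path as an edge index vector
tree_path_edges <- function(tree, leaf) {
  path <- integer(0)
  node <- leaf
  while (!identical(node, tree$root)) {
    i <- which(tree$edges$child == node)
    path <- c(i, path)
    node <- tree$edges$parent[i]
  }
  path
}

#' Preset cell-type tree designs
#'
#' Two study designs: `"separate3"` is a star tree with three well-separated
#' cell types (equal, large branch weights), and `"nested8"` is a two-level
#' tree with 8 leaves — 3 cell types containing (3, 3, 2) cell states —
#' where between-type branches are deep and within-type branches shallow, so
#' states are sub-populations of their type. Both presets use uniform cell
#' fractions. The exact topologies and weights are this package's
#' approximations of the nested/separate designs; they are overridable by
#' constructing a [cell_type_tree()] directly.
#'
#' @param design `"separate3"` or `"nested8"`.
#' @return a [cell_type_tree()].
#' @export
#' @examples
#' preset_tree("separate3")
#' preset_tree("nested8")
preset_tree <- function(design = c("separate3", "nested8")) {
  design <- tryCatch(match.arg(design), error = function(e) {
    abort("unknown design; valid designs are \"separate3\" and \"nested8\"")
  })
  if (design == "separate3") {
    cell_type_tree(tibble::tibble(
      parent = "root",
      child = c("type1", "type2", "type3"),
      branch_weight = 4
    ))
  } else {
    types <- c("typeA", "typeB", "typeC")
    states <- list(paste0("A", 1:3), paste0("B", 1:3), paste0("C", 1:2))
    edges <- dplyr::bind_rows(
      tibble::tibble(parent = "root", child = types, branch_weight = 4),
      purrr::map2_dfr(types, states, function(ty, st) {
        tibble::tibble(parent = ty, child = st, branch_weight = 0.05)
      })
    )
    cell_type_tree(edges)
  }
}

#' Serialize a cell-type tree to Newick
#'
#' Branch weights are written as Newick branch lengths. Cell fractions are
#' not representable in Newick; supply them separately when reading back.
#'
#' @param tree a [cell_type_tree()].
#' @param path optional file to write to; if `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_tree_newick <- function(tree, path = NULL) {
  render <- function(node) {
    kids <- tree$edges[tree$edges$parent == node, ]
    if (nrow(kids) == 0L) return(node)
    inner <- vapply(seq_len(nrow(kids)), function(i) {
      sprintf("%s:%g", render(kids$child[i]), kids$branch_weight[i])
    }, "")
    sprintf("(%s)%s", paste(inner, collapse = ","), node)
  }
  nwk <- paste0(render(tree$root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Read a cell-type tree from a Newick file
#'
#' @param path Newick file with branch lengths (as written by
#'   [write_tree_newick()]); parsed with \pkg{ape}.
#' @param cell_fractions optional named fractions per leaf; default uniform.
#' @return a [cell_type_tree()].
#' @export
read_tree_newick <- function(path, cell_fractions = NULL) {
  phy <- ape::read.tree(path)
  if (is.null(phy$edge.length)) abort("Newick file has no branch lengths")
  n_tip <- length(phy$tip.label)
  node_name <- function(id) {
    if (id <= n_tip) phy$tip.label[id]
    else if (!is.null(phy$node.label) && nzchar(phy$node.label[id - n_tip])) {
      phy$node.label[id - n_tip]
    } else paste0("node", id)
  }
  edges <- tibble::tibble(
    parent = vapply(phy$edge[, 1], node_name, ""),
    child = vapply(phy$edge[, 2], node_name, ""),
    branch_weight = phy$edge.length
  )
  cell_type_tree(edges, cell_fractions)
}
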