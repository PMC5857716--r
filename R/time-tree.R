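#' Construct a time tree
#'
#' A `time_tree` couples a rooted binary topology (an [ape::read.tree()]
#' `phylo` object) with absolute node ages in Ma (tips at 0) and,
#' optionally, per-node substitution rates in substitutions/site/Ma. Node
#' ages are indexed by the `phylo` node numbering (tips `1..n`, root
#' `n + 1`). Every internal node carries a unique label, used to attach
#' fossil calibrations; unlabelled nodes are assigned labels `nd<k>`.
#'
#' @param phylo A rooted, binary `phylo` object.
#' @param ages_ma Numeric vector of node ages, length `2n - 1`.
#' @param rates Optional numeric vector of per-node rates, same length.
#' @return A `time_tree` object.
#' @export
time_tree <- function(phylo, ages_ma, rates = NULL) {
  if (!inherits(phylo, "phylo")) abort("phylo must be an ape 'phylo' object")
  if (!ape::is.rooted(phylo)) abort("topology must be rooted")
  if (!ape::is.binary(phylo)) abort("topology must be binary")
  n <- length(phylo$tip.label)
  m <- 2L * n - 1L
  if (length(ages_ma) != m) {
    abort(paste0("ages_ma must have length ", m, " (one per node)"))
  }
  if (any(abs(ages_ma[seq_len(n)]) > 1e-8)) {
    abort("leaf ages must be 0 (extant sampling)")
  }
  ages_ma[seq_len(n)] <- 0
  parent <- parent_vector(phylo)
  kids <- which(parent > 0)
  if (any(ages_ma[parent[kids]] <= ages_ma[kids])) {
    abort("every parent must be strictly older than its children")
  }
  if (ages_ma[n + 1L] <= 0) abort("root age must be positive")
  if (!is.null(rates)) {
    if (length(rates) != m) abort("rates must have one value per node")
    if (any(!is.finite(rates)) || any(rates <= 0)) {
      abort("rates must be positive")
    }
  }
  if (is.null(phylo$node.label) || any(phylo$node.label == "") ||
      anyNA(phylo$node.label)) {
    lab <- phylo$node.label %||% rep("", n - 1L)
    lab[is.na(lab) | lab == ""] <-
      paste0("nd", which(is.na(lab) | lab == ""))
    phylo$node.label <- lab
  }
  if (anyDuplicated(c(phylo$tip.label, phylo$node.label))) {
    abort("node labels must be unique")
  }
  structure(
    list(phylo = phylo, ages_ma = unname(ages_ma),
         rates = if (is.null(rates)) NULL else unname(rates)),
    class = "time_tree"
  )
}

# Parent node id per node (0 for the root), in phylo numbering.
parent_vector <- function(phylo) {
  n <- length(phylo$tip.label)
  parent <- integer(2L * n - 1L)
  parent[phylo$edge[, 2]] <- phylo$edge[, 1]
  parent
}

# Children list per node id (empty for tips).
children_list <- function(phylo) {
  m <- 2L * length(phylo$tip.label) - 1L
  kids <- vector("list", m)
  for (i in seq_len(m)) kids[[i]] <- integer(0)
  for (e in seq_len(nrow(phylo$edge))) {
    p <- phylo$edge[e, 1]
    kids[[p]] <- c(kids[[p]], phylo$edge[e, 2])
  }
  kids
}

# Internal nodes ordered children-before-parents.
postorder_internal <- function(phylo) {
  po <- ape::reorder.phylo(phylo, "postorder")
  unique(po$edge[, 1])
}

#' @export
print.time_tree <- function(x, ...) {
  n <- length(x$phylo$tip.label)
  cat(sprintf(
    "time_tree: %d tips, root age %.4g Ma%s\n", n,
    x$ages_ma[n + 1L],
    if (is.null(x$rates)) "" else ", with branch rates"
  ))
  invisible(x)
}

#' Node labels of a time tree
#'
#' @param tree A `time_tree`.
#' @return Character vector of labels indexed by node id.
#' @export
node_labels <- function(tree) {
  c(tree$phylo$tip.label, tree$phylo$node.label)
}

#' @export
tidy.time_tree <- function(x, ...) {
  n <- length(x$phylo$tip.label)
  m <- 2L * n - 1L
  parent <- parent_vector(x$phylo)
  lab <- node_labels(x)
  tibble::tibble(
    node_id = seq_len(m),
    label = lab,
    is_tip = seq_len(m) <= n,
    parent_label = ifelse(parent > 0, lab[pmax(parent, 1)], NA_character_),
    age_ma = x$ages_ma,
    rate = if (is.null(x$rates)) NA_real_ else x$rates
  )
}

#' Convert between chronogram Newick and time trees
#'
#' `as_time_tree()` interprets a `phylo` whose edge lengths are in Ma
#' (an ultrametric chronogram) as a `time_tree`; `time_tree_newick()`
#' renders a `time_tree` back to a Newick string with Ma branch lengths
#' and internal node labels. `read_time_tree()`/`write_time_tree()` do the
#' same through files.
#'
#' @param phylo A `phylo` with edge lengths in Ma.
#' @param tol Tolerance (Ma) for the ultrametricity check.
#' @return A `time_tree`, a Newick string, or a file path.
#' @export
as_time_tree <- function(phylo, tol = 1e-6) {
  if (is.null(phylo$edge.length)) {
    abort("chronogram must carry branch lengths in Ma")
  }
  depth <- ape::node.depth.edgelength(phylo)
  n <- length(phylo$tip.label)
  height <- max(depth[seq_len(n)])
  if (max(abs(depth[seq_len(n)] - height)) > tol) {
    abort("tree is not ultrametric: tip depths differ")
  }
  ages <- height - depth
  ages[seq_len(n)] <- 0
  time_tree(phylo, ages)
}

#' @rdname as_time_tree
#' @param tree A `time_tree`.
#' @export
time_tree_newick <- function(tree) {
  phy <- tree$phylo
  phy$edge.length <- tree$ages_ma[phy$edge[, 1]] - tree$ages_ma[phy$edge[, 2]]
  ape::write.tree(phy)
}

#' @rdname as_time_tree
#' @param path File path.
#' @export
write_time_tree <- function(tree, path) {
  writeLines(time_tree_newick(tree), path)
  invisible(path)
}

#' @rdname as_time_tree
#' @export
read_time_tree <- function(path) {
  as_time_tree(ape::read.tree(path))
}
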