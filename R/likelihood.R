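# Alignment encoding and the pruning-likelihood API.

# Encode an alignment tibble as an integer pattern matrix ordered to match
# the tree's tips. Gaps, 'X' and any non-standard letter are missing data
# (state 0: an all-ones conditional vector in the pruning recursion).
# Identical site patterns are collapsed with weights; the likelihood is
# invariant to this compression.
encode_alignment <- function(alignment, tip_labels) {
  alignment <- as_alignment(alignment)
  missing <- setdiff(tip_labels, alignment$label)
  if (length(missing) > 0) {
    abort(paste0("alignment lacks sequences for tips: ",
                 paste(missing, collapse = ", ")))
  }
  seqs <- setNames(alignment$sequence, alignment$label)[tip_labels]
  n_sites <- nchar(seqs[[1]])
  if (n_sites == 0) abort("alignment has no columns")
  chars <- vapply(seqs, function(s) strsplit(s, "")[[1]],
                  character(n_sites))
  chars <- matrix(chars, nrow = n_sites)  # sites x tips
  codes <- match(chars, aa_states())
  codes[is.na(codes)] <- 0L
  codes <- matrix(as.integer(codes), nrow = n_sites)
  key <- apply(codes, 1, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.numeric(table(factor(key, levels = key[first])))
  list(states = codes[first, , drop = FALSE], weights = weights)
}

# Shared C++-facing topology encoding (0-based ids).
pruner_topology <- function(phylo) {
  kids <- children_list(phylo)
  list(
    children = lapply(kids, function(k) as.integer(k - 1L)),
    ntip = length(phylo$tip.label),
    postorder = as.integer(postorder_internal(phylo) - 1L)
  )
}

#' Phylogenetic log-likelihood under the Poisson + gamma model
#'
#' Computes the Felsenstein pruning log-likelihood of an amino-acid
#' alignment on a dated, rated tree: each site's likelihood is averaged
#' over the equal-weight discrete-gamma categories, branch lengths in
#' expected substitutions/site come from [branch_length()], and gaps or
#' `'X'` are treated as missing data. Site patterns are compressed
#' internally; this does not change the value. Sites that are impossible
#' under a zero-length tree yield `-Inf`.
#'
#' @param alignment A tibble with `label`/`sequence` columns (or named
#'   character vector); labels must cover the tree's tips.
#' @param tree A [time_tree()] carrying ages and rates.
#' @param model A [poisson_gamma_model()].
#' @return The log-likelihood (a scalar; possibly `-Inf`).
#' @export
clock_log_likelihood <- function(alignment, tree,
                                 model = poisson_gamma_model()) {
  if (is.null(tree$rates)) {
    abort("tree must carry branch rates (see simulate_rates())")
  }
  enc <- encode_alignment(alignment, tree$phylo$tip.label)
  topo <- pruner_topology(tree$phylo)
  elen <- edge_lengths(tree$phylo, tree$ages_ma, tree$rates)
  cat_rates <- gamma_category_rates(model$alpha, model$n_categories)
  poisson_pruning_loglik(enc$states, enc$weights, topo$children, topo$ntip,
                         topo$postorder, elen, cat_rates)
}
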