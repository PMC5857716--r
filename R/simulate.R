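# Forward simulators: Yule chronograms, autocorrelated branch rates, and
# amino-acid alignments under the Poisson + gamma model. Every simulator
# is bit-reproducible given `seed` and leaves the caller's RNG state
# untouched.

#' Simulate a Yule chronogram
#'
#' Draws a pure-birth tree conditioned on the number of tips and rescales
#' node ages so the root sits exactly at `root_age_ma` with all leaves at
#' 0.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param root_age_ma Root age in Ma.
#' @param birth_rate Yule speciation rate (only the relative node spacing
#'   depends on it once the root is rescaled).
#' @param seed Integer seed.
#' @return A [time_tree()] (no rates).
#' @export
simulate_chronogram <- function(n_taxa, root_age_ma, birth_rate = 1,
                                seed = 1L) {
  if (n_taxa < 3) abort("n_taxa must be at least 3")
  if (root_age_ma <= 0) abort("root_age_ma must be positive")
  withr::local_seed(seed)
  phy <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  phy$node.label <- NULL
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth)
  ages <- (height - depth) / height * root_age_ma
  ages[seq_len(n_taxa)] <- 0
  time_tree(phy, ages)
}

#' Simulate autocorrelated branch rates on a chronogram
#'
#' The root receives `root_rate`; each child's log rate is drawn from
#' `Normal(log r_parent - sigma2 * dt / 2, sigma2 * dt)`, the
#' mean-preserving geometric Brownian process scored by
#' [log_prior_rates()]. `sigma2 = 0` collapses to a strict clock.
#'
#' @param tree A [time_tree()].
#' @param sigma2 Log-rate variance per Ma (>= 0).
#' @param root_rate Rate at the root, substitutions/site/Ma.
#' @param seed Integer seed.
#' @return The tree with a `rates` vector attached.
#' @export
simulate_rates <- function(tree, sigma2, root_rate, seed = 1L) {
  if (sigma2 < 0 || root_rate <= 0) {
    abort("sigma2 must be >= 0 and root_rate > 0")
  }
  withr::local_seed(seed)
  phy <- tree$phylo
  n <- length(phy$tip.label)
  m <- 2L * n - 1L
  parent <- parent_vector(phy)
  rates <- numeric(m)
  rates[n + 1L] <- root_rate
  # preorder: parents before children
  ord <- rev(ape::reorder.phylo(phy, "postorder")$edge[, 2])
  for (v in ord) {
    dt <- tree$ages_ma[parent[v]] - tree$ages_ma[v]
    rates[v] <- if (sigma2 == 0) rates[parent[v]] else
      exp(rnorm(1, base::log(rates[parent[v]]) - sigma2 * dt / 2,
                sqrt(sigma2 * dt)))
  }
  time_tree(phy, tree$ages_ma, rates)
}

#' Simulate an amino-acid alignment on a rated chronogram
#'
#' Root states are drawn from the uniform stationary distribution; each
#' site is assigned one of the equal-probability discrete-gamma categories
#' (fixed along the tree); states then propagate down each branch under
#' the closed-form Poisson kernel with the branch's expected length from
#' [branch_length()]. No indels are simulated.
#'
#' @param tree A [time_tree()] with rates.
#' @param n_sites Alignment length.
#' @param alpha Gamma shape of among-site rate variation; `Inf` disables
#'   heterogeneity.
#' @param n_categories Discrete categories.
#' @param seed Integer seed.
#' @return An alignment tibble (`label`, `sequence`) for the tips.
#' @export
simulate_alignment <- function(tree, n_sites, alpha = 1, n_categories = 4L,
                               seed = 1L) {
  if (is.null(tree$rates)) abort("tree must carry rates")
  if (n_sites < 1) abort("n_sites must be >= 1")
  withr::local_seed(seed)
  phy <- tree$phylo
  n <- length(phy$tip.label)
  m <- 2L * n - 1L
  parent <- parent_vector(phy)
  cat_rates <- if (is.infinite(alpha)) rep(1, n_categories) else
    gamma_category_rates(alpha, n_categories)
  site_cat <- sample.int(n_categories, n_sites, replace = TRUE)
  site_rate <- cat_rates[site_cat]

  states <- matrix(0L, m, n_sites)
  states[n + 1L, ] <- sample.int(20L, n_sites, replace = TRUE)
  elen <- edge_lengths(phy, tree$ages_ma, tree$rates, parent)
  ord <- rev(ape::reorder.phylo(phy, "postorder")$edge[, 2])
  for (v in ord) {
    d <- elen[v] * site_rate
    e <- exp(-(20 / 19) * d)
    p_same <- 1 / 20 + (19 / 20) * e
    par_state <- states[parent[v], ]
    stay <- runif(n_sites) < p_same
    new_state <- par_state
    n_sub <- sum(!stay)
    if (n_sub > 0) {
      # jump uniformly to one of the 19 other residues
      shift <- sample.int(19L, n_sub, replace = TRUE)
      new_state[!stay] <- 1L + (par_state[!stay] - 1L + shift) %% 20L
    }
    states[v, ] <- new_state
  }
  aa <- aa_states()
  tibble::tibble(
    label = phy$tip.label,
    sequence = vapply(seq_len(n), function(i) {
      paste(aa[states[i, ]], collapse = "")
    }, character(1))
  )
}

#' Build a complete gene-duplication test fixture
#'
#' Emulates the structure of the PsaA/PsaB problem: a rooted tree whose
#' oldest split after the root is a gene duplication joining two mirrored
#' paralogue subtrees (labels `A*` and `B*`) over the same species, with a
#' small outgroup clade attached at the root. Node ages, autocorrelated
#' rates and an alignment are simulated with known ground truth, and
#' fossil-style calibrations are synthesised as windows of +/- 15% around
#' the true ages of three nodes (both paralogue MRCAs and one shallow
#' within-paralogue node).
#'
#' @param n_clade_taxa Tips per paralogue subtree (>= 2).
#' @param n_outgroup Outgroup tips (>= 1).
#' @param root_age_ma True root age, Ma.
#' @param sigma2 Rate-autocorrelation variance per Ma.
#' @param root_rate Root rate, substitutions/site/Ma.
#' @param alpha Gamma shape for site-rate variation.
#' @param n_sites Alignment columns.
#' @param seed Integer seed.
#' @return A list of class `duplication_fixture` with elements
#'   `alignment`, `tree` (true ages and rates), `calibrations`, `truth`
#'   (tibble of true node ages plus `sigma2`, `alpha`,
#'   `duplication_label`).
#' @export
make_duplication_fixture <- function(n_clade_taxa = 3, n_outgroup = 2,
                                     root_age_ma = 3500, sigma2 = 1e-4,
                                     root_rate = 1.5e-4, alpha = 0.5,
                                     n_sites = 200, seed = 1L) {
  if (n_clade_taxa < 2) abort("n_clade_taxa must be >= 2")
  if (n_outgroup < 1) abort("n_outgroup must be >= 1")
  withr::local_seed(seed)

  ladder <- function(tips, node_prefix) {
    # caterpillar newick over `tips` with labelled internal nodes
    s <- tips[1]
    for (i in seq_along(tips)[-1]) {
      s <- sprintf("(%s,%s)%s%d", s, tips[i], node_prefix, i - 1)
    }
    s
  }
  a_tips <- paste0("A", seq_len(n_clade_taxa))
  b_tips <- paste0("B", seq_len(n_clade_taxa))
  o_tips <- paste0("out", seq_len(n_outgroup))
  a_nwk <- ladder(a_tips, "A_nd")
  b_nwk <- ladder(b_tips, "B_nd")
  o_nwk <- if (n_outgroup == 1) o_tips else ladder(o_tips, "out_nd")
  nwk <- sprintf("(%s,(%s,%s)duplication)root;", o_nwk, a_nwk, b_nwk)
  phy <- ape::read.tree(text = nwk)

  n <- length(phy$tip.label)
  m <- 2L * n - 1L
  lab <- c(phy$tip.label, phy$node.label)
  parent <- parent_vector(phy)
  kids <- children_list(phy)
  ages <- numeric(m)
  root_id <- n + 1L
  ages[root_id] <- root_age_ma
  # preorder: draw each internal age as a fraction of its parent's age
  ord <- rev(ape::reorder.phylo(phy, "postorder")$edge[, 2])
  for (v in ord) {
    if (v <= n) next
    frac <- if (lab[v] == "duplication") runif(1, 0.75, 0.95) else
      runif(1, 0.45, 0.85)
    ages[v] <- ages[parent[v]] * frac
  }
  tree <- time_tree(phy, ages)
  tree <- simulate_rates(tree, sigma2, root_rate,
                         seed = sample.int(.Machine$integer.max / 2, 1))
  alignment <- simulate_alignment(tree, n_sites, alpha = alpha,
                                  seed = sample.int(.Machine$integer.max / 2, 1))

  a_mrca <- paste0("A_nd", n_clade_taxa - 1)
  b_mrca <- paste0("B_nd", n_clade_taxa - 1)
  cal_nodes <- c(a_mrca, b_mrca,
                 if (n_clade_taxa > 2) "A_nd1")  # one shallow window
  lab_all <- node_labels(tree)
  true_age <- function(l) tree$ages_ma[match(l, lab_all)]
  cal_ages <- unname(vapply(cal_nodes, true_age, 1))
  calibrations <- tibble::tibble(
    node_label = cal_nodes,
    min_ma = 0.85 * cal_ages,
    max_ma = 1.15 * cal_ages
  )

  truth <- tidy(tree)
  structure(
    list(alignment = alignment, tree = tree, calibrations = calibrations,
         truth = list(ages = truth, sigma2 = sigma2, alpha = alpha,
                      root_rate = root_rate,
                      duplication_label = "duplication")),
    class = "duplication_fixture"
  )
}

#' Write a duplication fixture to disk
#'
#' Emits the ready-to-run dating inputs: aligned FASTA, labelled Newick
#' chronogram, calibration TSV, and a truth JSON with the simulated node
#' ages, rates and hyperparameters.
#'
#' @param fixture A [make_duplication_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    alignment = file.path(dir, "alignment.fasta"),
    tree = file.path(dir, "chronogram.nwk"),
    calibrations = file.path(dir, "calibrations.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_aligned_fasta(fixture$alignment, paths["alignment"])
  write_time_tree(fixture$tree, paths["tree"])
  write_calibrations(fixture$calibrations, paths["calibrations"])
  truth <- fixture$truth
  jsonlite::write_json(
    list(ages = truth$ages, sigma2 = truth$sigma2, alpha = truth$alpha,
         root_rate = truth$root_rate,
         duplication_label = truth$duplication_label),
    paths["truth"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
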