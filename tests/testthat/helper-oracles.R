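# Independent oracles used across the suite. These deliberately avoid the
# package's own likelihood path: transition matrices come from a matrix
# exponential of the generator, gamma categories from phangorn, and tree
# likelihoods from explicit enumeration of internal states.

# Generator of the 20-state equal-rate chain scaled to 1 expected
# substitution per unit length.
poisson_generator <- function() {
  Q <- matrix(1 / 19, 20, 20)
  diag(Q) <- -1
  Q
}

# Transition matrix via matrix exponential (oracle for transition_prob).
expm_transition <- function(d) {
  as.matrix(Matrix::expm(poisson_generator() * d))
}

# Brute-force pruning oracle: enumerate all internal-state assignments.
# Only feasible for <= 4 tips. `alignment` is a label/sequence tibble with
# no gaps; `tree` a time_tree with rates; gamma categories come from
# phangorn::discrete.gamma.
brute_force_loglik <- function(alignment, tree, alpha, n_cat = 4) {
  phy <- tree$phylo
  n <- length(phy$tip.label)
  stopifnot(n <= 4)
  m <- 2L * n - 1L
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  seqs <- setNames(alignment$sequence, alignment$label)[phy$tip.label]
  chars <- do.call(cbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  tipstates <- matrix(match(chars, aa), nrow = nrow(chars))  # sites x tips

  parent <- integer(m)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  dlen <- numeric(m)
  kid <- which(parent > 0)
  dlen[kid] <- (tree$ages_ma[parent[kid]] - tree$ages_ma[kid]) *
    (tree$rates[parent[kid]] + tree$rates[kid]) / 2

  cat_rates <- phangorn::discrete.gamma(alpha, n_cat)
  internal <- (n + 1L):m
  assign_grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))

  ll <- 0
  for (site in seq_len(nrow(tipstates))) {
    site_lik <- 0
    for (cr in cat_rates) {
      P <- lapply(seq_len(m), function(v) {
        if (parent[v] == 0) NULL else expm_transition(dlen[v] * cr)
      })
      lik <- rep(1 / 20, nrow(assign_grid))
      for (v in kid) {
        zp <- assign_grid[, match(parent[v], internal)]
        zc <- if (v <= n) rep(tipstates[site, v], nrow(assign_grid)) else
          assign_grid[, match(v, internal)]
        lik <- lik * P[[v]][cbind(zp, zc)]
      }
      site_lik <- site_lik + sum(lik) / n_cat
    }
    ll <- ll + log(site_lik)
  }
  ll
}

# Random gapless amino-acid alignment.
random_alignment <- function(labels, n_sites, seed) {
  withr::with_seed(seed, {
    aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    tibble::tibble(
      label = labels,
      sequence = vapply(labels, function(l) {
        paste(sample(aa, n_sites, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}

# A tiny fixed 3-taxon topology with labelled internal nodes.
three_taxon_tree <- function() {
  ape::read.tree(text = "((a,b)inner,c)root;")
}
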