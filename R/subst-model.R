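#' Poisson amino-acid substitution model with discrete-gamma rates
#'
#' The Poisson (equal-input) model: all 20 amino acids exchange at the same
#' rate and have equal stationary frequencies (1/20). Among-site rate
#' heterogeneity follows a discretised gamma distribution with shape
#' `alpha` and `n_categories` equal-probability categories (mean-of-category
#' representation), whose rates average to 1.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param n_categories Number of discrete rate categories.
#' @return A `subst_model` object.
#' @export
poisson_gamma_model <- function(alpha = 1, n_categories = 4L) {
  if (!is.numeric(alpha) || alpha <= 0) abort("alpha must be positive")
  if (n_categories < 1) abort("n_categories must be at least 1")
  structure(
    list(n_states = 20L, alpha = alpha, n_categories = as.integer(n_categories)),
    class = "subst_model"
  )
}

#' Mean rates of equal-probability discrete-gamma categories
#'
#' Splits a Gamma(`alpha`, `alpha`) distribution (mean 1) into `k`
#' equal-probability bins and returns the mean rate within each bin. The
#' category rates are normalised so their average is exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories.
#' @return Numeric vector of `k` increasing rates with mean 1.
#' @export
gamma_category_rates <- function(alpha, k = 4L) {
  if (alpha <= 0) abort("alpha must be positive")
  if (k == 1) return(1)
  breaks <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # E[X; a < X < b] for X ~ Gamma(alpha, alpha) via the shape+1 identity
  mass <- pgamma(breaks, shape = alpha + 1, rate = alpha)
  r <- k * diff(mass)
  r / mean(r)
}

#' Transition probabilities of the Poisson model
#'
#' Closed form for the 20-state equal-rate chain: along a branch of
#' expected length `length * category_rate` substitutions/site,
#' `P(same) = 1/20 + (19/20) exp(-(20/19) d)` and all off-diagonal entries
#' are equal. Rows sum to 1 and the chain is stationary at 1/20.
#'
#' @param length Expected substitutions/site (>= 0).
#' @param category_rate Rate multiplier of the site's gamma category.
#' @return A 20 x 20 stochastic matrix with amino-acid dimnames.
#' @export
transition_prob <- function(length, category_rate = 1) {
  if (!is.finite(length) && !(is.infinite(length) && length > 0)) {
    abort("length must be a non-negative number")
  }
  if (length < 0) abort("length must be non-negative")
  d <- length * category_rate
  e <- exp(-(20 / 19) * d)
  p_same <- 1 / 20 + (19 / 20) * e
  p_diff <- 1 / 20 - e / 20
  P <- matrix(p_diff, 20, 20, dimnames = list(aa_states(), aa_states()))
  diag(P) <- p_same
  P
}

#' Expected substitutions along a branch of a time tree
#'
#' Converts a branch duration and the rates at its two endpoint nodes to an
#' expected number of substitutions per site, using the arithmetic mean of
#' the endpoint rates (the branch rate convention used throughout the
#' relaxed clock).
#'
#' @param parent_age_ma,child_age_ma Endpoint ages in Ma
#'   (`parent_age_ma >= child_age_ma`).
#' @param parent_rate,child_rate Endpoint rates in substitutions/site/Ma.
#' @return Expected substitutions/site (vectorised).
#' @export
branch_length <- function(parent_age_ma, child_age_ma, parent_rate,
                          child_rate) {
  if (any(parent_age_ma < child_age_ma)) {
    abort("parent must not be younger than child")
  }
  if (any(parent_rate < 0) || any(child_rate < 0)) {
    abort("rates must be positive")
  }
  (parent_age_ma - child_age_ma) * (parent_rate + child_rate) / 2
}

# Expected substitutions on the edge above every non-root node.
# Returns a vector indexed by node id (root entry 0).
edge_lengths <- function(phylo, ages, rates, parent = parent_vector(phylo)) {
  len <- numeric(length(ages))
  kids <- which(parent > 0)
  len[kids] <- (ages[parent[kids]] - ages[kids]) *
    (rates[parent[kids]] + rates[kids]) / 2
  len
}
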