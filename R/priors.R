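# Prior densities: soft-bound fossil calibrations, the autocorrelated
# log-normal rate process, and the node-age prior.

#' Soft-bound calibration density
#'
#' A fossil window `[min_ma, max_ma]` becomes a piecewise density: a
#' uniform core over the window carrying `1 - 2 * tail_prob` of the mass,
#' and exponential tails below the minimum and above the maximum each
#' carrying exactly `tail_prob`. The tail scale is 10% of the window width
#' -- a smoothing choice, not a statement about fossil uncertainty.
#' `psoft_bound()` is the corresponding CDF.
#'
#' @param x Age(s) in Ma.
#' @param min_ma,max_ma Calibration bounds (Ma), `min_ma < max_ma`.
#' @param tail_prob Probability mass outside each bound, in (0, 0.5).
#' @param log Return the log density?
#' @return Density (or log density) / cumulative probability at `x`.
#' @export
dsoft_bound <- function(x, min_ma, max_ma, tail_prob = 0.025, log = FALSE) {
  check_bounds(min_ma, max_ma, tail_prob)
  s <- 0.1 * (max_ma - min_ma)
  core <- (1 - 2 * tail_prob) / (max_ma - min_ma)
  d <- ifelse(
    x < min_ma, tail_prob * dexp(min_ma - x, rate = 1 / s),
    ifelse(x > max_ma, tail_prob * dexp(x - max_ma, rate = 1 / s), core)
  )
  if (log) base::log(d) else d
}

#' @rdname dsoft_bound
#' @export
psoft_bound <- function(x, min_ma, max_ma, tail_prob = 0.025) {
  check_bounds(min_ma, max_ma, tail_prob)
  s <- 0.1 * (max_ma - min_ma)
  core <- (1 - 2 * tail_prob) / (max_ma - min_ma)
  ifelse(
    x < min_ma, tail_prob * exp(-(min_ma - x) / s),
    ifelse(x > max_ma,
           1 - tail_prob * exp(-(x - max_ma) / s),
           tail_prob + core * (x - min_ma))
  )
}

check_bounds <- function(min_ma, max_ma, tail_prob) {
  if (min_ma >= max_ma) abort("min_ma must be smaller than max_ma")
  if (tail_prob <= 0 || tail_prob >= 0.5) {
    abort("tail_prob must lie in (0, 0.5)")
  }
  invisible(TRUE)
}

# Single-bound variants. A minimum-only calibration keeps a uniform core
# from the bound up to the current root age (the natural upper limit for
# an internal node under the order-constrained age prior) with 1 - tail
# mass, and an exponential tail below the bound with `tail` mass and scale
# 10% of the bound. Maximum-only mirrors this on [0, max].
dsoft_min_only <- function(x, min_ma, upper, tail_prob = 0.05, log = FALSE) {
  if (upper <= min_ma) {
    # window collapsed: everything is in the tail region
    return(if (log) rep(-Inf, length(x)) else rep(0, length(x)))
  }
  s <- 0.1 * min_ma
  core <- (1 - tail_prob) / (upper - min_ma)
  d <- ifelse(
    x < min_ma, tail_prob * dexp(min_ma - x, rate = 1 / s),
    ifelse(x <= upper, core, 0)
  )
  if (log) base::log(d) else d
}

dsoft_max_only <- function(x, max_ma, tail_prob = 0.05, log = FALSE) {
  s <- 0.1 * max_ma
  core <- (1 - tail_prob) / max_ma
  d <- ifelse(
    x > max_ma, tail_prob * dexp(x - max_ma, rate = 1 / s),
    ifelse(x >= 0, core, 0)
  )
  if (log) base::log(d) else d
}

#' Root age prior
#'
#' A Normal prior on the root age, truncated below at the oldest calibrated
#' minimum among the root's descendants (enforced in the sampler). The
#' convention "3.5 +/- 0.05 Ga" maps to `root_prior(3500, 50)`.
#'
#' @param mean_ma,sd_ma Mean and standard deviation in Ma (> 0).
#' @return A `root_prior` object.
#' @export
root_prior <- function(mean_ma, sd_ma) {
  if (mean_ma <= 0 || sd_ma <= 0) abort("mean_ma and sd_ma must be positive")
  structure(list(mean_ma = mean_ma, sd_ma = sd_ma), class = "root_prior")
}

#' Log-prior of branch rates under the autocorrelated log-normal clock
#'
#' Each non-root node's rate is log-normally distributed around its
#' parent's rate: `log r_child ~ Normal(log r_parent - sigma2 * dt / 2,
#' sigma2 * dt)` where `dt` is the branch duration in Ma. The `-sigma2 *
#' dt / 2` shift makes the process mean-preserving
#' (`E[r_child | r_parent] = r_parent`), the standard geometric-Brownian
#' parameterisation of rate autocorrelation.
#'
#' @param tree A [time_tree()] with ages and rates.
#' @param sigma2 Variance of the log-rate increment per Ma (> 0).
#' @return The log density, summed over non-root nodes.
#' @export
log_prior_rates <- function(tree, sigma2) {
  if (sigma2 <= 0) abort("sigma2 must be positive")
  if (is.null(tree$rates)) abort("tree must carry rates")
  parent <- parent_vector(tree$phylo)
  lp_rates_raw(tree$ages_ma, tree$rates, sigma2, parent)
}

lp_rates_raw <- function(ages, rates, sigma2, parent) {
  kids <- which(parent > 0)
  dt <- ages[parent[kids]] - ages[kids]
  sum(dnorm(base::log(rates[kids]),
            mean = base::log(rates[parent[kids]]) - sigma2 * dt / 2,
            sd = sqrt(sigma2 * dt), log = TRUE) -
        base::log(rates[kids]))
}

#' Log-prior of node ages with soft-bound calibrations
#'
#' The joint age prior factorises as: a Normal density on the root age
#' ([root_prior()]); a uniform distribution of the remaining internal ages
#' over the order-constrained simplex given the root (contributing
#' `-(m - 1) * log(root_age)` for `m` internal nodes); and one soft-bound
#' factor per calibrated node ([dsoft_bound()]; minimum-only bounds use a
#' 5% single tail).
#'
#' @param tree A [time_tree()].
#' @param calibrations A tibble with columns `node_label`, `min_ma`,
#'   `max_ma` (NA = absent bound) and optionally `tail_prob`; may be
#'   `NULL` for no calibrations.
#' @param root A [root_prior()].
#' @return The log prior density (up to the order-simplex combinatorial
#'   constant, which does not depend on any sampled quantity).
#' @export
log_prior_ages <- function(tree, calibrations, root) {
  cal <- prepare_calibrations(calibrations, tree)
  n <- length(tree$phylo$tip.label)
  lp_ages_raw(tree$ages_ma, cal, root, n)
}

lp_ages_raw <- function(ages, cal, root, n_tips) {
  root_id <- n_tips + 1L
  root_age <- ages[root_id]
  lp <- dnorm(root_age, root$mean_ma, root$sd_ma, log = TRUE) -
    (n_tips - 2L) * base::log(root_age)
  if (!is.null(cal) && nrow(cal) > 0) {
    for (i in seq_len(nrow(cal))) {
      x <- ages[cal$node_id[i]]
      lp <- lp + if (!is.na(cal$min_ma[i]) && !is.na(cal$max_ma[i])) {
        dsoft_bound(x, cal$min_ma[i], cal$max_ma[i], cal$tail_prob[i],
                    log = TRUE)
      } else if (!is.na(cal$min_ma[i])) {
        dsoft_min_only(x, cal$min_ma[i], upper = root_age,
                       tail_prob = cal$tail_prob[i], log = TRUE)
      } else {
        dsoft_max_only(x, cal$max_ma[i], tail_prob = cal$tail_prob[i],
                       log = TRUE)
      }
    }
  }
  lp
}

# Resolve calibration node labels to node ids and fill default tail
# probabilities (2.5% two-sided, 5% single-bound).
prepare_calibrations <- function(calibrations, tree) {
  if (is.null(calibrations) || nrow(calibrations) == 0) return(NULL)
  cal <- tibble::as_tibble(calibrations)
  if (!all(c("node_label") %in% names(cal))) {
    abort("calibrations need a node_label column")
  }
  cal$min_ma <- as.numeric(cal$min_ma %||% NA)
  cal$max_ma <- as.numeric(cal$max_ma %||% NA)
  if (any(is.na(cal$min_ma) & is.na(cal$max_ma))) {
    abort("each calibration needs at least one bound")
  }
  both <- !is.na(cal$min_ma) & !is.na(cal$max_ma)
  if (any(both & cal$min_ma >= cal$max_ma)) {
    abort("min_ma must be smaller than max_ma")
  }
  if (!"tail_prob" %in% names(cal)) cal$tail_prob <- NA_real_
  cal$tail_prob <- ifelse(is.na(cal$tail_prob),
                          ifelse(both, 0.025, 0.05), cal$tail_prob)
  lab <- node_labels(tree)
  cal$node_id <- match(cal$node_label, lab)
  if (anyNA(cal$node_id)) {
    abort(paste0("calibration labels not found in tree: ",
                 paste(cal$node_label[is.na(cal$node_id)], collapse = ", ")))
  }
  n <- length(tree$phylo$tip.label)
  if (any(cal$node_id <= n)) {
    abort("calibrations must target internal nodes, not tips")
  }
  if (any(cal$node_id == n + 1L)) {
    abort("the root is constrained through root_prior(), not a calibration")
  }
  cal
}

#' Read and write calibration tables
#'
#' Tab-separated with columns `node_label`, `min_ma`, `max_ma`; empty
#' cells mean an absent bound.
#'
#' @param calibrations A calibration tibble.
#' @param path File path.
#' @return A tibble, or `path` invisibly.
#' @export
read_calibrations <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  tibble::as_tibble(tbl)
}

#' @rdname read_calibrations
#' @export
write_calibrations <- function(calibrations, path) {
  utils::write.table(calibrations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
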