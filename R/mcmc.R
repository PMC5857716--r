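# Metropolis-Hastings sampler for the relaxed-clock node-dating model.
#
# Parameter space: internal node ages (Ma), per-node branch rates
# (substitutions/site/Ma), the autocorrelation variance sigma2 (per Ma)
# and the gamma shape alpha. The posterior combines the pruning
# likelihood, the order-constrained age prior with soft-bound
# calibrations, the autocorrelated log-normal rate prior, and exponential
# hyperpriors. Node ages move by bounded uniform slides (between the
# parent's age and the oldest child's age), everything positive moves by
# log-scale multipliers. Every proposal respects the parent-older-than-
# child constraint by construction, so invalid states are never visited.

#' Sampler settings for the relaxed clock
#'
#' @param n_iter Total sweeps per chain (one sweep updates every
#'   parameter once).
#' @param burn_in Sweeps discarded before recording; proposal step sizes
#'   are tuned during burn-in and frozen afterwards, preserving detailed
#'   balance of the recorded portion.
#' @param thin Record every `thin`-th post-burn-in sweep.
#' @param seed Integer seed; chain `i` uses `seed + i - 1`, making runs
#'   bit-reproducible.
#' @param n_chains Number of independent chains (run sequentially).
#' @param rhat_threshold Convergence is flagged when any monitored
#'   split-R-hat exceeds this.
#' @return A `clock_control` list.
#' @export
clock_control <- function(n_iter = 4000, burn_in = 1000, thin = 2,
                          seed = 1L, n_chains = 2L,
                          rhat_threshold = 1.05) {
  if (n_iter <= burn_in) abort("n_iter must exceed burn_in")
  if (thin < 1) abort("thin must be >= 1")
  structure(
    list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         thin = as.integer(thin), seed = as.integer(seed),
         n_chains = as.integer(n_chains),
         rhat_threshold = rhat_threshold),
    class = "clock_control"
  )
}

#' Relaxed-clock model settings
#'
#' `sigma2` and `root_rate` double as initial values and as the centre of
#' their priors: `sigma2 ~ Exponential(mean 1e-3 per Ma)` (i.e. mean 1 per
#' Ga) and the root node's rate has a wide log-normal prior centred on
#' `root_rate` with `root_rate_sdlog` on the log scale.
#'
#' @param sigma2 Initial autocorrelation variance of log rate, per Ma.
#' @param root_rate Prior centre for the root rate, substitutions/site/Ma.
#' @param root_rate_sdlog Log-scale sd of the root-rate prior.
#' @return A `clock_model` list.
#' @export
clock_model <- function(sigma2 = 1e-4, root_rate = 2.5e-4,
                        root_rate_sdlog = 1.5) {
  if (sigma2 <= 0 || root_rate <= 0) {
    abort("sigma2 and root_rate must be positive")
  }
  structure(list(sigma2 = sigma2, root_rate = root_rate,
                 root_rate_sdlog = root_rate_sdlog),
            class = "clock_model")
}

sigma2_hyper_rate <- 1000  # Exponential prior: mean 1e-3 per Ma = 1 per Ga

#' Sample the relaxed-clock posterior by MCMC
#'
#' Runs Metropolis-Hastings chains over node ages, branch rates and
#' hyperparameters on a fixed rooted binary topology. With
#' `likelihood = FALSE` the data term is dropped and the sampler draws
#' from the prior (a prior-predictive check of the calibration densities).
#'
#' @param alignment Alignment tibble covering the tree's tips (may be
#'   `NULL` when `likelihood = FALSE`).
#' @param tree A [time_tree()] (its ages initialise the chain) or a
#'   labelled `phylo` topology.
#' @param calibrations Calibration tibble (see [log_prior_ages()]), or
#'   `NULL`.
#' @param root A [root_prior()].
#' @param model A [poisson_gamma_model()]; its `alpha` initialises the
#'   shape parameter.
#' @param clock A [clock_model()].
#' @param control A [clock_control()].
#' @param likelihood Include the data likelihood? `FALSE` gives a
#'   prior-only run.
#' @return A `clock_posterior` object; see [tidy.clock_posterior()],
#'   [glance.clock_posterior()], [rates_vs_time()].
#' @export
clock_mcmc <- function(alignment, tree, calibrations = NULL,
                       root = root_prior(3500, 50),
                       model = poisson_gamma_model(),
                       clock = clock_model(),
                       control = clock_control(),
                       likelihood = TRUE) {
  tree <- init_time_tree(tree, root)
  cal <- prepare_calibrations(calibrations, tree)
  # a start far outside a calibration window can underflow the soft-bound
  # tails; pull calibrated nodes into their windows and repair the ordering
  if (!is.finite(lp_ages_raw(tree$ages_ma, cal, root,
                             length(tree$phylo$tip.label)))) {
    tree <- time_tree(tree$phylo,
                      repair_init_ages(tree$ages_ma, cal, tree$phylo),
                      tree$rates)
  }
  phy <- tree$phylo
  n <- length(phy$tip.label)
  m <- 2L * n - 1L
  root_id <- n + 1L

  if (likelihood) {
    if (is.null(alignment)) abort("alignment required when likelihood = TRUE")
    enc <- encode_alignment(alignment, phy$tip.label)
    topo <- pruner_topology(phy)
  } else {
    enc <- topo <- NULL
  }

  chains <- lapply(seq_len(control$n_chains), function(ch) {
    run_clock_chain(ch, tree, cal, root, model, clock, control,
                    likelihood, enc, topo)
  })

  trace <- dplyr::bind_rows(lapply(seq_along(chains), function(ch) {
    out <- tibble::as_tibble(chains[[ch]]$trace)
    dplyr::bind_cols(tibble::tibble(chain = ch,
                                    iteration = chains[[ch]]$iterations),
                     out)
  }))
  acceptance <- dplyr::bind_rows(lapply(seq_along(chains), function(ch) {
    dplyr::bind_cols(tibble::tibble(chain = ch), chains[[ch]]$acceptance)
  }))

  params <- setdiff(names(trace), c("chain", "iteration"))
  rhat <- split_rhat(trace, params)
  monitored <- c(paste0("age_", phy$node.label[1]), "sigma2",
                 if (likelihood) "alpha")
  monitored <- intersect(monitored, rhat$term)
  max_rhat <- max(rhat$rhat[rhat$term %in% monitored], na.rm = TRUE)
  converged <- is.finite(max_rhat) && max_rhat < control$rhat_threshold
  if (!converged) {
    warn(sprintf("chains may not have converged: max split-Rhat %.3f", max_rhat))
  }

  structure(
    list(trace = trace, tree = tree, calibrations = calibrations,
         root = root, model = model, clock = clock, control = control,
         likelihood = likelihood, acceptance = acceptance, rhat = rhat,
         converged = converged),
    class = "clock_posterior"
  )
}

# Coerce the topology input and build initial ages if absent: relative
# node heights (longest tip-path below each node) scaled to the root
# prior mean.
init_time_tree <- function(tree, root) {
  if (inherits(tree, "time_tree")) return(tree)
  if (!inherits(tree, "phylo")) {
    abort("tree must be a time_tree or phylo object")
  }
  n <- length(tree$tip.label)
  m <- 2L * n - 1L
  kids <- children_list(tree)
  h <- numeric(m)
  for (v in postorder_internal(tree)) {
    h[v] <- max(h[kids[[v]]]) + 1
  }
  ages <- h / h[n + 1L] * root$mean_ma
  time_tree(tree, ages)
}

# Move calibrated nodes to the middle of their windows, then restore the
# parent-older-than-child ordering bottom-up.
repair_init_ages <- function(ages, cal, phy) {
  if (is.null(cal)) return(ages)
  for (i in seq_len(nrow(cal))) {
    v <- cal$node_id[i]
    ages[v] <- if (!is.na(cal$min_ma[i]) && !is.na(cal$max_ma[i])) {
      (cal$min_ma[i] + cal$max_ma[i]) / 2
    } else if (!is.na(cal$min_ma[i])) {
      cal$min_ma[i] * 1.05
    } else {
      cal$max_ma[i] / 2
    }
  }
  kids <- children_list(phy)
  for (v in postorder_internal(phy)) {
    mx <- max(ages[kids[[v]]])
    if (ages[v] <= mx) ages[v] <- mx * 1.05 + 1
  }
  ages
}

run_clock_chain <- function(chain_id, tree, cal, root, model, clock,
                            control, likelihood, enc, topo) {
  set.seed(control$seed + chain_id - 1L)
  phy <- tree$phylo
  n <- length(phy$tip.label)
  m <- 2L * n - 1L
  root_id <- n + 1L
  parent <- parent_vector(phy)
  kids <- children_list(phy)
  lab <- node_labels(tree)
  # internal nodes except the root
  free_int <- if (m >= n + 2L) seq(n + 2L, m) else integer(0)

  # 0-based dirty sets for the pruning cache: path from a node to the root
  path0 <- vector("list", m)
  for (v in seq_len(m)) {
    p <- if (v <= n) parent[v] else v
    path <- integer(0)
    while (p != 0) {
      path <- c(path, p)
      p <- parent[p]
    }
    path0[[v]] <- as.integer(path - 1L)
  }

  trunc_min <- if (!is.null(cal)) max(c(cal$min_ma, 0), na.rm = TRUE) else 0

  # --- state ---
  ages <- tree$ages_ma
  rates <- tree$rates %||% rep(clock$root_rate, m)
  sigma2 <- clock$sigma2
  alpha <- model$alpha
  cat_rates <- gamma_category_rates(alpha, model$n_categories)

  lp_rates_all <- function(ages, rates, sigma2) {
    lp_rates_raw(ages, rates, sigma2, parent) +
      dlnorm(rates[root_id], base::log(clock$root_rate),
             clock$root_rate_sdlog, log = TRUE)
  }
  lp_hyper <- function(sigma2, alpha) {
    dexp(sigma2, rate = sigma2_hyper_rate, log = TRUE) +
      dexp(alpha, rate = 1, log = TRUE)
  }

  if (likelihood) {
    xp <- pruner_create(enc$states, enc$weights, topo$children, topo$ntip,
                        topo$postorder, model$n_categories)
    elen <- edge_lengths(phy, ages, rates, parent)
    ll <- pruner_full(xp, elen, cat_rates)
  } else {
    xp <- NULL
    ll <- 0
  }
  lpA <- lp_ages_raw(ages, cal, root, n)
  lpR <- lp_rates_all(ages, rates, sigma2)
  lpH <- lp_hyper(sigma2, alpha)

  # --- bookkeeping ---
  deltas <- c(age_local = 0.3, root_age = 0.05, rate = 0.6, sigma2 = 1.0,
              alpha = 0.4)
  acc <- win <- setNames(numeric(6), c("node_age", names(deltas)))
  acc_total <- try_total <- acc
  tune_every <- 100L

  n_keep <- (control$n_iter - control$burn_in) %/% control$thin
  par_names <- c(paste0("age_", lab[c(root_id, free_int)]),
                 paste0("rate_", lab), "sigma2", "alpha",
                 "log_lik", "log_prior")
  out <- matrix(NA_real_, n_keep, length(par_names),
                dimnames = list(NULL, par_names))
  iterations <- integer(n_keep)
  k <- 0L

  ll_path <- function(dirty) {
    elen_new <- edge_lengths(phy, ages, rates, parent)
    pruner_propose(xp, elen_new, cat_rates, dirty)
  }

  for (iter in seq_len(control$n_iter)) {
    # -- internal node ages (bounded uniform slide) --
    for (v in free_int) {
      lo <- max(ages[kids[[v]]])
      hi <- ages[parent[v]]
      x_new <- runif(1, lo, hi)
      x_old <- ages[v]
      ages[v] <- x_new
      lpA_new <- lp_ages_raw(ages, cal, root, n)
      lpR_new <- lp_rates_all(ages, rates, sigma2)
      ll_new <- if (likelihood) ll_path(path0[[v]]) else 0
      log_r <- (lpA_new + lpR_new + ll_new) - (lpA + lpR + ll)
      if (!is.nan(log_r) && base::log(runif(1)) < log_r) {
        lpA <- lpA_new; lpR <- lpR_new; ll <- ll_new
        if (likelihood) pruner_accept(xp)
        acc["node_age"] <- acc["node_age"] + 1
      } else {
        ages[v] <- x_old
      }
      win["node_age"] <- win["node_age"] + 1
    }

    # -- internal node ages, local refinement (tuned symmetric slide) --
    for (v in free_int) {
      lo <- max(ages[kids[[v]]])
      hi <- ages[parent[v]]
      x_old <- ages[v]
      x_new <- x_old + deltas["age_local"] * (hi - lo) * (runif(1) - 0.5)
      win["age_local"] <- win["age_local"] + 1
      if (x_new <= lo || x_new >= hi) next
      ages[v] <- x_new
      lpA_new <- lp_ages_raw(ages, cal, root, n)
      lpR_new <- lp_rates_all(ages, rates, sigma2)
      ll_new <- if (likelihood) ll_path(path0[[v]]) else 0
      log_r <- (lpA_new + lpR_new + ll_new) - (lpA + lpR + ll)
      if (!is.nan(log_r) && base::log(runif(1)) < log_r) {
        lpA <- lpA_new; lpR <- lpR_new; ll <- ll_new
        if (likelihood) pruner_accept(xp)
        acc["age_local"] <- acc["age_local"] + 1
      } else {
        ages[v] <- x_old
      }
    }

    # -- root age (log-scale multiplier, truncated below) --
    f <- exp(deltas["root_age"] * (runif(1) - 0.5))
    x_old <- ages[root_id]
    x_new <- x_old * f
    win["root_age"] <- win["root_age"] + 1
    lo <- max(ages[kids[[root_id]]], trunc_min)
    if (x_new > lo) {
      ages[root_id] <- x_new
      lpA_new <- lp_ages_raw(ages, cal, root, n)
      lpR_new <- lp_rates_all(ages, rates, sigma2)
      ll_new <- if (likelihood) ll_path(path0[[root_id]]) else 0
      log_r <- (lpA_new + lpR_new + ll_new) - (lpA + lpR + ll) +
        base::log(f)
      if (!is.nan(log_r) && base::log(runif(1)) < log_r) {
        lpA <- lpA_new; lpR <- lpR_new; ll <- ll_new
        if (likelihood) pruner_accept(xp)
        acc["root_age"] <- acc["root_age"] + 1
      } else {
        ages[root_id] <- x_old
      }
    }

    # -- per-node rates (log-scale multipliers) --
    for (v in seq_len(m)) {
      f <- exp(deltas["rate"] * (runif(1) - 0.5))
      r_old <- rates[v]
      rates[v] <- r_old * f
      lpR_new <- lp_rates_all(ages, rates, sigma2)
      ll_new <- if (likelihood) ll_path(path0[[v]]) else 0
      log_r <- (lpR_new + ll_new) - (lpR + ll) + base::log(f)
      if (!is.nan(log_r) && base::log(runif(1)) < log_r) {
        lpR <- lpR_new; ll <- ll_new
        if (likelihood) pruner_accept(xp)
        acc["rate"] <- acc["rate"] + 1
      } else {
        rates[v] <- r_old
      }
      win["rate"] <- win["rate"] + 1
    }

    # -- sigma2 --
    f <- exp(deltas["sigma2"] * (runif(1) - 0.5))
    s_old <- sigma2
    sigma2 <- s_old * f
    lpR_new <- lp_rates_all(ages, rates, sigma2)
    lpH_new <- lp_hyper(sigma2, alpha)
    log_r <- (lpR_new + lpH_new) - (lpR + lpH) + base::log(f)
    if (!is.nan(log_r) && base::log(runif(1)) < log_r) {
      lpR <- lpR_new; lpH <- lpH_new
      acc["sigma2"] <- acc["sigma2"] + 1
    } else {
      sigma2 <- s_old
    }
    win["sigma2"] <- win["sigma2"] + 1

    # -- alpha (only relevant with data) --
    if (likelihood) {
      f <- exp(deltas["alpha"] * (runif(1) - 0.5))
      a_old <- alpha
      a_new <- a_old * f
      win["alpha"] <- win["alpha"] + 1
      if (a_new > 1e-3 && a_new < 1e3) {
        cat_new <- gamma_category_rates(a_new, model$n_categories)
        elen_now <- edge_lengths(phy, ages, rates, parent)
        ll_new <- pruner_propose(xp, elen_now, cat_new,
                                 as.integer(postorder_internal(phy) - 1L))
        lpH_new <- lp_hyper(sigma2, a_new)
        log_r <- (lpH_new + ll_new) - (lpH + ll) + base::log(f)
        if (!is.nan(log_r) && base::log(runif(1)) < log_r) {
          alpha <- a_new; cat_rates <- cat_new
          lpH <- lpH_new; ll <- ll_new
          pruner_accept(xp)
          acc["alpha"] <- acc["alpha"] + 1
        }
      }
    }

    # -- step-size tuning, burn-in only --
    if (iter <= control$burn_in && iter %% tune_every == 0L) {
      for (nm in names(deltas)) {
        if (win[nm] > 0) {
          rate_acc <- acc[nm] / win[nm]
          deltas[nm] <- min(5, max(1e-3,
                                   deltas[nm] * exp(1.5 * (rate_acc - 0.3))))
        }
      }
      acc_total <- acc_total + acc
      try_total <- try_total + win
      acc[] <- 0; win[] <- 0
    }

    # -- record --
    if (iter > control$burn_in &&
        (iter - control$burn_in) %% control$thin == 0L) {
      k <- k + 1L
      out[k, ] <- c(ages[c(root_id, free_int)], rates, sigma2, alpha,
                    if (likelihood) ll else NA_real_, lpA + lpR + lpH)
      iterations[k] <- iter
    }
  }

  acc_total <- acc_total + acc
  try_total <- try_total + win
  list(
    trace = out[seq_len(k), , drop = FALSE],
    iterations = iterations[seq_len(k)],
    acceptance = tibble::tibble(
      move = names(acc_total),
      accepted = as.numeric(acc_total),
      proposed = as.numeric(try_total),
      rate = ifelse(try_total > 0, acc_total / try_total, NA_real_)
    )
  )
}

# Split-R-hat (each chain halved, pooled-variance formulation).
split_rhat <- function(trace, params) {
  halves <- lapply(split(trace, trace$chain), function(ch) {
    ns <- nrow(ch)
    h <- ns %/% 2
    list(ch[seq_len(h), , drop = FALSE],
         ch[(ns - h + 1):ns, , drop = FALSE])
  })
  halves <- unlist(halves, recursive = FALSE)
  purrr::map_dfr(params, function(p) {
    draws <- vapply(halves, function(h) unlist(h[[p]]), numeric(nrow(halves[[1]])))
    nseq <- ncol(draws)
    ndraw <- nrow(draws)
    mu <- colMeans(draws)
    w <- mean(apply(draws, 2, stats::var))
    b <- ndraw * stats::var(mu)
    rh <- if (anyNA(draws)) {
      NA_real_
    } else if (!is.finite(w) || w <= 0) {
      if (stats::var(as.vector(draws)) == 0) 1 else NA_real_
    } else {
      sqrt(((ndraw - 1) / ndraw * w + b / ndraw) / w)
    }
    tibble::tibble(term = p, rhat = rh)
  })
}
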