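# Posterior summaries and derived quantities.

#' @export
print.clock_posterior <- function(x, ...) {
  n_samp <- nrow(x$trace)
  cat(sprintf(
    "clock_posterior: %d samples (%d chain%s), %s run\n",
    n_samp, x$control$n_chains, if (x$control$n_chains > 1) "s" else "",
    if (x$likelihood) "posterior" else "prior-only"
  ))
  root_lab <- x$tree$phylo$node.label[1]
  s <- summarize_posterior(x)
  root_row <- s[s$term == paste0("age_", root_lab), ]
  if (nrow(root_row) == 1) {
    cat(sprintf("  root age: %.2f +/- %.2f Ga (95%% CI %.2f-%.2f)\n",
                root_row$mean / 1000, root_row$sd / 1000,
                root_row$conf.low / 1000, root_row$conf.high / 1000))
  }
  cat(sprintf("  converged: %s (max monitored split-Rhat threshold %.2f)\n",
              x$converged, x$control$rhat_threshold))
  invisible(x)
}

#' Summarise a clock posterior
#'
#' One row per sampled parameter: posterior mean, standard deviation, the
#' central 95% credible interval, its half-width, and split-R-hat. Node
#' ages are in Ma; rates in substitutions/site/Ma. `tidy()` is an alias.
#'
#' @param x A `clock_posterior`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `kind`, `node`, `mean`, `sd`,
#'   `conf.low`, `conf.high`, `ci_half_width`, `rhat`.
#' @export
summarize_posterior <- function(x, ...) {
  if (!inherits(x, "clock_posterior")) abort("x must be a clock_posterior")
  if (nrow(x$trace) == 0) abort("posterior trace is empty")
  params <- setdiff(names(x$trace), c("chain", "iteration"))
  sums <- purrr::map_dfr(params, function(p) {
    v <- x$trace[[p]]
    qs <- unname(quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
    tibble::tibble(
      term = p,
      mean = mean(v), sd = sd(v),
      conf.low = qs[1], conf.high = qs[2],
      ci_half_width = (qs[2] - qs[1]) / 2
    )
  })
  sums$kind <- dplyr::case_when(
    startsWith(sums$term, "age_") ~ "age",
    startsWith(sums$term, "rate_") ~ "rate",
    sums$term %in% c("sigma2", "alpha") ~ "hyper",
    TRUE ~ "diagnostic"
  )
  sums$node <- ifelse(sums$kind %in% c("age", "rate"),
                      sub("^(age|rate)_", "", sums$term), NA_character_)
  sums <- dplyr::left_join(sums, x$rhat, by = "term")
  sums[, c("term", "kind", "node", "mean", "sd", "conf.low", "conf.high",
           "ci_half_width", "rhat")]
}

#' @rdname summarize_posterior
#' @export
tidy.clock_posterior <- function(x, ...) summarize_posterior(x, ...)

#' One-line posterior diagnostics
#'
#' @param x A `clock_posterior`.
#' @param ... Unused.
#' @return A tibble with sample counts, convergence flag and the maximum
#'   split-R-hat over all recorded parameters.
#' @export
glance.clock_posterior <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$trace),
    n_chains = x$control$n_chains,
    n_iter = x$control$n_iter,
    burn_in = x$control$burn_in,
    likelihood = x$likelihood,
    max_rhat = suppressWarnings(max(x$rhat$rhat, na.rm = TRUE)),
    converged = x$converged
  )
}

#' Posterior mean evolutionary rate against node age
#'
#' Pairs each node's posterior mean age with its posterior mean rate (tips
#' sit at age 0 with their sampled tip-branch rate), converting rates to
#' amino-acid changes per site per Ga for plotting on geological scales.
#'
#' @param x A `clock_posterior`.
#' @return A tibble with columns `node`, `is_tip`, `mean_age_ma`,
#'   `mean_rate` (subst/site/Ma) and `mean_rate_per_ga`.
#' @export
rates_vs_time <- function(x) {
  s <- summarize_posterior(x)
  ages <- s[s$kind == "age", c("node", "mean")]
  names(ages)[2] <- "mean_age_ma"
  rates <- s[s$kind == "rate", c("node", "mean")]
  names(rates)[2] <- "mean_rate"
  out <- dplyr::left_join(rates, ages, by = "node")
  out$is_tip <- out$node %in% x$tree$phylo$tip.label
  out$mean_age_ma[out$is_tip] <- 0
  out$mean_rate_per_ga <- out$mean_rate * 1000
  out[, c("node", "is_tip", "mean_age_ma", "mean_rate", "mean_rate_per_ga")]
}

#' Compare posteriors across calibration choices
#'
#' Re-runs the dating analysis under each calibration variant (same
#' topology, alignment, root prior and sampler settings) and collects
#' per-node posterior summaries, the paired age comparison against the
#' first (baseline) variant, and a focus-node table in the
#' root-age-vs-duplication-age style.
#'
#' @param alignment Alignment tibble.
#' @param tree Topology (`time_tree` or labelled `phylo`).
#' @param variants Named list (>= 2) of calibration tibbles; `NULL`
#'   entries mean "no calibrations".
#' @param root A [root_prior()].
#' @param focus_label Internal-node label highlighted in the summary table
#'   (defaults to the root's first child-side deepest node, i.e. none).
#' @param ... Passed on to [clock_mcmc()] (`model`, `clock`, `control`,
#'   `likelihood`).
#' @return A `calibration_sensitivity` object with elements `summaries`
#'   (long tibble), `pairs` (baseline vs variant posterior mean ages per
#'   node) and `table` (per-variant root and focus-node mean +/- sd).
#' @export
calibration_sensitivity <- function(alignment, tree, variants, root,
                                    focus_label = NULL, ...) {
  if (length(variants) < 2) abort("need at least two calibration variants")
  if (is.null(names(variants)) || any(names(variants) == "")) {
    names(variants) <- paste0("variant_", seq_along(variants))
  }
  fits <- purrr::imap(variants, function(cal, nm) {
    clock_mcmc(alignment, tree, calibrations = cal, root = root, ...)
  })
  summaries <- purrr::imap_dfr(fits, function(fit, nm) {
    dplyr::bind_cols(tibble::tibble(variant = nm), summarize_posterior(fit))
  })
  ages <- summaries[summaries$kind == "age", ]
  base_nm <- names(variants)[1]
  base <- ages[ages$variant == base_nm, c("node", "mean")]
  names(base)[2] <- "baseline_mean_ma"
  pairs <- dplyr::left_join(
    ages[, c("variant", "node", "mean", "conf.low", "conf.high")],
    base, by = "node"
  )
  root_lab <- fits[[1]]$tree$phylo$node.label[1]
  tab <- purrr::imap_dfr(fits, function(fit, nm) {
    s <- summarize_posterior(fit)
    pick <- function(lbl) s[s$term == paste0("age_", lbl), ]
    r <- pick(root_lab)
    row <- tibble::tibble(
      variant = nm,
      root_mean_ma = r$mean, root_sd_ma = r$sd,
      converged = fit$converged
    )
    if (!is.null(focus_label)) {
      f <- pick(focus_label)
      row$focus_mean_ma <- f$mean
      row$focus_sd_ma <- f$sd
      row$focus_conf.low <- f$conf.low
      row$focus_conf.high <- f$conf.high
      row$focus_ci_width <- f$conf.high - f$conf.low
    }
    row
  })
  structure(
    list(summaries = summaries, pairs = pairs, table = tab,
         focus_label = focus_label, fits = fits),
    class = "calibration_sensitivity"
  )
}

#' @export
tidy.calibration_sensitivity <- function(x, ...) x$summaries

#' @export
print.calibration_sensitivity <- function(x, ...) {
  cat("calibration_sensitivity across",
      length(unique(x$summaries$variant)), "variants\n")
  print(x$table)
  invisible(x)
}
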