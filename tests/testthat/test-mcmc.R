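# Small, fast sampler checks; the heavier calibration and recovery
# experiments live in test-acceptance.R.

tiny_setup <- function() {
  phy <- three_taxon_tree()
  tr <- time_tree(phy, c(0, 0, 0, 1000, 400))
  tr <- simulate_rates(tr, 1e-4, 2e-4, seed = 1)
  aln <- simulate_alignment(tr, 60, alpha = 1, seed = 2)
  list(tree = tr, aln = aln)
}

test_that("identical seed and config give bit-identical traces", {
  s <- tiny_setup()
  ctl <- clock_control(n_iter = 120, burn_in = 40, thin = 2, seed = 7,
                       n_chains = 2)
  run <- function() {
    suppressWarnings(clock_mcmc(s$aln, s$tree, NULL,
                                root = root_prior(1000, 100),
                                model = poisson_gamma_model(1),
                                control = ctl))
  }
  p1 <- run(); p2 <- run()
  expect_identical(p1$trace, p2$trace)
  # chains differ from each other
  t1 <- p1$trace[p1$trace$chain == 1, ]
  t2 <- p1$trace[p1$trace$chain == 2, ]
  expect_false(identical(t1$age_root, t2$age_root))
})

test_that("every retained sample respects the node-age ordering", {
  fix <- make_duplication_fixture(n_clade_taxa = 2, n_outgroup = 1,
                                  root_age_ma = 2000, n_sites = 80, seed = 9)
  ctl <- clock_control(n_iter = 400, burn_in = 100, thin = 2, seed = 3,
                       n_chains = 1)
  post <- suppressWarnings(
    clock_mcmc(fix$alignment, fix$tree, fix$calibrations,
               root = root_prior(2000, 50), model = poisson_gamma_model(1),
               control = ctl)
  )
  td <- tidy(fix$tree)
  internal <- td[!td$is_tip, ]
  for (i in seq_len(nrow(internal))) {
    lab <- internal$label[i]
    par <- internal$parent_label[i]
    if (is.na(par)) next
    expect_true(all(post$trace[[paste0("age_", par)]] >
                      post$trace[[paste0("age_", lab)]]))
  }
  expect_true(all(post$trace$sigma2 > 0))
  expect_true(all(post$trace$alpha > 0))
})

test_that("a near-degenerate root prior pins the posterior root age", {
  s <- tiny_setup()
  ctl <- clock_control(n_iter = 1500, burn_in = 500, thin = 2, seed = 11,
                       n_chains = 1)
  post <- suppressWarnings(
    clock_mcmc(s$aln, s$tree, NULL, root = root_prior(1000, 1),
               model = poisson_gamma_model(1),
               clock = clock_model(sigma2 = 1e-6),
               control = ctl)
  )
  root_mean <- mean(post$trace$age_root)
  expect_lt(abs(root_mean - 1000), 3)
})

test_that("posterior summaries reduce correctly on hand-built traces", {
  fake <- structure(
    list(
      trace = tibble::tibble(chain = 1L, iteration = 1:2,
                             age_root = c(10, 20), sigma2 = c(1, 1)),
      rhat = tibble::tibble(term = c("age_root", "sigma2"), rhat = c(1, 1)),
      control = clock_control(n_iter = 2, burn_in = 0, thin = 1,
                              n_chains = 1),
      likelihood = FALSE, converged = TRUE
    ),
    class = "clock_posterior"
  )
  s <- summarize_posterior(fake)
  expect_equal(s$mean[s$term == "age_root"], 15)
  # a constant parameter collapses to a point
  expect_equal(s$sd[s$term == "sigma2"], 0)
  expect_equal(s$conf.low[s$term == "sigma2"],
               s$conf.high[s$term == "sigma2"])
  empty <- fake
  empty$trace <- fake$trace[0, ]
  expect_error(summarize_posterior(empty), "empty")
})

test_that("prior-only sampling reproduces the soft-bound mean", {
  phy <- three_taxon_tree()
  cal <- tibble::tibble(node_label = "inner", min_ma = 82, max_ma = 127)
  ctl <- clock_control(n_iter = 22000, burn_in = 2000, thin = 4, seed = 5,
                       n_chains = 1)
  post <- suppressWarnings(
    clock_mcmc(NULL, phy, cal, root = root_prior(4000, 100),
               control = ctl, likelihood = FALSE)
  )
  x <- post$trace$age_inner
  # analytic mean of the soft-bound density: symmetric tails cancel, 104.5
  expect_lt(abs(mean(x) - 104.5), 2)
})

test_that("rates_vs_time converts units and anchors tips at zero age", {
  s <- tiny_setup()
  ctl <- clock_control(n_iter = 200, burn_in = 100, thin = 2, seed = 13,
                       n_chains = 1)
  post <- suppressWarnings(
    clock_mcmc(s$aln, s$tree, NULL, root = root_prior(1000, 100),
               control = ctl)
  )
  rt <- rates_vs_time(post)
  expect_equal(nrow(rt), 5)
  expect_equal(rt$mean_rate_per_ga, rt$mean_rate * 1000)
  expect_true(all(rt$mean_age_ma[rt$is_tip] == 0))
  expect_true(all(rt$mean_age_ma[!rt$is_tip] > 0))
})

test_that("glance reports convergence diagnostics", {
  s <- tiny_setup()
  ctl <- clock_control(n_iter = 200, burn_in = 100, thin = 2, seed = 17,
                       n_chains = 2)
  post <- suppressWarnings(
    clock_mcmc(s$aln, s$tree, NULL, root = root_prior(1000, 100),
               control = ctl)
  )
  g <- glance(post)
  expect_equal(g$n_chains, 2L)
  expect_true(is.finite(g$max_rhat))
  expect_equal(g$n_samples, 2 * 50)
})
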