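test_that("the soft-bound density is proper with the stated tail masses", {
  dens <- function(x) dsoft_bound(x, 82, 127, 0.025)
  total <- stats::integrate(dens, -200, 600, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  below <- stats::integrate(dens, -200, 82, rel.tol = 1e-9)$value
  above <- stats::integrate(dens, 127, 600, rel.tol = 1e-9)$value
  expect_equal(below, 0.025, tolerance = 1e-6)
  expect_equal(above, 0.025, tolerance = 1e-6)
  # interior density is the flat core level
  expect_equal(dens(100), (1 - 0.05) / 45)
  expect_equal(dens(83), dens(126.9))
})

test_that("the soft-bound CDF agrees with quadrature of the density", {
  for (x in c(60, 82, 90, 127, 140)) {
    byq <- stats::integrate(function(z) dsoft_bound(z, 82, 127, 0.025),
                            -300, x, rel.tol = 1e-9)$value
    expect_equal(psoft_bound(x, 82, 127, 0.025), byq, tolerance = 1e-6)
  }
  expect_error(dsoft_bound(1, 127, 82), "smaller")
  expect_error(dsoft_bound(1, 82, 127, tail_prob = 0.6), "tail_prob")
})

test_that("single-bound calibrations carry 5% outside the bound", {
  dens <- function(x) paleoclock:::dsoft_min_only(x, 600, upper = 3000,
                                                  tail_prob = 0.05)
  below <- stats::integrate(dens, -1000, 600, rel.tol = 1e-9)$value
  total <- below + stats::integrate(dens, 600, 3000, rel.tol = 1e-9)$value
  expect_equal(below, 0.05, tolerance = 1e-6)
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("the rate prior matches the closed-form log-normal density", {
  # both tip branches have dt = 1, child rate = parent * exp(-1/2) with
  # sigma2 = 1: each term is the standard normal log-density at 0 minus
  # log(child rate)
  phy <- ape::read.tree(text = "(a,b)r;")
  rp <- 2e-4
  rc <- rp * exp(-1 / 2)
  tr <- time_tree(phy, c(0, 0, 1), rates = c(rc, rc, rp))
  expect_equal(log_prior_rates(tr, 1),
               2 * (dnorm(0, log = TRUE) - log(rc)))
  expect_error(log_prior_rates(tr, 0), "positive")
})

test_that("the forward rate process is mean-preserving and matches its density", {
  withr::with_seed(99, {
    rp <- 3e-4; s2 <- 0.5; dt <- 2
    draws <- exp(rnorm(1e5, log(rp) - s2 * dt / 2, sqrt(s2 * dt)))
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - rp), 3 * se)
  })

  # average forward log-density equals the analytic negative entropy
  phy <- three_taxon_tree()
  base <- time_tree(phy, c(0, 0, 0, 1000, 400))
  s2 <- 2e-4
  lps <- vapply(1:3000, function(s) {
    tr <- simulate_rates(base, s2, 2e-4, seed = s)
    log_prior_rates(tr, s2)
  }, numeric(1))
  parent <- paleoclock:::parent_vector(phy)
  kids <- which(parent > 0)
  dts <- base$ages_ma[parent[kids]] - base$ages_ma[kids]
  # lognormal entropy: mu + 1/2 log(2 pi e sigma^2); mu depends on the
  # (random) parent rate, E[mu] = log(root_rate) - sum of upstream drift
  neg_entropy <- function(mu, v) -(mu + 0.5 * log(2 * pi * exp(1) * v))
  mus <- numeric(length(base$ages_ma))
  mus[4] <- log(2e-4)
  expected <- 0
  ord <- rev(ape::reorder.phylo(phy, "postorder")$edge[, 2])
  for (v in ord) {
    dt <- base$ages_ma[parent[v]] - base$ages_ma[v]
    mus[v] <- mus[parent[v]] - s2 * dt / 2
    expected <- expected + neg_entropy(mus[v], s2 * dt)
  }
  se <- sd(lps) / sqrt(length(lps))
  expect_lt(abs(mean(lps) - expected), 4 * se)
})

test_that("the age prior combines root density, order simplex, and bounds", {
  phy <- three_taxon_tree()
  tr <- time_tree(phy, c(0, 0, 0, 3000, 100))
  rp <- root_prior(3000, 50)
  # no calibrations: root normal plus the order-simplex volume term
  expect_equal(log_prior_ages(tr, NULL, rp),
               dnorm(3000, 3000, 50, log = TRUE) - log(3000))
  # a two-sided calibration multiplies in the soft-bound core
  cal <- tibble::tibble(node_label = "inner", min_ma = 82, max_ma = 127)
  expect_equal(log_prior_ages(tr, cal, rp),
               dnorm(3000, 3000, 50, log = TRUE) - log(3000) +
                 log((1 - 0.05) / 45))
})

test_that("calibration mapping is validated", {
  phy <- three_taxon_tree()
  tr <- time_tree(phy, c(0, 0, 0, 3000, 100))
  rp <- root_prior(3000, 50)
  expect_error(
    log_prior_ages(tr, tibble::tibble(node_label = "nope", min_ma = 10,
                                      max_ma = 20), rp),
    "not found"
  )
  expect_error(
    log_prior_ages(tr, tibble::tibble(node_label = "a", min_ma = 10,
                                      max_ma = 20), rp),
    "internal nodes"
  )
  expect_error(
    log_prior_ages(tr, tibble::tibble(node_label = "root", min_ma = 10,
                                      max_ma = 20), rp),
    "root"
  )
  expect_error(
    log_prior_ages(tr, tibble::tibble(node_label = "inner", min_ma = NA,
                                      max_ma = NA), rp),
    "at least one bound"
  )
})
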