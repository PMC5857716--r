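test_that("chronogram simulation is exact at the root and reproducible", {
  tr <- simulate_chronogram(3, 2000, seed = 11)
  expect_equal(length(tr$phylo$tip.label), 3)
  expect_equal(sum(tr$ages_ma > 0), 2)  # exactly n - 1 internal nodes
  expect_equal(max(tr$ages_ma), 2000)
  expect_equal(tr$ages_ma[1:3], c(0, 0, 0))

  a <- simulate_chronogram(8, 3500, seed = 21)
  b <- simulate_chronogram(8, 3500, seed = 21)
  expect_identical(time_tree_newick(a), time_tree_newick(b))
  expect_false(identical(time_tree_newick(a),
                         time_tree_newick(simulate_chronogram(8, 3500, 22))))
  expect_error(simulate_chronogram(2, 100), "at least 3")
})

test_that("rate simulation is reproducible and collapses to a strict clock", {
  tr <- simulate_chronogram(6, 3000, seed = 31)
  strict <- simulate_rates(tr, 0, 2.5e-4, seed = 1)
  expect_true(all(strict$rates == 2.5e-4))
  r1 <- simulate_rates(tr, 1e-4, 2.5e-4, seed = 5)
  r2 <- simulate_rates(tr, 1e-4, 2.5e-4, seed = 5)
  expect_identical(r1$rates, r2$rates)
  expect_true(all(r1$rates > 0))
})

test_that("simulated alignments follow the closed-form identity expectation", {
  # two tips joined at the root: total path 0.1 substitutions/site, no
  # rate heterogeneity -> P(match) = 1/20 + (19/20) exp(-2/19)
  phy <- ape::read.tree(text = "(a,b)r;")
  tr <- time_tree(phy, c(0, 0, 100), rates = rep(5e-4, 3))
  aln <- simulate_alignment(tr, 1e5, alpha = Inf, seed = 41)
  obs <- percent_identity(aln$sequence[1], aln$sequence[2]) / 100
  expected <- 1 / 20 + (19 / 20) * exp(-2 / 19)
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(obs - expected), 4 * se)

  # determinism
  expect_identical(simulate_alignment(tr, 50, seed = 42),
                   simulate_alignment(tr, 50, seed = 42))

  # near-zero tree length: all sequences identical
  tiny <- time_tree(phy, c(0, 0, 1e-6), rates = rep(1e-9, 3))
  a0 <- simulate_alignment(tiny, 200, seed = 43)
  expect_equal(a0$sequence[1], a0$sequence[2])

  # saturation: identity approaches the stationary 5%
  far <- time_tree(phy, c(0, 0, 5000), rates = rep(5e-3, 3))
  af <- simulate_alignment(far, 1e4, seed = 44)
  obs_far <- percent_identity(af$sequence[1], af$sequence[2])
  expect_lt(abs(obs_far - 5), 1.5)
})

test_that("pairwise identity decreases with path length in expectation", {
  tr <- simulate_chronogram(6, 3000, seed = 51)
  tr <- simulate_rates(tr, 0, 2e-4, seed = 51)
  aln <- simulate_alignment(tr, 2000, alpha = Inf, seed = 52)
  seqs <- setNames(aln$sequence, aln$label)
  # strict clock: pairwise path length is twice the MRCA age
  mrca_age <- function(x, y) {
    tr$ages_ma[ape::getMRCA(tr$phylo, c(x, y))]
  }
  combs <- utils::combn(tr$phylo$tip.label, 2)
  ages <- apply(combs, 2, function(p) mrca_age(p[1], p[2]))
  ids <- apply(combs, 2, function(p) percent_identity(seqs[[p[1]]],
                                                      seqs[[p[2]]]))
  # bin into shallow vs deep splits
  expect_gt(mean(ids[ages < stats::median(ages)]),
            mean(ids[ages >= stats::median(ages)]))
})

test_that("the duplication fixture has the advertised structure", {
  fix <- make_duplication_fixture(seed = 6)
  lab <- node_labels(fix$tree)
  dup_age <- fix$tree$ages_ma[match("duplication", lab)]
  root_age <- fix$tree$ages_ma[match("root", lab)]
  expect_equal(root_age, 3500)
  # the duplication is the oldest node after the root
  others <- fix$tree$ages_ma[-match(c("root", "duplication"), lab)]
  expect_true(all(others < dup_age))
  expect_lt(dup_age, root_age)
  expect_equal(nrow(fix$calibrations), 3)
  # calibration windows bracket the true ages
  for (i in seq_len(3)) {
    age <- fix$tree$ages_ma[match(fix$calibrations$node_label[i], lab)]
    expect_gt(age, fix$calibrations$min_ma[i])
    expect_lt(age, fix$calibrations$max_ma[i])
  }
  # determinism
  fix2 <- make_duplication_fixture(seed = 6)
  expect_identical(fix$alignment, fix2$alignment)
  expect_identical(fix$tree$rates, fix2$tree$rates)
})

test_that("cross-paralogue identity sits in the deep-divergence regime", {
  # with the default rates the A-vs-B comparisons should be far diverged
  # (tens of percent identity) without being fully saturated
  ids <- vapply(1:5, function(s) {
    fix <- make_duplication_fixture(seed = 200 + s, n_sites = 400)
    seqs <- setNames(fix$alignment$sequence, fix$alignment$label)
    percent_identity(seqs[["A1"]], seqs[["B1"]])
  }, numeric(1))
  expect_gt(mean(ids), 25)
  expect_lt(mean(ids), 60)
})

test_that("fixtures round-trip through the on-disk formats", {
  fix <- make_duplication_fixture(seed = 7)
  dir <- withr::local_tempdir()
  paths <- write_fixture(fix, dir)
  expect_true(all(file.exists(paths)))
  back_tree <- read_time_tree(paths["tree"])
  merged <- dplyr::inner_join(tidy(back_tree)[, c("label", "age_ma")],
                              tidy(fix$tree)[, c("label", "age_ma")],
                              by = "label")
  expect_equal(nrow(merged), 15)
  expect_equal(merged$age_ma.x, merged$age_ma.y, tolerance = 1e-4)
  back_aln <- read_aligned_fasta(paths["alignment"])
  expect_equal(back_aln$sequence, fix$alignment$sequence)
  back_cal <- read_calibrations(paths["calibrations"])
  expect_equal(back_cal$min_ma, fix$calibrations$min_ma, tolerance = 1e-6)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$duplication_label, "duplication")
  expect_equal(truth$sigma2, fix$truth$sigma2)
})
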