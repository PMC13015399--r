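test_that("the coexistence diagram has 11 sectors at pi0 = 0.4 and 0.6", {
  pd <- phase_diagram(0.4, n_grid = 121)
  expect_equal(count_sectors(pd), 11)
  pd6 <- phase_diagram(0.6, n_grid = 121)
  expect_equal(count_sectors(pd6), 11)
})

test_that("sector counts never exceed the 12-ordering combinatorial bound", {
  # fixing pi0 != 0 pins the relative order of the two genotype-0 pairs,
  # halving the 4! = 24 permutations
  for (pi0 in c(0.15, 0.3, 0.45, 0.7, 0.85)) {
    pd <- phase_diagram(pi0, n_grid = 61)
    expect_lte(count_sectors(pd), 12)
    lab <- pd$label[!pd$boundary]
    g0_first <- grepl("g0p1.*g0p0", lab) # pi0 < 0.5: f00 < f01 everywhere
    if (pi0 < 0.5) expect_true(all(g0_first)) else expect_true(!any(g0_first))
  }
})

test_that("sector count is robust across fitness ratios", {
  for (ratio in c(1.5, 2, 4)) {
    pd <- phase_diagram(0.4, X0 = 0.1, X1 = 0.1 / ratio, n_grid = 101)
    expect_equal(count_sectors(pd), 11)
  }
})

test_that("pi0 = 0.5 degenerates to a fully tied diagram", {
  # the structural tie f00 = f01 holds in every cell (phenotype assignment of
  # genotype 0 is symmetric), so the whole plane is boundary-flagged and no
  # strict ordering sector remains
  n <- 61
  pd <- phase_diagram(0.5, n_grid = n)
  expect_true(all(pd$boundary))
  expect_equal(count_sectors(pd), 0)
  for (cell in list(c(10, 3), c(31, 50), c(55, 20))) {
    eq <- equilibrium_2x2(0.5, pd$pi1[cell[1]], pd$mu[cell[2]], 0.1, 0.05)
    expect_equal(eq$feq[["g0p0"]], eq$feq[["g0p1"]])
  }
})

test_that("a flat landscape is ordered by mapping probabilities alone", {
  # with X0 = X1 both genotypes grow identically, so mutation strength drops
  # out: every grid row (fixed pi1) carries one label for all mu, and the
  # orderings follow the mapping probabilities (0.2, 0.3, pi1/2, (1-pi1)/2)
  pd <- phase_diagram(0.4, X0 = 0.1, X1 = 0.1, n_grid = 61)
  expect_true(all(apply(pd$label, 1, function(r) length(unique(r)) == 1)))
  expect_equal(count_sectors(pd), 4)
  i <- which.min(abs(pd$pi1 - 0.9))
  expect_equal(pd$label[i, 1], "g1p0>g0p1>g0p0>g1p1")
  i2 <- which.min(abs(pd$pi1 - 0.1))
  expect_equal(pd$label[i2, 1], "g1p1>g0p1>g0p0>g1p0")
})

test_that("there are six pairwise boundary relations and curves sit on ties", {
  bc <- boundary_curves(0.4, pi1_grid = ((1:21) - 0.5) / 21, n_scan = 101)
  # all 6 unordered pairs are examined; those crossing this window appear
  expect_lte(length(unique(bc$pair)), 6)
  expect_gte(length(unique(bc$pair)), 4)
  feq_at <- function(p1, mu) equilibrium_2x2(0.4, p1, mu, 0.1, 0.05)$feq
  for (r in sample(nrow(bc), min(nrow(bc), 40))) {
    f <- feq_at(bc$pi1[r], bc$mu[r])
    ij <- strsplit(bc$pair[r], "=")[[1]]
    expect_lt(abs(f[[ij[1]]] - f[[ij[2]]]), 1e-9)
  }
})

test_that("boundary curves coincide with label changes of the grid diagram", {
  n <- 61
  pd <- phase_diagram(0.4, n_grid = n)
  bc <- boundary_curves(0.4, pi1_grid = pd$pi1[seq(3, n - 2, by = 6)],
                        n_scan = 201)
  cell <- 1 / n
  for (r in seq_len(nrow(bc))) {
    i <- which.min(abs(pd$pi1 - bc$pi1[r]))
    j <- findInterval(bc$mu[r], c(0, pd$mu + cell / 2))
    js <- unique(pmin(pmax(c(j - 1, j, j + 1), 1), n))
    labs <- pd$label[i, js]
    flag <- pd$boundary[i, js]
    # within one cell of the root the grid labels change or a tie is flagged
    expect_true(length(unique(labs)) > 1 || any(flag))
  }
})

test_that("empirical simulator orderings agree with theory off the boundaries", {
  # scaled-down lattice; cells with comfortable frequency gaps only
  pi1s <- c(0.15, 0.5, 0.85)
  mus <- c(0.15, 0.5, 0.85)
  agree <- 0; total <- 0
  for (p1 in pi1s) for (mu in mus) {
    eq <- equilibrium_2x2(0.4, p1, mu, 0.1, 0.05)
    if (min(abs(diff(sort(eq$feq)))) < 0.03) next
    m <- build_two_by_two(0.4, p1, mu, 0.1, 0.05, N = 1e4)
    trs <- run_prosed(m, matrix(0.25, 2, 2), n_dilutions = 300, dt = 1,
                      n_trials = 3, base_seed = round(1e4 * p1 + 100 * mu),
                      record_every = 10, engine = "batch")
    es <- ensemble_stats(trs)
    tail_mean <- apply(es$mean[es$dilution >= 200, , ], c(2, 3), mean)
    emp <- ordering_label(as.vector(t(tail_mean)))$label
    total <- total + 1
    agree <- agree + (emp == ordering_label(eq)$label)
  }
  expect_gte(total, 5)
  expect_gte(agree / total, 0.95)
})
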