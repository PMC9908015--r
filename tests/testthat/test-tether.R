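test_that("tether specs encode the composite chain geometry", {
  # unbound: linker | 66-nt ssDNA | linker
  u <- build_tether_spec(state = "unbound")
  expect_equal(nrow(u$segments), 3)
  expect_equal(u$total_contour, 66 * 0.63 + 2 * 1.25)

  # 66 nt at 0.63 nm/nt with zero-length linkers: ssDNA contour 41.58 nm
  u0 <- build_tether_spec(linker_contour = 0)
  expect_equal(u0$total_contour, 41.58)

  # bound: rigid 3-nm complex flanked by two 15-nt arms
  b <- build_tether_spec(state = "bound", endotoxin_length = 3)
  expect_equal(b$segments$label,
               c("linker_5p", "ssDNA_5p", "complex", "ssDNA_3p", "linker_3p"))
  expect_equal(b$segments$contour_length[b$segments$label == "complex"], 3)
  expect_equal(b$segments$contour_length[b$segments$label == "ssDNA_5p"],
               15 * 0.63)
  expect_true(b$segments$rigid[b$segments$label == "complex"])

  # degenerate fold: empty binding region at zero complex length keeps the
  # unbound contour
  d <- build_tether_spec(state = "bound", endotoxin_length = 0,
                         binding_region_nt = 0)
  expect_equal(d$total_contour, u$total_contour)
})

test_that("tether spec construction rejects invalid input", {
  expect_error(build_tether_spec(sequence = "ACGTX"), "unknown base")
  expect_error(build_tether_spec(state = "bound", endotoxin_length = 5),
               "\\[2, 4\\]")
  expect_error(build_tether_spec(state = "bound", endotoxin_length = 1.5),
               "\\[2, 4\\]")
  # a tether shorter than one Kuhn link cannot be discretised
  expect_error(
    sample_chain_conformations(
      build_tether_spec(sequence = "A", linker_contour = 0),
      n_chains = 10, seed = 1),
    "Kuhn link")
  expect_error(
    sample_chain_conformations(build_tether_spec(), n_chains = 10),
    "seed")
})

test_that("a single rigid rod samples uniformly over the upper hemisphere", {
  rod <- tether_spec(segment_spec("rod", 5, rigid = TRUE))
  ens <- sample_chain_conformations(rod, n_chains = 2e4, seed = 42)
  # uniform hemisphere orientation makes z uniform on [0, L]: mean L/2
  expect_equal(mean(ens$z_nm), 2.5, tolerance = 0.02)
  expect_lt(ks_distance(ens$z_nm, stats::qunif(stats::ppoints(2e4), 0, 5)),
            0.02)
})

test_that("sampling is deterministic under a fixed seed", {
  spec <- build_tether_spec()
  a <- sample_chain_conformations(spec, n_chains = 500, seed = 7)
  b <- sample_chain_conformations(spec, n_chains = 500, seed = 7)
  expect_identical(a$z_nm, b$z_nm)
  c <- sample_chain_conformations(spec, n_chains = 500, seed = 8)
  expect_false(identical(a$z_nm, c$z_nm))
})

test_that("bound tethers sit lower than unbound ones at every seed", {
  u <- build_tether_spec(state = "unbound")
  for (seed in 1:3) {
    mu <- mean(sample_chain_conformations(u, n_chains = 1e4,
                                          seed = seed)$z_nm)
    for (el in c(2, 3, 4)) {
      b <- build_tether_spec(state = "bound", endotoxin_length = el)
      mb <- mean(sample_chain_conformations(b, n_chains = 1e4,
                                            seed = seed)$z_nm)
      expect_lt(mb, mu)
    }
  }
})

test_that("mean height grows with contour length in the unbound state", {
  seqs <- c(substr(rd1_sequence(), 1, 22), substr(rd1_sequence(), 1, 44),
            rd1_sequence())
  means <- vapply(seqs, function(s) {
    spec <- build_tether_spec(sequence = s, linker_contour = 0)
    mean(sample_chain_conformations(spec, n_chains = 5e3, seed = 1)$z_nm)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("end-constrained free chains match the reflected-Gaussian oracle", {
  spec <- build_tether_spec(linker_contour = 0)
  ens <- sample_chain_conformations(spec, n_chains = 2e4, seed = 3,
                                    constraint = "end_only")
  # brute-force oracle: unconstrained freely jointed walks, final z
  # reflected into the half space
  lens <- plasmonruler:::.tether_links(spec)
  set.seed(99)
  oracle <- numeric(0)
  for (chunk in 1:25) {
    m <- matrix(stats::runif(2e4 * length(lens), -1, 1), 2e4)
    oracle <- c(oracle, abs(as.vector(m %*% lens)))
  }
  expect_lt(ks_distance(ens$z_nm, oracle), 0.02)
})

test_that("summarize_z returns plain moments and a unit-mass histogram", {
  s <- summarize_z(rep(4.2, 100))
  expect_equal(s$mean, 4.2)
  expect_equal(s$sd, 0)

  ens <- sample_chain_conformations(build_tether_spec(), n_chains = 5e3,
                                    seed = 2)
  s2 <- summarize_z(ens, bin_width = 0.25)
  expect_equal(sum(s2$histogram$density) * 0.25, 1, tolerance = 1e-12)
  expect_equal(s2$mean, mean(ens$z_nm))
  expect_error(summarize_z(numeric(0)), "empty")
})
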