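# Toy structures, planted Potts models, and Gibbs-sampled alignments.

test_that("toy chains satisfy geometry and determinism contracts", {
  st <- generate_structure(2, seed = 1)
  D <- structure_distances(st)
  expect_equal(D[1, 2], st$chain_step, tolerance = 1e-6)
  expect_true(structure_contacts(st)[1, 2])   # 3.8 < 8

  st1 <- generate_structure(40, seed = 9)
  st2 <- generate_structure(40, seed = 9)
  expect_identical(st1$coords, st2$coords)

  # consecutive-site spacing and excluded volume
  D40 <- structure_distances(st1)
  steps <- D40[cbind(1:39, 2:40)]
  expect_equal(steps, rep(3.8, 39), tolerance = 1e-6)
  offd <- D40[upper.tri(D40)]
  expect_gte(min(offd), 2.0)

  # contact density at L = 50 sits in the calibrated band
  frac <- vapply(1:5, function(s) {
    cm <- structure_contacts(generate_structure(50, seed = s))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  expect_true(all(frac > 0.02 & frac < 0.25))

  # L >= 30 chains always carry at least one long-range contact
  for (s in 1:5) {
    cm <- structure_contacts(generate_structure(30, seed = 20 + s))
    sep <- abs(outer(1:30, 1:30, "-"))
    expect_true(any(cm & sep >= 24))
  }
})

test_that("planted couplings live exactly on the contact map", {
  st <- generate_structure(20, seed = 3)
  cfg <- sim_config(L = 20, N = 10, seed = 3)
  model <- plant_potts(st, cfg)
  cm <- structure_contacts(st)

  for (r in seq_len(min(10, nrow(model$planted_pairs)))) {
    i <- model$planted_pairs[r, 1]; j <- model$planted_pairs[r, 2]
    expect_equal(sqrt(sum(potts_coupling(model, i, j)^2)),
                 cfg$coupling_strength * sqrt(21))
  }
  noncontact <- which(!cm & upper.tri(cm), arr.ind = TRUE)
  for (r in seq_len(min(10, nrow(noncontact)))) {
    expect_equal(max(abs(potts_coupling(model, noncontact[r, 1],
                                        noncontact[r, 2]))), 0)
  }

  # zero coupling strength: J identically zero
  cfg0 <- sim_config(L = 20, N = 10, coupling_strength = 0, seed = 3)
  expect_equal(max(abs(plant_potts(st, cfg0)$W)), 0)
})

test_that("Gibbs sampling reproduces known single-site distributions", {
  # free model (J = 0, h = 0): uniform column frequencies within 3 SE
  L <- 4; N <- 5000
  free <- structure(list(h = matrix(0, L, 21),
                         W = matrix(0, 21 * L, 21 * L), L = L,
                         planted_pairs = matrix(integer(0), 0, 2)),
                    class = "coev_potts")
  cfg <- sim_config(L = L, N = N, burn_in = 20, seed = 5)
  aln <- gibbs_sample_msa(free, cfg)
  f <- msa_frequencies(aln)
  se <- sqrt((1 / 21) * (20 / 21) / N)
  expect_lt(max(abs(f$f1 - 1 / 21)), 3.6 * se)

  # strong field at one site: frequencies match the softmax closed form
  h <- matrix(0, L, 21); h[2, 5] <- 2
  field <- free; field$h <- h
  aln2 <- gibbs_sample_msa(field, sim_config(L = L, N = N, burn_in = 20,
                                             seed = 6))
  f2 <- msa_frequencies(aln2)
  pexp <- exp(h[2, ]) / sum(exp(h[2, ]))
  expect_lt(max(abs(f2$f1[2, ] - pexp)), 4 * sqrt(max(pexp) * (1 - max(pexp)) / N))

  # determinism
  aln3 <- gibbs_sample_msa(field, sim_config(L = L, N = 50, burn_in = 20,
                                             seed = 6))
  aln4 <- gibbs_sample_msa(field, sim_config(L = L, N = 50, burn_in = 20,
                                             seed = 6))
  expect_identical(aln3$codes, aln4$codes)
})

test_that("planted pair frequencies concentrate on favored state pairs", {
  st <- generate_structure(8, seed = 13)
  cfg <- sim_config(L = 8, N = 1500, coupling_strength = 2, field_scale = 0,
                    burn_in = 60, seed = 13)
  model <- plant_potts(st, cfg)
  aln <- gibbs_sample_msa(model, cfg)
  f <- msa_frequencies(aln)
  cm <- structure_contacts(st)
  pp <- model$planted_pairs[1, ]
  i <- pp[1]; j <- pp[2]
  blk <- f$f2[((i - 1) * 21 + 1):(i * 21), ((j - 1) * 21 + 1):(j * 21)]
  fav <- potts_coupling(model, i, j) > 0
  # mass on favored cells far exceeds the uniform expectation of 1/21
  expect_gt(sum(blk[fav]), 3 * (1 / 21))
  # a non-contacting, non-adjacent pair stays near independence
  nc <- which(!cm & abs(outer(1:8, 1:8, "-")) > 1, arr.ind = TRUE)
  if (nrow(nc) > 0) {
    i2 <- nc[1, 1]; j2 <- nc[1, 2]
    blk2 <- f$f2[((i2 - 1) * 21 + 1):(i2 * 21), ((j2 - 1) * 21 + 1):(j2 * 21)]
    indep <- outer(f$f1[i2, ], f$f1[j2, ])
    expect_lt(max(abs(blk2 - indep)), 0.06)
  }
})

test_that("two-site reduction matches the exact Boltzmann distribution", {
  # L = 2, couplings confined to two states: long-run pair frequencies
  # should match exp(h_i(a) + h_j(b) + J_ij(a,b)) / Z within sampling error
  L <- 2
  h <- matrix(-4, L, 21); h[, 1:2] <- 0    # push mass onto states 1-2
  W <- matrix(0, 42, 42)
  J <- matrix(0, 21, 21); J[1, 1] <- 1; J[2, 2] <- 1
  W[1:21, 22:42] <- J; W[22:42, 1:21] <- t(J)
  model <- structure(list(h = h, W = W, L = L,
                          planted_pairs = cbind(1L, 2L)),
                     class = "coev_potts")
  N <- 6000
  aln <- gibbs_sample_msa(model, sim_config(L = L, N = N, burn_in = 40,
                                            seed = 17))
  # exact Boltzmann over the 21 x 21 state space
  E <- outer(h[1, ], h[2, ], "+") + J
  Pexact <- exp(E) / sum(exp(E))
  f <- msa_frequencies(aln)
  Pemp <- f$f2[1:21, 22:42]
  se <- sqrt(Pexact * (1 - Pexact) / N)
  expect_true(all(abs(Pemp - Pexact) <= 3 * se + 1e-3))
})

test_that("training examples carry matching shapes and symmetric labels", {
  st <- generate_structure(12, seed = 2)
  cfg <- sim_config(L = 12, N = 40, burn_in = 30, seed = 2)
  aln <- gibbs_sample_msa(plant_potts(st, cfg), cfg)
  ex <- make_training_example(st, aln, plm_maxit = 10)
  expect_named(ex$features, c("cov", "pre", "plm"))
  for (t in ex$features) expect_identical(dim(t), c(12L, 12L, 441L))
  expect_identical(dim(ex$labels$bins), c(12L, 12L))
  expect_equal(ex$labels$bins, t(ex$labels$bins))
  expect_identical(diag(ex$labels$bins), rep(0L, 12))

  aln_bad <- coev_alignment(matrix(0L, 3, 5))
  expect_error(make_training_example(st, aln_bad, plm_maxit = 5), "mismatch")
})
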