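# Distance binning, labels, network forward/backward, losses, training.

random_tensors <- function(L, features = c("cov", "pre", "plm"), seed = 1) {
  set.seed(seed)
  out <- lapply(features, function(f) array(rnorm(L * L * 441), c(L, L, 441)))
  names(out) <- features
  out
}

test_that("distance discretization follows the 12-bin half-open scheme", {
  expect_identical(discretize_distance(4.2), 0L)
  expect_identical(discretize_distance(7.999), 3L)
  expect_identical(discretize_distance(15.0), 11L)
  expect_identical(discretize_distance(5.0), 1L)
  expect_identical(discretize_distance(14.999), 10L)
  expect_identical(discretize_distance(0), 0L)
  expect_error(discretize_distance(-1), "finite")
  expect_error(discretize_distance(NaN), "finite")

  # bin membership in the first four bins is exactly the d < 8 contact rule
  set.seed(2)
  d <- runif(10000, 0, 30)
  bins <- discretize_distance(d)
  expect_identical(bins %in% bin_scheme()$contact_bins, d < 8)
})

test_that("labels from coordinates respect the strict 8 A contact rule", {
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  lab <- labels_from_structure(coords)
  expect_true(lab$contacts[1, 2])
  expect_true(lab$contacts[2, 3])
  expect_true(lab$contacts[1, 3])          # 7.6 < 8
  expect_identical(lab$bins[1, 3], 3L)     # 7 <= 7.6 < 8

  # exactly 8.0 is not a contact
  coords8 <- rbind(c(0, 0, 0), c(8, 0, 0))
  expect_false(labels_from_structure(coords8)$contacts[1, 2])

  # missing residues are masked out everywhere
  coords_na <- rbind(c(0, 0, 0), c(NA, NA, NA), c(7.6, 0, 0))
  lab_na <- labels_from_structure(coords_na)
  expect_false(any(lab_na$mask[2, ]))
  expect_false(any(lab_na$mask[, 2]))
  expect_true(lab_na$mask[1, 3])
  expect_error(labels_from_structure(rbind(c(0, 0, 0), c(NA, NA, NA))),
               "fewer than 2")

  # labels symmetric; contact flag consistent with contact bins
  set.seed(3)
  lab_r <- labels_from_structure(generate_structure(15, seed = 3)$coords)
  expect_equal(lab_r$bins, t(lab_r$bins))
  m <- lab_r$mask
  expect_identical(lab_r$bins[m] %in% bin_scheme()$contact_bins,
                   lab_r$contacts[m])
})

test_that("the model builds, outputs a simplex, and symmetrizes", {
  cfg <- net_config(channels_hidden = 4, blocks_per_branch = 1,
                    fusion_blocks = 1, seed = 2)
  m <- build_model(cfg)
  expect_identical(cfg$fusion_channels_in, 12L)   # 3 x 4 channels

  tens <- random_tensors(16)
  pred <- model_forward(m, tens)
  expect_identical(dim(pred$probs), c(16L, 16L, 12L))
  expect_lt(max(abs(apply(pred$probs, c(1, 2), sum) - 1)), 1e-6)
  expect_true(all(pred$probs >= 0 & pred$probs <= 1))
  expect_equal(pred$probs, aperm(pred$probs, c(2, 1, 3)))

  # deterministic parameter count; doubling channels increases it
  m2 <- build_model(net_config(channels_hidden = 8, blocks_per_branch = 1,
                               fusion_blocks = 1, seed = 2))
  expect_gt(n_parameters(m2), n_parameters(m))
  expect_identical(n_parameters(build_model(cfg)), n_parameters(m))

  expect_error(model_forward(m, tens[c("cov", "pre")]), "must include")
})

test_that("symmetrized output is invariant to transposing the input maps", {
  # transposing the pair axes with the channel remap 21a+b -> 21b+a is the
  # same protein seen in the (j, i) orientation
  cfg <- net_config(channels_hidden = 4, blocks_per_branch = 1,
                    fusion_blocks = 1, dropout = 0, seed = 4)
  m <- build_model(cfg)
  tens <- lapply(random_tensors(9, seed = 5), function(t) {
    # make each tensor block-symmetric like a real feature
    tensor_to_blocks(t) |> (\(M) (M + t(M)) / 2)() |> assemble_feature_tensor()
  })
  chan_remap <- as.vector(t(matrix(1:441, 21, 21)))
  tens_t <- lapply(tens, function(t) aperm(t, c(2, 1, 3))[, , chan_remap])
  p1 <- model_forward(m, tens)$probs
  p2 <- model_forward(m, tens_t)$probs
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("losses satisfy their closed-form identities and loop oracle", {
  L <- 10
  lab <- labels_from_structure(generate_structure(L, seed = 6)$coords)
  n_pairs <- sum(lab$mask)

  # uniform prediction: loss is T log 12
  unif <- array(1 / 12, c(L, L, 12))
  expect_equal(distance_nll_loss(unif, lab), n_pairs * log(12))

  # perfect prediction: loss 0
  perfect <- array(0, c(L, L, 12))
  for (i in 1:L) for (j in 1:L) {
    b <- if (is.na(lab$bins[i, j])) 1L else lab$bins[i, j] + 1L
    perfect[i, j, b] <- 1
  }
  expect_equal(distance_nll_loss(perfect, lab), 0)
  expect_equal(binary_bce_loss(perfect, lab), 0, tolerance = 1e-6)

  # p = 0.5 contact probability everywhere: BCE is T log 2
  half <- array(0, c(L, L, 12)); half[, , 1] <- 0.5; half[, , 12] <- 0.5
  expect_equal(binary_bce_loss(half, lab), n_pairs * log(2))

  # random prediction matches the scalar loop oracle
  set.seed(7)
  raw <- array(runif(L * L * 12), c(L, L, 12))
  raw <- raw / array(rep(apply(raw, c(1, 2), sum), 12), c(L, L, 12))
  expect_equal(distance_nll_loss(raw, lab), nll_loop_oracle(raw, lab),
               tolerance = 1e-9)
  expect_error(distance_nll_loss(raw, list(bins = lab$bins,
                                           mask = lab$mask & FALSE)),
               "empty")
})

test_that("contact probability is the mass of the first four bins", {
  L <- 5
  p <- array(0, c(L, L, 12))
  p[, , 1:4] <- 0.1; p[, , 12] <- 0.6
  expect_equal(contact_probability(p), matrix(0.4, L, L))
  p0 <- array(0, c(L, L, 12)); p0[, , 12] <- 1
  expect_equal(contact_probability(p0), matrix(0, L, L))
  p1 <- array(0, c(L, L, 12)); p1[, , 1] <- 1
  expect_equal(contact_probability(p1), matrix(1, L, L))
})

test_that("network gradients match finite differences", {
  cfg <- net_config(channels_hidden = 3, blocks_per_branch = 1,
                    fusion_blocks = 1, dropout = 0, seed = 8)
  m <- build_model(cfg)
  L <- 7
  tens <- random_tensors(L, seed = 9)
  lab <- labels_from_structure(generate_structure(L, seed = 9)$coords)
  for (loss_fn in list(distance_nll_loss, binary_bce_loss)) {
    pred <- model_forward(m, tens, keep_cache = TRUE)
    lg <- loss_fn(pred, lab, gradient = TRUE)
    grads <- model_backward(m, attr(pred, "cache"), lg$dP)
    set.seed(10)
    for (nm in sample(ls(m$params), 6)) {
      v <- m$params[[nm]]
      k <- sample(length(v), 1)
      eps <- 1e-5
      m$params[[nm]][k] <- v[k] + eps
      f1 <- loss_fn(model_forward(m, tens), lab)
      m$params[[nm]][k] <- v[k] - eps
      f2 <- loss_fn(model_forward(m, tens), lab)
      m$params[[nm]][k] <- v[k]
      fd <- (f1 - f2) / (2 * eps)
      denom <- max(abs(fd), 1e-4)
      expect_lt(abs(fd - grads[[nm]][k]) / denom, 1e-3)
    }
  }
})

test_that("a tiny network overfits one example and trains deterministically", {
  set.seed(11)
  scfg <- sim_config(L = 16, N = 60, burn_in = 40, seed = 11)
  sim <- simulate_protein(scfg)
  ex <- make_training_example(sim$structure, sim$alignment, plm_maxit = 30)
  cfg <- net_config(channels_hidden = 8, blocks_per_branch = 1,
                    fusion_blocks = 1, dropout = 0, seed = 12)
  m <- build_model(cfg)
  fit <- train_model(m, list(ex), epochs = 150, lr = 5e-3, seed = 12)
  h <- fit$history$loss
  expect_lt(h[length(h)], 0.05 * h[1])

  # moving-average loss is non-increasing up to a small tolerance band
  ma <- stats::filter(h, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) < 0.05 * h[1]))

  # same seed, same data: identical final loss
  fit2 <- train_model(build_model(cfg), list(ex), epochs = 5, lr = 5e-3,
                      seed = 12)
  fit3 <- train_model(build_model(cfg), list(ex), epochs = 5, lr = 5e-3,
                      seed = 12)
  expect_equal(tail(fit2$history$loss, 1), tail(fit3$history$loss, 1),
               tolerance = 1e-9)

  # the input model's parameters are untouched by training
  expect_equal(as.list(m$params), as.list(build_model(cfg)$params),
               tolerance = 1e-12)

  # tidy/glance accessors
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(glance(fit)$loss_type, "distance")
})
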