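# COV, PRE, PLM features and the Frobenius/APC pair scoring.

test_that("covariance feature matches hand counts and is block-symmetric", {
  # identical sequences: S is exactly zero
  cv0 <- compute_cov(msa_frequencies(coev_alignment(rep("ACDE", 4))))
  expect_equal(max(abs(cv0$S)), 0)

  # two-state toy: S[0,1,A,A] = 0.5 - 0.25, S[0,1,A,C] = 0 - 0.25
  cv <- compute_cov(msa_frequencies(coev_alignment(c("AA", "CC"))))
  expect_equal(cv$S[1, 22], 0.25)
  expect_equal(cv$S[1, 23], -0.25)

  # global symmetry S[i,j,a,b] = S[j,i,b,a] and zero block margins
  set.seed(11)
  aln <- coev_alignment(matrix(sample(0:20, 8 * 5, TRUE), 8, 5))
  cvr <- compute_cov(msa_frequencies(aln, weights = runif(8, 0.1, 1)))
  expect_equal(cvr$S, t(cvr$S), tolerance = 1e-12)
  for (i in 1:5) for (j in 1:5) {
    blk <- cvr$S[((i - 1) * 21 + 1):(i * 21), ((j - 1) * 21 + 1):(j * 21)]
    expect_lt(max(abs(rowSums(blk))), 1e-9)
    expect_lt(max(abs(colSums(blk))), 1e-9)
  }
})

test_that("closed-form precision solves the ridge objective exactly", {
  rho <- exp(-6)
  # S = identity: Theta = theta* I with 2 rho theta^2 + theta - 1 = 0
  pre_i <- compute_pre(diag(1, 42), rho = rho, shrinkage = 0)
  theta_star <- (-1 + sqrt(1 + 8 * rho)) / (4 * rho)
  expect_equal(pre_i$theta, diag(theta_star, 42), tolerance = 1e-10)

  # rho -> 0+: Theta approaches S^-1 for well-conditioned S
  set.seed(5)
  A <- matrix(rnorm(64), 8, 8); S <- crossprod(A) / 8 + diag(8)
  pre_small <- compute_pre(S, rho = 1e-12, shrinkage = 0)
  expect_equal(pre_small$theta, solve(S), tolerance = 1e-6)

  # stationarity residual vanishes at the solution
  set.seed(6)
  B <- matrix(rnorm(100), 10, 10); S2 <- (B + t(B)) / 2
  pre2 <- compute_pre(S2, shrinkage = 0)
  expect_lt(pre_stationarity_residual(pre2), 1e-6 * max(abs(S2)))
  expect_true(all(eigen(pre2$theta, symmetric = TRUE,
                        only.values = TRUE)$values > 0))

  # agreement with an independent numerical minimizer on a random
  # covariance-like matrix (the domain the estimator is used on; an
  # indefinite S sends Theta entries to ~1/(2 rho) where absolute 1e-5
  # agreement is beyond what a first-order method can deliver)
  set.seed(7)
  C <- matrix(rnorm(60), 10, 6); S3 <- crossprod(C) / 10 + diag(0.3, 6)
  pre3 <- compute_pre(S3, shrinkage = 0)
  oracle <- pre_numeric_oracle(S3, exp(-6))
  expect_lt(max(abs(pre3$theta - oracle)), 1e-5)
})

test_that("PLM analytic gradient matches central finite differences", {
  set.seed(21)
  codes <- matrix(sample(0:20, 6 * 4, TRUE), 6, 4)
  obj <- plm_objective(coev_alignment(codes))
  par <- rnorm(obj$n_par, sd = 0.1)
  g <- obj$gr(par)
  eps <- 1e-5
  idx <- c(1:30, sample(85:obj$n_par, 80))
  fd <- vapply(idx, function(k) {
    p1 <- par; p2 <- par
    p1[k] <- p1[k] + eps; p2[k] <- p2[k] - eps
    (obj$fn(p1) - obj$fn(p2)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(fd - g[idx]) / pmax(abs(fd), 1e-8)), 1e-5)
})

test_that("PLM fit is weight-scale invariant and detects coupled columns", {
  # columns 2 and 5 perfect copies, others i.i.d.: pair (2,5) dominates
  set.seed(31)
  n <- 400; l <- 6
  codes <- matrix(sample(0:19, n * l, TRUE), n, l)
  codes[, 5] <- codes[, 2]
  aln <- coev_alignment(codes)
  w <- msa_weights(aln)
  fit <- compute_plm(aln, weights = w, maxit = 200)
  sc <- apc_correct(frobenius_score(fit))
  top <- rank_contacts(sc$scores, range = "all", depth = 1)
  expect_identical(c(top$i, top$j), c(2L, 5L))

  # scaling all weights leaves the fit unchanged
  fit2 <- compute_plm(aln, weights = 10 * w, maxit = 200)
  expect_equal(fit$W, fit2$W, tolerance = 1e-8)
  expect_equal(fit$h, fit2$h, tolerance = 1e-8)

  # self-coupling blocks are exactly zero; couplings block-symmetric
  expect_equal(max(abs(potts_coupling(fit, 3, 3))), 0)
  expect_equal(potts_coupling(fit, 2, 5), t(potts_coupling(fit, 5, 2)))
})

test_that("Frobenius scores equal the elementwise norm oracle", {
  set.seed(41)
  L <- 4
  W <- matrix(0, 21 * L, 21 * L)
  blk <- matrix(rnorm(441), 21, 21)
  W[1:21, 22:42] <- blk; W[22:42, 1:21] <- t(blk)
  model <- structure(list(W = W, L = L), class = "coev_potts")

  ps <- frobenius_score(model, exclude_gap = FALSE)
  expect_equal(ps$scores[1, 2], sqrt(sum(blk^2)))
  ps20 <- frobenius_score(model, exclude_gap = TRUE)
  expect_equal(ps20$scores[1, 2], sqrt(sum(blk[1:20, 1:20]^2)))
  expect_equal(ps$scores, t(ps$scores))

  # single nonzero entry: score is its absolute value
  W2 <- matrix(0, 21 * L, 21 * L)
  W2[3, 25] <- -0.7; W2[25, 3] <- -0.7
  m2 <- structure(list(W = W2, L = L), class = "coev_potts")
  expect_equal(frobenius_score(m2, exclude_gap = FALSE)$scores[1, 2], 0.7)

  # all-zero blocks give all-zero scores
  m0 <- structure(list(W = matrix(0, 21 * L, 21 * L), L = L),
                  class = "coev_potts")
  expect_equal(max(abs(frobenius_score(m0)$scores)), 0)
})

test_that("APC removes constant background and preserves dominant pairs", {
  mk <- function(M) structure(list(scores = M, method = "plm",
                                   apc_applied = FALSE, min_separation = 1L),
                              class = "coev_pairscore")
  # constant matrix: zero after APC
  Mc <- matrix(2, 4, 4); diag(Mc) <- 0
  apc_c <- apc_correct(mk(Mc))
  expect_lt(max(abs(apc_c$scores)), 1e-12)

  # one dominant pair on constant background stays the argmax
  Md <- matrix(1, 4, 4); diag(Md) <- 0
  Md[1, 3] <- Md[3, 1] <- 5
  apc_d <- apc_correct(mk(Md))
  top <- rank_contacts(apc_d$scores, range = "all", depth = 1)
  expect_identical(c(top$i, top$j), c(1L, 3L))
  expect_equal(apc_d$scores, t(apc_d$scores))

  # APC of a rank-one (outer product) score matrix is ~ 0; the means
  # exclude the diagonal, so cancellation is only approximate and improves
  # with size
  v <- seq(0.5, 3, length.out = 30)
  Mr <- outer(v, v); diag(Mr) <- 0
  apc_r <- apc_correct(mk(Mr))
  expect_lt(max(abs(apc_r$scores)) / max(Mr), 0.05)

  expect_warning(apc_correct(mk(matrix(0, 3, 3))), "all-zero")
})

test_that("feature tensor assembly is a faithful channel reordering", {
  set.seed(51)
  L <- 7L
  aln <- coev_alignment(matrix(sample(0:20, 30 * L, TRUE), 30, L))
  cv <- compute_cov(msa_frequencies(aln))
  tens <- assemble_feature_tensor(cv)
  expect_identical(dim(tens), c(L, L, 441L))

  # round-trip
  expect_equal(tensor_to_blocks(tens), cv$S, tolerance = 0)

  # channel c = 21a + b: entry (a,b) of block (i,j)
  a <- 3L; b <- 17L; i <- 2L; j <- 6L   # 0-based states
  expect_equal(tens[i, j, 21L * a + b + 1L],
               cv$S[(i - 1L) * 21L + a + 1L, (j - 1L) * 21L + b + 1L])
  # block symmetry appears as channel transposition
  expect_equal(tens[i, j, 21L * a + b + 1L], tens[j, i, 21L * b + a + 1L])
})
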