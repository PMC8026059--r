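# The raw coevolutionary feature triplet: covariance (COV), ridge-regularized
# precision (PRE), and pseudolikelihood-maximization Potts couplings (PLM),
# plus the classical Frobenius + average-product-correction pair scoring.

#' Residue-pair covariance feature (COV)
#'
#' `S[i,j,a,b] = f_ij(a,b) - f_i(a) f_j(b)`, stored as a flattened
#' `21L x 21L` block matrix. Captures marginal (possibly transitive)
#' dependency between alignment columns.
#'
#' @param freqs A `coev_freqs` object from [msa_frequencies()].
#' @return Object of class `coev_cov` with elements `S` (21L x 21L), `L`.
#' @export
compute_cov <- function(freqs) {
  stopifnot(inherits(freqs, "coev_freqs"))
  p <- as.vector(t(freqs$f1))              # block order: state fastest
  if (length(p) != nrow(freqs$f2)) stop("f1/f2 shape mismatch")
  S <- freqs$f2 - tcrossprod(p)
  structure(list(S = S, L = freqs$L), class = "coev_cov")
}

#' Ridge-regularized precision matrix feature (PRE)
#'
#' Minimizes `G(Theta) = tr(S Theta) - log det Theta + rho * sum ||Theta_ij||^2`
#' over symmetric positive-definite matrices, in closed form: with the
#' eigendecomposition `S = U diag(lambda) U'`, the unique stationary point is
#' `Theta = U diag(theta) U'` where each `theta_k` is the positive root of
#' `2 rho theta^2 + lambda theta - 1 = 0`. An optional shrinkage step
#' `S <- (1 - gamma) S + gamma * mean(diag(S)) I` stabilizes the spectrum of
#' rank-deficient sample covariances before solving.
#'
#' @param cov A `coev_cov`, or a bare symmetric matrix.
#' @param rho Ridge strength, default `exp(-6)`.
#' @param shrinkage Shrinkage weight `gamma` in `[0, 1)`, default 0.1.
#' @return Object of class `coev_pre`: `theta` (21L x 21L SPD), `rho`,
#'   `shrinkage`, `L`.
#' @export
compute_pre <- function(cov, rho = exp(-6), shrinkage = 0.1) {
  S <- if (inherits(cov, "coev_cov")) cov$S else cov
  L <- if (inherits(cov, "coev_cov")) cov$L else NA_integer_
  stopifnot(is.matrix(S), nrow(S) == ncol(S), rho > 0,
            shrinkage >= 0, shrinkage < 1)
  if (!all(is.finite(S))) stop("non-finite entries in covariance matrix")
  if (shrinkage > 0) {
    S <- (1 - shrinkage) * S + shrinkage * mean(diag(S)) * diag(nrow(S))
  }
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- eg$values
  disc <- sqrt(lam^2 + 8 * rho)
  # positive root of 2*rho*theta^2 + lambda*theta - 1 = 0, in the
  # cancellation-free form for each sign of lambda
  theta_eig <- ifelse(lam >= 0, 2 / (lam + disc), (disc - lam) / (4 * rho))
  theta <- eg$vectors %*% (theta_eig * t(eg$vectors))
  theta <- (theta + t(theta)) / 2
  structure(list(theta = theta, rho = rho, shrinkage = shrinkage,
                 S_solved = S, L = L),
            class = "coev_pre")
}

#' Stationarity residual of a precision estimate
#'
#' Max-norm of the gradient `S - Theta^-1 + 2 rho Theta` of the regularized
#' negative log-likelihood, evaluated at the (possibly shrunk) matrix the
#' solver actually inverted. Near zero at the exact solution.
#'
#' @param pre A `coev_pre`.
#' @return Scalar max-absolute residual.
#' @export
pre_stationarity_residual <- function(pre) {
  stopifnot(inherits(pre, "coev_pre"))
  G <- pre$S_solved - solve(pre$theta) + 2 * pre$rho * pre$theta
  max(abs(G))
}

# ---- pseudolikelihood maximization (PLM) ----------------------------------

# Parameter vector layout: c(h) with h an L x 21 matrix packed state-fastest
# (as.vector(t(h))), followed by the L(L-1)/2 upper coupling blocks J_ij
# (i < j, 21 x 21 each, column-major). The full coupling matrix W is block
# symmetric, W[block i, block j] = J_ij = t(J_ji), with zero diagonal blocks.

plm_n_par <- function(L) N_STATES * L + (L * (L - 1) / 2) * N_STATES^2

plm_unpack <- function(par, L) {
  ns <- N_STATES
  hvec <- par[seq_len(ns * L)]
  W <- matrix(0, ns * L, ns * L)
  off <- ns * L
  blk <- ns * ns
  for (i in seq_len(L - 1L)) {
    bi <- block_idx(i)
    for (j in (i + 1L):L) {
      Jij <- matrix(par[(off + 1L):(off + blk)], ns, ns)
      bj <- block_idx(j)
      W[bi, bj] <- Jij
      W[bj, bi] <- t(Jij)
      off <- off + blk
    }
  }
  list(hvec = hvec, W = W)
}

plm_pack_grad <- function(gh, A, lambda_J, W, L) {
  ns <- N_STATES
  blk <- ns * ns
  out <- numeric(plm_n_par(L))
  out[seq_len(ns * L)] <- gh
  off <- ns * L
  for (i in seq_len(L - 1L)) {
    bi <- block_idx(i)
    for (j in (i + 1L):L) {
      bj <- block_idx(j)
      g <- A[bi, bj] + t(A[bj, bi]) + 2 * lambda_J * W[bi, bj]
      out[(off + 1L):(off + blk)] <- g
      off <- off + blk
    }
  }
  out
}

#' Weighted negative log-pseudolikelihood and its gradient
#'
#' Builds closures evaluating the regularized negative log-pseudolikelihood
#' of a Potts model on an alignment —
#' `-sum_m w_m sum_l log P(sigma_l^m | sigma_{-l}^m) + lambda_h ||h||^2 +
#' lambda_J sum_{i<j} ||J_ij||^2` — where each site conditional is the
#' softmax of `h_l(q) + sum_{k != l} J_lk(q, sigma_k^m)` over the 21 states.
#' Used by [compute_plm()] and directly testable against finite differences.
#'
#' @param aln A `coev_alignment`.
#' @param weights Sequence weights (default: identity-threshold 0.8 weights).
#'   Internally rescaled by their maximum, so scaling all weights by a
#'   constant does not change the fit.
#' @param lambda_h L2 penalty on fields, default 0.01.
#' @param lambda_J L2 penalty per coupling block, default `0.2 * (L - 1)`.
#' @return List with `fn(par)`, `gr(par)`, `n_par`, `L`, and `unpack(par)`.
#' @export
plm_objective <- function(aln, weights = NULL, lambda_h = 0.01, lambda_J = NULL) {
  stopifnot(inherits(aln, "coev_alignment"))
  n <- nrow(aln$codes); L <- ncol(aln$codes)
  if (L < 2L) stop("pseudolikelihood needs at least 2 positions")
  if (is.null(weights)) weights <- msa_weights(aln)
  stopifnot(length(weights) == n, all(weights >= 0), max(weights) > 0)
  w <- weights / max(weights)
  if (is.null(lambda_J)) lambda_J <- 0.2 * (L - 1)
  X <- one_hot_encode(aln)
  ns <- N_STATES
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL

  evaluate <- function(par) {
    up <- plm_unpack(par, L)
    hvec <- up$hvec; W <- up$W
    Z <- X %*% W
    Z <- Z + matrix(hvec, n, ns * L, byrow = TRUE)
    Zt <- t(Z)
    dim(Zt) <- c(ns, L * n)
    mx <- Zt[1L, ]
    for (q in 2:ns) mx <- pmax(mx, Zt[q, ])
    E <- exp(Zt - rep(mx, each = ns))
    ssum <- colSums(E)
    logZ <- log(ssum) + mx
    dim(logZ) <- c(L, n)
    nld <- sum(w * (colSums(logZ) - rowSums(Z * X)))
    # W holds each J_ij twice (as J_ij and t(J_ij)), so sum(W^2)/2 is the
    # penalty sum over i < j blocks
    pen <- lambda_h * sum(hvec^2) + lambda_J * sum(W^2) / 2
    P <- E / rep(ssum, each = ns)
    dim(P) <- c(ns * L, n)
    P <- t(P)
    R <- (P - X) * w
    gh <- colSums(R) + 2 * lambda_h * hvec
    A <- crossprod(X, R)
    list(value = nld + pen, grad = plm_pack_grad(gh, A, lambda_J, W, L))
  }

  get <- function(par) {
    if (is.null(cache$par) || !identical(par, cache$par)) {
      cache$res <- evaluate(par)
      cache$par <- par
    }
    cache$res
  }

  list(
    fn = function(par) get(par)$value,
    gr = function(par) get(par)$grad,
    n_par = plm_n_par(L),
    L = L,
    unpack = function(par) plm_unpack(par, L)
  )
}

#' Fit a Potts model by pseudolikelihood maximization (PLM)
#'
#' Minimizes the weighted, L2-regularized negative log-pseudolikelihood with
#' L-BFGS-B from a zero start. The returned coupling matrix is block
#' symmetric by construction (`J_ij = t(J_ji)`), with zero self-coupling
#' blocks; the raw couplings are the PLM feature fed to the network.
#'
#' @inheritParams plm_objective
#' @param maxit Iteration cap, default 500.
#' @param pgtol Projected-gradient tolerance, default 1e-4.
#' @return Object of class `c("coev_potts_fit", "coev_potts")`: `h` (L x 21),
#'   `W` (21L x 21L block-symmetric couplings), `L`, `lambda_h`, `lambda_J`,
#'   `nll`, `converged`, `iterations`, `message`.
#' @export
compute_plm <- function(aln, weights = NULL, lambda_h = 0.01, lambda_J = NULL,
                        maxit = 500, pgtol = 1e-4) {
  obj <- plm_objective(aln, weights, lambda_h, lambda_J)
  L <- obj$L
  if (is.null(lambda_J)) lambda_J <- 0.2 * (L - 1)
  par0 <- numeric(obj$n_par)
  opt <- stats::optim(par0, fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, pgtol = pgtol, factr = 1e7))
  if (opt$convergence != 0 && opt$convergence != 1) {
    warning(sprintf("PLM optimizer stopped abnormally: %s", opt$message))
  }
  up <- plm_unpack(opt$par, L)
  h <- t(matrix(up$hvec, N_STATES, L))
  colnames(h) <- coev_alphabet()
  structure(
    list(h = h, W = up$W, L = L, lambda_h = lambda_h, lambda_J = lambda_J,
         nll = opt$value, converged = opt$convergence == 0,
         iterations = opt$counts[["function"]], message = opt$message),
    class = c("coev_potts_fit", "coev_potts")
  )
}

#' Extract one coupling block
#' @param model A `coev_potts`.
#' @param i,j Positions (1-based).
#' @return 21 x 21 matrix `J_ij(a, b)`.
#' @export
potts_coupling <- function(model, i, j) {
  model$W[block_idx(i), block_idx(j)]
}

# ---- classical pair scoring (baseline) ------------------------------------

# blockwise Frobenius norms of a 21L x 21L matrix; optionally over the
# 20 x 20 gap-free sub-blocks.
block_frobenius <- function(M, L, exclude_gap = TRUE) {
  keep <- if (exclude_gap) seq_len(N_STATES - 1L) else seq_len(N_STATES)
  G <- matrix(0, N_STATES * L, L)          # aggregate columns into blocks
  for (j in seq_len(L)) G[block_idx(j)[keep], j] <- 1
  SQ <- M^2
  out <- sqrt(t(G) %*% SQ %*% G)
  # rows of t(G) pick row-blocks; quadratic form sums the kept sub-block
  out
}

#' Frobenius-norm pair scores
#'
#' `score[i, j] = ||block_ij||_F` over the gap-excluded 20 x 20 (default) or
#' full 21 x 21 sub-block of a coupling or covariance matrix; the sign of the
#' underlying potentials is ignored. Diagonal and pairs closer than
#' `min_separation` are floored to the minimum off-diagonal score so they
#' never rank.
#'
#' @param x A `coev_potts`, `coev_cov`, or `coev_pre`.
#' @param exclude_gap Drop the gap state row/column before the norm
#'   (default TRUE).
#' @param min_separation Pairs with `|i - j| < min_separation` are excluded
#'   (default 1: diagonal only).
#' @return Object of class `coev_pairscore`: `scores` (L x L symmetric),
#'   `method`, `apc_applied`, `min_separation`.
#' @export
frobenius_score <- function(x, exclude_gap = TRUE, min_separation = 1L) {
  if (inherits(x, "coev_potts")) {
    M <- x$W; L <- x$L; method <- "plm"
  } else if (inherits(x, "coev_cov")) {
    M <- x$S; L <- x$L; method <- "cov"
  } else if (inherits(x, "coev_pre")) {
    M <- x$theta; L <- nrow(x$theta) / N_STATES; method <- "pre"
  } else stop("unsupported input for frobenius_score")
  sc <- block_frobenius(M, L, exclude_gap)
  sc <- (sc + t(sc)) / 2
  diag(sc) <- 0
  ps <- structure(
    list(scores = sc, method = method, apc_applied = FALSE,
         min_separation = as.integer(min_separation)),
    class = "coev_pairscore"
  )
  .apply_separation_floor(ps)
}

.apply_separation_floor <- function(ps) {
  L <- nrow(ps$scores)
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  excl <- sep < ps$min_separation | sep == 0L
  if (any(!excl)) ps$scores[excl] <- min(ps$scores[!excl])
  ps
}

#' Average product correction (APC)
#'
#' `corrected[i, j] = raw[i, j] - mean_i(raw) * mean_j(raw) / mean(raw)`,
#' with all means taken over off-diagonal entries. Removes the background
#' per-column coupling bias from a nonnegative pair-score matrix.
#'
#' @param ps A `coev_pairscore` (raw, symmetric, nonnegative).
#' @return A `coev_pairscore` with `apc_applied = TRUE`.
#' @export
apc_correct <- function(ps) {
  stopifnot(inherits(ps, "coev_pairscore"))
  raw <- ps$scores
  L <- nrow(raw)
  offdiag <- matrix(TRUE, L, L); diag(offdiag) <- FALSE
  total_mean <- mean(raw[offdiag])
  if (total_mean == 0) {
    warning("all-zero pair scores; APC returns zeros")
    out <- raw * 0
  } else {
    rowm <- rowSums(raw * offdiag) / (L - 1)
    out <- raw - outer(rowm, rowm) / total_mean
    diag(out) <- 0
  }
  ps$scores <- (out + t(out)) / 2
  ps$apc_applied <- TRUE
  .apply_separation_floor(ps)
}

# ---- feature tensor assembly ----------------------------------------------

#' Assemble an L x L x 441 raw feature tensor
#'
#' Rearranges a flattened `21L x 21L` block matrix (COV `S`, PRE `Theta`, or
#' PLM couplings `W`) into the network's input layout: channel
#' `c = 21 * a + b` (0-based states `a`, `b`) holds entry `(a, b)` of block
#' `(i, j)`.
#'
#' @param x A `coev_cov`, `coev_pre`, `coev_potts`, or bare 21L x 21L matrix.
#' @return Numeric array of dim `c(L, L, 441)`.
#' @export
assemble_feature_tensor <- function(x) {
  M <- if (inherits(x, "coev_cov")) x$S
       else if (inherits(x, "coev_pre")) x$theta
       else if (inherits(x, "coev_potts")) x$W
       else x
  stopifnot(is.matrix(M), nrow(M) == ncol(M), nrow(M) %% N_STATES == 0)
  L <- nrow(M) / N_STATES
  A <- M
  dim(A) <- c(N_STATES, L, N_STATES, L)      # (a, i, b, j)
  T4 <- aperm(A, c(2L, 4L, 3L, 1L))          # (i, j, b, a); channel = a*21+b
  dim(T4) <- c(L, L, N_STATES^2)
  T4
}

#' Invert [assemble_feature_tensor()]
#' @param tensor L x L x 441 array.
#' @return 21L x 21L block matrix.
#' @export
tensor_to_blocks <- function(tensor) {
  d <- dim(tensor)
  stopifnot(length(d) == 3L, d[1] == d[2], d[3] == N_STATES^2)
  L <- d[1]
  T4 <- tensor
  dim(T4) <- c(L, L, N_STATES, N_STATES)     # (i, j, b, a)
  A <- aperm(T4, c(4L, 1L, 3L, 2L))          # (a, i, b, j)
  dim(A) <- c(N_STATES * L, N_STATES * L)
  A
}

#' Compute the full raw feature triplet for an alignment
#'
#' Convenience wrapper: sequence weights, frequencies, then COV, PRE and PLM
#' tensors with the package defaults.
#'
#' @param aln A `coev_alignment`.
#' @param which Character subset of `c("cov", "pre", "plm")`.
#' @param rho,shrinkage Passed to [compute_pre()].
#' @param plm_maxit Iteration cap for [compute_plm()].
#' @return Named list of `L x L x 441` arrays (subset of cov/pre/plm), with
#'   attribute `neff`.
#' @export
coev_features <- function(aln, which = c("cov", "pre", "plm"),
                          rho = exp(-6), shrinkage = 0.1, plm_maxit = 500) {
  which <- match.arg(which, several.ok = TRUE)
  w <- msa_weights(aln)
  out <- list()
  if (any(c("cov", "pre") %in% which)) {
    fr <- msa_frequencies(aln, weights = w)
    cv <- compute_cov(fr)
    if ("cov" %in% which) out$cov <- assemble_feature_tensor(cv)
    if ("pre" %in% which) {
      out$pre <- assemble_feature_tensor(compute_pre(cv, rho, shrinkage))
    }
  }
  if ("plm" %in% which) {
    out$plm <- assemble_feature_tensor(
      compute_plm(aln, weights = w, maxit = plm_maxit))
  }
  attr(out, "neff") <- sum(w) / ncol(aln$codes)
  out
}
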