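# Independent oracles used across tests.

# Numerical minimizer of G(Theta) = tr(S Theta) - log det Theta + rho ||Theta||_F^2
# over symmetric positive-definite Theta, via L-BFGS on the Cholesky factor
# Theta = R R' (R lower triangular, unconstrained entries) with the calculus
# gradient dG/dR = 2 (S - Theta^-1 + 2 rho Theta) R. Independent of the
# package's eigenvalue closed form (different parametrization, different
# algorithm, identity start).
pre_numeric_oracle <- function(S, rho, maxit = 20000) {
  n <- nrow(S)
  lt <- lower.tri(S, diag = TRUE)
  unpack <- function(v) {
    R <- matrix(0, n, n)
    R[lt] <- v
    R
  }
  fn <- function(v) {
    R <- unpack(v)
    dg <- abs(diag(R))
    if (any(dg < 1e-300)) return(1e10)
    Th <- tcrossprod(R)
    sum(S * Th) - 2 * sum(log(dg)) + rho * sum(Th^2)
  }
  gr <- function(v) {
    R <- unpack(v)
    Th <- tcrossprod(R)
    Rinv_t <- t(solve(R))
    M <- ((S + t(S)) / 2) %*% R + 2 * rho * (Th %*% R)
    G <- 2 * M - 2 * Rinv_t
    G[lt]
  }
  opt <- stats::optim(diag(1, n)[lt], fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10))
  tcrossprod(unpack(opt$par))
}

# brute-force weighted frequency counts by explicit loops (tiny inputs only)
freq_loop_oracle <- function(codes, w) {
  n <- nrow(codes); l <- ncol(codes)
  f1 <- matrix(0, l, 21)
  f2 <- array(0, c(l, l, 21, 21))
  for (m in seq_len(n)) {
    for (i in seq_len(l)) {
      a <- codes[m, i] + 1L
      f1[i, a] <- f1[i, a] + w[m]
      for (j in seq_len(l)) {
        b <- codes[m, j] + 1L
        f2[i, j, a, b] <- f2[i, j, a, b] + w[m]
      }
    }
  }
  list(f1 = f1 / sum(w), f2 = f2 / sum(w))
}

# scalar-loop negative log-likelihood of a distogram (oracle for the
# vectorized loss)
nll_loop_oracle <- function(probs, labels) {
  L <- dim(probs)[1]
  total <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (labels$mask[i, j]) {
      total <- total - log(probs[i, j, labels$bins[i, j] + 1L])
    }
  }
  total
}

# brute-force top-k precision: enumerate, sort, count (small L only)
precision_loop_oracle <- function(P, native, sep_min, sep_max, depth) {
  L <- nrow(P)
  recs <- NULL
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    s <- j - i
    if (s >= sep_min && s <= sep_max) {
      recs <- rbind(recs, c(i, j, P[i, j]))
    }
  }
  if (is.null(recs)) return(0)
  ord <- order(-recs[, 3], recs[, 1], recs[, 2])
  take <- ord[seq_len(min(depth, nrow(recs)))]
  mean(native[recs[take, 1:2, drop = FALSE]])
}

# small helper: planted-pair logical map from a potts model
planted_map <- function(model) {
  M <- matrix(FALSE, model$L, model$L)
  if (nrow(model$planted_pairs)) {
    M[model$planted_pairs] <- TRUE
    M[model$planted_pairs[, 2:1, drop = FALSE]] <- TRUE
  }
  M
}

# top-K recovery fraction of planted pairs by an APC-corrected score map
planted_recovery <- function(score_obj, model) {
  K <- nrow(model$planted_pairs)
  top <- rank_contacts(score_obj$scores, range = "all", depth = K)
  mean(planted_map(model)[cbind(top$i, top$j)])
}
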