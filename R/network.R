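# The four-branch residual distogram network: one ResNet per raw feature
# tensor, channel concatenation, a fusion ResNet, and a 12-bin softmax head
# symmetrized over (i, j) / (j, i).

#' Distance bin scheme
#'
#' Twelve bins: one below 5 A, ten 1-A intervals spanning 5-15 A, and one at
#' or above 15 A. The first four bins together cover exactly the d < 8 A
#' contact region, so the contact probability is their summed mass.
#'
#' @return Object of class `coev_bin_scheme`: `edges` (5..15), `n_bins` (12),
#'   `contact_bins` (0-based indices 0:3).
#' @export
bin_scheme <- function() {
  structure(list(edges = 5:15, n_bins = 12L, contact_bins = 0:3),
            class = "coev_bin_scheme")
}

#' Discretize distances into the 12-bin scheme
#'
#' Half-open convention: bin 0 is `d < 5`; bin k (1..10) is
#' `5 + (k-1) <= d < 5 + k`; bin 11 is `d >= 15`.
#'
#' @param d Numeric distances (Angstroms), finite and nonnegative.
#' @param scheme A [bin_scheme()].
#' @return Integer 0-based bin indices, same shape as `d`.
#' @export
discretize_distance <- function(d, scheme = bin_scheme()) {
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  b <- findInterval(d, scheme$edges)
  if (is.matrix(d)) b <- matrix(b, nrow(d), ncol(d))
  b
}

#' Distance-bin labels from per-residue coordinates
#'
#' Computes pairwise Euclidean distances between interaction sites (C-beta,
#' C-alpha for glycine, or toy chain sites), discretizes them, and derives
#' the binary contact map at the strict 8.0 A cutoff. Rows of `coords` that
#' contain `NA` are treated as unresolved residues and masked out; the
#' diagonal is always masked.
#'
#' @param coords L x 3 coordinate matrix, `NA` rows for missing residues.
#' @param scheme A [bin_scheme()].
#' @param contact_cutoff Contact definition, default 8.0 (strict `<`).
#' @return Object of class `coev_labels`: `bins` (L x L, 0-based, `NA` where
#'   unmasked), `mask` (L x L logical), `contacts` (L x L logical),
#'   `distances` (L x L).
#' @export
labels_from_structure <- function(coords, scheme = bin_scheme(),
                                  contact_cutoff = 8.0) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L)
  L <- nrow(coords)
  resolved <- stats::complete.cases(coords)
  if (sum(resolved) < 2L) stop("fewer than 2 resolved residues")
  D <- matrix(NA_real_, L, L)
  D[resolved, resolved] <- as.matrix(stats::dist(coords[resolved, , drop = FALSE]))
  mask <- outer(resolved, resolved, "&")
  diag(mask) <- FALSE
  bins <- matrix(NA_integer_, L, L)
  bins[mask] <- discretize_distance(D[mask], scheme)
  diag_resolved <- which(resolved)
  bins[cbind(diag_resolved, diag_resolved)] <- 0L   # self distance 0 -> bin 0
  contacts <- !is.na(D) & D < contact_cutoff
  diag(contacts) <- FALSE
  structure(list(bins = bins, mask = mask, contacts = contacts, distances = D),
            class = "coev_labels")
}

#' Network configuration
#'
#' The published-scale profile is 24 residual blocks per branch and 64
#' hidden channels; the package's desk-scale default is 2 blocks and 16
#' channels, which trains in minutes on a CPU while preserving the
#' architecture (1x1 channel reduction, instance normalization, residual
#' blocks, fusion over concatenated branches, 12-bin softmax head).
#'
#' @param features Character vector naming the input branches (subset of
#'   `c("cov", "pre", "plm")`).
#' @param channels_in Input channels per branch (441 = 21 x 21).
#' @param channels_hidden Hidden channels per branch (default 16).
#' @param blocks_per_branch Residual blocks per feature branch (default 2).
#' @param fusion_blocks Residual blocks after concatenation (default 2).
#' @param n_bins Output bins (12).
#' @param dropout Dropout rate inside residual blocks (default 0.2).
#' @param lr Adam learning rate (default 1e-3).
#' @param max_epochs Training epochs (default 100).
#' @param crop_size Random square crop side used when L exceeds it
#'   (default 128).
#' @param seed Initialization / training seed.
#' @return List of class `coev_net_config`.
#' @export
net_config <- function(features = c("cov", "pre", "plm"),
                       channels_in = 441L, channels_hidden = 16L,
                       blocks_per_branch = 2L, fusion_blocks = 2L,
                       n_bins = 12L, dropout = 0.2, lr = 1e-3,
                       max_epochs = 100L, crop_size = 128L, seed = 1L) {
  features <- match.arg(features, c("cov", "pre", "plm"), several.ok = TRUE)
  stopifnot(dropout >= 0, dropout < 1, channels_hidden >= 1, n_bins >= 2)
  structure(list(
    features = features,
    channels_in = as.integer(channels_in),
    channels_hidden = as.integer(channels_hidden),
    blocks_per_branch = as.integer(blocks_per_branch),
    fusion_blocks = as.integer(fusion_blocks),
    fusion_channels_in = as.integer(length(features) * channels_hidden),
    n_bins = as.integer(n_bins),
    dropout = dropout, lr = lr,
    max_epochs = as.integer(max_epochs),
    crop_size = as.integer(crop_size),
    seed = as.integer(seed)
  ), class = "coev_net_config")
}

#' Build the distogram network
#'
#' Per feature branch: 1x1 convolution reducing 441 channels to
#' `channels_hidden`, instance normalization, then `blocks_per_branch`
#' residual blocks. Branch outputs are concatenated along channels and fed
#' to the fusion trunk (1x1 reduction, instance normalization,
#' `fusion_blocks` residual blocks) ending in a 1x1 projection to `n_bins`
#' channels; a per-pixel softmax plus (i, j)/(j, i) averaging produces the
#' symmetrized distogram. Initialization is He-normal under `cfg$seed`.
#'
#' @param cfg A [net_config()].
#' @return Object of class `coev_model`.
#' @export
build_model <- function(cfg = net_config()) {
  stopifnot(inherits(cfg, "coev_net_config"))
  params <- new_param_set()
  with_seed(cfg$seed, {
    ch <- cfg$channels_hidden
    branches <- lapply(seq_along(cfg$features), function(f) {
      nm <- paste0("br", f)
      reduce <- make_conv(params, paste0(nm, ".reduce"), cfg$channels_in, ch, 1L)
      reduce$first <- TRUE            # input gradient is never needed
      c(list(reduce,
             make_inorm(params, paste0(nm, ".norm0"), ch)),
        lapply(seq_len(cfg$blocks_per_branch), function(b) {
          make_resblock(params, sprintf("%s.res%d", nm, b), ch, cfg$dropout)
        }))
    })
    fusion <- c(
      list(make_conv(params, "fu.reduce", cfg$fusion_channels_in, ch, 1L),
           make_inorm(params, "fu.norm0", ch)),
      lapply(seq_len(cfg$fusion_blocks), function(b) {
        make_resblock(params, sprintf("fu.res%d", b), ch, cfg$dropout)
      }),
      list(make_conv(params, "fu.head", ch, cfg$n_bins, 1L))
    )
    structure(list(cfg = cfg, params = params, branches = branches,
                   fusion = fusion),
              class = "coev_model")
  })
}

#' Number of trainable parameters
#' @param model A `coev_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(as.list(model$params), length, integer(1)))
}

#' @export
print.coev_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "<coev_model> %d branch(es) [%s], %d+%d residual blocks, %d channels, %d bins, %d parameters\n",
    length(cfg$features), paste(cfg$features, collapse = ","),
    cfg$blocks_per_branch, cfg$fusion_blocks, cfg$channels_hidden,
    cfg$n_bins, n_parameters(x)))
  invisible(x)
}

# transpose permutation of pixel indices on an L x L grid
transpose_idx <- function(L) {
  as.vector(t(matrix(seq_len(L * L), L, L)))
}

row_softmax <- function(Z) {
  mx <- do.call(pmax, as.data.frame(Z))
  E <- exp(Z - mx)
  E / rowSums(E)
}

#' Forward pass of the distogram network
#'
#' @param model A `coev_model`.
#' @param tensors Named list of `L x L x 441` arrays covering
#'   `model$cfg$features`.
#' @param train Logical; activates dropout (draws from the current RNG
#'   stream).
#' @param keep_cache Keep intermediate activations for backprop (internal).
#' @return Object of class `coev_distogram`: `probs` (L x L x n_bins array,
#'   symmetrized, rows summing to 1), `L`, plus an invisible cache when
#'   requested.
#' @export
model_forward <- function(model, tensors, train = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg
  feats <- cfg$features
  if (!all(feats %in% names(tensors)))
    stop(sprintf("tensors must include: %s", paste(feats, collapse = ", ")))
  dims <- lapply(tensors[feats], dim)
  L <- dims[[1]][1]
  for (d in dims) {
    if (!identical(as.integer(d), c(L, L, cfg$channels_in)))
      stop("feature tensors must share dimensions L x L x 441")
  }
  P <- L * L
  outs <- vector("list", length(feats))
  bcaches <- vector("list", length(feats))
  for (f in seq_along(feats)) {
    X <- tensors[[feats[f]]]
    dim(X) <- c(P, cfg$channels_in)
    # global z-scaling per input tensor: COV, PRE and PLM live on very
    # different numeric scales; a scalar standardization keeps them
    # comparable without touching the pairwise structure
    X <- (X - mean(X)) / (stats::sd(X) + 1e-12)
    r <- seq_forward(model$params, model$branches[[f]], X, train, L)
    outs[[f]] <- r$out
    bcaches[[f]] <- r$caches
  }
  Xf <- do.call(cbind, outs)
  rf <- seq_forward(model$params, model$fusion, Xf, train, L)
  Praw <- row_softmax(rf$out)
  tidx <- transpose_idx(L)
  Psym <- (Praw + Praw[tidx, , drop = FALSE]) / 2
  probs <- Psym
  dim(probs) <- c(L, L, cfg$n_bins)
  out <- structure(list(probs = probs, L = L, symmetrized = TRUE),
                   class = "coev_distogram")
  if (keep_cache) {
    attr(out, "cache") <- list(bcaches = bcaches, fcache = rf$caches,
                               Praw = Praw, tidx = tidx, L = L)
  }
  out
}

# backward pass: dPsym is (P x n_bins); returns grads environment
model_backward <- function(model, cache, dPsym) {
  grads <- new.env(parent = emptyenv())
  L <- cache$L
  Praw <- cache$Praw
  dP <- (dPsym + dPsym[cache$tidx, , drop = FALSE]) / 2
  # softmax backward per pixel
  dZ <- Praw * (dP - rowSums(dP * Praw))
  dXf <- seq_backward(model$params, model$fusion, cache$fcache, dZ, grads, L)
  ch <- model$cfg$channels_hidden
  for (f in seq_along(model$branches)) {
    cols <- ((f - 1L) * ch + 1L):(f * ch)
    seq_backward(model$params, model$branches[[f]], cache$bcaches[[f]],
                 dXf[, cols, drop = FALSE], grads, L)
  }
  grads
}

# ---- losses ----------------------------------------------------------------

# flatten a distogram / label pair into matrices, validating shapes
.loss_prep <- function(pred, labels) {
  probs <- if (inherits(pred, "coev_distogram")) pred$probs else pred
  d <- dim(probs)
  L <- d[1]
  if (!identical(dim(labels$bins), c(L, L))) stop("prediction/label shape mismatch")
  P <- matrix(probs, L * L, d[3])
  mask <- as.vector(labels$mask)
  if (!any(mask)) stop("empty label mask")
  list(P = P, mask = mask, bins = as.vector(labels$bins), L = L, K = d[3])
}

#' Distance-bin negative log-likelihood loss
#'
#' `loss = -sum_t sum_k y_t^k log p_t^k` over masked residue pairs, where
#' `y` is the one-hot distance-bin label. Pairs are the off-diagonal masked
#' entries of the L x L map.
#'
#' @param pred A `coev_distogram` or L x L x 12 probability array.
#' @param labels A `coev_labels`.
#' @param average Divide by the number of pairs (default FALSE).
#' @param gradient Also return the gradient w.r.t. the symmetrized
#'   probabilities (internal use).
#' @return Scalar loss, or a list `(value, dP)` when `gradient = TRUE`.
#' @export
distance_nll_loss <- function(pred, labels, average = FALSE, gradient = FALSE) {
  pr <- .loss_prep(pred, labels)
  idx <- cbind(which(pr$mask), pr$bins[pr$mask] + 1L)
  p <- pmax(pr$P[idx], 1e-12)
  val <- -sum(log(p))
  n <- nrow(idx)
  if (average) val <- val / n
  if (!gradient) return(val)
  dP <- matrix(0, nrow(pr$P), ncol(pr$P))
  dP[idx] <- -1 / p
  if (average) dP <- dP / n
  list(value = val, dP = dP)
}

#' Binary contact cross-entropy loss
#'
#' Two-state cross-entropy of the derived contact probability (summed mass
#' of the first four bins) against the 8 A contact labels; the loss variant
#' used to train the binary ablation.
#'
#' @inheritParams distance_nll_loss
#' @return Scalar loss, or `(value, dP)` when `gradient = TRUE`.
#' @export
binary_bce_loss <- function(pred, labels, average = FALSE, gradient = FALSE) {
  pr <- .loss_prep(pred, labels)
  cb <- bin_scheme()$contact_bins + 1L
  Pc <- rowSums(pr$P[, cb, drop = FALSE])
  m <- pr$mask
  y <- as.vector(labels$contacts)[m]
  pc <- pmin(pmax(Pc[m], 1e-9), 1 - 1e-9)
  val <- -sum(y * log(pc) + (1 - y) * log(1 - pc))
  n <- sum(m)
  if (average) val <- val / n
  if (!gradient) return(val)
  dPc <- numeric(nrow(pr$P))
  dPc[m] <- -y / pc + (1 - y) / (1 - pc)
  if (average) dPc <- dPc / n
  dP <- matrix(0, nrow(pr$P), ncol(pr$P))
  dP[, cb] <- dPc
  list(value = val, dP = dP)
}

#' Contact probability from a distogram
#'
#' `P[i, j]` is the summed probability mass of the first four distance bins
#' (all distances below 8 A).
#'
#' @param pred A `coev_distogram` or L x L x 12 array.
#' @param scheme A [bin_scheme()].
#' @return L x L symmetric matrix of contact probabilities in `[0, 1]`.
#' @export
contact_probability <- function(pred, scheme = bin_scheme()) {
  probs <- if (inherits(pred, "coev_distogram")) pred$probs else pred
  cb <- scheme$contact_bins + 1L
  apply(probs[, , cb, drop = FALSE], c(1, 2), sum)
}

# ---- training --------------------------------------------------------------

# random square crop of an example when L exceeds crop_size
.crop_example <- function(ex, crop) {
  L <- dim(ex$features[[1]])[1]
  if (L <= crop) return(ex)
  s <- sample.int(L - crop + 1L, 1L)
  rng <- s:(s + crop - 1L)
  feats <- lapply(ex$features, function(t) t[rng, rng, , drop = FALSE])
  lab <- ex$labels
  lab$bins <- lab$bins[rng, rng]
  lab$mask <- lab$mask[rng, rng]
  lab$contacts <- lab$contacts[rng, rng]
  lab$distances <- lab$distances[rng, rng]
  list(features = feats, labels = lab)
}

#' Train the distogram network
#'
#' Adam on the distance-bin negative log-likelihood (or the binary contact
#' cross-entropy), one protein per batch, dropout active during training
#' only, random square crops when a map exceeds `crop_size`. Deterministic
#' given `seed`.
#'
#' @param model A `coev_model` (modified copy returned).
#' @param dataset List of examples, each `list(features = <named list of
#'   L x L x 441 arrays>, labels = <coev_labels>)`.
#' @param epochs Number of epochs (default `model$cfg$max_epochs`).
#' @param lr Learning rate (default `model$cfg$lr`).
#' @param loss `"distance"` (default) or `"binary"`.
#' @param validation Optional held-out dataset; long-range top-L/5 precision
#'   is logged per epoch.
#' @param seed Training seed (default `model$cfg$seed`).
#' @param verbose Print per-epoch progress.
#' @return List of class `coev_fit`: `model`, `history` (tibble with epoch,
#'   mean training loss, optional validation precision), `loss`, `seed`.
#' @export
train_model <- function(model, dataset, epochs = NULL, lr = NULL,
                        loss = c("distance", "binary"), validation = NULL,
                        seed = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(inherits(model, "coev_model"), length(dataset) >= 1L)
  cfg <- model$cfg
  if (is.null(epochs)) epochs <- cfg$max_epochs
  if (is.null(lr)) lr <- cfg$lr
  if (is.null(seed)) seed <- cfg$seed
  loss_fn <- if (loss == "distance") distance_nll_loss else binary_bce_loss
  # parameters live in an environment; clone so the input model is untouched
  model$params <- list2env(as.list(model$params), parent = emptyenv())
  st <- adam_init(model$params)
  hist <- vector("list", epochs)
  with_seed(derive_seed(seed, 5150L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(dataset))
      ep_loss <- 0
      for (ix in ord) {
        ex <- .crop_example(dataset[[ix]], cfg$crop_size)
        pred <- model_forward(model, ex$features, train = TRUE,
                              keep_cache = TRUE)
        lr_ <- loss_fn(pred, ex$labels, average = TRUE, gradient = TRUE)
        if (!is.finite(lr_$value))
          stop(sprintf("non-finite loss at epoch %d (example %d)", ep, ix))
        grads <- model_backward(model, attr(pred, "cache"), lr_$dP)
        adam_step(model$params, grads, st, lr)
        ep_loss <- ep_loss + lr_$value
      }
      row <- tibble::tibble(epoch = ep, loss = ep_loss / length(dataset))
      if (!is.null(validation)) {
        row$val_precision_topL5 <-
          mean(vapply(validation, function(vx) {
            pred <- model_forward(model, vx$features)
            precision_at(contact_probability(pred), vx$labels$contacts,
                         range = "long", k_denominator = 5)
          }, numeric(1)))
      }
      hist[[ep]] <- row
      if (verbose) {
        cat(sprintf("epoch %3d  loss %.4f%s\n", ep, row$loss,
                    if (!is.null(validation))
                      sprintf("  val topL/5 %.3f", row$val_precision_topL5)
                    else ""))
      }
    }
  })
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 loss = loss, seed = seed),
            class = "coev_fit")
}

#' Predict a contact map from feature tensors
#'
#' @param object A `coev_model` or `coev_fit`.
#' @param tensors Named list of feature tensors (or a `coev_alignment`, in
#'   which case features are computed first).
#' @param ... Passed to [coev_features()] when `tensors` is an alignment.
#' @return List: `distogram` (a `coev_distogram`), `contact_map` (L x L).
#' @export
predict_contacts <- function(object, tensors, ...) {
  model <- if (inherits(object, "coev_fit")) object$model else object
  if (inherits(tensors, "coev_alignment")) {
    tensors <- coev_features(tensors, which = model$cfg$features, ...)
  }
  dg <- model_forward(model, tensors)
  list(distogram = dg, contact_map = contact_probability(dg))
}
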