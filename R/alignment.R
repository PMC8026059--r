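# Alignment handling: reading, encoding, sequence weighting and Neff.

#' The 21-letter alignment alphabet
#'
#' The 20 standard amino acids in alphabetical one-letter order followed by
#' the gap character `-`. Residues are encoded as 0-based integer codes
#' 0..20, with the gap fixed at code 20. Non-standard residue letters
#' (B, J, O, U, X, Z) are mapped to the gap state.
#'
#' @return Character vector of length 21.
#' @export
coev_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
}

GAP_CODE <- 20L
N_STATES <- 21L

# lookup table: uppercase letter -> 0-based code; non-standard -> gap
.code_lookup <- local({
  lut <- rep(NA_integer_, 127L)
  ab <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
  for (k in seq_along(ab)) lut[utf8ToInt(ab[k])] <- k - 1L
  for (ch in c("B", "J", "O", "U", "X", "Z", ".")) lut[utf8ToInt(ch)] <- 20L
  lut
})

#' Encode a residue string as integer codes
#'
#' @param s Single character string (one aligned sequence).
#' @return Integer vector of 0-based codes in `[0, 20]`.
#' @export
encode_sequence <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  ints <- utf8ToInt(toupper(s))
  if (any(ints > 126L)) stop("non-ASCII character in sequence")
  codes <- .code_lookup[ints]
  if (anyNA(codes)) {
    bad <- intToUtf8(ints[which(is.na(codes))[1L]])
    stop(sprintf("unrecognized residue character '%s'", bad))
  }
  codes
}

#' Construct an alignment object
#'
#' An alignment is an N x L integer matrix of 0-based residue codes over the
#' 21-state alphabet (see [coev_alphabet()]), together with sequence
#' identifiers and the index of the query row.
#'
#' @param sequences Character vector of aligned sequences (equal lengths), or
#'   an integer matrix of codes in `[0, 20]`.
#' @param ids Optional sequence identifiers (recycled default `seq_1`, ...).
#' @param query_index Row holding the query sequence (1-based, default 1).
#' @return Object of class `coev_alignment` with elements `codes`, `ids`,
#'   `query_index`.
#' @export
coev_alignment <- function(sequences, ids = NULL, query_index = 1L) {
  if (is.character(sequences)) {
    if (length(sequences) < 1L) stop("alignment needs at least one sequence")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) stop("ragged alignment: unequal sequence lengths")
    if (lens[1L] < 1L) stop("zero-length sequences")
    codes <- t(vapply(sequences, encode_sequence, integer(lens[1L]), USE.NAMES = FALSE))
  } else if (is.matrix(sequences)) {
    codes <- sequences
    storage.mode(codes) <- "integer"
  } else {
    stop("`sequences` must be a character vector or an integer matrix")
  }
  if (nrow(codes) < 1L || ncol(codes) < 1L) stop("empty alignment")
  if (anyNA(codes) || any(codes < 0L) || any(codes > GAP_CODE))
    stop("residue codes must lie in [0, 20]")
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_len(nrow(codes)))
  if (length(ids) != nrow(codes)) stop("`ids` length must match number of sequences")
  query_index <- as.integer(query_index)
  if (query_index < 1L || query_index > nrow(codes)) stop("`query_index` out of range")
  structure(
    list(codes = codes, ids = as.character(ids), query_index = query_index),
    class = "coev_alignment"
  )
}

#' @export
print.coev_alignment <- function(x, ...) {
  cat(sprintf("<coev_alignment> %d sequences x %d positions (query: %s)\n",
              nrow(x$codes), ncol(x$codes), x$ids[x$query_index]))
  invisible(x)
}

#' @export
dim.coev_alignment <- function(x) dim(x$codes)

#' Number of aligned positions
#' @param aln A `coev_alignment`.
#' @return Integer alignment length L.
#' @export
alignment_length <- function(aln) ncol(aln$codes)

#' Decode an alignment back to residue strings
#' @param aln A `coev_alignment`.
#' @return Character vector of sequences.
#' @export
alignment_strings <- function(aln) {
  ab <- coev_alphabet()
  apply(aln$codes, 1L, function(r) paste(ab[r + 1L], collapse = ""))
}

# Project one A3M sequence onto the query match columns: lowercase letters
# and '.' are insertion states and are removed.
.a3m_project <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  keep <- !(chars %in% letters) & chars != "."
  paste(chars[keep], collapse = "")
}

#' Read a multiple sequence alignment
#'
#' Reads plain aligned FASTA or A3M (HHblits dialect: lowercase letters are
#' insertion states relative to the query and are removed, leaving match
#' columns only). The first sequence is taken as the query. Non-standard
#' residues (B, J, O, U, X, Z) encode to the gap state.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"fasta"`, or `"a3m"`.
#' @return A [coev_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "a3m")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m" else "fasta"
  }
  if (!any(startsWith(readLines(path, warn = FALSE), ">")))
    stop("empty alignment file (no FASTA records)")
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE, seqonly = FALSE)
  if (length(recs) == 0L) stop("empty alignment file")
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1L))
  ids <- vapply(recs, function(r) attr(r, "name"), character(1L))
  if (format == "a3m") {
    seqs <- vapply(seqs, .a3m_project, character(1L), USE.NAMES = FALSE)
  } else {
    seqs <- gsub(".", "-", seqs, fixed = TRUE)
  }
  if (nchar(seqs[1L]) == 0L) stop("zero-length query sequence")
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment after A3M projection")
  coev_alignment(seqs, ids = ids, query_index = 1L)
}

#' Write an alignment to aligned FASTA
#'
#' @param aln A `coev_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqinr::write.fasta(as.list(alignment_strings(aln)), names = aln$ids,
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' Pairwise sequence identity
#'
#' Fraction of positions with identical codes. The default convention —
#' gap-gap counted as a match, normalized by the full alignment length —
#' is the simplest testable reading; both knobs are exposed because the
#' field is not unanimous about them.
#'
#' @param a,b Integer code vectors of equal length (or single strings).
#' @param count_gap_gap Count positions where both sequences have a gap as
#'   identical (default TRUE).
#' @param denominator `"full"` (alignment length, default) or `"union"`
#'   (positions where at least one sequence has a residue).
#' @return Identity in `[0, 1]` (0 when the denominator is empty).
#' @export
pairwise_identity <- function(a, b, count_gap_gap = TRUE,
                              denominator = c("full", "union")) {
  denominator <- match.arg(denominator)
  if (is.character(a)) a <- encode_sequence(a)
  if (is.character(b)) b <- encode_sequence(b)
  if (length(a) != length(b)) stop("sequence length mismatch")
  if (length(a) < 1L) stop("empty sequences")
  both_gap <- a == GAP_CODE & b == GAP_CODE
  # under the union denominator gap-gap positions leave numerator and
  # denominator together; count_gap_gap only matters for full-length
  drop_gg <- !count_gap_gap || denominator == "union"
  matches <- sum(a == b) - if (drop_gg) sum(both_gap) else 0L
  denom <- if (denominator == "full") length(a) else sum(!both_gap)
  if (denom == 0L) return(0)
  matches / denom
}

# one-hot encoding of the alignment: N x 21L dense matrix, column
# (i-1)*21 + code + 1 set for position i. Shared by weighting, frequency
# and pseudolikelihood code.
one_hot_encode <- function(aln) {
  codes <- aln$codes
  n <- nrow(codes); l <- ncol(codes)
  X <- matrix(0, n, N_STATES * l)
  cols <- sweep(codes, 2L, (seq_len(l) - 1L) * N_STATES, "+") + 1L
  X[cbind(rep(seq_len(n), l), as.vector(cols))] <- 1
  X
}

#' Sequence weights at an identity threshold
#'
#' Each sequence is down-weighted by the size of its identity cluster:
#' `w_n = 1 / (1 + #\{m != n : S_mn >= threshold\})`.
#'
#' @param aln A `coev_alignment`.
#' @param identity_threshold Identity threshold in (0, 1], default 0.8.
#' @inheritParams pairwise_identity
#' @return Numeric vector of N weights in (0, 1].
#' @export
msa_weights <- function(aln, identity_threshold = 0.8, count_gap_gap = TRUE,
                        denominator = c("full", "union")) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  denominator <- match.arg(denominator)
  l <- ncol(aln$codes)
  X <- one_hot_encode(aln)
  counts <- tcrossprod(X)                 # matches[m, n], includes self = L
  if (!count_gap_gap || denominator == "union") {
    gap_cols <- seq_len(l) * N_STATES
    gapgap <- tcrossprod(X[, gap_cols, drop = FALSE])
    counts <- counts - gapgap
  }
  denom <- if (denominator == "full") l else pmax(l - gapgap, 1)
  cluster <- rowSums(counts >= identity_threshold * denom - 1e-9)
  1 / cluster
}

#' Effective number of sequences (Neff)
#'
#' `Neff = (1/L) * sum_n w_n` with weights from [msa_weights()]: the number
#' of sequence clusters at the identity threshold, normalized by alignment
#' length. Invariant under duplicating any sequence.
#'
#' @inheritParams msa_weights
#' @param weights Optional precomputed weights (skips recomputation).
#' @return Nonnegative scalar.
#' @export
msa_neff <- function(aln, identity_threshold = 0.8, weights = NULL) {
  if (is.null(weights)) weights <- msa_weights(aln, identity_threshold)
  sum(weights) / ncol(aln$codes)
}

#' Decide whether an MSA needs a deeper homology search
#'
#' Pure predicate used by hierarchical MSA pipelines: a further search stage
#' is triggered when Neff falls strictly below the threshold (default 128).
#'
#' @param neff Effective sequence number, `>= 0`.
#' @param threshold Decision threshold (default 128).
#' @return Logical.
#' @export
needs_deeper_search <- function(neff, threshold = 128) {
  stopifnot(is.numeric(neff), neff >= 0)
  neff < threshold
}

#' Weighted single-site and pair frequencies
#'
#' Computes `f1[i, a]`, the weighted frequency of state `a` at position `i`,
#' and the pair-frequency matrix `f2` stored as a `21L x 21L` block matrix
#' whose `(i, j)` block holds `f_ij(a, b)`. Diagonal blocks are diagonal with
#' `f2[i, i, a, a] = f1[i, a]`. An optional pseudocount mixes each frequency
#' with the uniform distribution: `f <- (1 - lambda) f + lambda u`.
#'
#' @param aln A `coev_alignment`.
#' @param weights Sequence weights (default: uniform).
#' @param pseudocount Mixing weight `lambda` in `[0, 1)`, default 0.
#' @return List of class `coev_freqs`: `f1` (L x 21), `f2` (21L x 21L),
#'   `weights`, `pseudocount`, `L`.
#' @export
msa_frequencies <- function(aln, weights = NULL, pseudocount = 0) {
  n <- nrow(aln$codes); l <- ncol(aln$codes)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("`weights` must have one entry per sequence")
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be nonnegative, not all zero")
  X <- one_hot_encode(aln)
  wsum <- sum(weights)
  f1v <- as.vector(crossprod(X, weights)) / wsum        # 21L vector
  f2 <- crossprod(X * sqrt(weights)) / wsum             # 21L x 21L
  if (pseudocount > 0) {
    lam <- pseudocount
    f1v <- (1 - lam) * f1v + lam / N_STATES
    f2 <- (1 - lam) * f2 + lam / (N_STATES^2)
    # keep diagonal blocks consistent with f1 (they are one-site marginals)
    for (i in seq_len(l)) {
      idx <- block_idx(i)
      f2[idx, idx] <- diag(f1v[idx], N_STATES)
    }
  }
  f1 <- matrix(f1v, nrow = l, ncol = N_STATES, byrow = TRUE)
  colnames(f1) <- coev_alphabet()
  structure(
    list(f1 = f1, f2 = f2, weights = weights, pseudocount = pseudocount, L = l),
    class = "coev_freqs"
  )
}

# column indices of position i's 21-state block in a flattened 21L matrix
block_idx <- function(i) ((i - 1L) * N_STATES + 1L):(i * N_STATES)

#' Summary statistics of an alignment
#'
#' @param aln A `coev_alignment`.
#' @param identity_threshold Identity threshold for weighting (default 0.8).
#' @param neff_threshold Deep-search decision threshold (default 128).
#' @return One-row tibble: `n_sequences`, `length`, `neff`,
#'   `needs_deeper_search`, `gap_fraction`.
#' @export
msa_stats <- function(aln, identity_threshold = 0.8, neff_threshold = 128) {
  w <- msa_weights(aln, identity_threshold)
  neff <- sum(w) / ncol(aln$codes)
  tibble::tibble(
    n_sequences = nrow(aln$codes),
    length = ncol(aln$codes),
    neff = neff,
    needs_deeper_search = needs_deeper_search(neff, neff_threshold),
    gap_fraction = mean(aln$codes == GAP_CODE)
  )
}
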