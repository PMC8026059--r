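# CASP-style contact evaluation: separation-range filtering, top-L/k
# precision, report aggregation, and native-structure input.

.sep_range <- function(range = c("long", "medium", "all")) {
  range <- match.arg(range)
  switch(range,
         medium = c(12L, 23L),
         long = c(24L, .Machine$integer.max),
         all = c(1L, .Machine$integer.max))
}

#' Rank predicted contacts within a separation range
#'
#' Unordered pairs (i < j) whose sequence separation `j - i` falls in the
#' medium (12-23) or long (>= 24) range, sorted by descending probability
#' with deterministic ties (ascending i, then j), truncated to `depth`.
#'
#' @param P Symmetric L x L contact-probability matrix.
#' @param range `"medium"`, `"long"`, or `"all"` (separation >= 1).
#' @param depth Maximum number of pairs returned (default: all eligible).
#' @return Tibble with columns `i`, `j`, `separation`, `probability`.
#' @export
rank_contacts <- function(P, range = "long", depth = Inf) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (depth < 1) stop("`depth` must be >= 1")
  L <- nrow(P)
  rg <- .sep_range(range)
  idx <- which(upper.tri(P), arr.ind = TRUE)
  sep <- idx[, 2L] - idx[, 1L]
  keep <- sep >= rg[1L] & sep <= rg[2L]
  idx <- idx[keep, , drop = FALSE]
  sep <- sep[keep]
  p <- P[idx]
  ord <- order(-p, idx[, 1L], idx[, 2L])
  n <- min(length(ord), depth)
  ord <- ord[seq_len(n)]
  tibble::tibble(i = as.integer(idx[ord, 1L]), j = as.integer(idx[ord, 2L]),
                 separation = as.integer(sep[ord]), probability = p[ord])
}

#' Top-L/k contact precision
#'
#' Precision of the `floor(L / k)` highest-probability predicted pairs in a
#' separation range against a native contact map. When fewer eligible pairs
#' exist than the nominal depth, the denominator is the evaluated count.
#'
#' @param P Symmetric L x L predicted contact probabilities.
#' @param native L x L logical native contact map (or a `coev_labels`).
#' @param range `"medium"` or `"long"` (or `"all"`).
#' @param k_denominator One of 10, 5, 2, 1: evaluate the top L/k pairs.
#' @return Precision in `[0, 1]` (0 when no pairs are eligible).
#' @export
precision_at <- function(P, native, range = "long", k_denominator = 5) {
  if (inherits(native, "coev_labels")) native <- native$contacts
  stopifnot(identical(dim(P), dim(native)))
  L <- nrow(P)
  depth <- max(1L, L %/% k_denominator)
  top <- rank_contacts(P, range = range, depth = depth)
  if (nrow(top) == 0L) return(0)
  hits <- native[cbind(top$i, top$j)]
  sum(hits) / nrow(top)
}

#' Full medium/long x depth precision report
#'
#' The standard assessment grid: medium- (12 <= |i-j| <= 23) and long-range
#' (|i-j| >= 24) precision of the top L/10, L/5, L/2 and L predictions.
#'
#' @param pred A `coev_distogram`, or an L x L contact-probability matrix.
#' @param native A `coev_labels` or L x L logical contact map.
#' @param target Optional target identifier recorded in the report.
#' @return Tibble of class `coev_eval` with columns `target`, `range`,
#'   `depth` (`"L/10"`, ...), `n_evaluated`, `n_correct`, `precision`.
#' @export
evaluate_target <- function(pred, native, target = NA_character_) {
  P <- if (inherits(pred, "coev_distogram")) contact_probability(pred) else pred
  if (inherits(native, "coev_labels")) native <- native$contacts
  stopifnot(identical(dim(P), dim(native)))
  if (!any(native)) message("native map has no contacts; precisions are 0")
  L <- nrow(P)
  grid <- expand.grid(range = c("medium", "long"), k = c(10, 5, 2, 1),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    rg <- grid$range[r]; k <- grid$k[r]
    depth <- max(1L, L %/% k)
    top <- rank_contacts(P, range = rg, depth = depth)
    nc <- if (nrow(top)) sum(native[cbind(top$i, top$j)]) else 0L
    tibble::tibble(target = target, range = rg,
                   depth = sprintf("L/%d", k),
                   n_evaluated = nrow(top), n_correct = as.integer(nc),
                   precision = if (nrow(top)) nc / nrow(top) else 0)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("coev_eval", class(out))
  out
}

#' Read per-residue interaction sites from a PDB file
#'
#' One coordinate per residue: the C-beta atom when present, the C-alpha for
#' glycine (silently) or when C-beta is missing (with a warning). Altloc
#' ambiguity resolves to the first-listed conformer.
#'
#' @param path Single-chain PDB-format file.
#' @return List: `coords` (L x 3), `resno` (residue numbers), `resid`
#'   (3-letter residue names).
#' @export
read_structure_cb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety %in% c("CA", "CB"), , drop = FALSE]
  if (nrow(at) == 0L) stop("no CA/CB atoms found")
  # first-listed altloc wins
  at <- at[!duplicated(at[, c("resno", "chain", "elety")]), , drop = FALSE]
  resnos <- unique(at$resno)
  coords <- matrix(NA_real_, length(resnos), 3L)
  resid <- character(length(resnos))
  fallback <- character(0)
  for (r in seq_along(resnos)) {
    rows <- at[at$resno == resnos[r], , drop = FALSE]
    resid[r] <- rows$resid[1L]
    pick <- if ("CB" %in% rows$elety) "CB" else "CA"
    if (pick == "CA" && rows$resid[1L] != "GLY") {
      fallback <- c(fallback, as.character(resnos[r]))
    }
    xyz <- rows[rows$elety == pick, c("x", "y", "z")][1L, ]
    coords[r, ] <- as.numeric(xyz)
  }
  if (length(fallback) > 0) {
    warning(sprintf("C-beta missing for non-glycine residue(s) %s; used C-alpha",
                    paste(fallback, collapse = ", ")))
  }
  if (sum(stats::complete.cases(coords)) < 1L) stop("no parsable residues")
  list(coords = coords, resno = resnos, resid = resid)
}

#' Write a contact map in CASP RR format
#'
#' Lines `i j 0 8 probability` for ranked pairs (1-based residue numbers).
#'
#' @param P L x L contact-probability matrix (or `coev_distogram`).
#' @param path Output file.
#' @param min_separation Minimum `j - i` to report (default 1).
#' @param depth Maximum pairs written (default all).
#' @return `path`, invisibly.
#' @export
write_rr <- function(P, path, min_separation = 1L, depth = Inf) {
  if (inherits(P, "coev_distogram")) P <- contact_probability(P)
  top <- rank_contacts(P, range = "all", depth = Inf)
  top <- top[top$separation >= min_separation, , drop = FALSE]
  if (is.finite(depth)) top <- top[seq_len(min(nrow(top), depth)), , drop = FALSE]
  lines <- sprintf("%d %d 0 8 %.6f", top$i, top$j, top$probability)
  writeLines(lines, path)
  invisible(path)
}

#' Read a CASP RR contact file
#'
#' @param path RR file with lines `i j d1 d2 probability`.
#' @param L Sequence length of the reconstructed matrix (default: max index).
#' @return L x L symmetric contact-probability matrix.
#' @export
read_rr <- function(path, L = NULL) {
  lines <- readLines(path)
  lines <- lines[grepl("^\\s*\\d+\\s+\\d+\\s", lines)]
  if (length(lines) == 0L) stop("no contact records in RR file")
  fields <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(x) {
    as.numeric(x[c(1, 2, length(x))])
  }))
  if (is.null(L)) L <- max(fields[, 1:2])
  P <- matrix(0, L, L)
  P[fields[, 1:2, drop = FALSE]] <- fields[, 3L]
  P[fields[, 2:1, drop = FALSE]] <- fields[, 3L]
  P
}
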