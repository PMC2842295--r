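#' Position weight matrix
#'
#' Constructs a PWM object from an L x 4 probability matrix. Rows are
#' motif positions, columns the bases in A, C, G, T order; each row sums
#' to 1. `pseudocount` records the Dirichlet prior mass per base used in
#' estimation (0 for matrices not estimated from counts, e.g. converted
#' log-odds matrices).
#'
#' @param probs numeric L x 4 matrix of per-position base probabilities.
#' @param pseudocount non-negative prior mass per base.
#' @return an object of class `pwm`.
#' @seealso [build_pwm()] to estimate one from aligned sites.
#' @export
pwm <- function(probs, pseudocount = 0) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("a PWM needs exactly 4 columns (A, C, G, T)")
  if (nrow(probs) < 1L) stop("a PWM needs at least one position")
  if (any(probs < 0)) stop("PWM probabilities must be non-negative")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-9)) stop("each PWM row must sum to 1")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (pseudocount > 0 && any(probs <= 0)) {
    stop("with a positive pseudocount every PWM entry must be positive")
  }
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(list(probs = probs, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, digits = 3, ...) {
  cat("pwm: L =", nrow(x$probs), "bp, pseudocount =", x$pseudocount, "\n")
  print(round(x$probs, digits))
  invisible(x)
}

#' Motif length
#'
#' Number of positions of a `pwm` or `dwm` model.
#' @param model a `pwm` or `dwm`.
#' @return integer motif length in bp.
#' @export
motif_length <- function(model) {
  if (inherits(model, "pwm")) return(nrow(model$probs))
  if (inherits(model, "dwm")) return(nrow(model$marginal$probs))
  stop("not a pwm or dwm")
}

#' Estimate a PWM from aligned binding sites
#'
#' Relative base frequencies with an additive pseudocount:
#' `w[i, a] = (n[a, i] + kappa) / (N + 4 kappa)`, equivalent to the
#' posterior mean under a symmetric Dirichlet(kappa) prior on each
#' column. An empty alignment returns the pure prior (all entries 1/4).
#'
#' @param alignment a [site_alignment()].
#' @param pseudocount kappa, positive prior mass per base (default 1,
#'   the flat "uniform prior").
#' @return a [pwm()].
#' @examples
#' build_pwm(site_alignment(c("AA", "TT")))$probs  # A and T rows 1/3
#' @export
build_pwm <- function(alignment, pseudocount = 1) {
  stopifnot(inherits(alignment, "site_alignment"))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  pwm_from_counts(base_counts(alignment), alignment$N, pseudocount)
}

pwm_from_counts <- function(counts, N, pseudocount) {
  pwm((counts + pseudocount) / (N + 4 * pseudocount), pseudocount)
}

#' Dinucleotide weight matrix
#'
#' A DWM stores, for every ordered position pair i < j of a length-L
#' motif, the 4 x 4 joint probability of observing bases (a, b) at
#' (i, j), together with its single-nucleotide marginal PWM. Pairs with
#' i > j are defined by symmetry: `pair(j, i)[b, a] == pair(i, j)[a, b]`;
#' only i < j tables are stored (the object is quadratic in L, and this
#' halves it). Use [dwm_pair()] to access any orientation.
#'
#' @param pairs list of 4 x 4 joint tables in `pair_index()` order
#'   (rows = base at i, columns = base at j); each must sum to 1.
#' @param marginal the marginal [pwm()] of the same length.
#' @param prior_mass total prior pseudocount spread over the 16
#'   dinucleotides (default 16, i.e. the PWM-product prior normalised to
#'   sum to 16).
#' @return an object of class `dwm`.
#' @seealso [build_dwm()], [dwm_from_pwm()]
#' @export
dwm <- function(pairs, marginal, prior_mass = 16) {
  stopifnot(inherits(marginal, "pwm"))
  L <- nrow(marginal$probs)
  npair <- (L * (L - 1L)) %/% 2L
  if (length(pairs) != npair) {
    stop("expected ", npair, " pair tables for L = ", L, ", got ", length(pairs))
  }
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    if (!is.matrix(p) || any(dim(p) != 4L)) stop("pair table ", k, " is not 4 x 4")
    if (abs(sum(p) - 1) > 1e-9) stop("pair table ", k, " does not sum to 1")
    if (any(p < 0)) stop("pair table ", k, " has negative entries")
    dimnames(pairs[[k]]) <- list(DNA_BASES, DNA_BASES)
  }
  structure(list(pairs = pairs, marginal = marginal,
                 prior_mass = prior_mass),
            class = "dwm")
}

#' @export
print.dwm <- function(x, ...) {
  L <- motif_length(x)
  cat("dwm: L =", L, "bp,", length(x$pairs),
      "pair tables, prior_mass =", x$prior_mass, "\n")
  cat("marginal:\n")
  print(x$marginal)
  invisible(x)
}

#' Joint table for one position pair of a DWM
#'
#' Returns the 4 x 4 joint probability table for positions (i, j), rows
#' indexed by the base at i and columns by the base at j. For i > j the
#' stored i < j table is transposed, per the DWM symmetry convention.
#'
#' @param dwm a [dwm()].
#' @param i,j distinct 1-based positions.
#' @return 4 x 4 numeric matrix.
#' @export
dwm_pair <- function(dwm, i, j) {
  L <- motif_length(dwm)
  stopifnot(i >= 1L, j >= 1L, i <= L, j <= L, i != j)
  if (i < j) dwm$pairs[[pair_index(i, j, L)]] else t(dwm$pairs[[pair_index(j, i, L)]])
}

#' Estimate a DWM from aligned binding sites
#'
#' For each position pair i < j and dinucleotide (a, b), the joint
#' probability is `(m[a, b] + 16 w[i, a] w[j, b]) / (N + 16)`, where m is
#' the joint count and w the marginal PWM estimated from the same
#' alignment with the same pseudocount. The prior is thus the product of
#' the marginal PWM columns normalised to total mass 16 (one pseudocount
#' per dinucleotide in the independent-columns limit), rather than the
#' flat Dirichlet that complete ignorance would dictate: columns of real
#' motifs are roughly independent, and the marginal is estimated far
#' better than the joint.
#'
#' @inheritParams build_pwm
#' @return a [dwm()] with the marginal PWM stored.
#' @examples
#' d <- build_dwm(site_alignment(c("AA", "TT")))
#' dwm_pair(d, 1, 2)["A", "A"]  # (1 + 16/9) / 18 = 25/162
#' @export
build_dwm <- function(alignment, pseudocount = 1) {
  stopifnot(inherits(alignment, "site_alignment"))
  if (alignment$L < 2L) stop("a DWM needs a motif of length at least 2")
  dwm_from_counts(pair_counts(alignment), base_counts(alignment),
                  alignment$N, pseudocount)
}

dwm_from_counts <- function(pcounts, counts, N, pseudocount, prior_mass = 16) {
  marg <- pwm_from_counts(counts, N, pseudocount)
  L <- nrow(marg$probs)
  w <- marg$probs
  pairs <- vector("list", length(pcounts))
  for (i in seq_len(L - 1L)) {
    for (j in seq.int(i + 1L, L)) {
      k <- pair_index(i, j, L)
      prior <- prior_mass * (w[i, ] %o% w[j, ])
      pairs[[k]] <- (pcounts[[k]] + prior) / (N + prior_mass)
    }
  }
  dwm(pairs, marg, prior_mass)
}

#' Embed a PWM as a correlation-free DWM
#'
#' Sets every joint table to the outer product of the marginal columns,
#' `pair(i, j)[a, b] = w[i, a] w[j, b]`. Scoring with the result is
#' identical to scoring with the PWM (the posterior-likelihood
#' approximation reduces exactly to the PWM likelihood when all pairs
#' factorise).
#'
#' @param pwm a [pwm()].
#' @return a [dwm()].
#' @export
dwm_from_pwm <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  L <- nrow(pwm$probs)
  if (L < 2L) stop("a DWM needs a motif of length at least 2")
  w <- pwm$probs
  pairs <- vector("list", (L * (L - 1L)) %/% 2L)
  for (i in seq_len(L - 1L)) {
    for (j in seq.int(i + 1L, L)) {
      pairs[[pair_index(i, j, L)]] <- w[i, ] %o% w[j, ]
    }
  }
  dwm(pairs, pwm, prior_mass = 16)
}

#' Information content of a PWM column
#'
#' `2 + sum_a w[i, a] log2 w[i, a]` bits: 2 for a deterministic column,
#' 0 for a uniform one. Terms with w = 0 contribute 0.
#'
#' @param pwm a [pwm()].
#' @param i 1-based column (position) index.
#' @return information content in bits.
#' @export
column_information_content <- function(pwm, i) {
  stopifnot(inherits(pwm, "pwm"))
  L <- nrow(pwm$probs)
  if (i < 1L || i > L) stop("column index out of range")
  w <- pwm$probs[i, ]
  w <- w[w > 0]
  2 + sum(w * log2(w))
}

#' Reverse complement of a motif model
#'
#' Generic with methods for `pwm`, `dwm` and plain character strings.
#' For a PWM, `probs'[i, a] = probs[L+1-i, comp(a)]`; for a DWM,
#' `pair'(i, j)[a, b] = pair(L+1-j, L+1-i)[comp(b), comp(a)]`. Applying
#' it twice restores the original model bit-exactly. Scoring a sequence
#' with the reverse-complemented model equals scoring the
#' reverse-complemented sequence with the original.
#'
#' @param x model or string to reverse-complement.
#' @param ... unused.
#' @return object of the same type as `x`.
#' @export
revcomp <- function(x, ...) UseMethod("revcomp")

#' @rdname revcomp
#' @export
revcomp.character <- function(x, ...) {
  vapply(x, revcomp_string, character(1L), USE.NAMES = FALSE)
}

#' @rdname revcomp
#' @export
revcomp.pwm <- function(x, ...) {
  L <- nrow(x$probs)
  p <- x$probs[L:1L, COMP_IDX, drop = FALSE]
  pwm(p, x$pseudocount)
}

#' @rdname revcomp
#' @export
revcomp.dwm <- function(x, ...) {
  L <- motif_length(x)
  pairs <- vector("list", length(x$pairs))
  for (i in seq_len(L - 1L)) {
    for (j in seq.int(i + 1L, L)) {
      # source pair (L+1-j, L+1-i) has L+1-j < L+1-i, so it is stored
      src <- dwm_pair(x, L + 1L - j, L + 1L - i)
      pairs[[pair_index(i, j, L)]] <- t(src)[COMP_IDX, COMP_IDX]
    }
  }
  dwm(pairs, revcomp(x$marginal), x$prior_mass)
}

#' Build an alignment from site coordinates, with optional flanks
#'
#' Extracts each site (0-based, half-open coordinates) from its source
#' sequence, widened by `flank` bp on both sides; minus-strand sites are
#' reverse-complemented so all sites are in motif orientation. Sites
#' whose widened window overruns the sequence, or that contain non-ACGT
#' characters, are dropped with a message rather than padded or imputed:
#' padding would inject background composition into the matrix estimate.
#'
#' @param sites data.frame with columns `sequence_id`, `start`, `end`
#'   (0-based half-open), `strand` ("+"/"-"). All sites must have equal
#'   width.
#' @param genome named character vector (or `DNAStringSet`) of source
#'   sequences.
#' @param flank non-negative widening in bp per side.
#' @return a [site_alignment()] with `source_ids` set to `sequence_id`.
#' @export
extend_alignment_with_flank <- function(sites, genome, flank = 0L) {
  stopifnot(is.data.frame(sites), flank >= 0)
  nms <- names(genome)
  genome <- as.character(genome)
  names(genome) <- nms
  if (is.null(names(genome))) stop("genome sequences must be named")
  if (nrow(sites) == 0L) stop("no sites supplied")
  widths <- sites$end - sites$start
  if (length(unique(widths)) != 1L) stop("all sites must have equal width")
  seqs <- character(0)
  ids <- character(0)
  dropped <- 0L
  for (r in seq_len(nrow(sites))) {
    id <- as.character(sites$sequence_id[r])
    src <- genome[[id]]
    if (is.null(src) || is.na(src)) stop("unknown sequence_id: ", id)
    s <- sites$start[r] - flank
    e <- sites$end[r] + flank
    if (s < 0 || e > nchar(src)) { dropped <- dropped + 1L; next }
    win <- toupper(substr(src, s + 1L, e))
    if (identical(sites$strand[r], "-")) win <- revcomp_string(win)
    if (grepl("[^ACGT]", win)) { dropped <- dropped + 1L; next }
    seqs <- c(seqs, win)
    ids <- c(ids, id)
  }
  if (dropped > 0L) {
    message(dropped, " site(s) dropped (window out of bounds or non-ACGT)")
  }
  if (length(seqs) == 0L) {
    stop("all ", nrow(sites), " sites were dropped; empty alignment")
  }
  site_alignment(seqs, source_ids = ids)
}
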