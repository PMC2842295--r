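#' Aligned binding-site set
#'
#' A `site_alignment` holds N equal-length nucleotide strings, optionally
#' tagged with the sequence (probe) each site came from, so that
#' leave-one-out matrices can exclude all sites of one probe. All motif
#' matrices in the package are estimated from such alignments.
#'
#' @param sequences character vector of equal-length A/C/G/T strings
#'   (may be empty; the alignment length must then be given via `L`).
#' @param source_ids optional character vector, one label per sequence,
#'   recording the origin probe/sequence of each site.
#' @param L motif length; required when `sequences` is empty, otherwise
#'   inferred and checked.
#' @return an object of class `site_alignment` with fields `seqs`, `L`,
#'   `N`, `source_ids`.
#' @examples
#' aln <- site_alignment(c("ACGT", "ACGA"))
#' aln$N
#' @export
site_alignment <- function(sequences = character(), source_ids = NULL, L = NULL) {
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  if (n > 0L) {
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      stop("all aligned sequences must have the same length; observed lengths: ",
           paste(sort(unique(lens)), collapse = ", "))
    }
    if (!is.null(L) && L != lens[1L]) {
      stop("declared length L=", L, " does not match sequence length ", lens[1L])
    }
    L <- lens[1L]
    bad <- grep("[^ACGT]", sequences)
    if (length(bad) > 0L) {
      stop("non-ACGT character in aligned sequence ", bad[1L],
           " ('", sequences[bad[1L]], "')")
    }
  } else if (is.null(L)) {
    stop("an empty alignment needs an explicit motif length L")
  }
  if (!is.null(source_ids)) {
    source_ids <- as.character(source_ids)
    if (length(source_ids) != n) stop("source_ids must match the number of sequences")
  }
  structure(list(seqs = sequences, L = as.integer(L), N = n,
                 source_ids = source_ids),
            class = "site_alignment")
}

#' @export
print.site_alignment <- function(x, ...) {
  cat("site_alignment: N =", x$N, "sites of length L =", x$L, "bp\n")
  if (x$N > 0L) {
    show <- utils::head(x$seqs, 5L)
    cat(paste0("  ", show, collapse = "\n"), "\n")
    if (x$N > 5L) cat("  ...\n")
  }
  invisible(x)
}

# N x L integer matrix of base codes (1..4) for an alignment.
alignment_codes <- function(aln) {
  if (aln$N == 0L) return(matrix(integer(), 0L, aln$L))
  m <- matrix(match(unlist(strsplit(aln$seqs, "", fixed = TRUE)), DNA_BASES),
              nrow = aln$N, ncol = aln$L, byrow = TRUE)
  m
}

# L x 4 single-nucleotide count matrix n_{alpha i} (rows = positions).
base_counts <- function(aln) {
  codes <- alignment_codes(aln)
  t(apply(matrix(codes, ncol = aln$L), 2L, tabulate, nbins = 4L))
}

# Joint dinucleotide counts m_{alpha beta i j} for all ordered pairs i < j.
# Returns a list indexed by pair_index(i, j, L); each element is a 4 x 4
# matrix with rows = base at i, columns = base at j.
pair_counts <- function(aln) {
  L <- aln$L
  codes <- alignment_codes(aln)
  out <- vector("list", (L * (L - 1L)) %/% 2L)
  for (i in seq_len(L - 1L)) {
    for (j in seq.int(i + 1L, L)) {
      idx <- (codes[, i] - 1L) * 4L + codes[, j]
      out[[pair_index(i, j, L)]] <-
        matrix(tabulate(idx, nbins = 16L), 4L, 4L, byrow = TRUE,
               dimnames = list(DNA_BASES, DNA_BASES))
    }
  }
  out
}

# Linear index of ordered pair i < j in the enumeration
# (1,2),(1,3),...,(1,L),(2,3),...,(L-1,L).
pair_index <- function(i, j, L) {
  stopifnot(i < j)
  (i - 1L) * L - (i * (i - 1L)) %/% 2L + (j - i)
}
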