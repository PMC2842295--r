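#' Gapped-dinucleotide deviation statistics
#'
#' For every ordered column pair i < j of the alignment and every
#' dinucleotide (a, b), compares the observed number of sites carrying
#' (a, b) at (i, j) with the number expected under column independence:
#' `E = N p`, `sigma = sqrt(N p (1 - p))` with `p = w[i, a] w[j, b]`
#' taken from the supplied PWM (normally built from the same alignment,
#' so expectations include the pseudocount). A record is `significant`
#' when `|n_obs - E| > 2 sigma` (strict), and `abundant` when
#' `max(n_obs, E) >= 0.3 N` (at least), screening out deviations driven
#' by near-zero expected counts.
#'
#' @param alignment a [site_alignment()] with N >= 1.
#' @param pwm the [pwm()] giving the independence expectations; defaults
#'   to `build_pwm(alignment)`.
#' @return data.frame with one row per (i, j, a, b): columns `i`, `j`,
#'   `gap` (= j - i, adjacent columns have gap 1), `alpha`, `beta`,
#'   `n_obs`, `E`, `sigma`, `z`, `significant`, `abundant`.
#' @examples
#' aln <- site_alignment(rep(c("AA", "TT"), each = 50))
#' d <- pair_deviation_stats(aln)
#' subset(d, alpha == "A" & beta == "A")  # z about 6.07
#' @export
pair_deviation_stats <- function(alignment, pwm = build_pwm(alignment)) {
  stopifnot(inherits(alignment, "site_alignment"), inherits(pwm, "pwm"))
  if (alignment$N < 1L) stop("deviation statistics need at least one sequence")
  L <- alignment$L
  if (nrow(pwm$probs) != L) stop("PWM length does not match the alignment")
  N <- alignment$N
  w <- pwm$probs
  pc <- pair_counts(alignment)
  npair <- (L * (L - 1L)) %/% 2L
  ii <- jj <- integer(npair * 16L)
  aa <- bb <- integer(npair * 16L)
  nn <- integer(npair * 16L)
  grid <- expand.grid(b = 1:4, a = 1:4)[, c("a", "b")]  # a-major order
  row0 <- 0L
  for (i in seq_len(L - 1L)) {
    for (j in seq.int(i + 1L, L)) {
      k <- pair_index(i, j, L)
      idx <- row0 + 1:16
      ii[idx] <- i; jj[idx] <- j
      aa[idx] <- grid$a; bb[idx] <- grid$b
      nn[idx] <- pc[[k]][cbind(grid$a, grid$b)]
      row0 <- row0 + 16L
    }
  }
  p <- w[cbind(ii, aa)] * w[cbind(jj, bb)]
  E <- N * p
  sigma <- sqrt(N * p * (1 - p))
  z <- ifelse(sigma > 0, (nn - E) / sigma, 0)
  data.frame(i = ii, j = jj, gap = jj - ii,
             alpha = DNA_BASES[aa], beta = DNA_BASES[bb],
             n_obs = nn, E = E, sigma = sigma, z = z,
             significant = abs(nn - E) > 2 * sigma,
             abundant = pmax(nn, E) >= 0.3 * N,
             stringsAsFactors = FALSE)
}

#' Summarise flagged correlated dinucleotides
#'
#' Counts, over a deviation table (optionally spanning several factors
#' via a `factor` column): significant records, records passing both the
#' 2-sigma and the 30%-abundance filters, and distinct column pairs with
#' at least one such record ("correlated column pairs"). With a `factor`
#' column, per-factor pair counts and the number of factors having 3 or
#' more correlated column pairs are also returned.
#'
#' @param devs data.frame from [pair_deviation_stats()] (rows from
#'   several factors may be concatenated with a `factor` column added).
#' @return list with `n_significant`, `n_significant_abundant`,
#'   `n_correlated_pairs`, and (when a `factor` column is present)
#'   `per_factor` (data.frame factor / n_sig_abundant / n_pairs) and
#'   `n_factors_3plus`.
#' @export
flag_correlated_pairs <- function(devs) {
  if (is.null(devs) || nrow(devs) == 0L) {
    return(list(n_significant = 0L, n_significant_abundant = 0L,
                n_correlated_pairs = 0L))
  }
  hit <- devs$significant & devs$abundant
  fac <- if ("factor" %in% names(devs)) as.character(devs$factor) else
    rep("motif", nrow(devs))
  pair_key <- paste(fac, devs$i, devs$j)
  out <- list(
    n_significant = sum(devs$significant),
    n_significant_abundant = sum(hit),
    n_correlated_pairs = length(unique(pair_key[hit]))
  )
  if ("factor" %in% names(devs)) {
    per <- vapply(split(seq_len(nrow(devs)), fac), function(idx) {
      c(n_sig_abundant = sum(hit[idx]),
        n_pairs = length(unique(pair_key[idx][hit[idx]])))
    }, numeric(2))
    per_factor <- data.frame(factor = colnames(per),
                             n_sig_abundant = per["n_sig_abundant", ],
                             n_pairs = per["n_pairs", ],
                             row.names = NULL, stringsAsFactors = FALSE)
    out$per_factor <- per_factor
    out$n_factors_3plus <- sum(per_factor$n_pairs >= 3)
  }
  out
}

#' Gap distribution of flagged dinucleotide pairs
#'
#' Histograms the gaps (j - i) of flagged deviation records, both as raw
#' dinucleotide records and as distinct column pairs, and normalises by
#' availability: a motif of length L offers `max(L - g, 0)` column pairs
#' at gap g, so short gaps are over-represented before correction.
#' Gaps with zero availability are omitted.
#'
#' @param flagged data.frame of deviation records to histogram (the
#'   caller applies whatever filter defines "flagged", e.g.
#'   `significant & abundant`); an optional `factor` column separates
#'   motifs when counting distinct pairs.
#' @param motif_lengths integer vector of the lengths of the motifs the
#'   records came from (one entry per motif).
#' @return data.frame with columns `gap`, `count_records`,
#'   `count_pairs`, `availability`, `rate_records`, `rate_pairs`.
#' @export
gap_distribution <- function(flagged, motif_lengths) {
  stopifnot(length(motif_lengths) >= 1L)
  max_gap <- max(motif_lengths) - 1L
  if (max_gap < 1L) stop("motifs must have length at least 2")
  gaps <- seq_len(max_gap)
  avail <- vapply(gaps, function(g) sum(pmax(motif_lengths - g, 0L)), numeric(1))
  if (is.null(flagged) || nrow(flagged) == 0L) {
    cr <- cp <- rep(0L, max_gap)
  } else {
    fac <- if ("factor" %in% names(flagged)) as.character(flagged$factor) else
      rep("motif", nrow(flagged))
    cr <- vapply(gaps, function(g) sum(flagged$gap == g), integer(1))
    key <- paste(fac, flagged$i, flagged$j)
    cp <- vapply(gaps, function(g)
      length(unique(key[flagged$gap == g])), integer(1))
  }
  keep <- avail > 0
  data.frame(gap = gaps[keep], count_records = cr[keep],
             count_pairs = cp[keep], availability = avail[keep],
             rate_records = cr[keep] / avail[keep],
             rate_pairs = cp[keep] / avail[keep])
}
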