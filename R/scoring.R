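#' Background nucleotide model
#'
#' Single-nucleotide background probabilities in A, C, G, T order.
#' The default is uniform; [background_from_sequences()] estimates
#' genomic frequencies from a sequence collection.
#'
#' @param probs numeric length-4 vector of positive probabilities
#'   summing to 1.
#' @return named numeric vector of class `background_model`.
#' @export
background_model <- function(probs = rep(0.25, 4)) {
  probs <- as.numeric(probs)
  if (length(probs) != 4L) stop("a background model needs 4 probabilities")
  if (any(probs <= 0)) stop("background probabilities must be positive")
  if (abs(sum(probs) - 1) > 1e-12) stop("background probabilities must sum to 1")
  structure(setNames(probs, DNA_BASES), class = "background_model")
}

#' @rdname background_model
#' @param sequences character vector (or `DNAStringSet`) of sequences;
#'   mononucleotide frequencies are counted over A/C/G/T only, with one
#'   smoothing count per base so no frequency is zero.
#' @export
background_from_sequences <- function(sequences) {
  s <- toupper(paste(as.character(sequences), collapse = ""))
  codes <- match(strsplit(s, "", fixed = TRUE)[[1L]], DNA_BASES)
  counts <- tabulate(codes[!is.na(codes)], nbins = 4L)
  background_model((counts + 1) / (sum(counts) + 4))
}

as_background <- function(background) {
  if (is.null(background)) return(background_model())
  if (inherits(background, "background_model")) return(background)
  background_model(background)
}

encode_window <- function(window, L) {
  codes <- encode_dna(window)
  if (length(codes) != L) {
    stop("window length ", length(codes), " does not match model length ", L)
  }
  if (anyNA(codes)) stop("window contains a non-ACGT character")
  codes
}

#' PWM log-likelihood of a window
#'
#' Natural log of the product of per-position probabilities,
#' `sum_i ln w[i, s_i]`.
#'
#' @param pwm a [pwm()].
#' @param window nucleotide string of the model's length.
#' @return log-likelihood (natural log).
#' @export
pwm_log_likelihood <- function(pwm, window) {
  stopifnot(inherits(pwm, "pwm"))
  L <- nrow(pwm$probs)
  codes <- encode_window(window, L)
  sum(log(pwm$probs[cbind(seq_len(L), codes)]))
}

# log-space inputs for the C++ kernels
dwm_log_tables <- function(dwm) {
  L <- motif_length(dwm)
  lp <- matrix(NA_real_, length(dwm$pairs), 16L)
  for (k in seq_along(dwm$pairs)) {
    lp[k, ] <- as.vector(t(log(dwm$pairs[[k]])))  # row-major (a, b)
  }
  list(logw = log(dwm$marginal$probs), logpairs = lp)
}

#' DWM posterior log-likelihood of a window
#'
#' Approximates the probability of a window under a dinucleotide model
#' as the product over positions of the Bayesian posterior probability
#' of the observed base given all other bases in the window. For each
#' position i, the unnormalised weight of base a is
#' `u_i(a) = w[i, a] * prod_{j != i} pair(i, j)[a, s_j] / w[i, a]`
#' and the posterior is `u_i(s_i) / Z_i` with `Z_i = sum_a u_i(a)`.
#' All arithmetic is in natural-log space with a stable log-sum-exp for
#' `Z_i` (with L around 30, each `u_i` multiplies ~29 likelihood ratios
#' and would underflow in linear space). Each posterior column sums to
#' 1, but the product over windows is an unnormalised discrimination
#' score, not a distribution over sequences. When every pair table
#' factorises (see [dwm_from_pwm()]) the result equals the PWM
#' log-likelihood exactly.
#'
#' @param dwm a [dwm()].
#' @param window nucleotide string of the model's length.
#' @param profile return the per-position posterior profile as well?
#' @return if `profile = FALSE`, the log-likelihood; otherwise a list
#'   with `loglik`, and a `profile` list holding `u` (4 x L
#'   unnormalised weights), `Z` (length-L normalisers), and `posterior`
#'   (4 x L column-stochastic matrix).
#' @export
dwm_log_likelihood <- function(dwm, window, profile = FALSE) {
  stopifnot(inherits(dwm, "dwm"))
  L <- motif_length(dwm)
  codes <- encode_window(window, L)
  lt <- dwm_log_tables(dwm)
  res <- cpp_dwm_posterior(lt$logw, lt$logpairs, codes - 1L)
  if (!profile) return(res$loglik)
  logu <- res$logu
  logz <- res$logz
  post <- exp(sweep(logu, 2L, logz, "-"))
  dimnames(post) <- list(DNA_BASES, NULL)
  u <- exp(logu)
  dimnames(u) <- list(DNA_BASES, NULL)
  list(loglik = res$loglik,
       profile = list(u = u, Z = exp(logz), posterior = post))
}

#' Log-odds of a window
#'
#' Model log-likelihood minus the background log-likelihood
#' `sum_i ln b[s_i]`, in natural-log units.
#'
#' @param model_loglik model log-likelihood of the window (from
#'   [pwm_log_likelihood()] or [dwm_log_likelihood()]).
#' @param window the scored nucleotide string.
#' @param background a [background_model()] (or length-4 probabilities).
#' @return the log-odds.
#' @export
log_odds <- function(model_loglik, window, background = background_model()) {
  bg <- as_background(background)
  codes <- encode_window(window, nchar(window))
  model_loglik - sum(log(bg[codes]))
}

#' Scan a sequence on both strands
#'
#' Scores every length-L window of `seq` against the model and the
#' background, in both orientations (the window as-is, and its reverse
#' complement), and reports for each start position the better of the
#' two log-odds and its strand (ties go to "+"). Windows containing
#' non-ACGT characters are skipped. Coordinates are 0-based, half-open.
#'
#' @param model a [pwm()] or [dwm()].
#' @param seq nucleotide string to scan (length >= L; shorter input
#'   yields an empty result with a warning).
#' @param background a [background_model()]; default uniform.
#' @param seq_id label recorded in the output.
#' @return data.frame with columns `sequence_id`, `start`, `end`,
#'   `name`, `logodds`, `strand` (BED6-like).
#' @export
scan_sequence <- function(model, seq, background = background_model(),
                          seq_id = "seq") {
  bg <- as_background(background)
  L <- motif_length(model)
  seq <- toupper(as.character(seq))
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), name = character(),
                      logodds = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < L) {
    warning("sequence '", seq_id, "' shorter than the model (",
            nchar(seq), " < ", L, " bp)")
    return(empty)
  }
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES)
  codes0 <- ifelse(is.na(codes), -1L, codes - 1L)
  fwd_in <- model_log_inputs(model)
  rc_in <- model_log_inputs(revcomp(model))
  lo_f <- cpp_scan_logodds(fwd_in$logw, fwd_in$logpairs, codes0, log(bg))
  # scoring the forward window with the reverse-complemented model equals
  # scoring the reverse-complemented window with the model; the matching
  # background term uses complemented base probabilities
  lo_r <- cpp_scan_logodds(rc_in$logw, rc_in$logpairs, codes0, log(bg[COMP_IDX]))
  keep <- which(!is.na(lo_f))
  if (length(keep) == 0L) return(empty)
  best <- pmax(lo_f[keep], lo_r[keep])
  strand <- ifelse(lo_f[keep] >= lo_r[keep], "+", "-")
  start <- keep - 1L
  data.frame(sequence_id = seq_id, start = start, end = start + L,
             name = paste0(seq_id, "_", start),
             logodds = best, strand = strand, stringsAsFactors = FALSE)
}

model_log_inputs <- function(model) {
  if (inherits(model, "pwm")) {
    list(logw = log(model$probs), logpairs = NULL)
  } else if (inherits(model, "dwm")) {
    dwm_log_tables(model)
  } else stop("model must be a pwm or dwm")
}

#' Total log-odds of a scanned sequence
#'
#' Sum of the per-start best-orientation log-odds over all scored
#' windows of one sequence ("all possible sites"). With
#' `positive_only = TRUE` only positive contributions are summed.
#'
#' @param sites data.frame of scored sites (from [scan_sequence()]).
#' @param positive_only restrict the sum to positive log-odds?
#' @return the summed log-odds (0 for an empty site list).
#' @export
total_log_odds <- function(sites, positive_only = FALSE) {
  if (is.null(sites) || nrow(sites) == 0L) return(0)
  x <- sites$logodds
  if (positive_only) x <- x[x > 0]
  sum(x)
}
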