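#' Mixture-of-PWMs motif model
#'
#' A ground-truth generative model for correlated binding sites: each
#' site is drawn from one of several PWMs of common length, chosen with
#' the component weights. Although every component has independent
#' columns, the mixture induces pairwise correlations with a closed
#' form: `P(a at i, b at j) = sum_c weight_c w_c[i, a] w_c[j, b]`,
#' giving an exact analytic oracle for correlation-recovery tests
#' (unlike Gibbs samples from a pairwise field).
#'
#' @param weights positive component weights summing to 1.
#' @param components list of [pwm()] objects (or L x 4 probability
#'   matrices) of a common length.
#' @return an object of class `mixture_motif`.
#' @export
mixture_motif_model <- function(weights, components) {
  weights <- as.numeric(weights)
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(weights <= 0)) stop("mixture weights must be positive")
  if (length(weights) != length(components)) {
    stop("one weight per component required")
  }
  components <- lapply(components, function(p) {
    if (inherits(p, "pwm")) p else pwm(p)
  })
  Ls <- vapply(components, motif_length, integer(1))
  if (length(unique(Ls)) != 1L) stop("all components must have the same length")
  structure(list(weights = weights, components = components, L = Ls[1L]),
            class = "mixture_motif")
}

#' @rdname mixture_motif_model
#' @param model a `mixture_motif`.
#' @param i,j distinct 1-based positions.
#' @return `mixture_pair_joint`: the exact 4 x 4 joint probability of
#'   bases at positions (i, j) under the mixture.
#' @export
mixture_pair_joint <- function(model, i, j) {
  stopifnot(inherits(model, "mixture_motif"))
  out <- matrix(0, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  for (c in seq_along(model$weights)) {
    w <- model$components[[c]]$probs
    out <- out + model$weights[c] * (w[i, ] %o% w[j, ])
  }
  out
}

#' @rdname mixture_motif_model
#' @return `mixture_marginal`: the marginal single-nucleotide [pwm()]
#'   of the mixture.
#' @export
mixture_marginal <- function(model) {
  stopifnot(inherits(model, "mixture_motif"))
  probs <- Reduce(`+`, Map(function(wt, cmp) wt * cmp$probs,
                           model$weights, model$components))
  pwm(probs, pseudocount = 0)
}

sample_codes_from_probs <- function(probs, n) {
  L <- nrow(probs)
  codes <- matrix(0L, n, L)
  for (i in seq_len(L)) {
    codes[, i] <- sample.int(4L, n, replace = TRUE, prob = probs[i, ])
  }
  codes
}

codes_to_strings <- function(codes) {
  if (nrow(codes) == 0L) return(character(0))
  apply(codes, 1L, function(r) paste(DNA_BASES[r], collapse = ""))
}

#' Sample aligned sites from a PWM
#'
#' Each site draws every position independently from its PWM column.
#' Bit-exactly reproducible given `seed`; `seed = NULL` uses (and
#' advances) the current RNG stream.
#'
#' @param pwm a [pwm()].
#' @param n number of sites.
#' @param seed optional integer seed.
#' @return a [site_alignment()] of n sites.
#' @export
sample_pwm_sites <- function(pwm, n, seed = NULL) {
  stopifnot(inherits(pwm, "pwm"), n >= 0)
  with_seed(seed, {
    codes <- sample_codes_from_probs(pwm$probs, n)
    site_alignment(codes_to_strings(codes), L = motif_length(pwm))
  })
}

#' Sample aligned sites from a mixture motif model
#'
#' Draws a component per site by weight, then samples the site from
#' that component's PWM; empirical pair joints converge to
#' [mixture_pair_joint()].
#'
#' @param model a [mixture_motif_model()].
#' @param n number of sites.
#' @param seed optional integer seed.
#' @return a [site_alignment()] of n sites.
#' @export
sample_mixture_sites <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "mixture_motif"), n >= 0)
  with_seed(seed, {
    if (length(model$weights) == 1L) {
      # degenerate mixture: identical draw stream to sample_pwm_sites
      codes <- sample_codes_from_probs(model$components[[1L]]$probs, n)
    } else {
      comp <- sample.int(length(model$weights), n, replace = TRUE,
                         prob = model$weights)
      codes <- matrix(0L, n, model$L)
      for (c in seq_along(model$weights)) {
        idx <- which(comp == c)
        if (length(idx) > 0L) {
          codes[idx, ] <- sample_codes_from_probs(model$components[[c]]$probs,
                                                  length(idx))
        }
      }
    }
    site_alignment(codes_to_strings(codes), L = model$L)
  })
}

#' Sample background sequence
#'
#' i.i.d. draws from a single-nucleotide background model.
#'
#' @param background a [background_model()] (or length-4 probabilities).
#' @param length sequence length in bp.
#' @param seed optional integer seed.
#' @return a nucleotide string.
#' @export
sample_background <- function(background = background_model(), length,
                              seed = NULL) {
  bg <- as_background(background)
  stopifnot(length >= 0)
  if (length == 0L) return("")
  with_seed(seed,
            paste(DNA_BASES[sample.int(4L, length, replace = TRUE, prob = bg)],
                  collapse = ""))
}

#' Layout of an embedded-site benchmark sequence
#'
#' @param spacer_length bp of random spacer between embedded units
#'   (default 100).
#' @param flank bp of background flanking each embedded site inside its
#'   unit (default 10).
#' @return an object of class `embedding_layout`.
#' @export
embedding_layout <- function(spacer_length = 100L, flank = 10L) {
  stopifnot(spacer_length >= 0, flank >= 0)
  structure(list(spacer_length = as.integer(spacer_length),
                 flank = as.integer(flank)),
            class = "embedding_layout")
}

#' Build a benchmark sequence with embedded real and decoy sites
#'
#' Concatenates spacer, embedded unit, spacer, ..., unit, spacer, where
#' each unit is one site plus `flank` bp of background on each side.
#' The units are the supplied real sites plus an equal number of decoy
#' ("fake") sites sampled from `fake_model`, in randomised order.
#' Spacers and flanks are drawn from `background` (the composition of
#' the spacers is configurable; genomic flanks would require real
#' coordinates, so background flanks stand in for them). Ground-truth
#' intervals are returned in output coordinates: `start`/`end` span the
#' full flank-inclusive unit (consecutive units are separated by
#' exactly `spacer_length` bp), `core_start`/`core_end` the site
#' proper, and `label` is `"real"` or `"fake"`.
#'
#' @param real_sites character vector of at least one real site
#'   sequence.
#' @param fake_model [pwm()] from which decoy sites are sampled.
#' @param layout an [embedding_layout()].
#' @param background a [background_model()] for spacers and flanks.
#' @param seed optional integer seed.
#' @param seq_id label recorded in the truth table.
#' @return list with `sequence` (one string) and `truth` (data.frame
#'   `sequence_id`, `start`, `end`, `core_start`, `core_end`, `label`).
#' @export
build_embedded_benchmark <- function(real_sites, fake_model,
                                     layout = embedding_layout(),
                                     background = background_model(),
                                     seed = NULL, seq_id = "benchmark") {
  stopifnot(length(real_sites) >= 1L, inherits(fake_model, "pwm"),
            inherits(layout, "embedding_layout"))
  bg <- as_background(background)
  with_seed(seed, {
    n <- length(real_sites)
    fakes <- sample_pwm_sites(fake_model, n)$seqs
    units <- c(real_sites, fakes)
    labels <- rep(c("real", "fake"), each = n)
    ord <- sample.int(2L * n)
    units <- units[ord]
    labels <- labels[ord]
    pieces <- character(0)
    pos <- 0L
    truth <- vector("list", length(units))
    for (u in seq_along(units)) {
      spacer <- sample_background(bg, layout$spacer_length)
      lf <- sample_background(bg, layout$flank)
      rf <- sample_background(bg, layout$flank)
      unit <- paste0(lf, toupper(units[u]), rf)
      pieces <- c(pieces, spacer, unit)
      start <- pos + layout$spacer_length
      core_start <- start + layout$flank
      core_end <- core_start + nchar(units[u])
      end <- start + nchar(unit)
      truth[[u]] <- data.frame(sequence_id = seq_id, start = start,
                               end = end, core_start = core_start,
                               core_end = core_end, label = labels[u],
                               stringsAsFactors = FALSE)
      pos <- end
    }
    pieces <- c(pieces, sample_background(bg, layout$spacer_length))
    list(sequence = paste(pieces, collapse = ""),
         truth = do.call(rbind, truth))
  })
}
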