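# shared fixtures, all generated in code

# near-deterministic PWM for a consensus string: consensus base gets
# prob `p`, the rest share the remainder
consensus_pwm <- function(site, p = 0.91) {
  idx <- match(strsplit(site, "", fixed = TRUE)[[1L]], DNA_BASES)
  m <- matrix((1 - p) / 3, length(idx), 4L)
  for (i in seq_along(idx)) m[i, idx[i]] <- p
  pwm(m)
}

# random PWM with Dirichlet(1) rows
random_pwm <- function(L) {
  probs <- t(replicate(L, { g <- rgamma(4L, 1); g / sum(g) }))
  pwm(probs)
}

random_window <- function(L) {
  paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
}

# the AA/TT worked fixture: 2 sites, kappa = 1
aatt_alignment <- function(n_each = 1L) {
  site_alignment(rep(c("AA", "TT"), each = n_each))
}

# two-component mixture with conserved backbone and jointly switching
# A/T columns at positions 3, 6, 9 (L = 10); induces strong pairwise
# correlations with an exact closed form
correlated_mixture <- function(p_cons = 0.91, p_corr = 0.95) {
  backbone <- c("A", "C", NA, "G", "C", NA, "G", "T", NA, "A")
  corr_pos <- which(is.na(backbone))
  comp <- function(base_at_corr) {
    m <- matrix((1 - p_cons) / 3, 10L, 4L)
    for (i in 1:10) {
      b <- if (i %in% corr_pos) base_at_corr else backbone[i]
      pp <- if (i %in% corr_pos) p_corr else p_cons
      m[i, ] <- (1 - pp) / 3
      m[i, match(b, DNA_BASES)] <- pp
    }
    pwm(m)
  }
  mixture_motif_model(c(0.5, 0.5), list(comp("A"), comp("T")))
}

# one synthetic "ChIP" world for the bootstrap benchmark: n_probe
# probe sequences, each embedding sites_per_probe real (mixture) sites
# and as many decoys sampled from the mixture marginal
benchmark_world <- function(seed, n_probe = 20L, sites_per_probe = 10L,
                            spacer = 60L, flank = 5L) {
  mix <- correlated_mixture()
  marg <- mixture_marginal(mix)
  layout <- embedding_layout(spacer_length = spacer, flank = flank)
  probes <- character(n_probe)
  truths <- vector("list", n_probe)
  for (p in seq_len(n_probe)) {
    real <- sample_mixture_sites(mix, sites_per_probe,
                                 seed = seed * 1000L + p)$seqs
    bench <- build_embedded_benchmark(real, marg, layout,
                                      seed = seed * 1000L + 500L + p,
                                      seq_id = paste0("probe", p))
    probes[p] <- bench$sequence
    truths[[p]] <- bench$truth
  }
  names(probes) <- paste0("probe", seq_len(n_probe))
  list(mixture = mix, marginal = marg, probes = probes,
       truth = do.call(rbind, truths))
}

# real-site core intervals of a benchmark world, as a BED-like frame
world_real_cores <- function(world) {
  tr <- world$truth[world$truth$label == "real", ]
  data.frame(sequence_id = tr$sequence_id, start = tr$core_start,
             end = tr$core_end, stringsAsFactors = FALSE)
}

# precision at the first cutoff reaching 50% sensitivity, scanning each
# probe with its leave-one-out model
loo_precision_at_half_sensitivity <- function(fit, world, model) {
  preds <- do.call(rbind, lapply(names(world$probes), function(id) {
    m <- fit[[paste0("loo_", model)]][[id]]
    scan_sequence(m, world$probes[[id]], fit$background, seq_id = id)
  }))
  curve <- site_precision_curve(preds, world_real_cores(world),
                                mode = "midpoint-region", tolerance = 10)
  curve$precision[which(curve$sensitivity >= 0.5)[1L]]
}
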