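#' Site-selection criteria
#'
#' The three-branch selection rule applied to the scored windows of one
#' sequence: take all sites with log-odds strictly above
#' `primary_cutoff` (default 3.0, natural log); if there are none but
#' the best site reaches `fallback_cutoff` (default 1.5), take that
#' single site; otherwise reject the sequence.
#'
#' @param primary_cutoff natural-log log-odds above which every site is
#'   kept.
#' @param fallback_cutoff minimum log-odds for the single-best-site
#'   fallback; must not exceed `primary_cutoff`.
#' @return an object of class `selection_criteria`.
#' @export
selection_criteria <- function(primary_cutoff = 3.0, fallback_cutoff = 1.5) {
  if (primary_cutoff < fallback_cutoff) {
    stop("primary_cutoff must be >= fallback_cutoff")
  }
  structure(list(primary_cutoff = primary_cutoff,
                 fallback_cutoff = fallback_cutoff),
            class = "selection_criteria")
}

#' Select binding sites from a scored sequence
#'
#' Applies [selection_criteria()] to the scan of one sequence.
#'
#' @param scored data.frame of scored sites from [scan_sequence()] (one
#'   sequence).
#' @param criteria a [selection_criteria()].
#' @return the selected subset of `scored` (possibly empty).
#' @export
select_sites <- function(scored, criteria = selection_criteria()) {
  stopifnot(inherits(criteria, "selection_criteria"))
  if (is.null(scored) || nrow(scored) == 0L) {
    return(scored[0L, , drop = FALSE])
  }
  keep <- scored$logodds > criteria$primary_cutoff
  if (any(keep)) return(scored[keep, , drop = FALSE])
  best <- which.max(scored$logodds)
  if (scored$logodds[best] >= criteria$fallback_cutoff) {
    return(scored[best, , drop = FALSE])
  }
  scored[0L, , drop = FALSE]
}

# coerce a sequence collection (character vector / DNAStringSet) to a
# named uppercase character vector, keeping names
normalize_targets <- function(targets) {
  nms <- names(targets)
  targets <- toupper(as.character(targets))
  names(targets) <- nms
  if (is.null(nms) || any(nms == "")) stop("target sequences must be named")
  targets
}

# scan + select over a named collection of sequences; returns one
# data.frame of selected sites
select_sites_in_targets <- function(model, targets, background, criteria) {
  out <- vector("list", length(targets))
  for (t in seq_along(targets)) {
    id <- names(targets)[t]
    scored <- scan_sequence(model, targets[[t]], background, seq_id = id)
    out[[t]] <- select_sites(scored, criteria)
  }
  do.call(rbind, out)
}

# per-source count matrices for cheap leave-one-out rebuilding
grouped_counts <- function(aln) {
  ids <- aln$source_ids
  if (is.null(ids)) stop("alignment has no source_ids")
  groups <- split(seq_len(aln$N), ids)
  lapply(groups, function(idx) {
    sub <- site_alignment(aln$seqs[idx], source_ids = ids[idx])
    list(n = sub$N, base = base_counts(sub), pair = pair_counts(sub))
  })
}

sum_counts <- function(gc, L) {
  base <- matrix(0, L, 4L)
  npair <- (L * (L - 1L)) %/% 2L
  pair <- replicate(npair, matrix(0, 4L, 4L), simplify = FALSE)
  n <- 0L
  for (g in gc) {
    n <- n + g$n
    base <- base + g$base
    for (k in seq_len(npair)) pair[[k]] <- pair[[k]] + g$pair[[k]]
  }
  list(n = n, base = base, pair = pair)
}

subtract_counts <- function(total, g) {
  pair <- total$pair
  for (k in seq_along(pair)) pair[[k]] <- pair[[k]] - g$pair[[k]]
  list(n = total$n - g$n, base = total$base - g$base, pair = pair)
}

#' Two-step bootstrap construction of posterior PWMs and DWMs
#'
#' Step 1: sites are selected in each target with the prior PWM (using
#' [select_sites()]), widened by `flank` bp of genomic context on each
#' side, oriented, and used to build interim PWM and DWM matrices.
#' Step 2: sites are re-predicted on all targets with the interim
#' matrices (same criteria, no additional flank — the interim models
#' already span core + flank), and the final "posterior" matrices are
#' built from these predictions. In addition, for every target a
#' leave-one-out ("partial") matrix is built omitting all sites from
#' that target, so that predictions on a target never use its own sites
#' ("self-prediction"); targets that contributed no sites get the full
#' matrix. The PWM and DWM tracks are refined independently: the
#' posterior PWM is built from interim-PWM predictions and the posterior
#' DWM from interim-DWM predictions. The whole procedure is
#' deterministic given its inputs.
#'
#' @param prior_pwm the prior [pwm()] used for the initial site search.
#' @param targets named character vector (or `DNAStringSet`) of target
#'   (probe) sequences.
#' @param flank bp of flanking sequence added per side in step 1
#'   (default 10).
#' @param criteria a [selection_criteria()].
#' @param pseudocount kappa for all matrix construction.
#' @param background a [background_model()]; by default estimated from
#'   the target sequences themselves.
#' @param factor_name label used in diagnostics.
#' @return an object of class `dwm_bootstrap`: a list with the final
#'   `pwm` and `dwm`, named lists `loo_pwm` and `loo_dwm` (one model per
#'   target), the step-2 site tables `sites_pwm` and `sites_dwm`, the
#'   interim models, the `background`, and the `criteria`.
#' @export
bootstrap_build <- function(prior_pwm, targets, flank = 10L,
                            criteria = selection_criteria(),
                            pseudocount = 1, background = NULL,
                            factor_name = "motif") {
  stopifnot(inherits(prior_pwm, "pwm"))
  targets <- normalize_targets(targets)
  if (is.null(background)) background <- background_from_sequences(targets)
  background <- as_background(background)

  # step 1: prior scan, flank extension, interim matrices
  sites1 <- select_sites_in_targets(prior_pwm, targets, background, criteria)
  if (is.null(sites1) || length(unique(sites1$sequence_id)) < 2L) {
    stop("factor ", factor_name,
         ": fewer than 2 targets yielded sites with the prior PWM")
  }
  aln1 <- extend_alignment_with_flank(sites1, targets, flank)
  interim_pwm <- build_pwm(aln1, pseudocount)
  interim_dwm <- build_dwm(aln1, pseudocount)

  refine <- function(model) {
    sites <- select_sites_in_targets(model, targets, background, criteria)
    if (is.null(sites) || length(unique(sites$sequence_id)) < 2L) {
      stop("factor ", factor_name,
           ": fewer than 2 targets yielded sites with the interim model")
    }
    aln <- extend_alignment_with_flank(sites, targets, 0L)
    list(sites = sites, aln = aln)
  }
  step2p <- refine(interim_pwm)
  step2d <- refine(interim_dwm)

  L1 <- step2p$aln$L
  gc_p <- grouped_counts(step2p$aln)
  tot_p <- sum_counts(gc_p, L1)
  L2 <- step2d$aln$L
  gc_d <- grouped_counts(step2d$aln)
  tot_d <- sum_counts(gc_d, L2)

  final_pwm <- pwm_from_counts(tot_p$base, tot_p$n, pseudocount)
  final_dwm <- dwm_from_counts(tot_d$pair, tot_d$base, tot_d$n, pseudocount)

  loo_pwm <- loo_dwm <- stats::setNames(vector("list", length(targets)),
                                        names(targets))
  for (id in names(targets)) {
    if (!is.null(gc_p[[id]])) {
      cc <- subtract_counts(tot_p, gc_p[[id]])
      loo_pwm[[id]] <- pwm_from_counts(cc$base, cc$n, pseudocount)
    } else loo_pwm[[id]] <- final_pwm
    if (!is.null(gc_d[[id]])) {
      cc <- subtract_counts(tot_d, gc_d[[id]])
      loo_dwm[[id]] <- dwm_from_counts(cc$pair, cc$base, cc$n, pseudocount)
    } else loo_dwm[[id]] <- final_dwm
  }

  structure(list(pwm = final_pwm, dwm = final_dwm,
                 loo_pwm = loo_pwm, loo_dwm = loo_dwm,
                 sites_pwm = step2p$sites, sites_dwm = step2d$sites,
                 interim_pwm = interim_pwm, interim_dwm = interim_dwm,
                 background = background, criteria = criteria,
                 factor_name = factor_name),
            class = "dwm_bootstrap")
}

#' @export
print.dwm_bootstrap <- function(x, ...) {
  cat("dwm_bootstrap for", x$factor_name, "\n")
  cat("  posterior PWM/DWM length:", motif_length(x$pwm), "bp\n")
  cat("  targets with leave-one-out matrices:", length(x$loo_pwm), "\n")
  invisible(x)
}

#' Per-probe predictions from a bootstrap result
#'
#' Scans every target with the requested model (by default the
#' leave-one-out matrix of that target, so a probe is never scored with
#' a matrix containing its own sites) and aggregates per-probe scores:
#' the total log-odds over all windows and the best single-window
#' log-odds, plus the selected sites.
#'
#' @param fit a [bootstrap_build()] result.
#' @param targets the same named sequence collection.
#' @param model `"dwm"` or `"pwm"` track.
#' @param use_loo use the per-target leave-one-out matrices?
#' @param positive_only passed to [total_log_odds()].
#' @return list with `records` (data.frame `probe_id`, `total_logodds`,
#'   `best_logodds`, `n_selected`) and `sites` (selected sites over all
#'   probes).
#' @export
predict_probes <- function(fit, targets, model = c("dwm", "pwm"),
                           use_loo = TRUE, positive_only = FALSE) {
  stopifnot(inherits(fit, "dwm_bootstrap"))
  model <- match.arg(model)
  targets <- normalize_targets(targets)
  ids <- names(targets)
  recs <- vector("list", length(targets))
  sel <- vector("list", length(targets))
  for (t in seq_along(targets)) {
    id <- ids[t]
    m <- if (use_loo && id %in% names(fit[[paste0("loo_", model)]])) {
      fit[[paste0("loo_", model)]][[id]]
    } else fit[[model]]
    scored <- scan_sequence(m, targets[[t]], fit$background, seq_id = id)
    s <- select_sites(scored, fit$criteria)
    sel[[t]] <- s
    recs[[t]] <- data.frame(
      probe_id = id,
      total_logodds = total_log_odds(scored, positive_only),
      best_logodds = if (nrow(scored)) max(scored$logodds) else -Inf,
      n_selected = nrow(s), stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, recs), sites = do.call(rbind, sel))
}

#' Precision/sensitivity curve over probes
#'
#' Sweeps the log-odds cutoff over the observed per-probe best scores;
#' at cutoff lambda a probe is "predicted" when its best site scores at
#' least lambda. Precision is the fraction of predicted probes that are
#' annotated targets; sensitivity the fraction of annotated targets
#' predicted. The leading row (cutoff = Inf, zero predictions) reports
#' precision 1 by convention, flagged by `n_predicted = 0`.
#'
#' @param predictions data.frame with `probe_id` and `best_logodds`
#'   (e.g. `predict_probes(...)$records`).
#' @param annotated_targets character vector of annotated target probe
#'   ids (must be non-empty).
#' @return data.frame with `cutoff`, `n_predicted`, `precision`,
#'   `sensitivity`, one row per distinct cutoff (descending).
#' @export
precision_sensitivity_curve <- function(predictions, annotated_targets) {
  annotated_targets <- unique(as.character(annotated_targets))
  if (length(annotated_targets) == 0L) stop("empty annotated target set")
  stopifnot(all(c("probe_id", "best_logodds") %in% names(predictions)))
  cutoffs <- c(Inf, sort(unique(predictions$best_logodds), decreasing = TRUE))
  cutoffs <- cutoffs[is.finite(cutoffs) | cutoffs == Inf]
  res <- lapply(cutoffs, function(lam) {
    pred <- predictions$probe_id[predictions$best_logodds >= lam]
    n <- length(pred)
    tp <- length(intersect(pred, annotated_targets))
    data.frame(cutoff = lam, n_predicted = n,
               precision = if (n == 0L) 1 else tp / n,
               sensitivity = tp / length(annotated_targets))
  })
  do.call(rbind, res)
}

interval_mid <- function(start, end) (start + end) / 2

#' Does a predicted site hit an annotation?
#'
#' Two hit rules: `midpoint-midpoint` — the midpoints of prediction and
#' annotation lie within `tolerance` bp of each other (used against
#' point-like annotated sites); `midpoint-region` — the prediction's
#' midpoint falls within the annotation widened by `tolerance` bp on
#' each side, i.e. in `[start - tol, end + tol)` (used against
#' footprint regions of heterogeneous size).
#'
#' @param prediction list or one-row data.frame with `start`, `end`
#'   (0-based half-open).
#' @param annotation list or one-row data.frame with `start`, `end`.
#' @param mode hit rule.
#' @param tolerance bp (default 10).
#' @return logical flag.
#' @export
site_hit <- function(prediction, annotation,
                     mode = c("midpoint-midpoint", "midpoint-region"),
                     tolerance = 10) {
  mode <- match.arg(mode)
  mp <- interval_mid(prediction$start, prediction$end)
  if (mode == "midpoint-midpoint") {
    ma <- interval_mid(annotation$start, annotation$end)
    abs(mp - ma) <= tolerance
  } else {
    mp >= annotation$start - tolerance & mp < annotation$end + tolerance
  }
}

# logical matrix: predictions x intervals hit table
hit_matrix <- function(predictions, intervals, mode, tolerance) {
  np <- nrow(predictions)
  ni <- nrow(intervals)
  m <- matrix(FALSE, np, ni)
  if (np == 0L || ni == 0L) return(m)
  same_seq <- if ("sequence_id" %in% names(predictions) &&
                  "sequence_id" %in% names(intervals)) {
    outer(predictions$sequence_id, intervals$sequence_id, "==")
  } else matrix(TRUE, np, ni)
  for (q in seq_len(ni)) {
    h <- site_hit(predictions, intervals[q, ], mode, tolerance)
    m[, q] <- h & same_seq[, q]
  }
  m
}

#' Precision and discriminative precision against real and decoy sites
#'
#' Over predictions with log-odds at or above `cutoff`:
#' `precision = N_real / N_tot` and
#' `disc_precision = (N_real - N_fake) / N_tot`, where N_real and
#' N_fake count predictions hitting real and decoy (PWM-sampled)
#' intervals respectively, and sensitivity is the fraction of real
#' intervals hit. A negative discriminative precision means the model's
#' predictions resemble its own samples more than genuine sites.
#'
#' @param predictions data.frame of scored sites.
#' @param real_sites,fake_sites data.frames of ground-truth intervals
#'   (`start`, `end`, optionally `sequence_id`); the two sets must be
#'   disjoint.
#' @param cutoff log-odds threshold.
#' @param mode,tolerance hit rule, see [site_hit()]; default
#'   `midpoint-region` with 10 bp.
#' @return list with `precision`, `disc_precision`, `sensitivity`,
#'   `n_predictions`, and `degenerate = TRUE` (with NA precisions) when
#'   no prediction passes the cutoff.
#' @export
discriminative_precision <- function(predictions, real_sites, fake_sites,
                                     cutoff,
                                     mode = "midpoint-region",
                                     tolerance = 10) {
  keep <- predictions$logodds >= cutoff
  preds <- predictions[keep, , drop = FALSE]
  n_tot <- nrow(preds)
  hr <- hit_matrix(preds, real_sites, mode, tolerance)
  if (n_tot == 0L) {
    return(list(precision = NA_real_, disc_precision = NA_real_,
                sensitivity = 0, n_predictions = 0L, degenerate = TRUE))
  }
  hf <- hit_matrix(preds, fake_sites, mode, tolerance)
  n_real <- sum(apply(hr, 1L, any))
  n_fake <- sum(apply(hf, 1L, any))
  list(precision = n_real / n_tot,
       disc_precision = (n_real - n_fake) / n_tot,
       sensitivity = if (nrow(real_sites)) mean(apply(hr, 2L, any)) else NA_real_,
       n_predictions = n_tot, degenerate = FALSE)
}

#' Site-level precision curve
#'
#' Sweeps the cutoff over the observed prediction scores and reports,
#' at each, the fraction of passing predictions that hit a real
#' interval and the fraction of real intervals hit. Computed in one
#' cumulative pass over the score-sorted predictions, so it stays
#' linear in the number of predictions. With `fake_sites` supplied, a
#' `disc_precision` column ((N_real - N_fake) / N_tot, see
#' [discriminative_precision()]) is added.
#'
#' @inheritParams discriminative_precision
#' @param fake_sites optional decoy intervals.
#' @return data.frame `cutoff`, `n_predictions`, `precision`,
#'   `sensitivity` (and optionally `disc_precision`), cutoffs
#'   descending.
#' @export
site_precision_curve <- function(predictions, real_sites, fake_sites = NULL,
                                 mode = "midpoint-region", tolerance = 10) {
  ord <- order(predictions$logodds, decreasing = TRUE)
  preds <- predictions[ord, , drop = FALSE]
  hr <- hit_matrix(preds, real_sites, mode, tolerance)
  real_hit <- apply(hr, 1L, any)
  # a real interval counts as found once the cutoff drops to the best
  # score among predictions hitting it
  best_per_interval <- apply(hr, 2L, function(col) {
    if (any(col)) max(preds$logodds[col]) else -Inf
  })
  cum_real <- cumsum(real_hit)
  n_at <- seq_len(nrow(preds))
  if (!is.null(fake_sites)) {
    hf <- hit_matrix(preds, fake_sites, mode, tolerance)
    cum_fake <- cumsum(apply(hf, 1L, any))
  }
  # collapse tied scores: report the last (most inclusive) row per cutoff
  last <- !duplicated(preds$logodds, fromLast = TRUE)
  idx <- which(last)
  out <- data.frame(cutoff = preds$logodds[idx],
                    n_predictions = n_at[idx],
                    precision = cum_real[idx] / n_at[idx],
                    sensitivity = vapply(preds$logodds[idx], function(lam)
                      mean(best_per_interval >= lam), numeric(1)))
  if (!is.null(fake_sites)) {
    out$disc_precision <- (cum_real[idx] - cum_fake[idx]) / n_at[idx]
  }
  out
}

#' Correlate per-probe predictions with ChIP binding p-values
#'
#' For every probe, a combined binding p-value is formed as the
#' geometric mean of the rich-medium p-value and up to
#' `max_other` smallest p-values among the other conditions in which
#' binding was reported (p at or below `reported_threshold`; fewer are
#' averaged when fewer qualify). The Pearson correlation between the
#' per-probe total log-odds and the transformed combined p-value is
#' returned; the default transform is `-log(p)` so that a better
#' predictor gives a positive coefficient, `"raw"` correlates against
#' the p-value itself.
#'
#' @param predictions data.frame with `probe_id` and `total_logodds`.
#' @param binding data.frame of binding p-values, one row per probe.
#' @param probe_col name of the probe-id column in `binding`.
#' @param rich_col name of the rich-medium p-value column.
#' @param other_cols names of the other condition columns (default: all
#'   numeric columns except `rich_col`).
#' @param max_other maximum number of other conditions averaged in
#'   (default 2).
#' @param reported_threshold p-value at or below which binding counts
#'   as "reported" in a condition (default 0.001).
#' @param transform `"neglog"` (default) or `"raw"`.
#' @return the Pearson coefficient, with attributes `n` (probes used)
#'   and `degenerate` (TRUE, with value 0, when either variable has
#'   zero variance).
#' @export
correlate_with_binding <- function(predictions, binding,
                                   probe_col = "probe",
                                   rich_col = "rich_medium",
                                   other_cols = NULL,
                                   max_other = 2L,
                                   reported_threshold = 0.001,
                                   transform = c("neglog", "raw")) {
  transform <- match.arg(transform)
  stopifnot(probe_col %in% names(binding), rich_col %in% names(binding))
  if (is.null(other_cols)) {
    num <- vapply(binding, is.numeric, logical(1))
    other_cols <- setdiff(names(binding)[num], rich_col)
  }
  m <- merge(predictions, binding, by.x = "probe_id", by.y = probe_col)
  if (nrow(m) == 0L) stop("no overlapping probes between predictions and binding table")
  combined <- vapply(seq_len(nrow(m)), function(r) {
    rich <- m[[rich_col]][r]
    others <- unlist(m[r, other_cols, drop = FALSE])
    others <- others[!is.na(others) & others <= reported_threshold]
    chosen <- sort(others)[seq_len(min(max_other, length(others)))]
    exp(mean(log(c(rich, chosen))))
  }, numeric(1))
  y <- if (transform == "neglog") -log(combined) else combined
  x <- m$total_logodds
  if (nrow(m) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- 0
    attr(r, "degenerate") <- TRUE
  } else {
    r <- stats::cor(x, y)
    attr(r, "degenerate") <- FALSE
  }
  attr(r, "n") <- nrow(m)
  r
}
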