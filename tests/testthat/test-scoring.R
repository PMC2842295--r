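test_that("pwm_log_likelihood matches closed forms", {
  u <- pwm(matrix(0.25, 5, 4))
  expect_equal(pwm_log_likelihood(u, "ACGTA"), 5 * log(1/4))

  p <- build_pwm(aatt_alignment())
  expect_equal(pwm_log_likelihood(p, "AA"), 2 * log(1/3))
  expect_equal(pwm_log_likelihood(p, "AT"), 2 * log(1/3))

  cons <- consensus_pwm("ACG", p = 0.91)
  expect_equal(pwm_log_likelihood(cons, "ACG"), 3 * log(0.91))
  expect_error(pwm_log_likelihood(p, "AAA"), "length")
})

test_that("the AA/TT DWM discriminates where the PWM cannot", {
  d <- build_dwm(aatt_alignment())
  expect_equal(dwm_log_likelihood(d, "AA"), 2 * log(25/57), tolerance = 1e-12)
  expect_equal(dwm_log_likelihood(d, "AT"), 2 * log(16/57), tolerance = 1e-12)
  expect_gt(dwm_log_likelihood(d, "AA"), dwm_log_likelihood(d, "AT"))

  # the sequence-likelihood approximation is unnormalised over windows
  tot <- sum(vapply(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                    function(w) exp(dwm_log_likelihood(d, w)), numeric(1)))
  expect_gt(abs(tot - 1), 1e-3)

  # ... but every posterior column is normalised
  prof <- dwm_log_likelihood(d, "AT", profile = TRUE)
  expect_equal(colSums(prof$profile$posterior), rep(1, 2), tolerance = 1e-9)
  expect_equal(unname(prof$profile$posterior["A", 1]), 16/57,
               tolerance = 1e-12)
})

test_that("DWM scoring reduces to PWM scoring for factorised pairs", {
  set.seed(11)
  for (r in 1:20) {
    L <- sample(2:12, 1)
    P <- random_pwm(L)
    D <- dwm_from_pwm(P)
    for (k in 1:10) {
      w <- random_window(L)
      expect_equal(dwm_log_likelihood(D, w), pwm_log_likelihood(P, w),
                   tolerance = 1e-9)
    }
  }
})

test_that("posterior columns are normalised for estimated DWMs", {
  set.seed(12)
  for (r in 1:5) {
    L <- sample(3:10, 1)
    D <- build_dwm(sample_pwm_sites(random_pwm(L), 25L))
    prof <- dwm_log_likelihood(D, random_window(L), profile = TRUE)
    expect_equal(colSums(prof$profile$posterior), rep(1, L), tolerance = 1e-9)
    expect_equal(prof$profile$posterior,
                 sweep(prof$profile$u, 2, prof$profile$Z, "/"))
  }
})

test_that("raising the observed dinucleotide probability never lowers the score", {
  set.seed(13)
  D <- build_dwm(sample_pwm_sites(random_pwm(4L), 30L))
  w <- "ACGT"
  base <- dwm_log_likelihood(D, w)
  codes <- match(strsplit(w, "")[[1]], DNA_BASES)
  for (i in 1:3) for (j in (i + 1):4) {
    D2 <- D
    k <- pair_index(i, j, 4L)
    tab <- D2$pairs[[k]]
    tab[codes[i], codes[j]] <- tab[codes[i], codes[j]] * 1.5
    D2$pairs[[k]] <- tab / sum(tab)
    expect_gte(dwm_log_likelihood(D2, w), base)
  }
})

test_that("log_odds subtracts the background log-likelihood", {
  u <- pwm(matrix(0.25, 3, 4))
  expect_equal(log_odds(pwm_log_likelihood(u, "ACG"), "ACG"), 0)

  bg <- background_model(c(0.3, 0.2, 0.2, 0.3))
  expect_equal(log_odds(2 * log(1/3), "AA", bg), 2 * log(1/3) - 2 * log(0.3))

  # strand symmetry under a complement-symmetric background
  set.seed(14)
  P <- random_pwm(6L)
  for (r in 1:20) {
    w <- random_window(6L)
    lo1 <- log_odds(pwm_log_likelihood(P, w), w, bg)
    lo2 <- log_odds(pwm_log_likelihood(revcomp(P), revcomp_string(w)),
                    revcomp_string(w), bg)
    expect_equal(lo1, lo2, tolerance = 1e-9)
  }
})

test_that("scan_sequence picks the best orientation per start", {
  cons <- consensus_pwm("ACGCGTTA")
  one <- scan_sequence(cons, "ACGCGTTA")
  expect_equal(nrow(one), 1L)
  expect_equal(one$strand, "+")
  expect_equal(one$end - one$start, 8L)

  # non-ACGT windows are skipped
  expect_equal(nrow(scan_sequence(cons, strrep("N", 30))), 0L)
  expect_warning(short <- scan_sequence(cons, "ACG"), "shorter")
  expect_equal(nrow(short), 0L)

  # planted consensus is the arg-max against an exhaustive R oracle
  bgseq <- sample_background(length = 200, seed = 5)
  seq2 <- paste0(substr(bgseq, 1, 37), "ACGCGTTA", substr(bgseq, 38, 192))
  sc <- scan_sequence(cons, seq2)
  expect_equal(sc$start[which.max(sc$logodds)], 37L)
  oracle <- vapply(0:(nchar(seq2) - 8), function(s) {
    w <- substr(seq2, s + 1, s + 8)
    max(log_odds(pwm_log_likelihood(cons, w), w),
        log_odds(pwm_log_likelihood(cons, revcomp_string(w)),
                 revcomp_string(w)))
  }, numeric(1))
  expect_equal(sc$logodds, oracle, tolerance = 1e-12)

  # a planted reverse-complement site is found on the minus strand
  rcseq <- paste0(substr(bgseq, 1, 50), revcomp_string("ACGCGTTA"),
                  substr(bgseq, 51, 192))
  scr <- scan_sequence(cons, rcseq)
  expect_equal(scr$start[which.max(scr$logodds)], 50L)
  expect_equal(scr$strand[which.max(scr$logodds)], "-")
})

test_that("total_log_odds sums per-start scores, optionally positive-only", {
  expect_equal(total_log_odds(data.frame(logodds = numeric(0))), 0)
  sites <- data.frame(logodds = c(2.0, -1.0, 0.5))
  expect_equal(total_log_odds(sites), 1.5)
  expect_equal(total_log_odds(sites, positive_only = TRUE), 2.5)
})
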