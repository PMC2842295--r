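test_that("build_pwm matches the pseudocount formula", {
  p <- build_pwm(site_alignment(c("AA", "TT")), pseudocount = 1)
  expect_equal(unname(p$probs[1, ]), c(1/3, 1/6, 1/6, 1/3))
  expect_equal(unname(p$probs[2, ]), c(1/3, 1/6, 1/6, 1/3))

  # pure prior: empty alignment gives 1/4 everywhere
  p0 <- build_pwm(site_alignment(L = 3), pseudocount = 1)
  expect_equal(unname(p0$probs), matrix(0.25, 3, 4))

  # 50 x AC + 50 x AA
  p2 <- build_pwm(site_alignment(rep(c("AC", "AA"), each = 50)))
  expect_equal(unname(p2$probs[2, ]), c(51/104, 51/104, 1/104, 1/104))

  # kappa -> 0 convergence to raw frequencies
  aln <- site_alignment(rep(c("AC", "AA"), each = 50))
  raw <- rbind(c(1, 0, 0, 0), c(.5, .5, 0, 0))
  for (kap in c(1, 0.1, 0.001)) {
    p <- build_pwm(aln, kap)
    expect_lte(max(abs(p$probs - raw)), 4 * kap / (100 + 4 * kap))
  }
})

test_that("non-ACGT characters are rejected with a diagnostic", {
  expect_error(site_alignment(c("ACGT", "ACNT")), "sequence 2")
  expect_error(site_alignment(c("AC", "ACG")), "same length")
})

test_that("build_dwm matches the PWM-product-prior formula", {
  d <- build_dwm(aatt_alignment(), pseudocount = 1)
  tab <- dwm_pair(d, 1, 2)
  expect_equal(tab["A", "A"], (1 + 16/9) / 18)
  expect_equal(tab["A", "T"], (16/9) / 18)
  expect_equal(tab["T", "T"], (1 + 16/9) / 18)
  expect_equal(sum(tab), 1)

  # symmetry convention: pair(2,1)[b, a] == pair(1,2)[a, b]
  expect_equal(dwm_pair(d, 2, 1), t(tab))
})

test_that("pure-prior DWM marginals are the PWM columns exactly", {
  # for N = 0 the joint is the product prior, so rows sum to w exactly
  d <- build_dwm(site_alignment(L = 4), pseudocount = 1)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(unname(rowSums(dwm_pair(d, i, j))),
                 unname(d$marginal$probs[i, ]))
  }
})

test_that("DWM from independent-column samples approaches the outer product", {
  set.seed(421)
  P <- random_pwm(5L)
  aln <- sample_pwm_sites(P, 100L, seed = 77)
  d <- build_dwm(aln)
  w <- d$marginal$probs
  for (i in 1:4) for (j in (i + 1):5) {
    p <- w[i, ] %o% w[j, ]
    # estimator shrinks toward the product, so the raw-frequency
    # 3-standard-error binomial bound applies
    bound <- 3 * sqrt(p * (1 - p) / 100) + 1e-12
    expect_true(all(abs(dwm_pair(d, i, j) - p) <= bound))
  }
})

test_that("dwm_from_pwm is the exact outer-product embedding", {
  u <- pwm(matrix(0.25, 4, 4))
  du <- dwm_from_pwm(u)
  expect_equal(unname(dwm_pair(du, 1, 3)), matrix(1/16, 4, 4))
  set.seed(5)
  P <- random_pwm(6L)
  d <- dwm_from_pwm(P)
  for (k in seq_along(d$pairs)) expect_equal(sum(d$pairs[[k]]), 1)
})

test_that("row and pair-table normalisation holds for arbitrary alignments", {
  set.seed(33)
  for (rep in 1:10) {
    L <- sample(2:8, 1)
    n <- sample(1:40, 1)
    aln <- sample_pwm_sites(random_pwm(L), n)
    p <- build_pwm(aln, pseudocount = runif(1, 0.1, 2))
    expect_equal(rowSums(p$probs), rep(1, L), tolerance = 1e-9)
    d <- build_dwm(aln)
    for (k in seq_along(d$pairs)) {
      expect_equal(sum(d$pairs[[k]]), 1, tolerance = 1e-9)
    }
  }
})

test_that("column information content has the right landmarks", {
  p <- pwm(rbind(c(1, 0, 0, 0), c(.25, .25, .25, .25), c(.5, .5, 0, 0)))
  expect_equal(column_information_content(p, 1), 2)
  expect_equal(column_information_content(p, 2), 0)
  expect_equal(column_information_content(p, 3), 1)
  expect_error(column_information_content(p, 4), "out of range")
})

test_that("revcomp is an involution and matches sequence reversal", {
  set.seed(9)
  P <- random_pwm(7L)
  expect_equal(revcomp(revcomp(P)), P)
  aln <- sample_pwm_sites(P, 20L)
  D <- build_dwm(aln)
  D2 <- revcomp(revcomp(D))
  expect_equal(D2$pairs, D$pairs)
  expect_equal(D2$marginal$probs, D$marginal$probs)

  # palindromic (uniform) model maps to itself
  u <- pwm(matrix(0.25, 4, 4))
  expect_equal(revcomp(u), u)

  # scoring S with revcomp(model) == scoring revcomp(S) with model
  for (r in 1:20) {
    w <- random_window(7L)
    expect_equal(pwm_log_likelihood(revcomp(P), w),
                 pwm_log_likelihood(P, revcomp_string(w)), tolerance = 1e-12)
    expect_equal(dwm_log_likelihood(revcomp(D), w),
                 dwm_log_likelihood(D, revcomp_string(w)), tolerance = 1e-12)
  }
})

test_that("flank extension follows site orientation and drops overruns", {
  genome <- c(seq1 = paste(rep("ACGT", 20), collapse = ""))
  sites <- data.frame(sequence_id = "seq1", start = 20L, end = 26L,
                      strand = "+", stringsAsFactors = FALSE)
  aln <- extend_alignment_with_flank(sites, genome, flank = 10L)
  expect_equal(aln$seqs, substr(genome[[1]], 11, 36))  # window [10, 36)
  expect_equal(aln$L, 26L)

  # minus strand: reverse complement of the plus-strand slice
  sites$strand <- "-"
  aln_m <- extend_alignment_with_flank(sites, genome, flank = 10L)
  expect_equal(aln_m$seqs, revcomp_string(substr(genome[[1]], 11, 36)))

  # a site too close to the boundary is dropped; all-dropped errors
  near <- data.frame(sequence_id = "seq1", start = 3L, end = 9L,
                     strand = "+", stringsAsFactors = FALSE)
  both <- rbind(near, data.frame(sequence_id = "seq1", start = 20L,
                                 end = 26L, strand = "+"))
  expect_message(aln_b <- extend_alignment_with_flank(both, genome, 10L),
                 "dropped")
  expect_equal(aln_b$N, 1L)
  expect_error(
    suppressMessages(extend_alignment_with_flank(near, genome, 10L)),
    "empty alignment")
})
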