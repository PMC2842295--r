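test_that("PWM site sampling hits its column frequencies", {
  P <- consensus_pwm("ACGT", p = 1 - 3e-12)  # effectively deterministic
  expect_equal(sample_pwm_sites(P, 0, seed = 1)$N, 0L)
  aln <- sample_pwm_sites(P, 5L, seed = 1)
  expect_equal(aln$seqs, rep("ACGT", 5))

  set.seed(31)
  Q <- random_pwm(4L)
  big <- sample_pwm_sites(Q, 10000L, seed = 2)
  freq <- dwmotif:::base_counts(big) / 10000
  bound <- 3 * sqrt(Q$probs * (1 - Q$probs) / 10000)
  expect_true(all(abs(freq - Q$probs) <= bound + 1e-12))

  # bit-exact reproducibility
  expect_identical(sample_pwm_sites(Q, 50L, seed = 9)$seqs,
                   sample_pwm_sites(Q, 50L, seed = 9)$seqs)
})

test_that("mixture sampling matches the closed-form joint", {
  # degenerate single-component mixture == PWM sampling
  set.seed(32)
  Q <- random_pwm(3L)
  m1 <- mixture_motif_model(1, list(Q))
  expect_identical(sample_mixture_sites(m1, 20L, seed = 4)$seqs,
                   sample_pwm_sites(Q, 20L, seed = 4)$seqs)

  # closed form is the weighted sum of outer products
  allA <- pwm(matrix(c(1, 0, 0, 0), 2, 4, byrow = TRUE))
  allT <- pwm(matrix(c(0, 0, 0, 1), 2, 4, byrow = TRUE))
  mix <- mixture_motif_model(c(0.5, 0.5), list(allA, allT))
  J <- mixture_pair_joint(mix, 1, 2)
  expect_equal(J["A", "A"], 0.5)
  expect_equal(J["T", "T"], 0.5)
  expect_equal(sum(J), 1)
  W <- mixture_marginal(mix)$probs
  expect_equal(unname(W[1, ]), c(0.5, 0, 0, 0.5))
  # excess over independence
  expect_equal(unname(J["A", "A"] - W[1, "A"] * W[2, "A"]), 0.25)

  set.seed(33)
  mg <- correlated_mixture()
  Jg <- mixture_pair_joint(mg, 3, 6)
  manual <- 0.5 * (mg$components[[1]]$probs[3, ] %o%
                     mg$components[[1]]$probs[6, ]) +
    0.5 * (mg$components[[2]]$probs[3, ] %o% mg$components[[2]]$probs[6, ])
  expect_equal(Jg, manual)

  # empirical excess at n = 10000 within 3 binomial standard errors
  aln <- sample_mixture_sites(mix, 10000L, seed = 6)
  phat <- mean(aln$seqs == "AA")
  w1 <- mean(substr(aln$seqs, 1, 1) == "A")
  w2 <- mean(substr(aln$seqs, 2, 2) == "A")
  expect_lt(abs((phat - w1 * w2) - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("background sampling is i.i.d. from the stated frequencies", {
  expect_equal(sample_background(length = 0, seed = 1), "")
  onlyA <- background_model(c(1 - 3e-12, 1e-12, 1e-12, 1e-12))
  expect_equal(sample_background(onlyA, 8, seed = 1), "AAAAAAAA")

  s <- sample_background(length = 10000, seed = 3)
  freq <- table(factor(strsplit(s, "")[[1]], levels = DNA_BASES)) / 10000
  expect_true(all(abs(freq - 0.25) <= 3 * sqrt(0.25 * 0.75 / 10000)))
})

test_that("embedded benchmarks have the stated layout and are recoverable", {
  # 1 real 8bp site, flank 10, spacer 100: 100 + 28 + 100 + 28 + 100
  bench <- build_embedded_benchmark("ACGCGTTA", consensus_pwm("ACGCGTTA"),
                                    embedding_layout(100L, 10L), seed = 11)
  expect_equal(nchar(bench$sequence), 356L)
  expect_equal(nrow(bench$truth), 2L)
  expect_setequal(bench$truth$label, c("real", "fake"))

  # intervals are non-overlapping and separated by exactly the spacer
  mix <- correlated_mixture()
  real <- sample_mixture_sites(mix, 6L, seed = 12)$seqs
  b2 <- build_embedded_benchmark(real, mixture_marginal(mix),
                                 embedding_layout(100L, 10L), seed = 13)
  tr <- b2$truth[order(b2$truth$start), ]
  expect_true(all(tr$start[-1] - tr$end[-nrow(tr)] == 100L))
  expect_true(all(tr$core_start - tr$start == 10L))

  # scanning with the generating model recovers the planted sites
  sc <- scan_sequence(mixture_marginal(mix), b2$sequence, seq_id = "benchmark")
  hits <- select_sites(sc, selection_criteria())
  hr <- dwmotif:::hit_matrix(hits, tr[, c("sequence_id", "core_start", "core_end")] |>
                               stats::setNames(c("sequence_id", "start", "end")),
                             "midpoint-region", 10)
  expect_true(all(apply(hr, 2, any)))  # every unit (real or fake) found

  # reproducibility
  b3 <- build_embedded_benchmark(real, mixture_marginal(mix),
                                 embedding_layout(100L, 10L), seed = 13)
  expect_identical(b2, b3)
})
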