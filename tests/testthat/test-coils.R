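test_that("sequences shorter than the window score zero everywhere", {
  p <- toy_coils_params()
  prof <- coils_score(strrep("L", 10), p)
  expect_equal(prof$score, rep(0, 10))
  expect_equal(coils_probability(prof, p)$probability, rep(0, 10))
  expect_equal(length(coils_score("", p)$score), 0)
})

test_that("a uniform propensity table scores every residue exactly 1", {
  tab <- toy_coils_table()
  tab[] <- 1
  p <- coils_params(propensity_table = tab, window = 14)
  prof <- coils_score("LEKLEKEGAGAGAGLEKLEKE", p)
  expect_equal(prof$score, rep(1, 21))
})

test_that("illegal residues are rejected by position; X is neutral", {
  p <- toy_coils_params()
  expect_error(coils_score("LEKLEK1LEKLEKE", p), "position 7")
  expect_silent(coils_score(paste0(strrep("X", 7), toy_heptads(2)), p))
})

test_that("scores equal the exhaustive window x frame enumeration", {
  p <- toy_coils_params()
  seqs <- c(paste0(toy_heptads(2), "GGGG", toy_heptads(2)),
            strrep("G", 28), toy_heptads(4))
  set.seed(21)
  for (i in 1:6)
    seqs <- c(seqs, paste(sample(c("L", "E", "K", "G", "A"), 30,
                                 replace = TRUE), collapse = ""))
  for (s in seqs) {
    expect_equal(coils_score(s, p)$score, oracle_coils_score(s, p),
                 tolerance = 1e-12)
  }
})

test_that("position weights are honoured in the weighted geometric mean", {
  p <- coils_params(propensity_table = toy_coils_table(), window = 14,
                    position_weights = c(2.5, 1, 1, 2.5, 1, 1, 1),
                    gaussian_cc = c(1.6, 0.08), gaussian_gl = c(0.9, 0.15))
  s <- toy_heptads(3)
  expect_equal(coils_score(s, p)$score, oracle_coils_score(s, p),
               tolerance = 1e-12)
})

test_that("probabilities follow the two-Gaussian density ratio", {
  p <- toy_coils_params()
  prof <- structure(list(protein_id = "t", length = 3,
                         score = c(1.25, 1.6, 0.9), probability = NULL),
                    class = "coils_profile")
  pr <- coils_probability(prof, p)$probability
  # symmetric likelihoods give exactly 0.5
  gcc <- dnorm(prof$score, 1.6, 0.08); ggl <- dnorm(prof$score, 0.9, 0.15)
  expect_equal(pr, gcc / (gcc + ggl), tolerance = 1e-12)
  # score at the coiled-coil mean, well-separated models
  expect_gt(pr[2], 0.99)
  # score at the globular mean
  expect_lt(pr[3], 0.01)
})

test_that("a score with equal densities under both models gives P = 0.5", {
  p <- coils_params(propensity_table = toy_coils_table(), window = 14,
                    gaussian_cc = c(2, 0.5), gaussian_gl = c(1, 0.5))
  prof <- structure(list(protein_id = "t", length = 1, score = 1.5,
                         probability = NULL), class = "coils_profile")
  expect_equal(coils_probability(prof, p)$probability, 0.5)
})

test_that("segment calling finds maximal above-threshold runs", {
  p <- toy_coils_params()
  mkprof <- function(prob) structure(
    list(protein_id = "t", length = length(prob),
         score = rep(1, length(prob)), probability = prob),
    class = "coils_profile")

  expect_equal(nrow(detect_cc_segments(mkprof(rep(0, 40)), p)), 0)

  one <- detect_cc_segments(mkprof(c(rep(0, 5), rep(0.95, 30), rep(0, 5))), p)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(6L, 35L))
  expect_equal(one$score, 0.95)

  # two qualifying runs split by one sub-threshold residue stay two;
  # cross-checked by a longhand run scan
  prob <- c(rep(0.95, 10), 0.5, rep(0.95, 10))
  two <- detect_cc_segments(mkprof(prob), p)
  runs <- rle(prob >= p$prob_threshold)
  expect_equal(nrow(two), sum(runs$values & runs$lengths >= 7))
  expect_equal(nrow(two), 2)
  expect_equal(two$start, c(1L, 12L))

  # runs shorter than min_segment_len are dropped
  short <- detect_cc_segments(mkprof(c(rep(0.95, 6), rep(0, 20))), p)
  expect_equal(nrow(short), 0)
})

test_that("raising the threshold never increases segment count or length", {
  p <- toy_coils_params()
  seq <- paste0(strrep("G", 10), toy_heptads(4), strrep("G", 8),
                toy_heptads(3), strrep("G", 10))
  prof <- coils_probability(coils_score(seq, p), p)
  prev_n <- Inf; prev_len <- Inf
  for (thr in c(0.5, 0.7, 0.9, 0.99)) {
    p2 <- coils_params(propensity_table = toy_coils_table(), window = 14,
                       gaussian_cc = c(1.6, 0.08), gaussian_gl = c(0.9, 0.15),
                       prob_threshold = thr)
    seg <- detect_cc_segments(prof, p2)
    tot <- if (nrow(seg) == 0) 0 else sum(seg$end - seg$start + 1)
    expect_lte(nrow(seg), prev_n)
    expect_lte(tot, prev_len)
    prev_n <- nrow(seg); prev_len <- tot
  }
})

test_that("prepending anti-coil residues shifts segments by exactly k", {
  p <- toy_coils_params()
  # flank both sides so boundary windows behave the same before and after
  # the shift
  core <- paste0(strrep("G", 5), toy_heptads(5), strrep("G", 10))
  base <- detect_cc_segments(coils_probability(coils_score(core, p), p), p)
  expect_gt(nrow(base), 0)
  for (k in c(3, 11)) {
    shifted <- paste0(strrep("G", k), core)
    seg <- detect_cc_segments(
      coils_probability(coils_score(shifted, p), p), p)
    expect_equal(seg$start, base$start + k)
    expect_equal(seg$end, base$end + k)
  }
})

test_that("scan_coils emits the table dialect parse_coils_segments reads", {
  p <- toy_coils_params()
  seqs <- c(cc1 = paste0(strrep("G", 12), toy_heptads(5), strrep("G", 12)),
            flat = strrep("G", 60))
  hits <- scan_coils(seqs, p)
  expect_true(all(hits$protein_id == "cc1"))
  path <- tempfile()
  on.exit(unlink(path))
  write_cc_segments(hits, path)
  back <- parse_coils_segments(path)
  expect_equal(back$start, hits$start)
  expect_equal(back$end, hits$end)
  expect_equal(back$score, hits$score, tolerance = 1e-6)
})
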