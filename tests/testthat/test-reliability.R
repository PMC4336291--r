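test_that("position-spec parsing expands printed residue lists", {
  expect_equal(
    length(parse_position_spec(
      "9, 15, 23–29, 31–33, 47, 49, 51, 52, 74, 81, 84, 86, 87, 90 and 97")),
    23L)
  # the printed "46 residues" list expands to 47 distinct positions
  expect_equal(
    length(parse_position_spec(
      "2, 5, 9, 13, 15, 22–29, 31–33, 36, 40, 46, 47, 49–52, 56, 57, 59, 62, 65, 68, 74–81, 83–90 and 97")),
    47L)
  expect_equal(parse_position_spec("5-5"), 5L)
  expect_equal(parse_position_spec("3, 1, 2, 2"), 1:3)
  expect_error(parse_position_spec("9-5"), "descending")
  expect_error(parse_position_spec("a, 5"), "parse")
})

test_that("built-in critical-residue sets have the documented sizes", {
  hokc <- hokc_critical_residues()
  expect_equal(length(hokc$positions), 25L)
  expect_equal(hokc$protein_length, 50L)
  expect_equal(length(hiv1_protease_critical_residues()$positions), 47L)
  expect_equal(length(hiv1_protease_critical_residues(TRUE)$positions), 23L)

  # the shipped TSV fixtures agree with the in-code verbatim lists
  path <- system.file("extdata", "hokc_critical_residues.tsv",
                      package = "chispas")
  expect_equal(read_critical_set(path, 50)$positions, hokc$positions)
})

test_that("confusion metrics are right on a hand-checked toy", {
  cs <- critical_residue_set("toy", 10, c(1, 2, 3))
  m <- confusion_at_threshold(c(1, 2, 4, 3, 5:10), cs, 0.3)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(2, 1, 1, 6))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 6 / 7)

  perfect <- perfect_predictor(cs)
  mp <- confusion_at_threshold(perfect, cs, 0.3)
  expect_equal(c(mp$sensitivity, mp$specificity, mp$mcc), c(1, 1, 1))

  # threshold 1: everything positive, MCC denominator vanishes
  m1 <- confusion_at_threshold(perfect, cs, 1)
  expect_equal(c(m1$sensitivity, m1$specificity, m1$mcc), c(1, 0, 0))
})

test_that("sensitivity rises and specificity falls along the threshold sweep", {
  set.seed(88)
  for (i in 1:5) {
    cs <- critical_residue_set("toy", 40, sample(40, 12))
    rk <- random_predictor(40)
    sweep <- confusion_at_threshold(rk, cs, seq(0.05, 1, 0.05))
    expect_true(all(diff(sweep$sensitivity) >= 0))
    expect_true(all(diff(sweep$specificity) <= 0))
  }
})

test_that("MCC matches the correlation-coefficient oracle and stays in [-1,1]", {
  set.seed(19)
  for (i in 1:200) {
    L <- sample(10:60, 1)
    cs <- critical_residue_set("toy", L, sample(L, sample(2:(L - 2), 1)))
    rk <- random_predictor(L)
    t <- sample(seq(0.1, 0.9, 0.1), 1)
    m <- confusion_at_threshold(rk, cs, t)
    expect_gte(m$mcc, -1)
    expect_lte(m$mcc, 1)
    # oracle: Pearson correlation of the binary prediction/truth vectors
    k <- ceiling(t * L)
    pred <- as.integer(seq_len(L) %in% rk[seq_len(k)])
    truth <- as.integer(seq_len(L) %in% cs$positions)
    r <- suppressWarnings(cor(pred, truth))
    if (!is.na(r)) expect_equal(m$mcc, r, tolerance = 1e-12)
  }
})

test_that("partial rankings are padded with a warning; bad rankings error", {
  cs <- critical_residue_set("toy", 10, c(1, 2))
  expect_warning(m <- confusion_at_threshold(c(2, 1, 9), cs, 0.2), "padding")
  expect_equal(m$tp, 2)
  expect_error(confusion_at_threshold(c(1, 1, 2), cs, 0.2), "distinct")
  expect_error(confusion_at_threshold(c(1, 11), cs, 0.2), "distinct")
})

test_that("perturbation removes the rounded fraction, reproducibly", {
  hokc <- hokc_critical_residues()
  set.seed(1)
  pert <- perturb_criticals(hokc, 0.2)
  expect_equal(length(pert$positions), 20L)              # 25 - 5
  expect_true(all(pert$positions %in% hokc$positions))   # never adds
  expect_equal(pert$protein_length, hokc$protein_length)
  expect_equal(length(hokc$positions), 25L)              # original untouched

  expect_identical(perturb_criticals(hokc, 0), hokc)

  set.seed(99); a <- perturb_criticals(hokc, 0.2)
  set.seed(99); b <- perturb_criticals(hokc, 0.2)
  expect_identical(a$positions, b$positions)
})

test_that("random predictor sensitivity tracks the threshold on average", {
  cs <- critical_residue_set("toy", 100, 1:30)
  set.seed(4)
  t <- 0.4
  sens <- replicate(1000,
    confusion_at_threshold(random_predictor(100), cs, t)$sensitivity)
  # hypergeometric expectation: E[sens] = t, sd of the mean ~ small
  se <- sd(sens) / sqrt(length(sens))
  expect_lt(abs(mean(sens) - t), 3 * se + 0.01)

  set.seed(7); r1 <- random_predictor(50)
  set.seed(7); r2 <- random_predictor(50)
  expect_identical(r1, r2)
})

test_that("reliability envelope has coherent structure", {
  cs <- critical_residue_set("toy", 20, "1-6")
  set.seed(2)
  env <- reliability_envelope(perfect_predictor(cs), cs, fraction = 0.2,
                              replicates = 25, predictor = "perfect")
  expect_s3_class(env, "reliability_envelope")
  expect_equal(sort(unique(env$replicate)), 0:25)
  sm <- tidy(env)
  expect_true(all(sm$min <= sm$mean + 1e-12 & sm$mean <= sm$max + 1e-12))
  # perfect predictor scored against the perturbed set: its top-|P| window
  # always contains every perturbed positive
  at_p <- dplyr::filter(tibble::as_tibble(env), threshold >= 0.3,
                        replicate > 0)
  expect_true(all(at_p$sensitivity == 1))
})

test_that("scoring against the original set bounds the perfect predictor's loss", {
  cs <- critical_residue_set("toy", 20, "1-6")  # P = 6, drop floor(1.2) = 1
  set.seed(3)
  env <- reliability_envelope(perfect_predictor(cs), cs, fraction = 0.2,
                              replicates = 20, score_against = "original")
  at_p <- dplyr::filter(tibble::as_tibble(env), threshold >= 0.3,
                        replicate > 0)
  expect_true(all(at_p$sensitivity == 1))  # ranking fixed, truth unperturbed
})

test_that("zero perturbation collapses the envelope to the plain sweep", {
  cs <- critical_residue_set("toy", 20, "1-6")
  env <- reliability_envelope(perfect_predictor(cs), cs, fraction = 0,
                              replicates = 1)
  sweep <- confusion_at_threshold(perfect_predictor(cs), cs,
                                  seq(0.05, 0.95, 0.05))
  rep1 <- dplyr::filter(tibble::as_tibble(env), replicate == 1)
  expect_equal(rep1$sensitivity, sweep$sensitivity)
  expect_equal(rep1$mcc, sweep$mcc)
})

test_that("reliable region separates perfect from random on a clear case", {
  cs <- critical_residue_set("toy", 100, 1:30)
  set.seed(6)
  perf <- reliability_envelope(perfect_predictor(cs), cs, replicates = 50,
                               predictor = "perfect")
  rand <- reliability_envelope(random_predictor(100), cs, replicates = 50,
                               predictor = "random")
  reg <- reliable_region(perf, rand, "sensitivity")
  expect_equal(nrow(reg), 1L)
  expect_lte(reg$t_low, 0.30)
  expect_gte(reg$t_high, 0.30)
  # endpoints are grid members
  expect_true(all(c(reg$t_low, reg$t_high) %in% seq(0.05, 0.95, 0.05)))
  expect_true(competence(reg, cs))

  # identical envelopes: empty region, not competent
  reg0 <- reliable_region(perf, perf, "sensitivity")
  expect_equal(nrow(reg0), 0L)
  expect_false(competence(reg0, cs))
})

test_that("envelopes write as long TSV and plot", {
  cs <- critical_residue_set("toy", 20, "1-6")
  set.seed(8)
  env <- reliability_envelope(perfect_predictor(cs), cs, replicates = 3)
  path <- tempfile(fileext = ".tsv")
  write_envelope(env, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back),
               c("predictor", "replicate", "threshold", "sensitivity",
                 "specificity", "mcc"))
  expect_equal(nrow(back), nrow(env))
  p <- ggplot2::autoplot(env)
  expect_s3_class(p, "ggplot")
})

test_that("predictor rankings read with score-based tie-breaking", {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(rank = 1:4, position = c(4L, 2L, 3L, 1L),
                                  score = c(0.9, 0.9, 0.5, 0.2)), path)
  rk <- read_predictor_ranking(path)
  expect_equal(rk$position, c(2L, 4L, 3L, 1L))  # tie at 0.9 broken by position
})
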