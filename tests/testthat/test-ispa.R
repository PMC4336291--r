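test_that("BiM reproduces the worked 30/300 example", {
  call <- classify_bim(30, 300, mu = 0.062)
  expect_equal(call$minority_count, 30L)
  expect_equal(call$minority_phenotype, "WT")
  x <- 30 / 330
  expect_equal(call$bim_z, (x - 0.062) / sqrt(0.062 * 0.938 / 330))
  expect_equal(round(call$bim_z, 2), 2.18)
  expect_equal(call$bim_call, "TRUE_ISPA")
})

test_that("BiM boundary and degenerate behaviour", {
  # minority proportion exactly mu -> Z = 0 -> FALSE_ISPA
  call <- classify_bim(10, 90, mu = 0.1)
  expect_equal(call$bim_z, 0)
  expect_equal(call$bim_call, "FALSE_ISPA")

  # balanced counts maximise x at 0.5: TRUE for every depth at mu = 0.062
  k <- c(1L, 2L, 5L, 50L, 500L)
  calls <- classify_bim(k, k, mu = 0.062)
  expect_true(all(calls$bim_call == "TRUE_ISPA"))

  expect_error(classify_bim(0, 10, 0.062), "testable")
})

test_that("the wild-type-style case (510 minority of ~28%) is a clear TRUE_ISPA", {
  # counts implying 510 mutant-phenotype reads at 28% observed frequency
  mut <- 510L
  total <- round(510 / 0.28)
  wt <- as.integer(total - mut)
  call <- classify_bim(wt, mut, mu = 0.062)
  expect_equal(call$minority_phenotype, "MUT")
  expect_gt(call$bim_z, 1.65)
  expect_equal(call$bim_call, "TRUE_ISPA")
  pct <- 100 * mut / (wt + mut)
  expect_equal(round(pct), 28)
})

test_that("ByM classifies by the sign of the error/posterior discrepancy", {
  call <- classify_bym(30, 300, mu = 0.062)
  expect_equal(call$bym_mean, 0.062 - 31 / 332)
  expect_lt(call$bym_mean, 0)
  expect_equal(call$bym_call, "TRUE_ISPA")

  tiny <- classify_bym(1, 1e6, mu = 0.062)
  expect_gt(tiny$bym_mean, 0)
  expect_equal(tiny$bym_call, "FALSE_ISPA")

  # posterior mean exactly mu: boundary is FALSE_ISPA
  # Beta(1+9, 1+89): mean 0.1
  bound <- classify_bym(9, 89, mu = 0.1)
  expect_equal(bound$bym_mean, 0)
  expect_equal(bound$bym_call, "FALSE_ISPA")
})

test_that("both models are monotone in the minority count at fixed depth", {
  n_v <- 200L
  minority <- 1:100
  bim <- classify_bim(minority, n_v - minority, mu = 0.062)
  expect_true(all(diff(bim$bim_z) > 0))
  first_true <- match("TRUE_ISPA", bim$bim_call)
  expect_true(all(bim$bim_call[seq_len(first_true - 1)] == "FALSE_ISPA"))
  expect_true(all(bim$bim_call[first_true:length(minority)] == "TRUE_ISPA"))

  bym <- classify_bym(minority, n_v - minority, mu = 0.062)
  expect_true(all(diff(bym$bym_mean) < 0))
  ft <- match("TRUE_ISPA", bym$bym_call)
  expect_true(all(bym$bym_call[ft:length(minority)] == "TRUE_ISPA"))
})

test_that("doubling every count never shrinks |Z|", {
  set.seed(31)
  wt <- sample(1:200, 300, replace = TRUE)
  mut <- sample(1:200, 300, replace = TRUE)
  z1 <- classify_bim(wt, mut, mu = 0.062)$bim_z
  z2 <- classify_bim(2L * wt, 2L * mut, mu = 0.062)$bim_z
  expect_true(all(abs(z2) >= abs(z1) - 1e-12))
})

test_that("BiM call agrees with the exact binomial tail test on most small cases", {
  set.seed(97)
  mu <- 0.062
  alpha <- 0.05
  wt <- sample(1:25, 2000, replace = TRUE)
  mut <- sample(1:25, 2000, replace = TRUE)
  n_v <- wt + mut
  minority <- pmin(wt, mut)
  bim <- classify_bim(wt, mut, mu = mu, alpha = alpha)
  # oracle: exact one-sided binomial tail, independent of the Z machinery
  exact_reject <- pbinom(minority - 1L, n_v, mu, lower.tail = FALSE) < alpha
  agreement <- mean((bim$bim_call == "TRUE_ISPA") == exact_reject)
  disagree <- which((bim$bim_call == "TRUE_ISPA") != exact_reject)
  if (length(disagree)) {
    message("normal-approximation divergence on ", length(disagree),
            " of 2000 small cases; depths: ",
            paste(range(n_v[disagree]), collapse = "-"))
  }
  expect_gte(agreement, 0.9)
})

test_that("table classification partitions the B set and summarises it", {
  tab <- tibble::tibble(
    variant_aa = c("AAA", "BBB", "CCC", "DDD", "EEE"),
    variant_dna = NA_character_,
    wt_count = c(30L, 1000L, 150L, 0L, 3L),
    mut_count = c(300L, 20L, 0L, 80L, 3L))
  res <- classify_table(tab, 0.062)
  s <- glance(res)
  expect_equal(s$n_unique_variants, 5L)
  expect_equal(s$n_b_variants, 3L)
  expect_equal(s$n_u_variants, 2L)
  expect_equal(nrow(res$calls), 3L)
  expect_equal(s$n_true_bim + s$n_false_bim, s$n_b_variants)
  expect_equal(s$n_true_bym + s$n_false_bym, s$n_b_variants)
  expect_lte(s$n_common_true, min(s$n_true_bim, s$n_true_bym))
  # report frequency convention is 100 * mut / total even when WT is minority
  aaa <- res$calls[res$calls$variant_aa == "AAA", ]
  expect_equal(aaa$observed_ispa_pct, 100 * 300 / 330)
  # ordering: descending total
  expect_equal(res$calls$variant_aa, c("BBB", "AAA", "EEE"))
  expect_equal(tidy(res), res$calls)
})

test_that("a table with no both-phenotype variants yields an empty call set", {
  tab <- tibble::tibble(variant_aa = c("AAA", "BBB"),
                        variant_dna = NA_character_,
                        wt_count = c(10L, 0L), mut_count = c(0L, 5L))
  res <- classify_table(tab, 0.062)
  expect_equal(nrow(res$calls), 0L)
  expect_equal(glance(res)$n_true_bim, 0L)
  expect_true(glance(res)$budget_ok)
})

test_that("optional BH correction only removes TRUE calls", {
  set.seed(12)
  wt <- sample(5:50, 200, replace = TRUE)
  mut <- sample(200:400, 200, replace = TRUE)
  tab <- tibble::tibble(variant_aa = sprintf("v%03d", 1:200),
                        variant_dna = NA_character_,
                        wt_count = wt, mut_count = mut)
  plain <- classify_table(tab, 0.062)
  bh <- classify_table(tab, 0.062, adjust = "BH")
  expect_lte(glance(bh)$n_true_bim, glance(plain)$n_true_bim)
  # BH never promotes a variant the unadjusted test did not reject
  both <- dplyr::inner_join(tidy(plain), tidy(bh), by = "variant_aa")
  expect_false(any(both$bim_call.x == "FALSE_ISPA" &
                     both$bim_call.y == "TRUE_ISPA"))
})

test_that("error-budget check compares N*mu with B-set minority reads", {
  tab <- tibble::tibble(variant_aa = "AAA", variant_dna = NA_character_,
                        wt_count = 30L, mut_count = 300L)
  chk <- error_budget_check(tab, 0.062)
  expect_equal(chk$lhs, 330 * 0.062)
  expect_equal(chk$rhs, 30)
  expect_false(chk$pass)

  u_only <- tibble::tibble(variant_aa = "AAA", variant_dna = NA_character_,
                           wt_count = 100L, mut_count = 0L)
  chk2 <- error_budget_check(u_only, 0.062)
  expect_equal(chk2$rhs, 0)
  expect_true(chk2$pass)
})

test_that("ISPA reports round-trip their fixed column layout", {
  tab <- tibble::tibble(variant_aa = c("AAA", "BBB"),
                        variant_dna = NA_character_,
                        wt_count = c(30L, 5L), mut_count = c(300L, 400L))
  res <- classify_table(tab, 0.062)
  path <- tempfile(fileext = ".tsv")
  write_ispa_report(res, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back)[1:5],
               c("variant_aa", "variant_dna", "wt_count", "mut_count",
                 "observed_ispa_pct"))
  expect_equal(back$bim_call, res$calls$bim_call)
  expect_true(file.exists(paste0(path, ".summary.tsv")))
})
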