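#' Binomial-model (BiM) ISPA test for one or more variants
#'
#' A variant observed in both phenotype pools is an incorrect
#' sequence-phenotype assignment (ISPA). Whether it is a *true* ISPA
#' (cell-derived variation, e.g. a promoter mutation) or a *false* ISPA
#' (explained by experimental error) is decided by comparing the
#' minority-phenotype proportion `x = min(wt, mut) / (wt + mut)` against the
#' composed error budget `mu` with a one-sided Z-test:
#' `Z = (x - mu) / sqrt(mu (1 - mu) / N_v)`. Variants with
#' `Z <= z_(1-alpha)` (1.645 at the default alpha = 0.05) are explainable by
#' experimental/technical error (FALSE_ISPA); larger Z flags a TRUE_ISPA.
#'
#' @param wt_count,mut_count Positive read counts of the variant in the
#'   wild-type- and mutant-phenotype pools (vectorised). Both must be >= 1:
#'   variants seen in a single pool (U set) are not testable.
#' @param mu Expected error rate in (0, 1), e.g. from [compose_mu()].
#' @param alpha One-sided test level, default 0.05.
#' @return A tibble with columns `minority_count`, `minority_phenotype`,
#'   `bim_sigma`, `bim_z`, `bim_p`, `bim_call`.
#' @examples
#' classify_bim(30, 300, mu = 0.062) # Z ~ 2.18 -> TRUE_ISPA
#' @export
classify_bim <- function(wt_count, mut_count, mu, alpha = 0.05) {
  .check_counts(wt_count, mut_count)
  mu <- .check_mu(mu)
  stopifnot(alpha > 0, alpha < 1)
  n_v <- wt_count + mut_count
  minority <- pmin(wt_count, mut_count)
  x <- minority / n_v
  sigma <- sqrt(mu * (1 - mu) / n_v)
  z <- (x - mu) / sigma
  crit <- stats::qnorm(1 - alpha)
  tibble::tibble(
    minority_count = as.integer(minority),
    minority_phenotype = dplyr::if_else(wt_count <= mut_count, "WT", "MUT"),
    bim_sigma = sigma,
    bim_z = z,
    bim_p = stats::pnorm(z, lower.tail = FALSE),
    bim_call = dplyr::if_else(z > crit, "TRUE_ISPA", "FALSE_ISPA")
  )
}

#' Bayesian-model (ByM) ISPA test for one or more variants
#'
#' The minority-phenotype proportion gets a conjugate Beta posterior
#' (`Beta(prior_a + minority, prior_b + majority)`). The reported `bym_mean`
#' is the discrepancy `mu - posterior_mean`: a positive value means the
#' observed minority rate is explainable by the expected error rate
#' (FALSE_ISPA); a negative value flags a TRUE_ISPA. A posterior mean exactly
#' equal to `mu` is assigned FALSE_ISPA (documented tie-break). The HPD
#' interval of the posterior is reported alongside.
#'
#' @inheritParams classify_bim
#' @param prior_a,prior_b Beta prior shapes, default 1, 1.
#' @param mass HPD credibility mass, default 0.95.
#' @return A tibble with columns `bym_mean`, `bym_hpd_lower`,
#'   `bym_hpd_upper`, `bym_call`.
#' @examples
#' classify_bym(30, 300, mu = 0.062) # posterior mean ~0.093 > mu -> TRUE_ISPA
#' @export
classify_bym <- function(wt_count, mut_count, mu,
                         prior_a = 1, prior_b = 1, mass = 0.95) {
  .check_counts(wt_count, mut_count)
  mu <- .check_mu(mu)
  n_v <- wt_count + mut_count
  minority <- pmin(wt_count, mut_count)
  a <- prior_a + minority
  b <- prior_b + n_v - minority
  post_mean <- a / (a + b)
  hpd <- vapply(seq_along(a), function(i) {
    hpd_interval(structure(list(a = a[i], b = b[i],
                                prior_a = prior_a, prior_b = prior_b),
                           class = "beta_posterior"), mass)
  }, numeric(2))
  disc <- mu - post_mean
  tibble::tibble(
    bym_mean = disc,
    bym_hpd_lower = hpd[1, ],
    bym_hpd_upper = hpd[2, ],
    bym_call = dplyr::if_else(disc >= 0, "FALSE_ISPA", "TRUE_ISPA")
  )
}

.check_counts <- function(wt_count, mut_count) {
  if (any(wt_count < 1L) || any(mut_count < 1L)) {
    stop("both phenotype counts must be >= 1 (U-set variants, seen in a ",
         "single phenotype, are not testable)", call. = FALSE)
  }
}

.check_mu <- function(mu) {
  if (inherits(mu, "error_model")) mu <- mu$mu
  stopifnot(is.numeric(mu), length(mu) == 1L)
  if (mu <= 0 || mu >= 1) stop("mu must lie in (0, 1)", call. = FALSE)
  mu
}

#' Classify every both-phenotype variant of a screen
#'
#' Applies the BiM and ByM tests to every B-set variant of a variant table
#' (variants observed in both phenotype pools) and assembles the per-variant
#' report plus summary counts and the whole-experiment error-budget check.
#' The `observed_ispa_pct` column follows the report convention
#' `100 * mut_count / (wt_count + mut_count)` regardless of which phenotype
#' is the minority; the tests themselves always use the minority proportion.
#'
#' @param table A variant table from [count_variants()] or
#'   [read_variant_table()].
#' @param error_model An [compose_mu()] object, or a bare `mu` in (0, 1).
#' @param alpha One-sided BiM level (default 0.05).
#' @param prior_a,prior_b,mass ByM posterior settings.
#' @param adjust `"none"` (default; no multiple-testing correction is
#'   applied) or `"BH"` for Benjamini-Hochberg across the B-set BiM
#'   p-values.
#' @return An object of class `"ispa_result"`: list with `calls` (one row
#'   per B-set variant, ordered by descending total count then variant) and
#'   `summary` (one-row tibble; see [glance.ispa_result()]).
#' @examples
#' tab <- tibble::tibble(variant_aa = c("ITA", "PLH"),
#'                       variant_dna = NA_character_,
#'                       wt_count = c(1311L, 200L), mut_count = c(510L, 3L))
#' classify_table(tab, error_model = 0.062)
#' @export
classify_table <- function(table, error_model, alpha = 0.05,
                           prior_a = 1, prior_b = 1, mass = 0.95,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  mu <- .check_mu(error_model)
  stopifnot(is.data.frame(table),
            all(c("variant_aa", "wt_count", "mut_count") %in% names(table)))
  if (!"variant_dna" %in% names(table)) table$variant_dna <- NA_character_
  tab <- variant_sets(tibble::as_tibble(table))
  b <- dplyr::filter(tab, .data$set == "B")
  n_unique <- nrow(tab)

  if (nrow(b) == 0L) {
    calls <- tibble::tibble(
      variant_aa = character(0), variant_dna = character(0),
      wt_count = integer(0), mut_count = integer(0),
      total = integer(0), observed_ispa_pct = numeric(0),
      minority_count = integer(0), minority_phenotype = character(0),
      bim_sigma = numeric(0), bim_z = numeric(0), bim_p = numeric(0),
      bim_call = character(0), bym_mean = numeric(0),
      bym_hpd_lower = numeric(0), bym_hpd_upper = numeric(0),
      bym_call = character(0), consensus_call = character(0))
  } else {
    bim <- classify_bim(b$wt_count, b$mut_count, mu, alpha)
    if (adjust == "BH") {
      p_adj <- stats::p.adjust(bim$bim_p, method = "BH")
      bim$bim_call <- dplyr::if_else(p_adj < alpha, "TRUE_ISPA", "FALSE_ISPA")
    }
    bym <- classify_bym(b$wt_count, b$mut_count, mu, prior_a, prior_b, mass)
    calls <- dplyr::bind_cols(
      b[, c("variant_aa", "variant_dna", "wt_count", "mut_count")],
      tibble::tibble(
        total = b$wt_count + b$mut_count,
        observed_ispa_pct = 100 * b$mut_count / (b$wt_count + b$mut_count)),
      bim, bym) |>
      dplyr::mutate(consensus_call = dplyr::case_when(
        .data$bim_call == .data$bym_call ~ .data$bim_call,
        TRUE ~ "DISCORDANT")) |>
      dplyr::arrange(dplyr::desc(.data$total), .data$variant_aa,
                     .data$variant_dna)
  }

  n_reads <- attr(table, "n_reads_total")
  if (is.null(n_reads)) n_reads <- sum(tab$wt_count) + sum(tab$mut_count)
  budget <- error_budget_check(table, mu)

  summary <- tibble::tibble(
    n_reads_total = as.integer(n_reads),
    n_unique_variants = n_unique,
    n_u_variants = n_unique - nrow(b),
    n_b_variants = nrow(b),
    n_true_bim = sum(calls$bim_call == "TRUE_ISPA"),
    n_false_bim = sum(calls$bim_call == "FALSE_ISPA"),
    n_true_bym = sum(calls$bym_call == "TRUE_ISPA"),
    n_false_bym = sum(calls$bym_call == "FALSE_ISPA"),
    n_common_true = sum(calls$bim_call == "TRUE_ISPA" &
                          calls$bym_call == "TRUE_ISPA"),
    pct_true_bim_of_unique = 100 * sum(calls$bim_call == "TRUE_ISPA") /
      max(1L, n_unique),
    pct_true_bym_of_unique = 100 * sum(calls$bym_call == "TRUE_ISPA") /
      max(1L, n_unique),
    mu = mu, alpha = alpha,
    budget_lhs = budget$lhs, budget_rhs = budget$rhs,
    budget_ok = budget$pass
  )
  structure(list(calls = calls, summary = summary),
            class = "ispa_result")
}

#' Whole-experiment error-budget check
#'
#' Quality flag for the screen as a whole: the error budget `N * mu` (reads
#' times expected error rate) should cover the total minority-phenotype read
#' count summed over all both-phenotype variants. Failure signals
#' both-phenotype reads in excess of the budget — cell-derived variation is
#' present (or the error model underestimates the error rate).
#'
#' @param table A variant table.
#' @param mu Expected error rate (or an `"error_model"`).
#' @return A one-row tibble with `lhs` (`N * mu`), `rhs` (sum of B-set
#'   minority counts) and `pass` (`lhs >= rhs`).
#' @export
error_budget_check <- function(table, mu) {
  mu <- .check_mu(mu)
  tab <- variant_sets(tibble::as_tibble(table))
  n_reads <- attr(table, "n_reads_total")
  if (is.null(n_reads)) n_reads <- sum(tab$wt_count) + sum(tab$mut_count)
  b <- dplyr::filter(tab, .data$set == "B")
  rhs <- sum(pmin(b$wt_count, b$mut_count))
  lhs <- n_reads * mu
  tibble::tibble(lhs = lhs, rhs = rhs, pass = lhs >= rhs)
}

#' @export
print.ispa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<ispa_result> %d unique variants (%d U, %d B), N = %d reads, mu = %.4g\n",
    s$n_unique_variants, s$n_u_variants, s$n_b_variants, s$n_reads_total,
    s$mu))
  cat(sprintf("  BiM: %d TRUE / %d FALSE ISPAs (%.3g%% of unique variants)\n",
              s$n_true_bim, s$n_false_bim, s$pct_true_bim_of_unique))
  cat(sprintf("  ByM: %d TRUE / %d FALSE ISPAs (%.3g%% of unique variants)\n",
              s$n_true_bym, s$n_false_bym, s$pct_true_bym_of_unique))
  cat(sprintf("  common TRUE: %d; error budget %s (N*mu = %.4g vs %g)\n",
              s$n_common_true, if (s$budget_ok) "ok" else "EXCEEDED",
              s$budget_lhs, s$budget_rhs))
  invisible(x)
}

#' @rdname classify_table
#' @param x An `"ispa_result"`.
#' @param ... Unused.
#' @export
tidy.ispa_result <- function(x, ...) x$calls

#' Summary row of an ISPA classification
#'
#' @param x An `"ispa_result"` from [classify_table()].
#' @param ... Unused.
#' @return The one-row summary tibble: variant counts (U/B), TRUE/FALSE ISPA
#'   counts under each model, common TRUE count, percentages against all
#'   unique variants, and the error-budget check.
#' @export
glance.ispa_result <- function(x, ...) x$summary

#' Write the per-variant ISPA report and its summary (TSV)
#'
#' The report keeps a fixed column order:
#' `variant_aa, variant_dna, wt_count, mut_count, observed_ispa_pct, bim_z,
#' bim_call, bym_mean, bym_hpd_lower, bym_hpd_upper, bym_call,
#' consensus_call`. The summary is written both as key-value text
#' (`<path>.summary.txt`) and as a one-row TSV (`<path>.summary.tsv`).
#'
#' @param result An `"ispa_result"`.
#' @param path Path of the report TSV.
#' @return `path`, invisibly.
#' @export
write_ispa_report <- function(result, path) {
  stopifnot(inherits(result, "ispa_result"))
  cols <- c("variant_aa", "variant_dna", "wt_count", "mut_count",
            "observed_ispa_pct", "bim_z", "bim_call", "bym_mean",
            "bym_hpd_lower", "bym_hpd_upper", "bym_call", "consensus_call")
  readr::write_tsv(result$calls[, cols], path)
  s <- result$summary
  writeLines(sprintf("%s = %s", names(s),
                     vapply(s, format, character(1), digits = 10)),
             paste0(path, ".summary.txt"))
  readr::write_tsv(s, paste0(path, ".summary.tsv"))
  invisible(path)
}
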