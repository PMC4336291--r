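#' Agresti-Coull confidence interval for a binomial proportion
#'
#' Adjusted-Wald interval: with z the `1 - (1 - conf)/2` normal quantile,
#' `n' = n + z^2`, `x' = x + z^2/2`, `p' = x'/n'`, the interval is
#' `p' +/- z * sqrt(p'(1 - p')/n')`, clipped to `[0, 1]`. Preferred over the
#' plain Wald interval when the proportion is small, as experimental error
#' rates are.
#'
#' @param successes,trials Non-negative counts, `successes <= trials`,
#'   `trials >= 1`. Vectorised.
#' @param conf Confidence level in (0, 1); default 0.95.
#' @return A tibble with columns `successes`, `trials`, `estimate` (x/n),
#'   `adj_estimate` (p'), `lower`, `upper`, `conf`.
#' @examples
#' agresti_coull_interval(12, 400) # ~1.7% to ~5.2%
#' @export
agresti_coull_interval <- function(successes, trials, conf = 0.95) {
  stopifnot(conf > 0, conf < 1)
  if (any(trials < 1L)) stop("`trials` must be >= 1", call. = FALSE)
  if (any(successes < 0L) || any(successes > trials)) {
    stop("need 0 <= successes <= trials", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n_adj <- trials + z^2
  p_adj <- (successes + z^2 / 2) / n_adj
  half <- z * sqrt(p_adj * (1 - p_adj) / n_adj)
  tibble::tibble(
    successes = successes, trials = trials,
    estimate = successes / trials,
    adj_estimate = p_adj,
    lower = pmax(0, p_adj - half),
    upper = pmin(1, p_adj + half),
    conf = conf
  )
}

#' Conjugate Beta posterior for a binomial proportion
#'
#' `Beta(prior_a + successes, prior_b + trials - successes)`. This is the
#' Bayesian error model used throughout: the prior belief about the error
#' rate is a Beta density (flat `Beta(1, 1)` by default) and the phenotype
#' assignments are binomial draws, so the posterior is available in closed
#' form.
#'
#' @inheritParams agresti_coull_interval
#' @param prior_a,prior_b Positive prior shape parameters (default 1, 1).
#' @return An object of class `"beta_posterior"` with elements `a`, `b`,
#'   `prior_a`, `prior_b`. Its mean is `a / (a + b)`.
#' @examples
#' p <- beta_posterior(12, 400)
#' posterior_mean(p)
#' @export
beta_posterior <- function(successes, trials, prior_a = 1, prior_b = 1) {
  stopifnot(length(successes) == 1L, length(trials) == 1L)
  if (prior_a <= 0 || prior_b <= 0) {
    stop("prior shapes must be positive", call. = FALSE)
  }
  if (trials < 0L || successes < 0L || successes > trials) {
    stop("need 0 <= successes <= trials", call. = FALSE)
  }
  structure(list(a = prior_a + successes,
                 b = prior_b + trials - successes,
                 prior_a = prior_a, prior_b = prior_b),
            class = "beta_posterior")
}

#' @rdname beta_posterior
#' @param posterior A `"beta_posterior"` object.
#' @export
posterior_mean <- function(posterior) {
  posterior$a / (posterior$a + posterior$b)
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("<beta_posterior> Beta(%.4g, %.4g), mean %.4g\n",
              x$a, x$b, posterior_mean(x)))
  invisible(x)
}

#' Highest-posterior-density interval of a Beta posterior
#'
#' The shortest interval containing the requested posterior mass. For a
#' unimodal Beta this is found by one-dimensional optimisation over the lower
#' endpoint (the upper endpoint follows from the mass constraint); its width
#' is never larger than the equal-tailed interval at the same mass. For the
#' bimodal degenerate case `a < 1 && b < 1` the equal-tailed interval is
#' returned with a warning. For the flat `Beta(1, 1)` posterior every
#' interval of width `mass` is an HPD interval; the convention here is
#' `(0, mass)`.
#'
#' @param posterior A [beta_posterior()] object.
#' @param mass Posterior mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(beta_posterior(12, 400), 0.95)
#' @export
hpd_interval <- function(posterior, mass = 0.95) {
  stopifnot(inherits(posterior, "beta_posterior"), mass > 0, mass < 1)
  a <- posterior$a
  b <- posterior$b
  if (a < 1 && b < 1) {
    warning("Beta(", a, ", ", b, ") is not unimodal; ",
            "returning equal-tailed interval", call. = FALSE)
    return(c(lower = stats::qbeta((1 - mass) / 2, a, b),
             upper = stats::qbeta(1 - (1 - mass) / 2, a, b)))
  }
  if (a == 1 && b == 1) {
    return(c(lower = 0, upper = mass))
  }
  if (a <= 1) {                   # mode at 0: one-sided interval
    return(c(lower = 0, upper = stats::qbeta(mass, a, b)))
  }
  if (b <= 1) {                   # mode at 1
    return(c(lower = stats::qbeta(1 - mass, a, b), upper = 1))
  }
  width <- function(lo) {
    stats::qbeta(stats::pbeta(lo, a, b) + mass, a, b) - lo
  }
  hi_lo <- stats::qbeta(1 - mass, a, b)
  opt <- stats::optimize(width, c(0, hi_lo), tol = 1e-10)
  lo <- opt$minimum
  c(lower = lo, upper = lo + opt$objective)
}

#' Estimate selection leakiness from a plate assay
#'
#' Leakiness is the false-positive rate of the phenotypic selection: the
#' fraction of colonies carrying the wild-type gene that nevertheless survive
#' selection (display the mutant phenotype). It is estimated from one or more
#' plates of colonies by pooling counts, with both a frequentist
#' (Agresti-Coull) interval and a Beta posterior with HPD interval. The
#' dispersion term G of each model is the distance from the point estimate to
#' the model's upper limit.
#'
#' @param assay A data frame with columns `colonies_total` and `survivors`
#'   (one row per plate; `plate_id` optional), or a path readable by
#'   [read_leakiness_assay()].
#' @param conf Confidence / credibility level, default 0.95.
#' @param prior_a,prior_b Beta prior shapes for the Bayesian model.
#' @return An object of class `"leakiness_fit"`: a list with `successes`,
#'   `trials`, `p_hat`, `ci_lower`, `ci_upper`, `g_bim`, `posterior`,
#'   `hpd_lower`, `hpd_upper`, `g_bym`, `conf`.
#' @examples
#' assay <- data.frame(colonies_total = rep(100, 4), survivors = c(6, 2, 3, 1))
#' estimate_leakiness(assay)
#' @export
estimate_leakiness <- function(assay, conf = 0.95, prior_a = 1, prior_b = 1) {
  if (is.character(assay)) assay <- read_leakiness_assay(assay)
  stopifnot(is.data.frame(assay),
            all(c("colonies_total", "survivors") %in% names(assay)),
            nrow(assay) >= 1L)
  if (any(assay$survivors < 0L) ||
      any(assay$survivors > assay$colonies_total)) {
    stop("need 0 <= survivors <= colonies_total on every plate",
         call. = FALSE)
  }
  trials <- sum(assay$colonies_total)
  if (trials == 0L) stop("zero total colonies", call. = FALSE)
  successes <- sum(assay$survivors)
  ac <- agresti_coull_interval(successes, trials, conf)
  post <- beta_posterior(successes, trials, prior_a, prior_b)
  hpd <- hpd_interval(post, conf)
  structure(list(
    successes = successes, trials = trials,
    p_hat = successes / trials,
    ci_lower = ac$lower, ci_upper = ac$upper,
    g_bim = ac$upper - successes / trials,
    posterior = post,
    hpd_lower = unname(hpd["lower"]), hpd_upper = unname(hpd["upper"]),
    g_bym = unname(hpd["upper"]) - successes / trials,
    conf = conf
  ), class = "leakiness_fit")
}

#' @export
print.leakiness_fit <- function(x, ...) {
  cat(sprintf(
    "<leakiness_fit> %d/%d survivors: p_hat = %.4g\n", x$successes, x$trials,
    x$p_hat))
  cat(sprintf("  Agresti-Coull %g%% CI: %.4g - %.4g (G = %.4g)\n",
              100 * x$conf, x$ci_lower, x$ci_upper, x$g_bim))
  cat(sprintf("  Beta(%g, %g) posterior %g%% HPD: %.4g - %.4g (G = %.4g)\n",
              x$posterior$a, x$posterior$b, 100 * x$conf,
              x$hpd_lower, x$hpd_upper, x$g_bym))
  invisible(x)
}

#' Read a leakiness assay table (TSV)
#'
#' Expects columns `plate_id`, `colonies_total`, `survivors`.
#'
#' @param path File path.
#' @return A tibble, validated.
#' @export
read_leakiness_assay <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    plate_id = readr::col_character(),
    colonies_total = readr::col_integer(),
    survivors = readr::col_integer()
  ))
  missing <- setdiff(c("colonies_total", "survivors"), names(tab))
  if (length(missing)) {
    stop("assay table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(tab$survivors > tab$colonies_total) || any(tab$survivors < 0L)) {
    stop("need 0 <= survivors <= colonies_total", call. = FALSE)
  }
  tab
}

#' Compose the expected error rate mu = E + G
#'
#' The per-read error budget against which minority-phenotype frequencies are
#' tested combines the leakiness of the selection (its model-specific upper
#' limit, i.e. point estimate E plus dispersion G) with the per-read
#' sequencing/assignment error rate. Under the binomial model (BiM) the
#' leakiness upper limit is the Agresti-Coull bound; under the Bayesian model
#' (ByM) it is the HPD upper bound of the Beta posterior. `G_sequencing` is 0
#' by default (short-read substitution error is folded into `e_seq`). Any
#' component, or mu itself, can be overridden.
#'
#' @param leak A [estimate_leakiness()] fit.
#' @param e_seq Per-read sequencing/assignment error rate (default 0.01).
#' @param g_sequencing Dispersion of the sequencing error (default 0).
#' @param model `"bim"` or `"bym"`.
#' @param mu Optional direct override of the composed rate.
#' @return An object of class `"error_model"`: a list with the leakiness
#'   fields, `e_seq`, `g_sequencing`, `model` and the composed `mu`.
#' @examples
#' assay <- data.frame(colonies_total = rep(100, 4), survivors = c(6, 2, 3, 1))
#' compose_mu(estimate_leakiness(assay))   # mu ~ 0.062
#' @export
compose_mu <- function(leak, e_seq = 0.01, g_sequencing = 0,
                       model = c("bim", "bym"), mu = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(leak, "leakiness_fit"),
            e_seq >= 0, e_seq <= 1, g_sequencing >= 0, g_sequencing <= 1)
  if (is.null(mu)) {
    upper <- if (model == "bim") leak$ci_upper else leak$hpd_upper
    mu <- upper + e_seq + g_sequencing
  }
  if (mu <= 0 || mu >= 1) {
    stop("composed mu = ", signif(mu, 4), " outside (0, 1)", call. = FALSE)
  }
  structure(list(
    leakiness = leak, e_seq = e_seq, g_sequencing = g_sequencing,
    model = model, mu = mu
  ), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  lk <- x$leakiness
  upper <- if (x$model == "bim") lk$ci_upper else lk$hpd_upper
  cat(sprintf(
    "<error_model> %s: mu = %.4g (leakiness upper %.4g + e_seq %.4g + G_seq %.4g)\n",
    toupper(x$model), x$mu, upper, x$e_seq, x$g_sequencing))
  invisible(x)
}

#' Serialise / deserialise an error model as flat key-value text
#'
#' @param em An [compose_mu()] error model.
#' @param path File path.
#' @return `read_error_model()` returns an `"error_model"` object;
#'   `write_error_model()` returns `path` invisibly.
#' @export
write_error_model <- function(em, path) {
  stopifnot(inherits(em, "error_model"))
  lk <- em$leakiness
  kv <- c(
    model = em$model, conf = lk$conf,
    successes = lk$successes, trials = lk$trials,
    p_hat = lk$p_hat, ci_lower = lk$ci_lower, ci_upper = lk$ci_upper,
    hpd_lower = lk$hpd_lower, hpd_upper = lk$hpd_upper,
    prior_a = lk$posterior$prior_a, prior_b = lk$posterior$prior_b,
    e_seq = em$e_seq, g_sequencing = em$g_sequencing,
    mu = em$mu
  )
  writeLines(sprintf("%s = %s", names(kv),
                     vapply(kv, format, character(1), digits = 17)),
             path)
  invisible(path)
}

#' @rdname write_error_model
#' @export
read_error_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\\s*=\\s*")
  kv <- stats::setNames(vapply(parts, `[`, character(1), 2L),
                        vapply(parts, `[`, character(1), 1L))
  num <- function(k) as.numeric(kv[[k]])
  leak <- estimate_leakiness(
    data.frame(colonies_total = as.integer(num("trials")),
               survivors = as.integer(num("successes"))),
    conf = num("conf"), prior_a = num("prior_a"), prior_b = num("prior_b"))
  compose_mu(leak, e_seq = num("e_seq"), g_sequencing = num("g_sequencing"),
             model = kv[["model"]], mu = num("mu"))
}
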