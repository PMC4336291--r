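#' Tidy a leakiness fit
#'
#' @param x An [estimate_leakiness()] fit.
#' @param ... Unused.
#' @return A one-row tibble with the point estimate and both intervals.
#' @export
tidy.leakiness_fit <- function(x, ...) {
  tibble::tibble(
    successes = x$successes, trials = x$trials, p_hat = x$p_hat,
    ci_lower = x$ci_lower, ci_upper = x$ci_upper, g_bim = x$g_bim,
    hpd_lower = x$hpd_lower, hpd_upper = x$hpd_upper, g_bym = x$g_bym,
    conf = x$conf)
}

#' Tidy an error model
#'
#' @param x An [compose_mu()] error model.
#' @param ... Unused.
#' @return A one-row tibble with the mu decomposition.
#' @export
tidy.error_model <- function(x, ...) {
  lk <- x$leakiness
  tibble::tibble(
    model = x$model,
    leak_p_hat = lk$p_hat,
    leak_upper = if (x$model == "bim") lk$ci_upper else lk$hpd_upper,
    g_leakiness = if (x$model == "bim") lk$g_bim else lk$g_bym,
    e_seq = x$e_seq, g_sequencing = x$g_sequencing, mu = x$mu)
}

#' @rdname tidy.error_model
#' @export
glance.error_model <- function(x, ...) tidy.error_model(x, ...)
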