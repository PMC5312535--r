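#' Scale mutation-scaled coalescent estimates to natural units
#'
#' Sequence-based coalescent samplers report population sizes, divergence
#' times and migration rates per site in mutation units. With a per-site
#' per-year mutation rate `mu_year` and a generation time `gen_time` (the
#' study design uses 2.2e-9 / site / year and 3 years for the dog lineage):
#'
#' * `T_years = tau / mu_year`
#' * `Ne = theta / (4 * mu_year * gen_time)`
#' * `two_Nm = mig * theta / 2` — the sampler-manual convention in which the
#'   migration-band rate is the per-generation rate divided by the mutation
#'   rate per generation; the convention is carried in the output because
#'   reports rarely state theirs.
#'
#' @param theta mutation-scaled population size per site (4 Ne mu).
#' @param tau mutation-scaled divergence time per site.
#' @param mig mutation-scaled migration rate (optional, `NA` to skip).
#' @param mu_year per-site per-year mutation rate (> 0).
#' @param gen_time generation time in years (> 0).
#' @return object of class `demog_estimate`: list with the inputs and the
#'   derived `Ne`, `T_years`, `two_Nm`, plus `convention`.
#' @export
scale_estimates <- function(theta, tau, mig = NA, mu_year = 2.2e-9,
                            gen_time = 3) {
  if (!is.numeric(mu_year) || mu_year <= 0) stop("mu_year must be > 0")
  if (!is.numeric(gen_time) || gen_time <= 0) stop("gen_time must be > 0")
  if (any(c(theta, tau) < 0, na.rm = TRUE))
    stop("theta and tau must be non-negative")
  structure(list(
    theta = theta, tau = tau, mig = mig,
    mu_year = mu_year, gen_time = gen_time,
    Ne = theta / (4 * mu_year * gen_time),
    T_years = tau / mu_year,
    two_Nm = if (all(is.na(mig))) NA_real_ else mig * theta / 2,
    convention = "two_Nm = mig * theta_target / 2"
  ), class = "demog_estimate")
}

#' Invert [scale_estimates]
#'
#' Recovers the mutation-scaled parameters from natural units; used for
#' round-trip checks and to derive simulation truths from calendar-year
#' settings.
#'
#' @param Ne effective size in individuals.
#' @param T_years divergence time in years.
#' @param two_Nm population-scaled migration (optional).
#' @param mu_year,gen_time as in [scale_estimates].
#' @return list with `theta`, `tau`, `mig`.
#' @export
unscale_estimates <- function(Ne, T_years, two_Nm = NA, mu_year = 2.2e-9,
                              gen_time = 3) {
  theta <- Ne * 4 * mu_year * gen_time
  list(theta = theta,
       tau = T_years * mu_year,
       mig = if (all(is.na(two_Nm))) NA_real_ else 2 * two_Nm / theta)
}

#' @export
print.demog_estimate <- function(x, ...) {
  cat("demog_estimate (mu =", format(x$mu_year), "/site/year, g =",
      x$gen_time, "years)\n")
  cat(sprintf("  theta = %s -> Ne = %s individuals\n",
              format(x$theta), format(round(x$Ne, 1))))
  cat(sprintf("  tau   = %s -> T  = %s years\n",
              format(x$tau), format(round(x$T_years, 1))))
  if (!all(is.na(x$two_Nm)))
    cat(sprintf("  mig   = %s -> 2Nm = %s  [%s]\n",
                format(x$mig), format(signif(x$two_Nm, 3)), x$convention))
  invisible(x)
}

#' Summarise a pooled MCMC trace
#'
#' Per-parameter posterior mean and central 95% interval over the pooled
#' post-burn-in samples, plus per-replicate means for a between-replicate
#' consistency report. Empirical quantiles use the median-unbiased rule
#' (R's `type = 8`), fixed so that documented examples are exact.
#' Between-replicate consistency is assessed with a potential-scale-reduction
#' statistic over replicates (between-replicate variance of means against
#' mean within-replicate variance, Gelman-Rubin style): a parameter with
#' `rhat > 1.1` is flagged divergent.
#'
#' @param trace an `mcmc_trace` from [read_mcmc_trace].
#' @param params parameters to summarise (default all).
#' @return object of class `trace_summary`: list with `summary` (data frame
#'   `param`, `mean`, `q025`, `q975`), `replicate_means` (replicate x
#'   parameter matrix), `rhat` (named vector, `NA` with one replicate) and
#'   `divergent` (named logical vector).
#' @export
summarize_trace <- function(trace, params = NULL) {
  stopifnot(inherits(trace, "mcmc_trace"))
  if (is.null(params)) params <- trace$params
  if (nrow(trace$samples) < 10)
    stop("fewer than 10 retained samples")
  s <- trace$samples
  summ <- data.frame(
    param = params,
    mean = vapply(params, function(p) mean(s[[p]]), numeric(1)),
    q025 = vapply(params, function(p)
      unname(quantile(s[[p]], 0.025, type = 8)), numeric(1)),
    q975 = vapply(params, function(p)
      unname(quantile(s[[p]], 0.975, type = 8)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  reps <- sort(unique(s$replicate))
  rm_mat <- sapply(params, function(p)
    vapply(reps, function(r) mean(s[[p]][s$replicate == r]), numeric(1)))
  rm_mat <- matrix(rm_mat, nrow = length(reps),
                   dimnames = list(paste0("rep", reps), params))
  rhat <- setNames(rep(NA_real_, length(params)), params)
  if (length(reps) > 1) {
    for (p in params) {
      n_bar <- nrow(s) / length(reps)
      B <- n_bar * var(rm_mat[, p])
      W <- mean(vapply(reps, function(r)
        var(s[[p]][s$replicate == r]), numeric(1)))
      rhat[p] <- if (W == 0 && B == 0) 1
                 else sqrt(((n_bar - 1) / n_bar * W + B / n_bar) /
                             max(W, .Machine$double.xmin))
    }
  }
  structure(list(summary = summ, replicate_means = rm_mat,
                 rhat = rhat,
                 divergent = !is.na(rhat) & rhat > 1.1),
            class = "trace_summary")
}

#' @export
print.trace_summary <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  if (any(x$divergent, na.rm = TRUE))
    cat("warning: between-replicate divergence (rhat > 1.1) for:",
        paste(names(x$divergent)[x$divergent], collapse = ", "), "\n")
  invisible(x)
}
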