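#' Split-chain Gelman--Rubin diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends inflate the statistic.  Parameters with zero
#' variance everywhere (e.g. a coefficient fixed at its initial value
#' because its covariate never occurs) report 1.
#'
#' @param draws a list of iteration-by-parameter matrices (one per chain,
#'   equal dimensions), or an `opscr_fit`.
#' @return named vector of Rhat values, one per parameter.
#' @export
gelman_rubin <- function(draws) {
  if (inherits(draws, "opscr_fit")) draws <- draws$draws
  stopifnot(is.list(draws))
  if (length(draws) < 2) stop("at least two chains are required for Rhat")
  niter <- unique(vapply(draws, nrow, integer(1)))
  if (length(niter) != 1) stop("chains have unequal lengths")
  half <- floor(niter / 2)
  splits <- list()
  for (d in draws) {
    splits[[length(splits) + 1]] <- d[seq_len(half), , drop = FALSE]
    splits[[length(splits) + 1]] <- d[half + seq_len(half), , drop = FALSE]
  }
  m <- length(splits); n <- half
  p <- ncol(draws[[1]])
  out <- setNames(numeric(p), colnames(draws[[1]]))
  for (k in seq_len(p)) {
    x <- vapply(splits, function(s) s[, k], numeric(n))
    mu <- colMeans(x)
    W <- mean(apply(x, 2, var))
    B <- n * var(mu)
    if (!is.finite(W) || W <= 0) {
      out[k] <- if (!is.finite(B) || B <= 1e-300) 1 else Inf
    } else {
      out[k] <- sqrt(((n - 1) / n * W + B / n) / W)
    }
  }
  out
}

#' Pool posterior draws across chains
#'
#' @param x an `opscr_fit`.
#' @param ... unused.
#' @return one matrix with all kept iterations of all chains.
#' @export
as.matrix.opscr_fit <- function(x, ...) {
  do.call(rbind, x$draws)
}

#' Posterior summaries
#'
#' @param fit an `opscr_fit`.
#' @param pars parameter names (default all).
#' @param probs quantiles reported alongside the median.
#' @return data.frame with one row per parameter.
#' @export
posterior_summary <- function(fit, pars = NULL, probs = c(0.025, 0.975)) {
  d <- as.matrix(fit)
  if (is.null(pars)) pars <- colnames(d)
  data.frame(
    parameter = pars,
    median = apply(d[, pars, drop = FALSE], 2, median),
    lower = apply(d[, pars, drop = FALSE], 2, quantile, probs[1]),
    upper = apply(d[, pars, drop = FALSE], 2, quantile, probs[2]),
    row.names = NULL)
}

#' Collar-effect contrasts on the probability and percentage-point scales
#'
#' For every retained draw, evaluates the cause-specific mortality
#' probabilities of non-collared (`GPS = 0`) and collared (`GPS = 1`)
#' individuals at the stratum's intercepts, together with their sum
#' (overall mortality), and summarizes the posterior of each probability and
#' of the non-collared-minus-collared difference expressed in percentage
#' points.  Credible intervals are equal-tailed 2.5%/97.5% quantiles.
#'
#' @param fit an `opscr_fit`.
#' @param group stratum index.
#' @param season season index; required when the fit used season-specific
#'   intercepts, ignored otherwise.
#' @return data.frame with rows `legal`, `other`, `overall`; probability
#'   columns are on the 0--1 scale, `diff_pp_*` columns on the 0--100
#'   percentage-point scale.
#' @export
derive_collar_contrasts <- function(fit, group = 1, season = NULL) {
  d <- as.matrix(fit)
  tv <- any(grepl(sprintf("^h0_g%d_t", group), colnames(d)))
  if (tv) {
    if (is.null(season)) stop("season must be given for a season-specific fit")
    h0n <- sprintf("h0_g%d_t%d", group, season)
    w0n <- sprintf("w0_g%d_t%d", group, season)
  } else {
    h0n <- sprintf("h0_g%d", group)
    w0n <- sprintf("w0_g%d", group)
  }
  if (!all(c(h0n, w0n, "beta_h_gps", "beta_w_gps") %in% colnames(d)))
    stop("unknown group/season: no parameter columns ", h0n, ", ", w0n)
  h0 <- plogis(d[, h0n]); h1 <- plogis(d[, h0n] + d[, "beta_h_gps"])
  w0 <- plogis(d[, w0n]); w1 <- plogis(d[, w0n] + d[, "beta_w_gps"])
  rows <- list(legal = list(h0, h1), other = list(w0, w1),
               overall = list(h0 + w0, h1 + w1))
  qs <- function(x) c(median(x), quantile(x, c(0.025, 0.975), names = FALSE))
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    p0 <- rows[[nm]][[1]]; p1 <- rows[[nm]][[2]]
    dpp <- 100 * (p0 - p1)
    s0 <- qs(p0); s1 <- qs(p1); sd_ <- qs(dpp)
    data.frame(measure = nm,
               noncollared_median = s0[1], noncollared_lo = s0[2],
               noncollared_hi = s0[3],
               collared_median = s1[1], collared_lo = s1[2],
               collared_hi = s1[3],
               diff_pp_median = sd_[1], diff_pp_lo = sd_[2],
               diff_pp_hi = sd_[3])
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.opscr_fit <- function(x, ...) {
  cat("OPSCR fit:", length(x$draws), "chains x", nrow(x$draws[[1]]),
      "kept iterations,", length(x$param_names) - 1, "parameters\n")
  if (!is.null(x$rhat))
    cat("  max split-chain Rhat:", format(max(x$rhat), digits = 4), "\n")
  cat("  observed individuals:", x$n_observed, "; augmentation:",
      sum(x$M), "\n")
  invisible(x)
}

#' @export
summary.opscr_fit <- function(object, ...) {
  s <- posterior_summary(object)
  if (!is.null(object$rhat)) s$rhat <- object$rhat[s$parameter]
  s
}
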