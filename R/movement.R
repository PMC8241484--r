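#' Movement parameters
#'
#' @param tau standard deviation (km) of the isotropic bivariate-normal
#'   random walk of activity centres between seasons.
#' @param b_dens slope linking the habitat covariate `X` to the log intensity
#'   of the activity-centre point process.
#' @return an object of class `movement_params`.
#' @export
movement_params <- function(tau, b_dens = 0) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive number (km)")
  stopifnot(is.finite(b_dens))
  structure(list(tau = tau, b_dens = b_dens), class = "movement_params")
}

.region_cells <- function(habitat, region = NULL) {
  if (is.null(region)) seq_len(nrow(habitat$cells))
  else which(habitat$cells$region == region)
}

#' Initial activity-centre distribution
#'
#' The inhomogeneous point-process intensity `exp(b_dens * X)` normalized by
#' summation over the discrete habitat (optionally restricted to one region).
#' Normalization is done in log space, so extreme `b_dens * X` cannot
#' overflow.
#'
#' @param habitat a `habitat_grid`.
#' @param params a [movement_params()].
#' @param region optional region id restricting the support.
#' @return probability vector over all habitat cells (cells outside `region`
#'   get zero); sums to one.
#' @export
initial_ac_distribution <- function(habitat, params, region = NULL) {
  idx <- .region_cells(habitat, region)
  lw <- params$b_dens * habitat$cells$X[idx]
  lw <- lw - max(lw)
  p <- numeric(nrow(habitat$cells))
  p[idx] <- exp(lw) / sum(exp(lw))
  p
}

#' Between-season movement kernel
#'
#' Probability of the next-season activity-centre cell given the current one:
#' an isotropic Gaussian displacement with scale `tau`, re-weighted by the
#' habitat intensity `exp(b_dens * X)` and normalized by summation over the
#' habitat (including buffer cells), giving a proper categorical
#' distribution.
#'
#' @param from_cell 1-based habitat cell index of the current season.
#' @inheritParams initial_ac_distribution
#' @return probability vector over habitat cells; sums to one.
#' @export
movement_kernel <- function(from_cell, habitat, params, region = NULL) {
  stopifnot(from_cell >= 1, from_cell <= nrow(habitat$cells))
  if (is.null(region)) region_v <- NULL
  else region_v <- region
  idx <- .region_cells(habitat, region_v)
  dx <- habitat$cells$x[idx] - habitat$cells$x[from_cell]
  dy <- habitat$cells$y[idx] - habitat$cells$y[from_cell]
  lw <- -(dx^2 + dy^2) / (2 * params$tau^2) +
    params$b_dens * habitat$cells$X[idx]
  lw <- lw - max(lw)
  p <- numeric(nrow(habitat$cells))
  p[idx] <- exp(lw) / sum(exp(lw))
  p
}

#' Sample an activity-centre path
#'
#' Season 1 is drawn from [initial_ac_distribution()], later seasons from
#' [movement_kernel()] of the previous cell.  Reproducible under
#' `set.seed()`.
#'
#' @inheritParams initial_ac_distribution
#' @param horizon number of seasons `T >= 1`.
#' @return integer vector of 1-based habitat cell indices, length `horizon`.
#' @export
sample_ac_path <- function(habitat, params, horizon, region = NULL) {
  stopifnot(horizon >= 1)
  path <- integer(horizon)
  path[1] <- sample.int(nrow(habitat$cells), 1,
                        prob = initial_ac_distribution(habitat, params, region))
  if (horizon >= 2) for (t in 2:horizon) {
    path[t] <- sample.int(nrow(habitat$cells), 1,
                          prob = movement_kernel(path[t - 1], habitat, params,
                                                 region))
  }
  path
}
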