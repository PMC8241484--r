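#' Assemble an analysis-ready study from data tables
#'
#' Combines the spatial grids with detection records, collar histories and
#' dead recoveries into the object [run_mcmc()] consumes: the dense
#' subdetector-count array, the collar and previous-detection covariate
#' matrices, allowed-state masks from the hard evidence, and the
#' data-augmentation layout (observed individuals first, then augmented
#' pseudo-individuals per stratum, all with collar covariate zero).
#'
#' @param habitat a `habitat_grid`.
#' @param detectors a `detector_grid`.
#' @param detections data.frame of detection records (`individual_id`,
#'   `season`, `x`, `y`).
#' @param horizon number of monitoring seasons `T`.
#' @param M total augmented size per stratum (scalar for a single stratum, or
#'   an integer vector of length `G`); defaults to three times the number of
#'   observed individuals.
#' @param collars optional data.frame (`individual_id`, `season`, `gps`).
#' @param recoveries optional data.frame (`individual_id`, `season`, `cause`,
#'   `x`, `y`).
#' @param group optional named integer vector mapping observed
#'   `individual_id` to stratum (sex x region); default one stratum.
#' @param region_of_group integer vector, habitat region of each stratum.
#' @return an object of class `opscr_study`.
#' @export
build_study <- function(habitat, detectors, detections, horizon, M = NULL,
                        collars = NULL, recoveries = NULL, group = NULL,
                        region_of_group = NULL) {
  ytab <- assign_detections(detections, detectors)
  ids <- sort(unique(c(
    as.character(ytab$individual_id),
    if (!is.null(collars)) as.character(collars$individual_id[collars$gps == 1]),
    if (!is.null(recoveries)) as.character(recoveries$individual_id))))
  if (is.null(group)) group <- setNames(rep(1L, length(ids)), ids)
  if (!all(ids %in% names(group)))
    stop("observed individuals missing from `group`: ",
         paste(setdiff(ids, names(group)), collapse = ", "))
  G <- max(group)
  if (is.null(M)) M <- 3L * length(ids)
  if (length(M) == 1 && G > 1) stop("give one augmented size M per stratum")
  M <- rep(as.integer(M), length.out = G)
  if (is.null(region_of_group)) region_of_group <- rep(1L, G)
  .assemble_study(habitat, detectors, horizon, ids, group[ids], M,
                  region_of_group, ytab, collars, recoveries,
                  detections_records = detections)
}

# shared assembly used by build_study() and generate_study()
.assemble_study <- function(habitat, detectors, horizon, ids, group_obs, M,
                            region_of_group, ytab, collars, recoveries,
                            detections_records = NULL, truth = NULL) {
  G <- length(M)
  n_obs_g <- tabulate(group_obs, nbins = G)
  if (any(M < n_obs_g))
    stop("augmented size M is smaller than the number of observed ",
         "individuals in a stratum")
  ord <- order(group_obs, ids)
  ids <- ids[ord]; group_obs <- group_obs[ord]
  all_ids <- character(0); all_group <- integer(0)
  for (g in seq_len(G)) {
    obs_g <- ids[group_obs == g]
    aug_g <- if (M[g] > length(obs_g))
      sprintf("aug_g%d_%04d", g, seq_len(M[g] - length(obs_g))) else character(0)
    all_ids <- c(all_ids, obs_g, aug_g)
    all_group <- c(all_group, rep(g, M[g]))
  }
  n <- sum(M)
  J <- nrow(detectors$detectors)
  y <- array(0L, dim = c(n, J, horizon))
  if (nrow(ytab)) {
    ii <- match(as.character(ytab$individual_id), all_ids)
    jj <- match(ytab$detector, detectors$detectors$detector)
    if (anyNA(ii) || anyNA(jj)) stop("detection table references unknown ids")
    y[cbind(ii, jj, ytab$season)] <- ytab$y
  }
  gps <- matrix(0L, n, horizon)
  if (!is.null(collars) && nrow(collars)) {
    act <- collars[collars$gps == 1, , drop = FALSE]
    ii <- match(as.character(act$individual_id), all_ids)
    keep <- !is.na(ii)
    gps[cbind(ii[keep], act$season[keep])] <- 1L
  }
  det_seasons <- NULL
  if (nrow(ytab))
    det_seasons <- unique(data.frame(
      individual_id = as.character(ytab$individual_id), season = ytab$season))
  conmask <- state_constraints_from_recoveries(
    recoveries, horizon, all_ids, detections = det_seasons, collars = collars,
    complete_legal_reporting = TRUE)
  study <- list(habitat = habitat, detectors = detectors, horizon = horizon,
                M = M, n_observed = sum(n_obs_g), ids = all_ids,
                group = all_group, region_of_group = region_of_group,
                y = y, gps = gps, prev = prev_detected(y), conmask = conmask,
                detections = detections_records, collars = collars,
                recoveries = recoveries, truth = truth)
  class(study) <- "opscr_study"
  study
}

#' @export
print.opscr_study <- function(x, ...) {
  cat("OPSCR study:", x$horizon, "seasons,", x$n_observed,
      "observed individuals, augmented to", sum(x$M), "in", length(x$M),
      if (length(x$M) == 1) "stratum\n" else "strata\n")
  cat("  habitat:", nrow(x$habitat$cells), "cells of",
      x$habitat$cell_size, "km,", x$habitat$buffer_width, "km buffer\n")
  cat("  detectors:", nrow(x$detectors$detectors), "cells of",
      x$detectors$detector_size, "km, subdetectors of",
      x$detectors$subdetector_size, "km\n")
  cat("  positive counts:", sum(x$y > 0), "; collared individual-seasons:",
      sum(x$gps), "\n")
  invisible(x)
}
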