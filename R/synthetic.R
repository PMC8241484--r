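#' Configuration for a synthetic OPSCR study
#'
#' Returns the generator settings describing a complete simulated monitoring
#' programme: spatial design (habitat cells, detectors, subdetectors,
#' buffer), study horizon, stratification, generating parameter values, the
#' collaring programme and the dead-recovery reporting regime.  The
#' `"default"` preset emulates the full Scandinavian-style design (eight
#' seasons, two non-adjacent regions, two sexes, sparse collaring); the
#' `"flagship"` preset is the reduced single-stratum design used by the
#' parameter-recovery experiments (five seasons, 100 x 100 km core,
#' M = 300, roughly 20% of alive individual-seasons collared); `"null"` is a
#' smaller design with zero collar effects for calibration experiments;
#' `"tiny"` is a minimal smoke-test design.  The cause-specific mortality
#' medians of non-collared individuals (0.10 legal, 0.25 other) and the
#' logit-scale collar effects (-0.37, -1.08) are the preset generating truth.
#'
#' @param preset one of `"default"`, `"flagship"`, `"null"`, `"tiny"`.
#' @param ... named overrides of any config entry.
#' @return a list of generator settings (class `opscr_config`).
#' @export
study_config <- function(preset = c("default", "flagship", "null", "tiny"),
                         ...) {
  preset <- match.arg(preset)
  base <- list(
    horizon = 8L,
    regions = list(c(0, 200, 0, 200), c(0, 200, 340, 540)),
    cell_size = 20, detector_size = 10, subdetector_size = 2,
    buffer = 60,
    sexes = c("F", "M"),
    M = 300L,                    # per stratum
    psi = 0.5, gamma = 0.3,
    h0 = qlogis(0.10), w0 = qlogis(0.25),
    beta_h_gps = -0.37, beta_w_gps = -1.08,
    tau = 12, b_dens = 0.8, sigma = 9,
    p0 = 0.01, county_offsets = c(0.15, -0.15),
    beta_tracks = 0.3, beta_roads = -0.2, beta_snow = 0.2,
    beta_prev = 0.4, beta_gps_det = -0.3,
    collar = list(fraction = 0.02, duration = 2L, seasons = 1:6),
    report_other_prob = 0.03,
    sigma_max = 10, tau_max = 100)
  tweak <- switch(preset,
    default = list(),
    flagship = list(
      horizon = 5L, regions = list(c(0, 100, 0, 100)), sexes = "M",
      M = 300L, psi = 0.35, gamma = 0.1, buffer = 42, sigma = 6,
      sigma_max = 7, tau = 10, p0 = 0.04,
      collar = list(fraction = 0.45, duration = 2L, seasons = 1:4)),
    null = list(
      horizon = 4L, regions = list(c(0, 80, 0, 80)), sexes = "M",
      M = 150L, psi = 0.35, gamma = 0.12, buffer = 36, sigma = 5,
      sigma_max = 6, tau = 10,
      b_dens = 0.5, p0 = 0.03, beta_h_gps = 0, beta_w_gps = 0,
      beta_gps_det = 0,
      collar = list(fraction = 0.15, duration = 2L, seasons = 1:3)),
    tiny = list(
      horizon = 3L, regions = list(c(0, 40, 0, 40)), sexes = "M",
      M = 30L, buffer = 30, sigma = 5, sigma_max = 5, tau = 10,
      b_dens = 0.5, p0 = 0.05,
      collar = list(fraction = 0.2, duration = 2L, seasons = 1:2)))
  cfg <- base
  for (nm in names(tweak)) cfg[[nm]] <- tweak[[nm]]
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg$preset <- preset
  if (plogis(cfg$h0) + plogis(cfg$w0) >= 1 ||
      plogis(cfg$h0 + cfg$beta_h_gps) + plogis(cfg$w0 + cfg$beta_w_gps) >= 1)
    stop("infeasible generating truth: h + w >= 1 for a collar status")
  class(cfg) <- "opscr_config"
  cfg
}

# per-group value of a config entry that may be scalar or length-G
.pg <- function(x, g) if (length(x) == 1) x else x[g]

# spatial scaffolding shared by the generator and cmd_simulate: merged
# habitat over all regions, merged per-region detector grids, counties split
# east/west within each region, smooth standardized density covariate
.build_spatial <- function(cfg) {
  nreg <- length(cfg$regions)
  buffered <- lapply(cfg$regions, function(e)
    c(e[1] - cfg$buffer, e[2] + cfg$buffer, e[3] - cfg$buffer,
      e[4] + cfg$buffer))
  inside_any <- function(x, y) {
    r <- rep(NA_integer_, length(x))
    for (k in seq_len(nreg)) {
      b <- buffered[[k]]
      hit <- is.na(r) & x >= b[1] & x <= b[2] & y >= b[3] & y <= b[4]
      r[hit] <- k
    }
    r
  }
  # smooth density surface: a few Gaussian bumps per region, standardized
  nb <- 3L
  bumps <- do.call(rbind, lapply(cfg$regions, function(e) {
    data.frame(cx = runif(nb, e[1], e[2]), cy = runif(nb, e[3], e[4]),
               s = runif(nb, 30, 60), a = runif(nb, 0.5, 1.5))
  }))
  field <- function(x, y) {
    v <- numeric(length(x))
    for (b in seq_len(nrow(bumps)))
      v <- v + bumps$a[b] *
        exp(-((x - bumps$cx[b])^2 + (y - bumps$cy[b])^2) / (2 * bumps$s[b]^2))
    v[is.na(inside_any(x, y))] <- NA_real_
    v
  }
  core_bb <- c(min(vapply(cfg$regions, `[`, 0, 1)),
               max(vapply(cfg$regions, `[`, 0, 2)),
               min(vapply(cfg$regions, `[`, 0, 3)),
               max(vapply(cfg$regions, `[`, 0, 4)))
  habitat <- build_habitat_grid(core_bb, cell_size = cfg$cell_size,
                                covariate = field, buffer_width = cfg$buffer,
                                regions = inside_any,
                                sigma_max = cfg$sigma_max)
  habitat$cells$X <- as.numeric(scale(habitat$cells$X))
  dets <- vector("list", nreg)
  for (k in seq_len(nreg)) {
    e <- cfg$regions[[k]]
    mid <- (e[1] + e[2]) / 2
    county_fn <- local({
      k0 <- k; mid0 <- mid
      function(x, y) (k0 - 1L) * 2L + 1L + as.integer(x > mid0)
    })
    dets[[k]] <- build_detector_grid(e, cfg$detector_size,
                                     cfg$subdetector_size, habitat,
                                     county = county_fn)
  }
  detectors <- .merge_detector_grids(dets)
  Tn <- cfg$horizon
  J <- nrow(detectors$detectors)
  covs <- list(
    tracks = matrix(exp(rnorm(J * Tn, log(30), 0.4)), J, Tn),
    roads = matrix(rep(rexp(J, 1 / 5), Tn), J, Tn) +
      matrix(abs(rnorm(J * Tn, 0, 0.5)), J, Tn),
    snow = matrix(rbeta(J * Tn, 2, 2), J, Tn))
  detectors <- set_detector_covariates(detectors, covs)
  list(habitat = habitat, detectors = detectors)
}

.merge_detector_grids <- function(grids) {
  if (length(grids) == 1) return(grids[[1]])
  dd <- do.call(rbind, lapply(grids, `[[`, "detectors"))
  dd$detector <- seq_len(nrow(dd)) - 1L
  out <- grids[[1]]
  out$detectors <- dd
  out$sub_centres <- do.call(c, lapply(grids, `[[`, "sub_centres"))
  out$extent_core <- NULL
  out
}

#' Assign GPS collars over a realized alive matrix
#'
#' Sequentially over the assignment seasons, each alive, never-yet-collared
#' individual receives a collar with probability `fraction`; a collar is worn
#' for `duration_seasons` consecutive seasons and the covariate is 1 in worn
#' seasons while the individual is alive.
#'
#' @param alive logical matrix `n x T`, `TRUE` where the individual is alive.
#' @param fraction per-season collaring probability in `[0, 1]`.
#' @param duration_seasons worn duration in seasons (`>= 1`).
#' @param start_seasons seasons in which collars are put on (default: all).
#' @return integer `n x T` collar covariate matrix.
#' @export
assign_collars <- function(alive, fraction, duration_seasons,
                           start_seasons = NULL) {
  stopifnot(fraction >= 0, fraction <= 1, duration_seasons >= 1)
  n <- nrow(alive); Tn <- ncol(alive)
  if (is.null(start_seasons)) start_seasons <- seq_len(Tn)
  worn <- matrix(FALSE, n, Tn)
  ever <- logical(n)
  for (t in seq_len(Tn)) {
    if (t %in% start_seasons) {
      elig <- which(alive[, t] & !ever)
      sel <- elig[runif(length(elig)) < fraction]
      for (i in sel) worn[i, t:min(Tn, t + duration_seasons - 1)] <- TRUE
      ever[sel] <- TRUE
    }
  }
  matrix(as.integer(worn & alive), n, Tn)
}

#' Generate a complete synthetic OPSCR study
#'
#' Forward-simulates the full data-generating process the model assumes: a
#' density surface and habitat/detector geometry, latent four-state life
#' histories with collar-dependent logit hazards, covariate-weighted
#' Gaussian-random-walk activity-centre paths, half-normal binomial
#' subdetector detections (with search-effort, road, snow,
#' previous-detection and collar effects on the baseline), a rolling
#' collaring programme, complete legal-cull dead recoveries and sparsely
#' reported other-cause recoveries.  The returned study carries a truth
#' manifest for parameter-recovery experiments.
#'
#' @param config a [study_config()].
#' @param seed integer seed; the study is deterministic given
#'   `(config, seed)`.
#' @return an `opscr_study` whose `$truth` holds the generating parameters,
#'   the full latent state and activity-centre matrices, and bookkeeping.
#' @export
generate_study <- function(config = study_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  sp <- .build_spatial(cfg)
  habitat <- sp$habitat; detectors <- sp$detectors
  Tn <- cfg$horizon
  nreg <- length(cfg$regions)
  groups <- expand.grid(sex = cfg$sexes, region = seq_len(nreg),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  G <- nrow(groups)
  Mg <- rep(as.integer(cfg$M), length.out = G)
  dd <- detectors$detectors
  J <- nrow(dd)
  ncell <- nrow(habitat$cells)
  ncounty <- max(dd$county)
  p0int <- qlogis(cfg$p0) +
    rep(cfg$county_offsets, length.out = ncounty)
  detpar <- detection_params(p0int, cfg$sigma, cfg$beta_tracks,
                             cfg$beta_roads, cfg$beta_snow, cfg$beta_prev,
                             cfg$beta_gps_det)
  movepar <- movement_params(cfg$tau, cfg$b_dens)

  n <- sum(Mg)
  group <- rep(seq_len(G), times = Mg)
  z <- matrix(0L, n, Tn); ac <- matrix(0L, n, Tn)
  worn <- matrix(FALSE, n, Tn); gps <- matrix(0L, n, Tn)
  y <- array(0L, dim = c(n, J, Tn))
  ever_collared <- logical(n)
  recov <- list()

  # precomputed per-region movement transition matrices over cells
  kernels <- vector("list", nreg)
  init_p <- vector("list", nreg)
  for (r in seq_len(nreg)) {
    idx <- which(habitat$cells$region == r)
    init_p[[r]] <- initial_ac_distribution(habitat, movepar, r)[idx]
    d2 <- outer(habitat$cells$x[idx], habitat$cells$x[idx], "-")^2 +
      outer(habitat$cells$y[idx], habitat$cells$y[idx], "-")^2
    lw <- -d2 / (2 * cfg$tau^2) +
      matrix(cfg$b_dens * habitat$cells$X[idx], nrow(d2), ncol(d2),
             byrow = TRUE)
    lw <- lw - apply(lw, 1, max)
    kernels[[r]] <- exp(lw) / rowSums(exp(lw))
  }
  cell_of_region <- lapply(seq_len(nreg),
                           function(r) which(habitat$cells$region == r))

  dempar_g <- lapply(seq_len(G), function(g)
    demographic_params(.pg(cfg$psi, g), .pg(cfg$gamma, g), .pg(cfg$h0, g),
                       .pg(cfg$w0, g), cfg$beta_h_gps, cfg$beta_w_gps))
  reg_of_g <- groups$region

  simulate_detections_t <- function(t) {
    cov <- .det_covariates(detectors, t)
    lp0 <- detpar$p0_intercept[dd$county] + detpar$beta_tracks * cov$tracks +
      detpar$beta_roads * cov$roads + detpar$beta_snow * cov$snow
    prev_t <- if (t == 1) integer(n) else
      as.integer(rowSums(matrix(y[, , 1:(t - 1)], nrow = n)) > 0)
    for (i in which(z[, t] == 2L)) {
      cx <- habitat$cells$x[ac[i, t]]; cy <- habitat$cells$y[ac[i, t]]
      d2 <- (dd$x - cx)^2 + (dd$y - cy)^2
      p <- plogis(lp0 + detpar$beta_prev * prev_t[i] +
                    detpar$beta_gps * gps[i, t]) *
        exp(-d2 / (2 * cfg$sigma^2))
      y[i, , t] <<- rbinom(J, dd$K, p)
    }
  }
  # a collar fitted during season t is worn over the following
  # `duration` seasons, so the hazard of the (t, t+1] interval is the first
  # one exposed; assignment conditions on being alive at t and never biases
  # the already-survived interval into t
  # capture (hence collaring) happens inside the monitored core area, so
  # only alive individuals whose current AC lies within their region's core
  # extent are eligible
  in_core <- function(i, t) {
    e <- cfg$regions[[reg_of_g[group[i]]]]
    cx <- habitat$cells$x[ac[i, t]]; cy <- habitat$cells$y[ac[i, t]]
    cx >= e[1] & cx <= e[2] & cy >= e[3] & cy <= e[4]
  }
  assign_new_collars_t <- function(t) {
    if (!t %in% cfg$collar$seasons || t + 1L > Tn) return()
    elig <- which(z[, t] == 2L & !ever_collared)
    elig <- elig[vapply(elig, in_core, logical(1), t = t)]
    sel <- elig[runif(length(elig)) < cfg$collar$fraction]
    for (i in sel)
      worn[i, (t + 1L):min(Tn, t + cfg$collar$duration)] <<- TRUE
    ever_collared[sel] <<- TRUE
  }

  # season 1
  for (g in seq_len(G)) {
    rows <- which(group == g)
    z[rows, 1] <- ifelse(runif(length(rows)) < .pg(cfg$psi, g), 2L, 1L)
    r <- reg_of_g[g]
    ac[rows, 1] <- cell_of_region[[r]][
      sample.int(length(cell_of_region[[r]]), length(rows), replace = TRUE,
                 prob = init_p[[r]])]
  }
  assign_new_collars_t(1)
  simulate_detections_t(1)

  for (t in 2:Tn) {
    # the covariate is the deployment schedule (exogenous: capture date plus
    # the release mechanism), not realized wearing, so the same value
    # applies to every state path through season t
    gps_haz <- as.integer(worn[, t])
    for (g in seq_len(G)) {
      rows <- which(group == g)
      dem <- dempar_g[[g]]
      for (i in rows) {
        z[i, t] <- sample.int(
          4L, 1, prob = transition_distribution(z[i, t - 1], dem, t,
                                                gps_haz[i]))
      }
      r <- reg_of_g[g]
      loc <- match(ac[rows, t - 1], cell_of_region[[r]])
      for (kk in seq_along(rows)) {
        ac[rows[kk], t] <- cell_of_region[[r]][
          sample.int(length(cell_of_region[[r]]), 1,
                     prob = kernels[[r]][loc[kk], ])]
      }
    }
    gps[, t] <- as.integer(worn[, t])
    assign_new_collars_t(t)
    simulate_detections_t(t)
    # dead recoveries: legal culls are always reported, other deaths rarely
    for (i in which(z[, t] == 3L)) {
      recov[[length(recov) + 1]] <- data.frame(
        row = i, season = t, cause = "legal",
        x = habitat$cells$x[ac[i, t]] + rnorm(1, 0, 2),
        y = habitat$cells$y[ac[i, t]] + rnorm(1, 0, 2))
    }
    for (i in which(z[, t] == 4L & z[, t - 1] == 2L)) {
      if (runif(1) < cfg$report_other_prob)
        recov[[length(recov) + 1]] <- data.frame(
          row = i, season = t, cause = "other",
          x = habitat$cells$x[ac[i, t]] + rnorm(1, 0, 2),
          y = habitat$cells$y[ac[i, t]] + rnorm(1, 0, 2))
    }
  }

  ids <- sprintf("g%d_i%04d", group, unlist(lapply(Mg, seq_len)))
  recoveries <- if (length(recov)) {
    rr <- do.call(rbind, recov)
    data.frame(individual_id = ids[rr$row], season = rr$season,
               cause = rr$cause, x = rr$x, y = rr$y)
  } else NULL
  collars <- {
    idx <- which(gps == 1L, arr.ind = TRUE)
    if (nrow(idx))
      data.frame(individual_id = ids[idx[, 1]], season = idx[, 2], gps = 1L)
    else NULL
  }
  # detection records: one record per occupied subdetector, at its centre
  rec <- list()
  pos <- which(y > 0L, arr.ind = TRUE)
  if (nrow(pos)) for (r in seq_len(nrow(pos))) {
    i <- unname(pos[r, 1]); j <- unname(pos[r, 2]); t <- unname(pos[r, 3])
    sc <- detectors$sub_centres[[j]]
    picks <- sample.int(nrow(sc), y[i, j, t])
    rec[[length(rec) + 1]] <- data.frame(
      individual_id = ids[i], season = t, x = unname(sc[picks, 1]),
      y = unname(sc[picks, 2]), county = dd$county[j])
  }
  detections <- if (length(rec)) do.call(rbind, rec) else
    data.frame(individual_id = character(), season = integer(),
               x = numeric(), y = numeric(), county = integer())
  rownames(detections) <- NULL

  observed <- rowSums(matrix(y, nrow = n)) > 0 | ever_collared |
    ids %in% (recoveries$individual_id %||% character(0))
  obs_ids <- ids[observed]
  group_obs <- setNames(group[observed], obs_ids)

  ytab <- {
    posagg <- which(y > 0L, arr.ind = TRUE)
    if (nrow(posagg))
      data.frame(individual_id = ids[posagg[, 1]],
                 detector = dd$detector[posagg[, 2]],
                 season = posagg[, 3], y = y[posagg])
    else data.frame(individual_id = character(), detector = integer(),
                    season = integer(), y = integer())
  }

  truth <- list(
    config = cfg, seed = seed, groups = groups,
    params = list(psi = cfg$psi, gamma = cfg$gamma, h0 = cfg$h0, w0 = cfg$w0,
                  beta_h_gps = cfg$beta_h_gps, beta_w_gps = cfg$beta_w_gps,
                  tau = cfg$tau, b_dens = cfg$b_dens, sigma = cfg$sigma,
                  p0_intercept = p0int, beta_tracks = cfg$beta_tracks,
                  beta_roads = cfg$beta_roads, beta_snow = cfg$beta_snow,
                  beta_prev = cfg$beta_prev, beta_gps_det = cfg$beta_gps_det),
    z = z, ac = ac, gps = gps, ids = ids, group = group,
    observed = observed,
    n_alive = colSums(z == 2L))

  study <- .assemble_study(habitat, detectors, Tn, obs_ids,
                           group_obs[obs_ids], Mg, reg_of_g, ytab, collars,
                           recoveries, detections_records = detections,
                           truth = truth)
  study
}
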