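#' MCMC settings
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iterations iterations per chain, including burn-in.
#' @param burn burn-in iterations discarded (adaptation happens only here).
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed integer seed; chain `k` uses `seed + k - 1`.
#' @param sd_logit prior standard deviation of all logit-scale intercepts and
#'   slopes (Normal(0, `sd_logit`^2)).
#' @param sigma_max,tau_max upper bounds of the Uniform(0, max) priors on the
#'   detection scale and movement scale, km.
#' @param local_factor local-evaluation radius in multiples of the current
#'   `sigma` (detectors with zero counts beyond it are skipped; positive
#'   counts are always exact).  `Inf` forces full evaluation.
#' @param window log-weight truncation window of the activity-centre update.
#' @param time_varying estimate season-specific `gamma_t`, `h0_t`, `w0_t`
#'   (otherwise shared across seasons).
#' @param adapt_interval proposal-scale adaptation block length (burn-in
#'   only, targeting 20--45% acceptance).
#' @param n_dem_updates inner Metropolis sweeps over the mortality
#'   intercepts and collar effects per iteration.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(chains = 4, iterations = 42500, burn = 12500, thin = 1,
                       seed = 1, sd_logit = 2, sigma_max = 10, tau_max = 100,
                       local_factor = 6, window = 30, time_varying = FALSE,
                       adapt_interval = 50, n_dem_updates = 3) {
  stopifnot(iterations > burn, burn >= 0, thin >= 1, chains >= 1)
  structure(as.list(environment()), class = "fit_config")
}

# flatten the study into the structures the compiled kernels consume
.prepare_fit <- function(study, cfg) {
  hb <- study$habitat; dt <- study$detectors
  cells <- hb$cells; dd <- dt$detectors
  n <- nrow(study$y); J <- dim(study$y)[2]; Tn <- study$horizon
  d2cd <- outer(cells$x, dd$x, "-")^2 + outer(cells$y, dd$y, "-")^2
  d2cc <- outer(cells$x, cells$x, "-")^2 + outer(cells$y, cells$y, "-")^2
  G <- length(study$M)
  regionIds <- sort(unique(cells$region))
  regionCells <- lapply(regionIds, function(r) which(cells$region == r))
  regionPos <- match(study$region_of_group, regionIds)
  indRegion <- regionPos[study$group]
  if (is.null(dt$covariates)) {
    P <- 0L; detcov <- numeric(0); slope_names <- character(0)
  } else {
    P <- dim(dt$covariates)[3]
    detcov <- as.numeric(dt$covariates)
    slope_names <- dimnames(dt$covariates)[[3]]
  }
  anyY <- matrix(vapply(seq_len(Tn),
                        function(t) rowSums(study$y[, , t, drop = FALSE]) > 0,
                        logical(n)), nrow = n)
  pos <- which(study$y > 0L, arr.ind = TRUE)
  posLists <- vector("list", n * Tn)
  if (nrow(pos)) for (r in seq_len(nrow(pos))) {
    k <- pos[r, 1] + n * (pos[r, 3] - 1)
    posLists[[k]] <- c(posLists[[k]], pos[r, 2] - 1L)
  }
  lens <- vapply(posLists, length, integer(1))
  posOff <- as.integer(c(0, cumsum(lens)))
  posDet <- as.integer(unlist(posLists) %||% integer(0))
  list(n = n, J = J, Tn = Tn, G = G, C = max(dd$county), P = P,
       X = cells$X, d2cd = d2cd, d2cc = d2cc,
       regionCells = regionCells, indRegion = as.integer(indRegion),
       group = as.integer(study$group),
       K = as.integer(dd$K), county = as.integer(dd$county),
       detcov = detcov, slope_names = slope_names,
       yflat = as.integer(study$y),
       anyY = matrix(as.integer(anyY), n, Tn),
       conmask = as.integer(study$conmask),
       gps = matrix(as.integer(study$gps), n, Tn),
       prev = matrix(as.integer(study$prev), n, Tn),
       any_gps = any(study$gps == 1L),
       posOff = posOff, posDet = posDet,
       cells = cells, dd = dd)
}

# transition counts of the sampled state matrix, by stratum, season and
# collar status
.dem_counts <- function(z, gps, group, G, Tn) {
  nRec <- nStay <- matrix(0, G, Tn)
  nSurv <- nH <- nW <- array(0, c(G, Tn, 2))
  for (t in 2:Tn) {
    from <- z[, t - 1]; to <- z[, t]; gv <- gps[, t] + 1L
    for (g in seq_len(G)) {
      rows <- group == g
      f1 <- rows & from == 1L
      nRec[g, t] <- sum(f1 & to == 2L)
      nStay[g, t] <- sum(f1 & to == 1L)
      for (v in 1:2) {
        f2 <- rows & from == 2L & gv == v
        nSurv[g, t, v] <- sum(f2 & to == 2L)
        nH[g, t, v] <- sum(f2 & to == 3L)
        nW[g, t, v] <- sum(f2 & to == 4L)
      }
    }
  }
  list(nRec = nRec, nStay = nStay, nSurv = nSurv, nH = nH, nW = nW,
       nAlive1 = tabulate(group[z[, 1] == 2L], G),
       nUnborn1 = tabulate(group[z[, 1] == 1L], G))
}

# mortality-count log-likelihood; -Inf when any realized hazard pair is
# infeasible (h + w >= 1)
.dem_ll <- function(cts, h0m, w0m, bh, bw, any_gps) {
  ll <- 0
  for (v in 1:2) {
    if (v == 2 && !any_gps) next
    h <- plogis(h0m + bh * (v - 1))
    w <- plogis(w0m + bw * (v - 1))
    phi <- 1 - h - w
    if (any(phi <= 0)) return(-Inf)
    ll <- ll + sum(cts$nSurv[, , v] * log(phi)) +
      sum(cts$nH[, , v] * log(h)) + sum(cts$nW[, , v] * log(w))
  }
  ll
}

# initial activity centres: observed individuals at the habitat cell nearest
# their mean detection location, everyone else uniform over their region
.init_ac <- function(study, prep) {
  n <- prep$n; Tn <- prep$Tn
  ac <- matrix(0L, n, Tn)
  for (i in seq_len(n)) {
    cells_r <- prep$regionCells[[prep$indRegion[i]]]
    tot <- rowSums(matrix(study$y[i, , ], nrow = prep$J))
    if (sum(tot) > 0) {
      mx <- sum(prep$dd$x * tot) / sum(tot)
      my <- sum(prep$dd$y * tot) / sum(tot)
      c0 <- cells_r[which.min((prep$cells$x[cells_r] - mx)^2 +
                                (prep$cells$y[cells_r] - my)^2)]
    } else {
      c0 <- cells_r[sample.int(length(cells_r), 1)]
    }
    ac[i, ] <- c0
  }
  ac
}

#' Fit the OPSCR model by MCMC
#'
#' Metropolis-within-Gibbs sampler: latent states are drawn exactly by
#' forward-filtering backward-sampling of the four-state chain given the
#' evidence masks; inclusion and recruitment probabilities have conjugate
#' Beta updates; mortality intercepts, collar effects, detection and
#' movement parameters use adaptive random-walk Metropolis; activity centres
#' are re-drawn cell-by-cell from their categorical full conditionals with
#' local likelihood evaluation.  Chains run sequentially with seeds
#' `seed + 0:(chains-1)` and are bit-reproducible.
#'
#' @param study an `opscr_study` (from [generate_study()] or
#'   [build_study()]).
#' @param config a [fit_config()].
#' @param verbose print one line per chain.
#' @return an object of class `opscr_fit`: `draws` (list of kept-iteration
#'   matrices, one per chain), `rhat` (split-chain potential scale reduction
#'   per top-level parameter), `acceptance` rates, the configuration echo,
#'   and study metadata.
#' @export
run_mcmc <- function(study, config = fit_config(), verbose = FALSE) {
  stopifnot(inherits(study, "opscr_study"))
  cfg <- config
  prep <- .prepare_fit(study, cfg)
  draws <- vector("list", cfg$chains)
  acc <- NULL
  for (ch in seq_len(cfg$chains)) {
    set.seed(cfg$seed + ch - 1L)
    t0 <- proc.time()[3]
    res <- .run_chain(study, prep, cfg)
    draws[[ch]] <- res$draws
    acc <- res$acceptance
    if (verbose)
      message(sprintf("chain %d: %d iterations in %.1f s", ch,
                      cfg$iterations, proc.time()[3] - t0))
  }
  top <- setdiff(colnames(draws[[1]]), "Nsuper")
  rhat <- if (cfg$chains >= 2)
    gelman_rubin(lapply(draws, function(d) d[, top, drop = FALSE]))
  else NULL
  Nsuper <- unlist(lapply(draws, function(d) d[, "Nsuper"]))
  if (mean(Nsuper >= sum(study$M)) > 0.01)
    warning("more than 1% of posterior draws saturate the augmentation ",
            "limit M = ", sum(study$M), "; increase M and refit")
  fit <- list(draws = draws, rhat = rhat, acceptance = acc, config = cfg,
              M = study$M, groups = seq_along(study$M),
              n_observed = study$n_observed, horizon = study$horizon,
              param_names = colnames(draws[[1]]))
  class(fit) <- "opscr_fit"
  fit
}

.run_chain <- function(study, prep, cfg) {
  n <- prep$n; Tn <- prep$Tn; G <- prep$G; C <- prep$C; P <- prep$P
  tcols <- if (cfg$time_varying) 2:Tn else NULL

  # parameter state (modest overdispersed jitter per chain)
  jit <- function(s) rnorm(1, 0, s)
  psi <- pmin(0.9, pmax(0.1, rep(0.4, G) + rnorm(G, 0, 0.05)))
  gammam <- matrix(pmin(0.9, pmax(0.05, 0.25 + jit(0.05))), G, Tn)
  h0m <- matrix(qlogis(0.12) + rnorm(G, 0, 0.2), G, Tn)
  w0m <- matrix(qlogis(0.20) + rnorm(G, 0, 0.2), G, Tn)
  bh <- if (prep$any_gps) jit(0.2) else 0
  bw <- if (prep$any_gps) jit(0.2) else 0
  tau <- min(cfg$tau_max * 0.9, 15 * exp(jit(0.1)))
  bdens <- jit(0.2)
  sigma <- cfg$sigma_max * runif(1, 0.5, 0.7)
  p0int <- rep(qlogis(0.02), C) + rnorm(C, 0, 0.2)
  slopes <- rep(0, P) + rnorm(P, 0, 0.05)
  bprev <- jit(0.1)
  bgps_det <- if (prep$any_gps) jit(0.1) else 0
  ac <- .init_ac(study, prep)

  upd_names <- c(paste0("h0_g", seq_len(G)), paste0("w0_g", seq_len(G)),
                 "beta_h_gps", "beta_w_gps", "tau", "b_dens", "sigma",
                 paste0("p0_c", seq_len(C)),
                 if (P) paste0("beta_", prep$slope_names),
                 "beta_prev", "beta_gps_det")
  scales <- setNames(rep(0.2, length(upd_names)), upd_names)
  scales["tau"] <- 1; scales["sigma"] <- 0.4
  nacc <- ntry <- setNames(numeric(length(upd_names)), upd_names)

  par_names <- c(paste0("psi_g", seq_len(G)),
                 if (cfg$time_varying)
                   c(t(outer(seq_len(G), 2:Tn,
                             function(g, t) sprintf("gamma_g%d_t%d", g, t))),
                     t(outer(seq_len(G), 2:Tn,
                             function(g, t) sprintf("h0_g%d_t%d", g, t))),
                     t(outer(seq_len(G), 2:Tn,
                             function(g, t) sprintf("w0_g%d_t%d", g, t))))
                 else c(paste0("gamma_g", seq_len(G)),
                        paste0("h0_g", seq_len(G)),
                        paste0("w0_g", seq_len(G))),
                 "beta_h_gps", "beta_w_gps", "tau", "b_dens", "sigma",
                 paste0("p0_c", seq_len(C)),
                 if (P) paste0("beta_", prep$slope_names),
                 "beta_prev", "beta_gps_det", "Nsuper")
  kept <- floor((cfg$iterations - cfg$burn) / cfg$thin)
  out <- matrix(NA_real_, kept, length(par_names),
                dimnames = list(NULL, par_names))
  krow <- 0L

  lprior <- function(x) -x^2 / (2 * cfg$sd_logit^2)
  obs_ll <- function(ac_, alive_, sig_, p0_, sl_, bp_, bg_) {
    obs_ll_cpp(ac_, alive_, prep$d2cd, prep$yflat, prep$K, prep$county, p0_,
               prep$detcov, sl_, bp_, bg_, prep$gps, prep$prev, sig_,
               (cfg$local_factor * sig_)^2)
  }

  for (it in seq_len(cfg$iterations)) {
    adapting <- it <= cfg$burn
    localR2 <- (cfg$local_factor * sigma)^2

    E2 <- emission_alive_cpp(ac, prep$d2cd, prep$yflat, prep$K, prep$county,
                             p0int, prep$detcov, slopes, bprev, bgps_det,
                             prep$gps, prep$prev, sigma, localR2)
    z <- ffbs_cpp(E2, prep$anyY, prep$conmask, prep$gps, prep$group, psi,
                  gammam, h0m, w0m, bh, bw)
    cts <- .dem_counts(z, prep$gps, prep$group, G, Tn)

    psi <- rbeta(G, 1 + cts$nAlive1, 1 + cts$nUnborn1)
    if (cfg$time_varying) {
      for (t in 2:Tn)
        gammam[, t] <- rbeta(G, 1 + cts$nRec[, t], 1 + cts$nStay[, t])
    } else {
      gammam[] <- rep(rbeta(G, 1 + rowSums(cts$nRec), 1 + rowSums(cts$nStay)),
                      Tn)
    }

    dll <- .dem_ll(cts, h0m, w0m, bh, bw, prep$any_gps)
    for (rep_i in seq_len(cfg$n_dem_updates)) {
      for (g in seq_len(G)) {
        for (which_p in c("h0", "w0")) {
          nm <- paste0(which_p, "_g", g)
          m <- if (which_p == "h0") h0m else w0m
          cur <- m[g, Tn]
          prop <- m[g, ] + if (cfg$time_varying)
            c(0, rnorm(Tn - 1, 0, scales[nm])) else rnorm(1, 0, scales[nm])
          m2 <- m; m2[g, ] <- prop
          ll2 <- if (which_p == "h0")
            .dem_ll(cts, m2, w0m, bh, bw, prep$any_gps)
          else .dem_ll(cts, h0m, m2, bh, bw, prep$any_gps)
          dpr <- sum(lprior(prop[tcols %||% Tn])) -
            sum(lprior(m[g, tcols %||% Tn]))
          ntry[nm] <- ntry[nm] + 1
          if (is.finite(ll2) && log(runif(1)) < ll2 - dll + dpr) {
            if (which_p == "h0") h0m <- m2 else w0m <- m2
            dll <- ll2
            nacc[nm] <- nacc[nm] + 1
          }
        }
      }
      if (prep$any_gps) for (nm in c("beta_h_gps", "beta_w_gps")) {
        cur <- if (nm == "beta_h_gps") bh else bw
        prop <- cur + rnorm(1, 0, scales[nm])
        ll2 <- if (nm == "beta_h_gps")
          .dem_ll(cts, h0m, w0m, prop, bw, prep$any_gps)
        else .dem_ll(cts, h0m, w0m, bh, prop, prep$any_gps)
        ntry[nm] <- ntry[nm] + 1
        if (is.finite(ll2) &&
            log(runif(1)) < ll2 - dll + lprior(prop) - lprior(cur)) {
          if (nm == "beta_h_gps") bh <- prop else bw <- prop
          dll <- ll2
          nacc[nm] <- nacc[nm] + 1
        }
      }
    }

    norms <- move_norms_cpp(tau, bdens, prep$X, prep$d2cc, prep$regionCells)
    ac <- ac_gibbs_cpp(ac, z, prep$d2cc, prep$X, prep$indRegion,
                       prep$regionCells, norms$lognorm, norms$loginit, tau,
                       bdens, prep$d2cd, prep$yflat, prep$K, prep$county,
                       p0int, prep$detcov, slopes, bprev, bgps_det, prep$gps,
                       prep$prev, sigma, localR2, prep$posOff, prep$posDet,
                       cfg$window)

    alive <- matrix(as.integer(z == 2L), n, Tn)
    oll <- obs_ll(ac, alive, sigma, p0int, slopes, bprev, bgps_det)
    mh_det <- function(nm, cur, set_fn, lo = -Inf, hi = Inf,
                       prior = TRUE) {
      prop <- cur + rnorm(1, 0, scales[nm])
      ntry[nm] <<- ntry[nm] + 1
      if (prop <= lo || prop >= hi) return(invisible(NULL))
      st <- set_fn(prop)
      oll2 <- obs_ll(ac, alive, st$sigma, st$p0int, st$slopes, st$bprev,
                     st$bgps)
      dpr <- if (prior) lprior(prop) - lprior(cur) else 0
      if (is.finite(oll2) && log(runif(1)) < oll2 - oll + dpr) {
        sigma <<- st$sigma; p0int <<- st$p0int; slopes <<- st$slopes
        bprev <<- st$bprev; bgps_det <<- st$bgps
        oll <<- oll2
        nacc[nm] <<- nacc[nm] + 1
      }
      invisible(NULL)
    }
    cur_st <- function() list(sigma = sigma, p0int = p0int, slopes = slopes,
                              bprev = bprev, bgps = bgps_det)
    mh_det("sigma", sigma,
           function(v) { s <- cur_st(); s$sigma <- v; s },
           lo = 1e-3, hi = cfg$sigma_max, prior = FALSE)
    for (cc in seq_len(C))
      mh_det(paste0("p0_c", cc), p0int[cc],
             local({ c0 <- cc
               function(v) { s <- cur_st(); s$p0int[c0] <- v; s } }))
    if (P) for (pp in seq_len(P))
      mh_det(paste0("beta_", prep$slope_names[pp]), slopes[pp],
             local({ p0 <- pp
               function(v) { s <- cur_st(); s$slopes[p0] <- v; s } }))
    mh_det("beta_prev", bprev,
           function(v) { s <- cur_st(); s$bprev <- v; s })
    if (prep$any_gps)
      mh_det("beta_gps_det", bgps_det,
             function(v) { s <- cur_st(); s$bgps <- v; s })

    # movement parameters: never-recruited pseudo-individuals' paths are
    # marginalized out of the update (they integrate to one) and refreshed
    # from the new prior afterwards
    ever_alive <- which(rowSums(z == 2L) > 0)
    mll <- movement_ll_cpp(ac, ever_alive, tau, bdens, prep$X, prep$d2cc,
                           norms$lognorm, norms$loginit)
    for (rep_m in 1:3) {
      prop <- tau + rnorm(1, 0, scales["tau"])
      ntry["tau"] <- ntry["tau"] + 1
      if (prop > 1e-3 && prop < cfg$tau_max) {
        n2 <- move_norms_cpp(prop, bdens, prep$X, prep$d2cc,
                             prep$regionCells)
        mll2 <- movement_ll_cpp(ac, ever_alive, prop, bdens, prep$X,
                                prep$d2cc, n2$lognorm, n2$loginit)
        if (log(runif(1)) < mll2 - mll) {
          tau <- prop; norms <- n2; mll <- mll2
          nacc["tau"] <- nacc["tau"] + 1
        }
      }
      prop <- bdens + rnorm(1, 0, scales["b_dens"])
      ntry["b_dens"] <- ntry["b_dens"] + 1
      n2 <- move_norms_cpp(tau, prop, prep$X, prep$d2cc, prep$regionCells)
      mll2 <- movement_ll_cpp(ac, ever_alive, tau, prop, prep$X, prep$d2cc,
                              n2$lognorm, n2$loginit)
      if (log(runif(1)) < mll2 - mll + lprior(prop) - lprior(bdens)) {
        bdens <- prop; norms <- n2; mll <- mll2
        nacc["b_dens"] <- nacc["b_dens"] + 1
      }
    }
    phantom <- setdiff(seq_len(n), ever_alive)
    if (length(phantom))
      ac <- ac_prior_redraw_cpp(ac, phantom, prep$indRegion,
                                prep$regionCells, tau, bdens, prep$X,
                                prep$d2cc)

    if (adapting && it %% cfg$adapt_interval == 0) {
      rate <- ifelse(ntry > 0, nacc / ntry, 0.3)
      scales <- scales * exp(pmax(-0.5, pmin(0.5, rate - 0.3)))
      nacc[] <- 0; ntry[] <- 0
    }

    if (it > cfg$burn && (it - cfg$burn) %% cfg$thin == 0) {
      krow <- krow + 1L
      vals <- c(psi,
                if (cfg$time_varying)
                  c(t(gammam[, 2:Tn, drop = FALSE]),
                    t(h0m[, 2:Tn, drop = FALSE]),
                    t(w0m[, 2:Tn, drop = FALSE]))
                else c(gammam[, Tn], h0m[, Tn], w0m[, Tn]),
                bh, bw, tau, bdens, sigma, p0int, slopes, bprev, bgps_det,
                sum(rowSums(z == 2L) > 0))
      out[krow, ] <- vals
    }
  }
  list(draws = out[seq_len(krow), , drop = FALSE],
       acceptance = ifelse(ntry > 0, nacc / ntry, NA_real_))
}
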