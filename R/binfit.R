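# Censored log-normal maximum-likelihood fit per variant.
#
# A variant's single-cell fluorescence is modeled as log-normal. Sorting
# into J contiguous gates censors the observation to bin membership, so
# the model's bin probabilities are differences of the normal CDF on
# natural-log fluorescence at the bin boundaries, with the outer gates
# open (CDF 0 below the first, 1 above the last). The fit maximizes
#   logL(mu, sigma | p) = sum_j p_j log( F(B_j) - F(B_{j-1}) )
# over the occupancy probabilities p_j, by Nelder-Mead. Goodness of fit
# is the Kullback-Leibler divergence between p and the model's bin
# probabilities. Internally everything runs on the natural-log scale;
# boundaries supplied in log10 are converted once (x ln 10), so the mean
# fluorescence closed form exp(mu + sigma^2/2) holds directly.

#' Fit configuration
#'
#' @param detection_floor_log10,detection_ceiling_log10 Detection limits of
#'   the sorter in log10 arbitrary units; fitted mean activities outside
#'   `[10^floor, 10^ceiling]` are flagged `out_of_range`. Defaults 1.5 and
#'   5 match a typical cytometer range for a minimal-glucose run; rich-media
#'   runs may use a higher ceiling.
#' @param sigma_min Lower bound for the fitted log-scale spread, default
#'   1e-3. Prevents degenerate zero-variance optima when nearly all
#'   occupancy sits in one bin.
#' @param optimizer_tolerance Target parameter-scale accuracy of the
#'   optimizer, default 1e-4.
#' @param max_kl Kullback-Leibler cutoff above which a fit is flagged
#'   `poor_fit`, default 1.
#' @param min_cells Minimum estimated total sorted cells for a variant to
#'   be usable, default 1.
#' @return A list of class `pptp_fit_config`.
#' @export
fit_config <- function(detection_floor_log10 = 1.5,
                       detection_ceiling_log10 = 5,
                       sigma_min = 1e-3,
                       optimizer_tolerance = 1e-4,
                       max_kl = 1,
                       min_cells = 1) {
  if (detection_floor_log10 >= detection_ceiling_log10)
    stop("detection floor must be below the ceiling")
  if (sigma_min <= 0) stop("sigma_min must be positive")
  structure(list(detection_floor_log10 = detection_floor_log10,
                 detection_ceiling_log10 = detection_ceiling_log10,
                 sigma_min = sigma_min,
                 optimizer_tolerance = optimizer_tolerance,
                 max_kl = max_kl,
                 min_cells = min_cells),
            class = "pptp_fit_config")
}

#' Natural-log bin boundaries
#'
#' Converts the design's log10 boundaries to the natural-log breakpoint
#' vector `B_0..B_J` used by the likelihood, forcing the outer gates open
#' (`B_0 = -Inf`, `B_J = Inf`) regardless of any finite value recorded in
#' the table.
#'
#' @param bins A `pptp_bins` design.
#' @return Numeric vector of length `nrow(bins) + 1`.
#' @export
ln_breaks <- function(bins) {
  br <- c(bins$lower_log10, bins$upper_log10[nrow(bins)]) * log(10)
  br[1] <- -Inf
  br[length(br)] <- Inf
  br
}

# Model bin probabilities, conditioned on the included bins. When a bin is
# dropped from the design the likelihood stays proper by renormalizing the
# remaining mass. Floored away from zero so log never overflows.
model_bin_probs <- function(mu, sigma, breaks, included) {
  cdf <- stats::pnorm(breaks, mean = mu, sd = sigma)
  q <- diff(cdf)[included]
  s <- sum(q)
  if (s <= 0) return(rep(1e-300, length(q)))
  pmax(q / s, 1e-300)
}

binned_loglik <- function(mu, sigma, p_incl, breaks, included) {
  q <- model_bin_probs(mu, sigma, breaks, included)
  sum(p_incl * log(q))
}

#' Mean activity of a fitted log-normal
#'
#' The mean of a log-normal with natural-log location `mu` and spread
#' `sigma` is `exp(mu + sigma^2 / 2)`, in the fluorescence units of the
#' bin boundaries.
#'
#' @param mu,sigma Fitted parameters on the natural-log scale.
#' @return Mean fluorescence (arbitrary units).
#' @export
mean_activity <- function(mu, sigma) {
  if (any(sigma < 0, na.rm = TRUE)) stop("sigma must be nonnegative")
  exp(mu + sigma^2 / 2)
}

#' Kullback-Leibler divergence of occupancy from a fitted model
#'
#' `K = sum_j p_j log p_j - logL(mu, sigma | p)`, with the convention
#' `0 log 0 = 0`. Zero iff the occupancy equals the model's bin
#' probabilities; for a point mass on bin `j` it reduces to `-log q_j`
#' where `q_j` is the model's probability of that bin.
#'
#' @param occ A `pptp_occupancy` (or a bare probability vector over all
#'   bins).
#' @param mu,sigma Model parameters on the natural-log scale.
#' @param bins The `pptp_bins` design.
#' @return Nonnegative divergence (nats).
#' @export
kl_divergence <- function(occ, mu, sigma, bins) {
  if (inherits(occ, "pptp_occupancy")) {
    included <- occ$included
    p <- occ$probability[included]
  } else {
    included <- rep(TRUE, nrow(bins))
    p <- occ
  }
  breaks <- ln_breaks(bins)
  entropy <- sum(ifelse(p > 0, p * log(p), 0))
  entropy - binned_loglik(mu, sigma, p, breaks, included)
}

#' Maximum-likelihood log-normal fit to bin occupancy
#'
#' Maximizes the censored log-likelihood by Nelder-Mead, initialized by
#' the method of moments on bin midpoints (open outer bins get a
#' pseudo-midpoint one bin-width beyond the adjacent interior boundary).
#' sigma is optimized through a log parameterization floored at
#' `sigma_min`. The optimizer is restarted once from its own optimum; on
#' non-convergence a perturbed restart is tried and a persistent failure
#' is flagged `poor_fit` rather than raised. Occupancy concentrated in a
#' single bin cannot identify two parameters and is flagged `single_bin`
#' with `NA` parameters.
#'
#' @param occ A `pptp_occupancy` from [occupancy()].
#' @param bins The `pptp_bins` design.
#' @param config A [fit_config()].
#' @return A list of class `pptp_fit` with `mu`, `sigma`,
#'   `log_likelihood`, `kl`, `mean_activity`, `total_cells`, `qc_flags`
#'   (character vector) and `usable` (set by [apply_qc()]).
#' @export
fit_lognormal <- function(occ, bins, config = fit_config()) {
  breaks <- ln_breaks(bins)
  included <- occ$included
  flags <- character(0)
  result <- function(mu, sigma, ll, kl, flags) {
    fit <- structure(list(
      mu = mu, sigma = sigma, log_likelihood = ll, kl = kl,
      mean_activity = if (is.na(mu)) NA_real_ else mean_activity(mu, sigma),
      total_cells = occ$total_cells,
      qc_flags = flags, usable = NA
    ), class = "pptp_fit")
    apply_qc(fit, config)
  }
  if (occ$degenerate)
    return(result(NA_real_, NA_real_, NA_real_, NA_real_,
                  "degenerate_occupancy"))
  p <- occ$probability[included]
  if (sum(p > 0) < 2)
    return(result(NA_real_, NA_real_, NA_real_, NA_real_, "single_bin"))

  mid <- bin_pseudomidpoints(breaks)[included]
  mu0 <- sum(p * mid)
  sig0 <- sqrt(sum(p * (mid - mu0)^2))
  sig0 <- max(sig0, 10 * config$sigma_min)
  smin <- config$sigma_min
  nll <- function(par) {
    -binned_loglik(par[1], smin + exp(par[2]), p, breaks, included)
  }
  ctrl <- list(reltol = 1e-12, maxit = 3000)
  start <- c(mu0, log(max(sig0 - smin, smin)))
  opt <- stats::optim(start, nll, method = "Nelder-Mead", control = ctrl)
  # polish: Nelder-Mead benefits from a restart at its own optimum
  opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead", control = ctrl)
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$convergence != 0) {
    jit <- opt$par + c(0.1, 0.1)
    opt3 <- stats::optim(jit, nll, method = "Nelder-Mead", control = ctrl)
    if (opt3$value < opt$value) opt <- opt3
    if (opt3$convergence != 0) flags <- c(flags, "poor_fit")
  }
  mu_hat <- opt$par[1]
  sigma_hat <- smin + exp(opt$par[2])
  ll <- -opt$value
  # Occupancy supported on exactly two adjacent bins lies on a likelihood
  # ridge: along mu = B - sigma * qnorm(p1) (B the shared boundary) the
  # likelihood rises monotonically as sigma shrinks, flattening below
  # machine precision, so the simplex stalls at an arbitrary ridge point.
  # The floored maximum is exact and analytic: sigma = sigma_min, mu at
  # the ridge. Return it whenever it attains the simplex's likelihood.
  supp <- which(p > 0)
  occ_bins <- which(included)[supp]
  if (length(supp) == 2 && diff(occ_bins) == 1) {
    b_shared <- breaks[occ_bins[2]]
    mu_star <- b_shared - smin * stats::qnorm(p[supp[1]])
    ll_star <- binned_loglik(mu_star, smin, p, breaks, included)
    if (is.finite(ll_star) && ll_star >= ll - 1e-9) {
      mu_hat <- mu_star
      sigma_hat <- smin
      ll <- ll_star
    }
  }
  entropy <- sum(ifelse(p > 0, p * log(p), 0))
  kl <- entropy - ll
  result(mu_hat, sigma_hat, ll, kl, flags)
}

# Interior bins use their midpoint; the open first/last bin is assigned a
# pseudo-midpoint one interior-bin-width beyond its finite boundary.
bin_pseudomidpoints <- function(breaks) {
  jj <- length(breaks) - 1
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- if (jj >= 3) breaks[3] - breaks[2] else 1
  if (!is.finite(mid[1])) mid[1] <- breaks[2] - w
  if (!is.finite(mid[jj])) mid[jj] <- breaks[jj] + w
  mid
}

#' Apply quality-control filters to a fit
#'
#' A variant's fitted parameters are declared not-available when any of
#' the following holds: mean activity outside the detection limits
#' (`out_of_range`); estimated total sorted cells below `min_cells`
#' (`low_cells`); Kullback-Leibler divergence above `max_kl`
#' (`poor_fit`); all occupancy in one gate (`single_bin`); or occupancy
#' degenerate after noise adjustment (`degenerate_occupancy`). `usable`
#' is true iff no flag is set.
#'
#' @param fit A `pptp_fit`.
#' @param config A [fit_config()].
#' @return The fit with `qc_flags` and `usable` updated.
#' @export
apply_qc <- function(fit, config = fit_config()) {
  flags <- fit$qc_flags
  lo <- 10^config$detection_floor_log10
  hi <- 10^config$detection_ceiling_log10
  if (!is.na(fit$mean_activity) &&
      (fit$mean_activity < lo || fit$mean_activity > hi))
    flags <- union(flags, "out_of_range")
  if (!is.na(fit$total_cells) && fit$total_cells < config$min_cells)
    flags <- union(flags, "low_cells")
  if (!is.na(fit$kl) && fit$kl > config$max_kl)
    flags <- union(flags, "poor_fit")
  fit$qc_flags <- flags
  fit$usable <- length(flags) == 0
  fit
}

#' Fit every variant in a count table
#'
#' Runs calibration ([estimate_cells()], [occupancy()]) and the
#' log-normal fit for each (sgRNA, promoter, replicate) variant of a
#' dense count table.
#'
#' @param counts A `pptp_counts` table.
#' @param bins The `pptp_bins` design (per-replicate designs may be given
#'   as a named list keyed by `replicate_id`).
#' @param calib A [calibration_config()].
#' @param config A [fit_config()].
#' @return A data.frame with one row per variant: identifiers, `mu`,
#'   `sigma`, `mean_activity`, `log_likelihood`, `kl`, `total_cells`,
#'   `qc_flags` (semicolon-joined) and `usable`.
#' @export
fit_variants <- function(counts, bins, calib = calibration_config(),
                         config = fit_config()) {
  key <- paste(counts$sgrna_id, counts$promoter_id, counts$replicate_id,
               sep = "\r")
  groups <- split(seq_len(nrow(counts)), key)
  rows <- lapply(groups, function(idx) {
    sub <- counts[idx, , drop = FALSE]
    sub <- sub[order(sub$bin), , drop = FALSE]
    b <- if (is.data.frame(bins)) bins else bins[[sub$replicate_id[1]]]
    cells <- estimate_cells(sub$reads, b, calib)
    total <- sum(cells, na.rm = TRUE)
    fit <- if (total <= 0) {
      # no cells at all: unusable by the minimum-cell filter
      structure(list(mu = NA_real_, sigma = NA_real_,
                     log_likelihood = NA_real_, kl = NA_real_,
                     mean_activity = NA_real_, total_cells = total,
                     qc_flags = "low_cells", usable = FALSE),
                class = "pptp_fit")
    } else {
      occ <- occupancy(cells, b, calib)
      fit_lognormal(occ, b, config)
    }
    data.frame(sgrna_id = sub$sgrna_id[1],
               promoter_id = sub$promoter_id[1],
               replicate_id = sub$replicate_id[1],
               mu = fit$mu, sigma = fit$sigma,
               mean_activity = fit$mean_activity,
               log_likelihood = fit$log_likelihood,
               kl = fit$kl, total_cells = fit$total_cells,
               qc_flags = paste(fit$qc_flags, collapse = ";"),
               usable = fit$usable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$replicate_id, out$promoter_id, out$sgrna_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
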