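# Shared fixtures and the independent grid-search oracle for the
# censored log-normal fit.

# uniform sorting design with open outer gates
make_bins <- function(j = 16, lo = 1.5, hi = 5,
                      cells = 50000, reads = 1e6, included = NULL) {
  edges <- seq(lo, hi, length.out = j + 1)
  if (is.null(included)) included <- rep(TRUE, j)
  validate_bins(data.frame(
    bin_index = seq_len(j),
    lower_log10 = c(-Inf, edges[2:j]),
    upper_log10 = c(edges[2:j], Inf),
    cells_sorted = rep(cells, length.out = j),
    reads_total = rep(reads, length.out = j),
    included = included, stringsAsFactors = FALSE))
}

# exact bin probabilities of a log-normal (natural-log mu, sigma)
analytic_p <- function(mu, sigma, bins) {
  diff(stats::pnorm(ln_breaks(bins), mu, sigma))
}

# a minimal pptp_occupancy wrapper around a probability vector
as_occ <- function(p, included = rep(TRUE, length(p)), total_cells = 100) {
  structure(list(cells = p * total_cells, fraction = p,
                 adjusted_fraction = p, probability = p,
                 total_cells = total_cells, included = included,
                 degenerate = FALSE),
            class = "pptp_occupancy")
}

# --- independent brute-force oracle ------------------------------------
# Evaluates the censored log-normal log-likelihood on an explicit
# (mu, sigma) grid; written from the likelihood definition, sharing no
# code with the package's optimizer path. A coarse pass locates the
# optimum region, then a full 1e-3-step grid resolves it.
oracle_grid_eval <- function(mu_vec, sig_vec, p, breaks) {
  grid <- expand.grid(mu = mu_vec, sigma = sig_vec,
                      KEEP.OUT.ATTRS = FALSE)
  cdf <- vapply(breaks,
                function(b) stats::pnorm((b - grid$mu) / grid$sigma),
                numeric(nrow(grid)))
  q <- cdf[, -1, drop = FALSE] - cdf[, -ncol(cdf), drop = FALSE]
  q <- pmax(q, 1e-300)
  q <- q / rowSums(q)
  ll <- as.vector(log(q) %*% p)
  best <- which.max(ll)
  c(mu = grid$mu[best], sigma = grid$sigma[best], ll = ll[best])
}

grid_oracle <- function(p, bins, step = 1e-3, sigma_floor = 1e-3,
                        sigma_max = 3) {
  breaks <- ln_breaks(bins)
  occ <- which(p > 0)
  blo <- breaks[min(occ)]
  bhi <- breaks[max(occ) + 1]
  if (!is.finite(blo)) blo <- breaks[2] - 1
  if (!is.finite(bhi)) bhi <- breaks[length(breaks) - 1] + 1
  coarse <- oracle_grid_eval(seq(blo - 2, bhi + 2, by = 0.02),
                             seq(sigma_floor, sigma_max, by = 0.02),
                             p, breaks)
  fine <- oracle_grid_eval(
    seq(coarse["mu"] - 0.05, coarse["mu"] + 0.05, by = step),
    seq(max(sigma_floor, coarse["sigma"] - 0.05),
        min(sigma_max, coarse["sigma"] + 0.05), by = step),
    p, breaks)
  # Sigma-descent refinement: when the likelihood keeps rising toward the
  # sigma floor (occupancy confined to two adjacent bins), the optimal mu
  # tracks sigma and needs a mu grid refined in proportion to sigma for
  # the censored likelihood to stay resolvable. Walk sigma down to the
  # floor, re-centering and sharpening the mu grid at each step, then
  # sharpen mu at the floor itself; the final parameter resolution is
  # finer than `step` everywhere.
  s_prev <- 0.2
  best_mu <- coarse["mu"]
  floor_best <- NULL
  while (s_prev > sigma_floor) {
    s <- max(sigma_floor, s_prev / 2)
    row <- oracle_grid_eval(seq(best_mu - 4 * s_prev, best_mu + 4 * s_prev,
                                by = s / 10), s, p, breaks)
    best_mu <- row["mu"]
    floor_best <- row
    s_prev <- s
  }
  for (mustep in c(1e-4, 1e-5, 1e-6, 1e-7, 1e-8, 1e-9)) {
    row <- oracle_grid_eval(seq(best_mu - 20 * mustep, best_mu + 20 * mustep,
                                by = mustep), sigma_floor, p, breaks)
    best_mu <- row["mu"]
    floor_best <- row
  }
  # prefer the floor solution when the ridge makes it at least as likely
  if (!is.null(floor_best) && floor_best["ll"] >= fine["ll"] - 1e-9)
    floor_best else fine
}
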