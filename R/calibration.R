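# Read counts -> sorted-cell estimates -> noise-adjusted bin occupancy.
#
# Sorting is noisy: a constant background of cells lands in bins unrelated
# to their fluorescence. The occupancy step subtracts a per-bin noise floor
# epsilon from the observed cell fractions, renormalizes, and clamps at
# zero to obtain the pre-sort bin probabilities fed to the likelihood fit.

#' Calibration configuration
#'
#' @param epsilon Per-bin noise background subtracted from observed cell
#'   fractions, default 0.05. Must satisfy `0 <= epsilon < 1/J` over the
#'   included bins, otherwise every adjusted fraction can be nonpositive.
#' @param included_bins Integer vector of bin indices used in the
#'   analysis, or `NULL` to honor the `included` flags of the bin
#'   specification.
#' @return A list of class `pptp_calibration_config`.
#' @export
calibration_config <- function(epsilon = 0.05, included_bins = NULL) {
  if (epsilon < 0) stop("epsilon must be nonnegative")
  structure(list(epsilon = epsilon, included_bins = included_bins),
            class = "pptp_calibration_config")
}

# resolve the included-bin mask and enforce the epsilon guard
included_mask <- function(bins, config) {
  incl <- bins$included
  if (!is.null(config$included_bins)) {
    incl <- bins$bin_index %in% config$included_bins
  }
  n_incl <- sum(incl)
  if (n_incl < 2) stop("fewer than 2 included bins")
  if (config$epsilon >= 1 / n_incl)
    stop(sprintf(
      "epsilon = %g must be < 1/%d (the number of included bins)",
      config$epsilon, n_incl))
  incl
}

#' Estimate sorted cells per bin from read counts
#'
#' Read counts are not directly comparable across bins because each bin is
#' regrown, prepped and sequenced separately. Multiplying the reads
#' `r_j` of a variant in bin `j` by `C_j / R_j` (cells collected over
#' reads sequenced in that bin) recovers an estimate of the number of
#' cells of the variant sorted into the bin.
#'
#' @param reads Numeric vector of read counts, one per bin.
#' @param bins The `pptp_bins` design (supplies `cells_sorted` and
#'   `reads_total`).
#' @param config A [calibration_config()].
#' @return Numeric vector of estimated cell counts; excluded bins are
#'   `NA`.
#' @export
estimate_cells <- function(reads, bins, config = calibration_config()) {
  if (length(reads) != nrow(bins))
    stop("reads vector length must equal the number of bins")
  incl <- included_mask(bins, config)
  bad <- incl & reads > 0 & bins$reads_total == 0
  if (any(bad))
    stop("reads observed in bin(s) with zero total sequenced reads: ",
         paste(bins$bin_index[bad], collapse = ", "))
  cells <- rep(NA_real_, length(reads))
  ratio <- ifelse(bins$reads_total[incl] > 0,
                  bins$cells_sorted[incl] / bins$reads_total[incl], 0)
  cells[incl] <- reads[incl] * ratio
  cells
}

#' Noise-adjusted bin occupancy of one variant
#'
#' From estimated cell counts `c_j`, computes over the included bins:
#' the observed fraction `f_j = c_j / sum(c)`; the noise-adjusted fraction
#' `f_adj_j = (f_j - epsilon) / sum_j (f_j - epsilon)`; and the clamped
#' pre-sort probability `p_j = max(0, f_adj_j) / sum_j max(0, f_adj_j)`.
#' With `epsilon = 0` the adjustment is the identity. When every observed
#' fraction is at or below `epsilon` the occupancy is degenerate and the
#' variant is flagged rather than fitted.
#'
#' @param cells Numeric vector of estimated cell counts per bin (excluded
#'   bins `NA`, as produced by [estimate_cells()]).
#' @param bins The `pptp_bins` design.
#' @param config A [calibration_config()].
#' @return A list of class `pptp_occupancy` with full-length vectors
#'   `cells`, `fraction`, `adjusted_fraction`, `probability` (excluded
#'   bins `NA`), plus `total_cells` and the logical `degenerate`.
#' @export
occupancy <- function(cells, bins, config = calibration_config()) {
  incl <- included_mask(bins, config)
  j <- nrow(bins)
  if (length(cells) != j)
    stop("cells vector length must equal the number of bins")
  c_in <- cells[incl]
  if (anyNA(c_in)) stop("cell counts missing in included bins")
  if (any(c_in < 0)) stop("cell counts must be nonnegative")
  total <- sum(c_in)
  if (total <= 0) stop("all-zero cell counts: occupancy undefined")
  f <- c_in / total
  eps <- config$epsilon
  shifted <- f - eps
  denom <- sum(shifted)        # = 1 - n_incl * eps > 0 by the config guard
  f_adj <- shifted / denom
  clamped <- pmax(0, f_adj)
  degenerate <- sum(clamped) <= 0
  p <- if (degenerate) rep(NA_real_, length(f)) else clamped / sum(clamped)
  full <- function(x) { v <- rep(NA_real_, j); v[incl] <- x; v }
  structure(list(
    cells = full(c_in),
    fraction = full(f),
    adjusted_fraction = full(f_adj),
    probability = full(p),
    total_cells = total,
    included = incl,
    degenerate = degenerate
  ), class = "pptp_occupancy")
}
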