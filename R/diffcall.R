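# Differential promoter-activity calls under TF knockdown.
#
# Because per-variant activities are log-normal, comparing a knockdown
# variant's mean activity with the promoter's negative-control activity is
# a comparison of log-normal means. The Z statistic
#
#   Z = [M - M0 + (S^2 - S0^2)/2] /
#       sqrt( S^2/n + S0^2/n0 + (S^4/(n-1) + S0^4/(n0-1))/2 )
#
# tests equality of the two log-normal means (the (S^2 - S0^2)/2 term in
# the numerator carries the variance contribution to the log-normal mean).
# Two-sided p-values come from the standard normal reference, are adjusted
# across the full per-condition test family, and calls additionally
# require a substantial fold change against BOTH the negative-control
# activity and the promoter's median activity across all knockdown
# conditions - the latter guards against the few promoters whose control
# activity is itself atypical.

#' Call thresholds
#'
#' @param min_fold Minimum fold change (against control and median) for a
#'   substantial effect, default 1.7.
#' @param max_q False-discovery-rate cutoff, default 0.01.
#' @param fdr_method `"qvalue"` (Storey, default) or `"bh"`
#'   (Benjamini-Hochberg).
#' @return A list of class `pptp_thresholds`.
#' @export
call_thresholds <- function(min_fold = 1.7, max_q = 0.01,
                            fdr_method = c("qvalue", "bh")) {
  if (min_fold <= 1) stop("min_fold must exceed 1")
  if (max_q <= 0 || max_q >= 1) stop("max_q must lie in (0, 1)")
  structure(list(min_fold = min_fold, max_q = max_q,
                 fdr_method = match.arg(fdr_method)),
            class = "pptp_thresholds")
}

#' Log-normal mean-comparison Z score
#'
#' @param M,S,n Mean, sample standard deviation (n-1 denominator) and
#'   sample count of the knockdown variant's rescaled log activities.
#' @param M0,S0,n0 The same for the promoter's pooled negative controls.
#' @return The Z statistic (vectorized); `NA` where either side has
#'   `n < 2`.
#' @export
z_score <- function(M, S, n, M0, S0, n0) {
  num <- M - M0 + (S^2 - S0^2) / 2
  den <- sqrt(S^2 / n + S0^2 / n0 + (S^4 / (n - 1) + S0^4 / (n0 - 1)) / 2)
  z <- num / den
  z[n < 2 | n0 < 2] <- NA_real_
  z
}

#' False-discovery-rate adjustment
#'
#' `"bh"` is the Benjamini-Hochberg step-up. `"qvalue"` is Storey's
#' procedure: the null proportion pi0 is estimated on the lambda grid
#' 0.05, 0.10, ..., 0.95 via a cubic smoothing spline evaluated at the
#' largest lambda (clamped to (0, 1]), and q-values are pi0 times the
#' step-up adjusted p-values, so rank order is preserved under both
#' methods.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed,
#'   propagated).
#' @param method `"qvalue"` or `"bh"`.
#' @return q-values, same length as `p`.
#' @export
fdr_adjust <- function(p, method = c("qvalue", "bh")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  bh <- stats::p.adjust(p, method = "BH")
  if (method == "bh") return(bh)
  pmin(estimate_pi0(p[!is.na(p)]) * bh, 1)
}

# Storey's smoother estimate of the null proportion
estimate_pi0 <- function(p) {
  m <- length(p)
  if (m < 20) return(1)   # too few tests to estimate pi0; conservative
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
  min(pi0, 1)
}

#' Call differential promoter activity for one condition
#'
#' Pairs every non-excluded perturbation aggregate with its promoter's
#' control aggregate, computes Z, two-sided p, q over the whole family,
#' fold changes against control and against the promoter's median
#' knockdown activity, and assigns `up` / `down` / `ns` / `na`:
#' `up` needs `q <= max_q` and both folds `>= min_fold`; `down` needs
#' `q <= max_q` and both folds `<= 1/min_fold`; a variant whose Z-test
#' prerequisites are missing (excluded aggregate, missing control) is
#' `na`.
#'
#' @param aggregates Output of [aggregate_activity()].
#' @param library_tbl sgRNA annotation (supplies `target_tf`).
#' @param thresholds A [call_thresholds()].
#' @return A data.frame with columns `sgrna_id`, `promoter_id`,
#'   `target_tf`, `Z`, `p`, `q`, `fold_vs_control`, `fold_vs_median`,
#'   `call`.
#' @export
call_differential <- function(aggregates, library_tbl,
                              thresholds = call_thresholds()) {
  pert <- aggregates[aggregates$role == "perturbation", , drop = FALSE]
  ctrl <- aggregates[aggregates$role == "control", , drop = FALSE]
  ci <- match(pert$promoter_id, ctrl$promoter_id)

  # median knockdown activity per promoter over non-excluded aggregates
  ok <- pert[!pert$excluded, , drop = FALSE]
  med <- tapply(ok$M, ok$promoter_id, stats::median)
  med_i <- med[pert$promoter_id]

  testable <- !pert$excluded & !is.na(ci) & !ctrl$excluded[ci] &
    pert$n >= 2 & ctrl$n[ci] >= 2
  z <- rep(NA_real_, nrow(pert))
  z[testable] <- z_score(pert$M[testable], pert$S[testable],
                         pert$n[testable],
                         ctrl$M[ci[testable]], ctrl$S[ci[testable]],
                         ctrl$n[ci[testable]])
  p <- 2 * stats::pnorm(-abs(z))
  q <- fdr_adjust(p, thresholds$fdr_method)
  fold_ctrl <- exp(pert$M - ctrl$M[ci])
  fold_med <- exp(pert$M - unname(med_i))

  call <- rep("na", nrow(pert))
  has <- testable & !is.na(q) & !is.na(fold_ctrl) & !is.na(fold_med)
  sig <- has & q <= thresholds$max_q
  up <- sig & fold_ctrl >= thresholds$min_fold &
    fold_med >= thresholds$min_fold
  down <- sig & fold_ctrl <= 1 / thresholds$min_fold &
    fold_med <= 1 / thresholds$min_fold
  call[has] <- "ns"
  call[up] <- "up"
  call[down] <- "down"

  tf <- library_tbl$target_tf[match(pert$sgrna_id, library_tbl$sgrna_id)]
  out <- data.frame(sgrna_id = pert$sgrna_id,
                    promoter_id = pert$promoter_id,
                    target_tf = tf, Z = z, p = p, q = q,
                    fold_vs_control = fold_ctrl,
                    fold_vs_median = fold_med,
                    call = call, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
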