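# Seeded simulator for a pooled promoter-reporter sort-seq screen.
#
# The generative model mirrors the assay: every (sgRNA, promoter) variant
# has a log-normal single-cell fluorescence; cells are sorted into J
# contiguous log-scale gates for equal time, so cells collected per bin
# are proportional to the population density there; a fixed fraction of
# cells is misallocated to a uniformly random bin (sorter impurity, the
# noise floor the calibration's epsilon removes); sequencing reads per bin
# are drawn multinomially over variants in proportion to their sorted
# cells; and replicates redraw the per-variant location with a small
# between-replicate jitter plus a shared per-replicate scale offset that
# the rescaling step must undo. Regulatory effects are assigned per
# (TF, promoter) pair and realized through the sgRNA targeting that TF.

#' Simulation configuration
#'
#' @param n_promoters,n_tfs,n_controls Library dimensions: promoters,
#'   TF-targeting sgRNAs (one per TF gene) and non-targeting control
#'   sgRNAs. The library is the full cross of sgRNAs x promoters.
#' @param n_bins Number of sorting gates, default 16.
#' @param boundary_range_log10 Detector span in log10 units; the J-1
#'   interior gate boundaries are equally spaced inside it and the outer
#'   gates are open-ended. Default `c(1.5, 5)`.
#' @param cells_per_variant Pre-sort cells per variant (fixed count per
#'   replicate), default 1000.
#' @param reads_per_cell Sequencing depth: reads sequenced in a bin are
#'   `round(reads_per_cell * C_j)`, default 20 (a typical screen
#'   sequences tens of reads per sorted cell).
#' @param misallocation Probability a cell lands in a uniformly random
#'   bin instead of its fluorescence gate, default 0.05.
#' @param effect_fraction Fraction of (TF, promoter) pairs with a true
#'   regulatory effect, default 0.1.
#' @param effect_log_fold Magnitude(s) of true log fold changes (natural
#'   log); sampled uniformly per regulated pair, default `log(3)`.
#' @param prop_up Probability a regulated pair responds upward
#'   (repression lost on knockdown), default 0.9: bacterial knockdown
#'   screens see far more de-repression than lost activation.
#' @param replicate_cv Between-replicate standard deviation of a
#'   variant's natural-log location, default 0.1 (matches highly
#'   reproducible replicate correlations).
#' @param replicate_shift_sd Standard deviation of the per-replicate
#'   shared scale offset on the log location, default 0.1.
#' @param mu_range_log10 Range of baseline promoter locations in log10
#'   units, default `c(2, 4.5)` (inside the detection limits).
#' @param sigma_range Range of the true log-scale spread (natural log),
#'   default `c(0.3, 0.8)`, typical of reporter distributions.
#' @param n_replicates Number of biological replicates, default 3.
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return A list of class `pptp_sim_config`.
#' @export
simulation_config <- function(n_promoters = 20, n_tfs = 10, n_controls = 5,
                              n_bins = 16,
                              boundary_range_log10 = c(1.5, 5),
                              cells_per_variant = 1000,
                              reads_per_cell = 20,
                              misallocation = 0.05,
                              effect_fraction = 0.1,
                              effect_log_fold = log(3),
                              prop_up = 0.9,
                              replicate_cv = 0.1,
                              replicate_shift_sd = 0.1,
                              mu_range_log10 = c(2, 4.5),
                              sigma_range = c(0.3, 0.8),
                              n_replicates = 3,
                              seed = 1L) {
  stopifnot(n_bins >= 3, n_promoters >= 1, n_tfs >= 1, n_controls >= 1,
            misallocation >= 0, misallocation <= 1,
            effect_fraction >= 0, effect_fraction <= 1,
            prop_up >= 0, prop_up <= 1,
            length(boundary_range_log10) == 2,
            boundary_range_log10[1] < boundary_range_log10[2])
  structure(as.list(environment()), class = "pptp_sim_config")
}

# bins with equally spaced interior boundaries and open outer gates
sim_bins_skeleton <- function(config) {
  j <- config$n_bins
  edges <- seq(config$boundary_range_log10[1],
               config$boundary_range_log10[2], length.out = j + 1)
  data.frame(bin_index = seq_len(j),
             lower_log10 = c(-Inf, edges[2:j]),
             upper_log10 = c(edges[2:j], Inf),
             cells_sorted = 0, reads_total = 0,
             included = TRUE, stringsAsFactors = FALSE)
}

#' Simulate a sort-seq screen with known ground truth
#'
#' @param config A [simulation_config()].
#' @return A list with elements `bins` (named list of `pptp_bins`, one
#'   per replicate), `counts` (`pptp_counts` over all replicates),
#'   `library` (sgRNA annotation), `promoters` (promoter annotation; each
#'   promoter of index `<= n_tfs` drives the same-index TF gene, giving
#'   the network a diagonal of potential autoregulators), `truth`
#'   (per-pair `mu_true`, `sigma_true`, `fold_true`, `regulated`) and
#'   `replicate_truth` (the realized per-replicate natural-log location
#'   of every variant, for estimation-accuracy reports).
#' @export
simulate_experiment <- function(config = simulation_config()) {
  set.seed(config$seed)
  n_sg <- config$n_tfs + config$n_controls
  tf_names <- sprintf("tf%03d", seq_len(config$n_tfs))
  sg_ids <- c(sprintf("sg_%s", tf_names),
              sprintf("NC_%02d", seq_len(config$n_controls)))
  lib <- data.frame(
    sgrna_id = sg_ids,
    target_tf = c(tf_names, rep("", config$n_controls)),
    is_control = rep(c(FALSE, TRUE), c(config$n_tfs, config$n_controls)),
    stringsAsFactors = FALSE)
  pr_ids <- sprintf("P%04d", seq_len(config$n_promoters))
  promoters <- data.frame(
    promoter_id = pr_ids,
    operon = sprintf("op%04d", seq_len(config$n_promoters)),
    genes = sprintf("g%04d", seq_len(config$n_promoters)),
    tf_gene_of_promoter = ifelse(seq_len(config$n_promoters) <=
                                   config$n_tfs,
                                 sprintf("tf%03d",
                                         seq_len(config$n_promoters)), ""),
    stringsAsFactors = FALSE)

  # baseline promoter locations and spreads (natural log)
  mu0 <- stats::runif(config$n_promoters, config$mu_range_log10[1],
                      config$mu_range_log10[2]) * log(10)
  sigma0 <- stats::runif(config$n_promoters, config$sigma_range[1],
                         config$sigma_range[2])

  # regulatory effects per (TF, promoter) pair
  n_pairs <- config$n_tfs * config$n_promoters
  regulated <- stats::runif(n_pairs) < config$effect_fraction
  mag <- if (length(config$effect_log_fold) == 1)
    rep(config$effect_log_fold, n_pairs)
  else sample(config$effect_log_fold, n_pairs, replace = TRUE)
  dir <- ifelse(stats::runif(n_pairs) < config$prop_up, 1, -1)
  delta <- ifelse(regulated, dir * mag, 0)
  delta_mat <- matrix(delta, nrow = config$n_tfs,
                      ncol = config$n_promoters)   # [tf, promoter]

  # per-variant true locations: controls carry no effect
  variant_delta <- rbind(delta_mat,
                         matrix(0, config$n_controls, config$n_promoters))
  mu_true <- sweep(variant_delta, 2, mu0, `+`)     # [sgRNA, promoter]

  truth <- data.frame(
    sgrna_id = rep(sg_ids, times = config$n_promoters),
    promoter_id = rep(pr_ids, each = n_sg),
    mu_true = as.vector(mu_true),
    sigma_true = rep(sigma0, each = n_sg),
    fold_true = exp(as.vector(variant_delta)),
    regulated = as.vector(variant_delta) != 0,
    stringsAsFactors = FALSE)

  skeleton <- sim_bins_skeleton(config)
  breaks <- ln_breaks(validate_bins(skeleton))
  j <- config$n_bins
  rep_ids <- sprintf("rep%d", seq_len(config$n_replicates))
  shift <- stats::rnorm(config$n_replicates, 0, config$replicate_shift_sd)

  bins_out <- list()
  counts_out <- vector("list", config$n_replicates)
  rep_truth <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    mu_r <- mu_true + shift[r] +
      matrix(stats::rnorm(length(mu_true), 0, config$replicate_cv),
             nrow = nrow(mu_true))
    # sorting: multinomial cells per variant over bins
    cells <- matrix(0L, nrow = n_sg * config$n_promoters, ncol = j)
    for (v in seq_len(nrow(cells))) {
      sgi <- (v - 1) %% n_sg + 1
      pri <- (v - 1) %/% n_sg + 1
      q <- diff(stats::pnorm(breaks, mu_r[sgi, pri], sigma0[pri]))
      q <- (1 - config$misallocation) * q + config$misallocation / j
      cells[v, ] <- stats::rmultinom(1, config$cells_per_variant, q)
    }
    c_j <- colSums(cells)
    r_j <- round(config$reads_per_cell * c_j)
    reads <- matrix(0L, nrow = nrow(cells), ncol = j)
    for (b in seq_len(j)) {
      if (r_j[b] > 0 && c_j[b] > 0)
        reads[, b] <- stats::rmultinom(1, r_j[b], cells[, b])
    }
    bb <- skeleton
    bb$cells_sorted <- c_j
    bb$reads_total <- r_j
    bins_out[[rep_ids[r]]] <- validate_bins(bb)
    counts_out[[r]] <- data.frame(
      sgrna_id = rep(rep(sg_ids, times = config$n_promoters), times = j),
      promoter_id = rep(rep(pr_ids, each = n_sg), times = j),
      replicate_id = rep_ids[r],
      bin = rep(seq_len(j), each = nrow(cells)),
      reads = as.vector(reads),
      stringsAsFactors = FALSE)
    rep_truth[[r]] <- data.frame(
      sgrna_id = rep(sg_ids, times = config$n_promoters),
      promoter_id = rep(pr_ids, each = n_sg),
      replicate_id = rep_ids[r],
      mu_true_rep = as.vector(mu_r),
      sigma_true = rep(sigma0, each = n_sg),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, counts_out)
  counts <- counts[order(counts$replicate_id, counts$promoter_id,
                         counts$sgrna_id, counts$bin), , drop = FALSE]
  rownames(counts) <- NULL
  class(counts) <- c("pptp_counts", "data.frame")
  list(bins = bins_out, counts = counts, library = lib,
       promoters = promoters, truth = truth,
       replicate_truth = do.call(rbind, rep_truth))
}

#' Estimation and calling accuracy against simulated ground truth
#'
#' @param sim Output of [simulate_experiment()].
#' @param fits Fit table from [fit_variants()] on the simulated counts.
#' @param calls Optional call table from [call_differential()].
#' @return A list: `mu_bias`, `mu_rmse`, `sigma_bias`, `sigma_rmse`
#'   (usable fits, per-replicate realized truth); and when `calls` is
#'   given, `by_fold` (a data.frame of call rates stratified by true fold
#'   change, where the rate at fold 1 is the false-positive rate and at
#'   fold > 1 the direction-correct sensitivity).
#' @export
recovery_report <- function(sim, fits, calls = NULL) {
  rt <- sim$replicate_truth
  key <- function(d) paste(d$sgrna_id, d$promoter_id, d$replicate_id,
                           sep = "\r")
  i <- match(key(fits), key(rt))
  usable <- fits$usable %in% TRUE & !is.na(i)
  dmu <- fits$mu[usable] - rt$mu_true_rep[i[usable]]
  dsig <- fits$sigma[usable] - rt$sigma_true[i[usable]]
  out <- list(n_usable = sum(usable),
              mu_bias = mean(dmu), mu_rmse = sqrt(mean(dmu^2)),
              sigma_bias = mean(dsig), sigma_rmse = sqrt(mean(dsig^2)))
  if (!is.null(calls)) {
    tkey <- paste(sim$truth$sgrna_id, sim$truth$promoter_id, sep = "\r")
    ti <- match(paste(calls$sgrna_id, calls$promoter_id, sep = "\r"), tkey)
    fold <- sim$truth$fold_true[ti]
    correct <- (calls$call == "up" & fold > 1) |
      (calls$call == "down" & fold < 1)
    called <- calls$call %in% c("up", "down")
    strata <- split(seq_along(fold), signif(fold, 3))
    out$by_fold <- do.call(rbind, lapply(strata, function(idx) {
      data.frame(fold_true = fold[idx[1]],
                 n = length(idx),
                 n_tested = sum(calls$call[idx] != "na"),
                 call_rate = mean(called[idx]),
                 correct_rate = mean(if (fold[idx[1]] == 1) called[idx]
                                     else correct[idx]),
                 stringsAsFactors = FALSE)
    }))
    rownames(out$by_fold) <- NULL
  }
  out
}
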