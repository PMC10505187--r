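# Replicate harmonization and per-variant aggregation.
#
# Biological replicates of a sort are run on different days, so their
# fluorescence scales differ systematically. Each replicate's log mean
# activities are mapped onto a reference replicate's scale by ordinary
# least squares over the variants usable in both. Aggregation then
# summarizes each (sgRNA, promoter) variant across replicates as a mean M,
# standard deviation S, and sample count n, and pools the non-targeting
# control sgRNAs per promoter (replicates treated as independent samples,
# interquartile-range outliers removed) into the control reference
# (M0, S0, n0) for the downstream Z-test.

#' Fit per-replicate linear rescaling maps
#'
#' For every replicate other than the reference, regresses the reference's
#' log mean activity on the replicate's log mean activity over variants
#' usable in both (ordinary least squares), yielding a slope and intercept
#' that put the replicate on the reference scale. The reference maps to
#' itself with slope 1, intercept 0.
#'
#' @param fits A fit table from [fit_variants()] (all replicates).
#' @param reference_replicate The `replicate_id` whose scale is kept.
#' @param min_shared Minimum number of shared usable variants required to
#'   fit a map, default 20.
#' @return A data.frame with columns `replicate_id`, `slope`, `intercept`,
#'   `reference_replicate`, `n_shared`.
#' @export
fit_rescale <- function(fits, reference_replicate, min_shared = 20) {
  reps <- unique(fits$replicate_id)
  if (!reference_replicate %in% reps)
    stop("reference replicate not present: ", reference_replicate)
  usable <- fits[fits$usable %in% TRUE, , drop = FALSE]
  usable$key <- paste(usable$sgrna_id, usable$promoter_id, sep = "\r")
  ref <- usable[usable$replicate_id == reference_replicate, , drop = FALSE]
  maps <- lapply(reps, function(r) {
    if (r == reference_replicate)
      return(data.frame(replicate_id = r, slope = 1, intercept = 0,
                        reference_replicate = reference_replicate,
                        n_shared = nrow(ref), stringsAsFactors = FALSE))
    cur <- usable[usable$replicate_id == r, , drop = FALSE]
    idx <- match(cur$key, ref$key)
    shared <- !is.na(idx)
    if (sum(shared) < min_shared)
      stop(sprintf(
        "replicate %s shares only %d usable variants with reference %s (need >= %d)",
        r, sum(shared), reference_replicate, min_shared))
    x <- log(cur$mean_activity[shared])
    y <- log(ref$mean_activity[idx[shared]])
    co <- stats::coef(stats::lm(y ~ x))
    data.frame(replicate_id = r, slope = unname(co[2]),
               intercept = unname(co[1]),
               reference_replicate = reference_replicate,
               n_shared = sum(shared), stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Apply rescaling maps to a fit table
#'
#' Adds a `log_activity_rescaled` column: `slope * log(mean_activity) +
#' intercept` per the replicate's map. Non-usable fits get `NA`.
#'
#' @param fits A fit table from [fit_variants()].
#' @param maps Output of [fit_rescale()].
#' @return `fits` with the extra column.
#' @export
apply_rescale <- function(fits, maps) {
  i <- match(fits$replicate_id, maps$replicate_id)
  if (anyNA(i)) stop("fit table contains replicates with no rescale map")
  la <- log(fits$mean_activity)
  fits$log_activity_rescaled <-
    ifelse(fits$usable %in% TRUE, maps$slope[i] * la + maps$intercept[i],
           NA_real_)
  fits
}

# interquartile-range outlier mask; quantiles by linear interpolation
iqr_keep <- function(x, multiplier = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  x >= q[1] - multiplier * iqr & x <= q[2] + multiplier * iqr
}

#' Aggregate rescaled activities across replicates
#'
#' Perturbation variants: per (sgRNA, promoter), the mean `M`, sample
#' standard deviation `S` (n-1 denominator) and count `n` of the rescaled
#' log activities over replicates where the fit is usable. Variants with
#' `S > s_max` are excluded (`high_S`); variants with fewer than two
#' usable replicates cannot enter the Z-test and are excluded
#' (`insufficient_n`).
#'
#' Controls: per promoter, all non-excluded control sgRNAs x replicates
#' are pooled as independent samples; outliers are removed by the
#' interquartile-range rule before computing `M0`, `S0`, `n0`. A known
#' misbehaving control sgRNA can be dropped via `controls_exclude`.
#'
#' @param fits A rescaled fit table from [apply_rescale()].
#' @param library_tbl sgRNA annotation from [read_library()].
#' @param controls_exclude Character vector of control sgRNA ids to drop
#'   from the pools.
#' @param s_max Between-replicate standard-deviation cutoff, default 0.7.
#' @param iqr_multiplier Fence multiplier for control outlier removal,
#'   default 1.5.
#' @return A data.frame with columns `sgrna_id`, `promoter_id`, `role`
#'   (`perturbation` or `control`; control rows have empty `sgrna_id` and
#'   summarize the promoter's pool), `M`, `S`, `n`, `excluded`,
#'   `exclude_reason`.
#' @export
aggregate_activity <- function(fits, library_tbl,
                               controls_exclude = character(0),
                               s_max = 0.7, iqr_multiplier = 1.5) {
  if (!"log_activity_rescaled" %in% names(fits))
    stop("fits must be rescaled first (see apply_rescale)")
  lib_i <- match(fits$sgrna_id, library_tbl$sgrna_id)
  if (anyNA(lib_i))
    stop("fit table contains sgRNAs absent from the library annotation: ",
         paste(unique(fits$sgrna_id[is.na(lib_i)]), collapse = ", "))
  fits$is_control <- library_tbl$is_control[lib_i]
  ok <- fits[!is.na(fits$log_activity_rescaled), , drop = FALSE]

  # perturbation variants
  pert <- ok[!ok$is_control, , drop = FALSE]
  pkey <- paste(pert$sgrna_id, pert$promoter_id, sep = "\r")
  prows <- lapply(split(seq_len(nrow(pert)), pkey), function(idx) {
    v <- pert$log_activity_rescaled[idx]
    n <- length(v)
    s <- if (n >= 2) stats::sd(v) else NA_real_
    reason <- ""
    if (n < 2) reason <- "insufficient_n"
    else if (s > s_max) reason <- "high_S"
    data.frame(sgrna_id = pert$sgrna_id[idx[1]],
               promoter_id = pert$promoter_id[idx[1]],
               role = "perturbation", M = mean(v), S = s, n = n,
               excluded = nzchar(reason), exclude_reason = reason,
               stringsAsFactors = FALSE)
  })

  # per-promoter negative-control pools
  ctrl <- ok[ok$is_control & !(ok$sgrna_id %in% controls_exclude), ,
             drop = FALSE]
  promoters <- unique(fits$promoter_id)
  crows <- lapply(promoters, function(pr) {
    v <- ctrl$log_activity_rescaled[ctrl$promoter_id == pr]
    if (length(v) == 0)
      return(data.frame(sgrna_id = "", promoter_id = pr, role = "control",
                        M = NA_real_, S = NA_real_, n = 0L,
                        excluded = TRUE, exclude_reason = "insufficient_n",
                        stringsAsFactors = FALSE))
    v <- v[iqr_keep(v, iqr_multiplier)]
    n <- length(v)
    s <- if (n >= 2) stats::sd(v) else NA_real_
    reason <- if (n < 2) "insufficient_n" else ""
    data.frame(sgrna_id = "", promoter_id = pr, role = "control",
               M = mean(v), S = s, n = n,
               excluded = nzchar(reason), exclude_reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(prows, crows))
  out <- out[order(out$role, out$promoter_id, out$sgrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
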