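# Signed TF -> promoter perturbation-response networks, autoregulation,
# cross-condition comparison, and relative binding-strength analysis.
#
# Sign convention: CRISPRi knockdown lowers the TF level, so a promoter
# that goes UP under knockdown is repressed by the TF, and one that goes
# DOWN is activated by it.

#' Build the perturbation-response network from differential calls
#'
#' One signed edge per non-`ns` call: `up` maps to `repression`, `down`
#' to `activation`.
#'
#' @param calls Output of [call_differential()].
#' @param condition Growth-condition label attached to every edge.
#' @return A data.frame with columns `tf`, `promoter_id`, `sign`,
#'   `condition`, `fold_vs_control`, `q`.
#' @export
build_network <- function(calls, condition = "condition1") {
  hits <- calls[calls$call %in% c("up", "down"), , drop = FALSE]
  out <- data.frame(
    tf = hits$target_tf,
    promoter_id = hits$promoter_id,
    sign = ifelse(hits$call == "up", "repression", "activation"),
    condition = rep(condition, nrow(hits)),
    fold_vs_control = hits$fold_vs_control,
    q = hits$q,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Autoregulatory edges
#'
#' Keeps edges whose TF equals the TF gene driven by the edge's own
#' promoter, i.e. the TF perturbs its own promoter.
#'
#' @param edges Output of [build_network()].
#' @param promoters Promoter annotation from [read_promoters()]
#'   (`tf_gene_of_promoter` column).
#' @return The autoregulatory subset of `edges`.
#' @export
autoregulation <- function(edges, promoters) {
  own <- promoters$tf_gene_of_promoter[
    match(edges$promoter_id, promoters$promoter_id)]
  own[is.na(own)] <- ""
  edges[nzchar(own) & edges$tf == own, , drop = FALSE]
}

#' Cross-condition overlap of regulatory edges
#'
#' Partitions the union of (tf, promoter, sign) tuples over two or more
#' conditions by their membership pattern (which conditions contain the
#' tuple) - the cells of a Venn diagram.
#'
#' @param edge_sets Named list of edge data.frames, one per condition.
#' @return A data.frame with columns `membership_pattern` (condition
#'   names joined by `+`), `sign`, `count`.
#' @export
condition_overlap <- function(edge_sets) {
  if (length(edge_sets) < 2) stop("need at least two conditions")
  if (is.null(names(edge_sets)) || any(!nzchar(names(edge_sets))))
    stop("edge_sets must be a named list")
  conds <- names(edge_sets)
  tuples <- lapply(edge_sets, function(e)
    unique(paste(e$tf, e$promoter_id, e$sign, sep = "\r")))
  all_t <- unique(unlist(tuples))
  if (length(all_t) == 0)
    return(data.frame(membership_pattern = character(0),
                      sign = character(0), count = integer(0)))
  member <- vapply(tuples, function(tt) all_t %in% tt,
                   logical(length(all_t)))
  member <- matrix(member, nrow = length(all_t),
                   dimnames = list(NULL, conds))
  pattern <- apply(member, 1, function(m) paste(conds[m], collapse = "+"))
  sign <- vapply(strsplit(all_t, "\r", fixed = TRUE), `[`, character(1), 3)
  agg <- stats::aggregate(list(count = rep(1L, length(all_t))),
                          by = list(membership_pattern = pattern,
                                    sign = sign), FUN = sum)
  agg <- agg[order(agg$membership_pattern, agg$sign), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Relative binding strengths from a binding-site table
#'
#' When a TF has several sites on one promoter, only the strongest
#' (highest fold enrichment) is kept. Two normalizations are computed on
#' the retained sites: per TF (enrichment divided by the TF's maximum
#' over its promoters) and per promoter (enrichment divided by the
#' maximum over TFs bound to the promoter); both lie in (0, 1]. The
#' site's position is summarized as its interval midpoint relative to the
#' transcription start site (negative = upstream on the given coordinate
#' system).
#'
#' @param sites Binding-site table from [read_binding()].
#' @param promoter_ids Optional vector of known promoter ids; sites on
#'   unknown promoters are dropped with a warning.
#' @return A data.frame with one row per (tf, promoter): `tf`,
#'   `promoter_id`, `fold_enrichment`, `rel_strength_per_tf`,
#'   `rel_strength_per_promoter`, `tss_relative_center`.
#' @export
relative_binding <- function(sites, promoter_ids = NULL) {
  if (!is.null(promoter_ids)) {
    unknown <- !(sites$promoter_id %in% promoter_ids)
    if (any(unknown)) {
      warning(sum(unknown), " binding site(s) reference unknown promoters",
              " and were skipped")
      sites <- sites[!unknown, , drop = FALSE]
    }
  }
  if (nrow(sites) == 0)
    return(data.frame(tf = character(0), promoter_id = character(0),
                      fold_enrichment = numeric(0),
                      rel_strength_per_tf = numeric(0),
                      rel_strength_per_promoter = numeric(0),
                      tss_relative_center = numeric(0)))
  key <- paste(sites$tf, sites$promoter_id, sep = "\r")
  best <- do.call(rbind, lapply(split(seq_len(nrow(sites)), key),
    function(idx) sites[idx[which.max(sites$fold_enrichment[idx])], ,
                        drop = FALSE]))
  max_tf <- tapply(best$fold_enrichment, best$tf, max)
  max_pr <- tapply(best$fold_enrichment, best$promoter_id, max)
  out <- data.frame(
    tf = best$tf,
    promoter_id = best$promoter_id,
    fold_enrichment = best$fold_enrichment,
    rel_strength_per_tf =
      best$fold_enrichment / unname(max_tf[best$tf]),
    rel_strength_per_promoter =
      best$fold_enrichment / unname(max_pr[best$promoter_id]),
    tss_relative_center =
      (best$site_start + best$site_end) / 2 - best$tss_position,
    stringsAsFactors = FALSE)
  out <- out[order(out$tf, out$promoter_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare binding features between regulating and non-regulating pairs
#'
#' Annotates each retained binding site with whether its (tf, promoter)
#' pair carries a regulatory edge, then tests each feature (position,
#' relative strengths, and any extra numeric columns named in `features`)
#' for a location difference between the two groups by the Wilcoxon
#' rank-sum test, Benjamini-Hochberg adjusted across features. A feature
#' with fewer than three members in either group returns `NA`.
#'
#' @param binding Output of [relative_binding()] (extra numeric columns,
#'   e.g. a TF-concentration measurement, are allowed).
#' @param edges Regulatory edges from [build_network()].
#' @param features Character vector of feature columns to test.
#' @return A data.frame with columns `feature`, `n_regulating`,
#'   `n_nonregulating`, `median_regulating`, `median_nonregulating`,
#'   `p`, `p_adj`, plus the input `binding` with a `regulating` column as
#'   attribute `"annotated"`.
#' @export
regulating_vs_nonregulating <- function(binding, edges,
    features = c("tss_relative_center", "rel_strength_per_tf",
                 "rel_strength_per_promoter")) {
  missing <- setdiff(features, names(binding))
  if (length(missing) > 0)
    stop("feature column(s) not present: ", paste(missing, collapse = ", "))
  edge_key <- unique(paste(edges$tf, edges$promoter_id, sep = "\r"))
  reg <- paste(binding$tf, binding$promoter_id, sep = "\r") %in% edge_key
  rows <- lapply(features, function(fe) {
    x <- binding[[fe]][reg]
    y <- binding[[fe]][!reg]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    p <- if (length(x) < 3 || length(y) < 3) NA_real_ else
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    data.frame(feature = fe,
               n_regulating = length(x), n_nonregulating = length(y),
               median_regulating = if (length(x)) stats::median(x)
                                   else NA_real_,
               median_nonregulating = if (length(y)) stats::median(y)
                                      else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  annotated <- binding
  annotated$regulating <- reg
  attr(out, "annotated") <- annotated
  out
}
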