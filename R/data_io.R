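# Readers and writers for the tabular artifacts of a pooled promoter
# reporter sort-seq screen. All identifiers are case-sensitive opaque
# strings; no computation happens here beyond parsing and schema checks.

#' Read a bin specification table
#'
#' A bin specification describes the sorting design: for each fluorescence
#' gate it gives the bin boundaries on a log10 scale, the number of cells
#' collected in the bin, and the number of sequencing reads attributed to
#' the bin. Bins must be contiguous (the upper boundary of bin j equals the
#' lower boundary of bin j+1) and strictly increasing. The outermost
#' boundaries may be the sentinels `-inf`/`inf` (serialized as those
#' strings): the first and last gates are open-ended, and the model treats
#' them as unbounded regardless of any finite value recorded there.
#'
#' @param path Path to a TSV or JSON file with columns/fields `bin_index`,
#'   `lower_log10`, `upper_log10`, `cells_sorted`, `reads_total` and
#'   optionally `included` (defaults to `TRUE`).
#' @param format `"tsv"` or `"json"`.
#' @return A `data.frame` of class `pptp_bins`, ordered by `bin_index`.
#' @export
read_bin_spec <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("bin spec file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character",
                            check.names = FALSE, na.strings = "NA")
  } else {
    df <- as.data.frame(jsonlite::fromJSON(path))
    df[] <- lapply(df, as.character)
  }
  required <- c("bin_index", "lower_log10", "upper_log10",
                "cells_sorted", "reads_total")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("bin spec is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"included" %in% names(df)) df$included <- "TRUE"
  bins <- data.frame(
    bin_index    = as.integer(df$bin_index),
    lower_log10  = parse_boundary(df$lower_log10),
    upper_log10  = parse_boundary(df$upper_log10),
    cells_sorted = as.numeric(df$cells_sorted),
    reads_total  = as.numeric(df$reads_total),
    included     = parse_logical(df$included),
    stringsAsFactors = FALSE
  )
  bins <- bins[order(bins$bin_index), , drop = FALSE]
  rownames(bins) <- NULL
  validate_bins(bins)
}

# "-inf"/"inf" sentinels round-trip exactly; plain numerals use the C locale
# decimal point.
parse_boundary <- function(x) {
  out <- rep(NA_real_, length(x))
  low <- tolower(trimws(x))
  out[low %in% c("-inf", "-infinity")] <- -Inf
  out[low %in% c("inf", "+inf", "infinity")] <- Inf
  plain <- is.na(out)
  out[plain] <- as.numeric(x[plain])
  out
}

parse_logical <- function(x) {
  low <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[low %in% c("true", "t", "1", "yes")] <- TRUE
  out[low %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) stop("cannot parse logical column value: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Validate a bin specification
#'
#' Checks monotone, contiguous boundaries and a minimum of three bins.
#' Used by [read_bin_spec()] and by the simulator; call it directly when
#' constructing a bin table in code.
#'
#' @param bins A data.frame with the columns of [read_bin_spec()].
#' @return The validated `bins`, with class `pptp_bins`.
#' @export
validate_bins <- function(bins) {
  j <- nrow(bins)
  if (j < 3) stop("a bin specification needs at least 3 bins, got ", j)
  if (!identical(bins$bin_index, seq_len(j)))
    stop("bin_index must be 1..", j, " with no gaps")
  if (anyNA(bins$lower_log10) || anyNA(bins$upper_log10))
    stop("bin boundaries contain unparseable values")
  if (any(bins$upper_log10 <= bins$lower_log10))
    stop("bin boundaries must be strictly increasing within each bin")
  interior_ok <- bins$upper_log10[-j] == bins$lower_log10[-1]
  if (!all(interior_ok))
    stop("bins are not contiguous at boundary after bin ",
         paste(which(!interior_ok), collapse = ", "))
  if (any(bins$cells_sorted < 0) || any(bins$reads_total < 0))
    stop("cells_sorted and reads_total must be nonnegative")
  class(bins) <- c("pptp_bins", "data.frame")
  bins
}

#' Read a long-format variant read-count table
#'
#' The canonical count format is long ("tidy"): one row per
#' (sgRNA, promoter, replicate, bin) with a nonnegative `reads` value.
#' Rows absent for a (variant, bin) combination are zero reads, so sparse
#' tables are valid input; the result is densified over all bins of the
#' design.
#'
#' @param path Path to a TSV with columns `sgrna_id`, `promoter_id`,
#'   `replicate_id`, `bin`, `reads`.
#' @param bins A `pptp_bins` table defining the valid bin range.
#' @return A `data.frame` of class `pptp_counts`: one row per variant and
#'   bin (dense), ordered by variant then bin.
#' @export
read_counts <- function(path, bins) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  required <- c("sgrna_id", "promoter_id", "replicate_id", "bin", "reads")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("counts table is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$bin <- as.integer(df$bin)
  df$reads <- as.numeric(df$reads)
  validate_counts(df, bins)
}

#' Validate and densify a count table
#'
#' @param df A data.frame with columns `sgrna_id`, `promoter_id`,
#'   `replicate_id`, `bin`, `reads`.
#' @param bins The associated `pptp_bins` design.
#' @return A dense `pptp_counts` data.frame (every variant x bin cell
#'   present, zeros filled in).
#' @export
validate_counts <- function(df, bins) {
  j <- nrow(bins)
  if (any(df$bin < 1 | df$bin > j))
    stop("bin index outside the 1..", j, " range of the bin specification")
  if (any(df$reads < 0)) stop("negative read counts are not allowed")
  if (any(df$reads != floor(df$reads)))
    stop("read counts must be integers")
  key <- paste(df$sgrna_id, df$promoter_id, df$replicate_id, df$bin,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- df[dup, , drop = FALSE][1, ]
    stop(sprintf(
      "duplicate (variant, bin) row: sgrna=%s promoter=%s replicate=%s bin=%d",
      d$sgrna_id, d$promoter_id, d$replicate_id, d$bin))
  }
  variants <- unique(df[, c("sgrna_id", "promoter_id", "replicate_id")])
  dense <- variants[rep(seq_len(nrow(variants)), each = j), , drop = FALSE]
  dense$bin <- rep(seq_len(j), times = nrow(variants))
  dense$reads <- 0
  idx <- match(
    paste(df$sgrna_id, df$promoter_id, df$replicate_id, df$bin, sep = "\r"),
    paste(dense$sgrna_id, dense$promoter_id, dense$replicate_id, dense$bin,
          sep = "\r"))
  dense$reads[idx] <- df$reads
  rownames(dense) <- NULL
  class(dense) <- c("pptp_counts", "data.frame")
  dense
}

#' Read the sgRNA library annotation
#'
#' Maps each sgRNA to its target transcription-factor gene, or marks it as
#' a non-targeting negative control. Controls must have an empty
#' `target_tf`; targeting guides must have a nonempty one.
#'
#' @param path TSV with columns `sgrna_id`, `target_tf`, `is_control`.
#' @return A validated `data.frame`.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  required <- c("sgrna_id", "target_tf", "is_control")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("library table is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$is_control <- parse_logical(df$is_control)
  df$target_tf[is.na(df$target_tf)] <- ""
  if (any(df$is_control & nzchar(df$target_tf)))
    stop("control sgRNAs must have an empty target_tf")
  if (any(!df$is_control & !nzchar(df$target_tf)))
    stop("non-control sgRNAs must have a nonempty target_tf")
  if (anyDuplicated(df$sgrna_id))
    stop("duplicate sgrna_id in library table")
  df
}

#' Read the promoter annotation table
#'
#' @param path TSV with columns `promoter_id`, `operon`, `genes`
#'   (semicolon-joined gene names) and `tf_gene_of_promoter` (the TF gene
#'   this promoter drives, empty when the promoter does not control a TF;
#'   used to detect autoregulation).
#' @return A `data.frame` with `genes` as a list-column of character
#'   vectors.
#' @export
read_promoters <- function(path) {
  if (!file.exists(path)) stop("promoters file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  required <- c("promoter_id", "operon", "genes", "tf_gene_of_promoter")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("promoters table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$promoter_id))
    stop("duplicate promoter_id in promoters table")
  df$genes <- lapply(strsplit(df$genes, ";", fixed = TRUE),
                     function(g) g[nzchar(g)])
  df
}

#' Read a TF binding-site table
#'
#' BED-like intervals (0-based, half-open) of in-vitro TF binding sites on
#' promoter regions, with a fold-enrichment score over background and the
#' position of the promoter's transcription start site on the same
#' coordinate system.
#'
#' @param path TSV with columns `tf`, `promoter_id`, `site_start`,
#'   `site_end`, `fold_enrichment`, `tss_position`.
#' @return A `data.frame`.
#' @export
read_binding <- function(path) {
  if (!file.exists(path)) stop("binding file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("tf", "promoter_id", "site_start", "site_end",
                "fold_enrichment", "tss_position")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("binding table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (any(df$site_end <= df$site_start))
    stop("binding intervals must satisfy site_start < site_end")
  if (any(df$fold_enrichment <= 0))
    stop("fold_enrichment must be positive")
  df
}

#' Write a result table as TSV
#'
#' Floating-point values are written at 6 significant digits; missing
#' values render as the literal string `NA`; infinite boundaries render as
#' `-inf`/`inf` so a table round-trips bit-exactly through
#' [read_bin_spec()].
#'
#' @param records A data.frame (list-columns are semicolon-joined).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  df <- as.data.frame(records)
  out <- lapply(df, function(col) {
    if (is.list(col)) {
      vapply(col, function(x) paste(x, collapse = ";"), character(1))
    } else if (is.double(col)) {
      format_num(col)
    } else {
      col
    }
  })
  out <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(df)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

format_num <- function(x) {
  out <- rep(NA_character_, length(x))
  out[is.finite(x)] <- formatC(signif(x[is.finite(x)], 6), format = "g",
                               digits = 6)
  out[x == Inf & !is.na(x)] <- "inf"
  out[x == -Inf & !is.na(x)] <- "-inf"
  out
}
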