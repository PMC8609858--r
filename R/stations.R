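#' Station table of chlorophyll, iron and ISIP expression
#'
#' Validates a per-station table for the correlation analysis: unique station
#' ids, non-negative chlorophyll (mg/m^3), iron (umol/m^3) and expression
#' values for the four iron-starvation-induced protein genes (ISIP1, ISIP2a,
#' ISIP2b, ISIP3), and a strictly positive total diatom unigene expression
#' used for normalization.
#'
#' @param df data frame with columns `station_id`, `chlorophyll`, `iron`,
#'   `isip1`, `isip2a`, `isip2b`, `isip3`, `diatom_unigene_total`.
#' @return The validated data frame with class `station_table` prepended.
#' @export
station_table <- function(df) {
  cols <- c("station_id", "chlorophyll", "iron", "isip1", "isip2a",
            "isip2b", "isip3", "diatom_unigene_total")
  if (!is.data.frame(df) || !all(cols %in% names(df))) {
    stop(sprintf("station table must have columns: %s",
                 paste(cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$station_id)) {
    stop("duplicate `station_id` values", call. = FALSE)
  }
  num <- setdiff(cols, "station_id")
  for (col in num) {
    if (!is.numeric(df[[col]]) || any(!is.finite(df[[col]]))) {
      stop(sprintf("column `%s` must be finite numeric", col), call. = FALSE)
    }
  }
  if (any(df$chlorophyll < 0) || any(df$iron < 0) ||
      any(df$isip1 < 0) || any(df$isip2a < 0) ||
      any(df$isip2b < 0) || any(df$isip3 < 0)) {
    stop("chlorophyll, iron and ISIP expressions must be non-negative",
         call. = FALSE)
  }
  if (any(df$diatom_unigene_total <= 0)) {
    stop("`diatom_unigene_total` must be strictly positive", call. = FALSE)
  }
  class(df) <- unique(c("station_table", class(df)))
  df
}

isip_genes <- c("isip1", "isip2a", "isip2b", "isip3")

#' Iron concentration bins for stratified correlation
#'
#' Ordered closed intervals of dissolved iron concentration (umol/m^3) used to
#' stratify stations before correlating chlorophyll with ISIP expression
#' share. Intervals must not overlap. [default_iron_bins()] gives the four
#' strata 1.24-1.39, 0.98-1.13, 0.13-0.30 and 0-0.05 umol/m^3.
#'
#' @param lower,upper numeric vectors of interval bounds, `lower <= upper`.
#' @param labels optional labels; default `"lower-upper"`.
#' @return A data frame of class `iron_bins` with columns `label`, `lower`,
#'   `upper`.
#' @export
iron_bins <- function(lower, upper, labels = NULL) {
  if (!is.numeric(lower) || !is.numeric(upper) ||
      length(lower) != length(upper) || length(lower) == 0L) {
    stop("`lower` and `upper` must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (any(lower > upper) || any(lower < 0)) {
    stop("bins need 0 <= lower <= upper", call. = FALSE)
  }
  ord <- order(lower)
  if (any(lower[ord][-1] <= upper[ord][-length(ord)])) {
    stop("iron bins must not overlap", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- sprintf("%g-%g", lower, upper)
  }
  structure(
    data.frame(label = labels, lower = lower, upper = upper,
               stringsAsFactors = FALSE),
    class = c("iron_bins", "data.frame")
  )
}

#' @rdname iron_bins
#' @export
default_iron_bins <- function() {
  iron_bins(lower = c(1.24, 0.98, 0.13, 0),
            upper = c(1.39, 1.13, 0.30, 0.05))
}

#' Normalized ISIP expression shares per station
#'
#' Each ISIP gene is first expressed as a percentage of the summed expression
#' of ISIP1 + ISIP2a + ISIP2b + ISIP3 at that station, then divided by the
#' station's total diatom unigene expression. Stations whose four-gene sum is
#' zero carry no share information; they are dropped with a warning. Because
#' the unigene total is a positive per-station scalar, applying it before or
#' after the percentage step changes only the scale, not any within-bin
#' Pearson correlation.
#'
#' @param table a [station_table()].
#' @return The table (minus excluded stations) with eight added columns:
#'   `<gene>_share_pct` (percentage of the four-gene sum) and
#'   `<gene>_share_norm` (percentage divided by `diatom_unigene_total`).
#' @export
isip_share <- function(table) {
  table <- station_table(table)
  four_sum <- table$isip1 + table$isip2a + table$isip2b + table$isip3
  bad <- four_sum == 0
  if (any(bad)) {
    warning(sprintf("excluding %d station(s) with zero four-gene ISIP sum: %s",
                    sum(bad),
                    paste(table$station_id[bad], collapse = ", ")),
            call. = FALSE)
    table <- table[!bad, , drop = FALSE]
    four_sum <- four_sum[!bad]
  }
  if (nrow(table) == 0L) {
    stop("no station has a positive four-gene ISIP sum", call. = FALSE)
  }
  for (g in isip_genes) {
    pct <- 100 * table[[g]] / four_sum
    table[[paste0(g, "_share_pct")]] <- pct
    table[[paste0(g, "_share_norm")]] <- pct / table$diatom_unigene_total
  }
  table
}

pearson_row <- function(x, y) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(n = n, r = NA_real_, p = NA_real_, computable = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(n = n, r = unname(ct$estimate), p = ct$p.value,
             computable = TRUE)
}

#' Iron-stratified Pearson correlation of chlorophyll and ISIP share
#'
#' Within each iron bin, computes the Pearson product-moment correlation (and
#' its two-sided p-value from the t distribution on n - 2 degrees of freedom,
#' via [stats::cor.test()]) between station chlorophyll content and the
#' normalized expression share of one ISIP gene. A pooled row over all
#' stations — including those falling outside every bin — is appended. Bins
#' with fewer than 3 stations or zero variance in either variable are marked
#' not computable.
#'
#' @param table a [station_table()].
#' @param bins an [iron_bins()] stratification (default
#'   [default_iron_bins()]).
#' @param gene which ISIP gene's normalized share to correlate (default
#'   `"isip1"`).
#' @return A data frame with one row per bin plus a `"pooled"` row: `bin`,
#'   `iron_lower`, `iron_upper`, `n`, `r`, `p`, `computable`.
#' @examples
#' tab <- make_station_table(seed = 1)
#' stratified_pearson(tab)
#' @export
stratified_pearson <- function(table, bins = default_iron_bins(),
                               gene = "isip1") {
  stopifnot(inherits(bins, "iron_bins"))
  gene <- match.arg(gene, isip_genes)
  shares <- isip_share(table)
  y_all <- shares[[paste0(gene, "_share_norm")]]
  x_all <- shares$chlorophyll
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    inside <- shares$iron >= bins$lower[i] & shares$iron <= bins$upper[i]
    cbind(data.frame(bin = bins$label[i], iron_lower = bins$lower[i],
                     iron_upper = bins$upper[i]),
          pearson_row(x_all[inside], y_all[inside]))
  })
  pooled <- cbind(data.frame(bin = "pooled", iron_lower = NA_real_,
                             iron_upper = NA_real_),
                  pearson_row(x_all, y_all))
  out <- rbind(do.call(rbind, rows), pooled)
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt transform
#'
#' Standard comparative-Ct quantification of qRT-PCR data against an internal
#' reference gene and a calibrator sample:
#' `fold = 2^-((Ct_target - Ct_ref) - (Ct_target_cal - Ct_ref_cal))`.
#'
#' @param ct_target,ct_reference Ct values of target and reference gene in the
#'   sample of interest (vectorized).
#' @param ct_target_cal,ct_reference_cal Ct values in the calibrator sample.
#' @return Fold change relative to the calibrator.
#' @examples
#' relative_expression_ddct(20, 15, 21, 15)  # one cycle earlier -> 2-fold
#' @export
relative_expression_ddct <- function(ct_target, ct_reference,
                                     ct_target_cal, ct_reference_cal) {
  vals <- c(ct_target, ct_reference, ct_target_cal, ct_reference_cal)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("all Ct values must be finite numbers", call. = FALSE)
  }
  ddct <- (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)
  2^(-ddct)
}

#' Read and write station tables as CSV
#'
#' Plain CSV with the exact [station_table()] column names; the reader
#' validates all invariants.
#'
#' @param path file path.
#' @return `read_station_csv()` returns a [station_table()];
#'   `write_station_csv()` invisibly returns `path`.
#' @export
read_station_csv <- function(path) {
  station_table(utils::read.csv(path, comment.char = "#"))
}

#' @rdname read_station_csv
#' @param table a [station_table()] to write.
#' @export
write_station_csv <- function(table, path) {
  table <- station_table(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
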