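# Median-split Mann-Whitney screen for instability-associated miRNAs, and
# the network enrichment of screen hits.

#' Split samples at the median of a value vector
#'
#' Labels each value `high` (strictly above the median), `low` (strictly
#' below) or `at_median` (equal; excluded from downstream tests). The
#' median of an even number of values is the midpoint of the two central
#' order statistics. Missing values stay `NA`.
#'
#' @param values numeric vector with at least 4 non-missing values.
#' @return character vector of labels aligned with `values`.
#' @export
median_split <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 4L)
    stop("median split needs at least 4 non-missing values", call. = FALSE)
  if (all(v == v[1L]))
    stop("all values identical; no median split possible", call. = FALSE)
  m <- stats::median(v)
  out <- rep(NA_character_, length(values))
  out[!is.na(values) & values > m] <- "high"
  out[!is.na(values) & values < m] <- "low"
  out[!is.na(values) & values == m] <- "at_median"
  out
}

#' Screen miRNAs for association with mutation burden
#'
#' For each miRNA, samples are split at the median of its expression and
#' the mutation counts of the high- and low-expression groups are compared
#' by the Mann-Whitney U test ([mw_test()]). Both one-sided p-values are
#' computed; the smaller is reported together with its direction
#' (`positive` when the high-expression group has the larger median
#' mutation count). A miRNA is flagged significant when that one-sided
#' p-value falls below `alpha`; no multiple-testing correction is applied
#' by default, so the effective per-miRNA false-positive rate of this
#' doubled one-sided rule is at most `2 * alpha`. miRNAs with more than
#' `max_missing` missing values, or whose median split leaves an empty
#' group, are skipped with a warning.
#'
#' @param expr expression matrix (miRNAs x samples).
#' @param index instability index from [mutation_counts()].
#' @param alpha per-miRNA one-sided significance level (default 0.01).
#' @param max_missing maximum tolerated fraction of missing expression
#'   values per miRNA (default 0.2).
#' @param adjust `"none"` (default, mirrors the raw-alpha rule) or `"BH"`
#'   for Benjamini-Hochberg on the one-sided p-values.
#' @return data.frame of class `"screen_result"`: `mirna_id`, `direction`,
#'   `p_one_sided`, `median_high_expr_mut`, `median_low_expr_mut`,
#'   `significant`; skipped miRNAs listed in `attr(, "skipped")`.
#' @export
screen_mirnas <- function(expr, index, alpha = 0.01, max_missing = 0.2,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1)
  samples <- intersect(colnames(expr), index$sample_id)
  if (length(samples) < 4L)
    stop("fewer than 4 samples shared between expression and index",
         call. = FALSE)
  counts <- index$mutation_count[match(samples, index$sample_id)]
  rows <- vector("list", nrow(expr))
  skipped <- character(0)
  for (i in seq_len(nrow(expr))) {
    id <- rownames(expr)[i]
    v <- expr[i, samples]
    if (mean(is.na(v)) > max_missing) {
      skipped <- c(skipped, id)
      next
    }
    lab <- tryCatch(median_split(v), error = function(e) NULL)
    if (is.null(lab)) { skipped <- c(skipped, id); next }
    hi <- counts[lab %in% "high"]
    lo <- counts[lab %in% "low"]
    if (!length(hi) || !length(lo)) { skipped <- c(skipped, id); next }
    mw <- mw_test(hi, lo)
    mh <- mw$median_x; ml <- mw$median_y
    direction <- if (mh > ml) "positive" else if (mh < ml) "negative" else
      if (mw$p_greater <= mw$p_less) "positive" else "negative"
    rows[[i]] <- data.frame(mirna_id = id, direction = direction,
                            p_one_sided = min(mw$p_greater, mw$p_less),
                            median_high_expr_mut = mh,
                            median_low_expr_mut = ml,
                            stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(length(skipped), " miRNA(s) skipped (missingness or degenerate split): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "", call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    stop("no miRNA could be screened", call. = FALSE)
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_one_sided, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_one_sided < alpha
  }
  structure(out, alpha = alpha, skipped = skipped,
            class = c("screen_result", "data.frame"))
}

#' Enrichment of screen hits in the miRNA-DDR regulatory network
#'
#' Builds the 2x2 table (in-network significant, in-network
#' non-significant, out-of-network significant, out-of-network
#' non-significant) over the tested miRNA universe and returns the
#' two-sided Fisher exact result plus membership lists.
#'
#' @param screened screen results ([screen_mirnas()]).
#' @param network network edge list ([read_network_edges()]).
#' @param universe miRNA identifiers tested (default: all screened).
#' @return list with `table`, `p_value`, `odds_ratio`,
#'   `in_network_significant`, `out_network_significant`,
#'   `network_members`.
#' @export
network_enrichment <- function(screened, network,
                               universe = screened$mirna_id) {
  universe <- unique(normalize_mirna_id(universe))
  if (!length(universe)) stop("empty miRNA universe", call. = FALSE)
  members <- intersect(unique(normalize_mirna_id(network$mirna_id)), universe)
  sig <- intersect(
    normalize_mirna_id(screened$mirna_id[screened$significant %in% TRUE]),
    universe)
  a <- length(intersect(sig, members))
  b <- length(setdiff(members, sig))
  c_ <- length(setdiff(sig, members))
  d <- length(universe) - a - b - c_
  fe <- fisher_exact_2x2(c(a, b, c_, d))
  list(table = fe$table, p_value = fe$p_value, odds_ratio = fe$odds_ratio,
       in_network_significant = intersect(sig, members),
       out_network_significant = setdiff(sig, members),
       network_members = members)
}
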