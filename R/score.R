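# The k-miRNA point score: a sample gains one point per positive-direction
# miRNA expressed strictly above the cohort median and per negative-direction
# miRNA strictly below it. Rank-based by construction, no fitted weights.

#' Construct a signed miRNA signature
#'
#' @param positive miRNAs scoring a point when expression is strictly above
#'   the cohort median.
#' @param negative miRNAs scoring a point when expression is strictly below
#'   the cohort median.
#' @param name signature label.
#' @return list of class `"signature_spec"` with normalized identifier
#'   sets and `k = length(positive) + length(negative)`.
#' @export
signature_spec <- function(positive, negative, name = "signature") {
  positive <- unique(normalize_mirna_id(positive))
  negative <- unique(normalize_mirna_id(negative))
  if (length(intersect(positive, negative)))
    stop("positive and negative signature sets must be disjoint",
         call. = FALSE)
  if (!length(positive) && !length(negative))
    stop("signature must contain at least one miRNA", call. = FALSE)
  structure(list(positive = positive, negative = negative, name = name,
                 k = length(positive) + length(negative)),
            class = "signature_spec")
}

#' Read a signature from a TSV file
#'
#' Two columns: `mirna` and `direction` in `{+, -}` (also accepts
#' `positive`/`negative`).
#'
#' @param path TSV file path, or `"-"` for stdin.
#' @param name signature label (default: file name).
#' @return [signature_spec()] object.
#' @export
read_signature <- function(path, name = NULL) {
  raw <- .read_tsv(path)
  need <- c("mirna", "direction")
  if (!all(need %in% colnames(raw)))
    stop("signature file needs columns 'mirna' and 'direction'",
         call. = FALSE)
  d <- tolower(trimws(raw$direction))
  pos <- raw$mirna[d %in% c("+", "positive", "pos")]
  neg <- raw$mirna[d %in% c("-", "negative", "neg")]
  if (length(pos) + length(neg) != nrow(raw))
    stop("direction values must be '+' or '-'", call. = FALSE)
  signature_spec(pos, neg, name = name %||% basename(path))
}

#' The default 10-miRNA instability signature
#'
#' Six miRNAs whose higher expression tracks higher mutation burden
#' (miR-151, miR-301b, miR-505*, miR-324, miR-502, miR-421) and four whose
#' lower expression does (let-7a*, miR-320, miR-146a*, miR-193a).
#'
#' @return [signature_spec()] of the 10-miRNA score.
#' @export
signature10 <- function() {
  signature_spec(
    positive = c("mir-151", "mir-301b", "mir-505*", "mir-324", "mir-502",
                 "mir-421"),
    negative = c("let-7a*", "mir-320", "mir-146a*", "mir-193a"),
    name = "10-miRNA-score")
}

#' Compute k-miRNA scores
#'
#' Medians are recomputed across the scored cohort (pass `medians` to
#' freeze e.g. training-set medians). Ties at the median contribute no
#' point in either direction. A sample missing a signature miRNA's value
#' contributes 0 for that miRNA and is flagged.
#'
#' @param expr expression matrix containing every signature miRNA (an
#'   error lists any that are absent).
#' @param sig [signature_spec()].
#' @param medians optional named numeric vector of frozen per-miRNA
#'   medians.
#' @return data.frame of class `"score_result"` with `sample_id` and
#'   `score`; the per-miRNA point breakdown is in `attr(, "points")`, the
#'   medians used in `attr(, "medians")`, missing-value flags in
#'   `attr(, "missing_flags")`.
#' @export
compute_scores <- function(expr, sig, medians = NULL) {
  rownames(expr) <- normalize_mirna_id(rownames(expr))
  want <- c(sig$positive, sig$negative)
  absent <- setdiff(want, rownames(expr))
  if (length(absent))
    stop("signature miRNA(s) absent from expression matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  sub <- expr[want, , drop = FALSE]
  if (is.null(medians)) {
    medians <- apply(sub, 1L, stats::median, na.rm = TRUE)
  } else {
    if (!all(want %in% names(medians)))
      stop("frozen medians must cover every signature miRNA", call. = FALSE)
    medians <- medians[want]
  }
  points <- matrix(0L, nrow = length(want), ncol = ncol(sub),
                   dimnames = dimnames(sub))
  for (m in sig$positive)
    points[m, ] <- as.integer(!is.na(sub[m, ]) & sub[m, ] > medians[[m]])
  for (m in sig$negative)
    points[m, ] <- as.integer(!is.na(sub[m, ]) & sub[m, ] < medians[[m]])
  out <- data.frame(sample_id = colnames(sub),
                    score = as.integer(colSums(points)),
                    stringsAsFactors = FALSE)
  structure(out, points = points, medians = medians,
            missing_flags = is.na(sub), k = sig$k, signature = sig$name,
            class = c("score_result", "data.frame"))
}

#' Assign high/low score groups
#'
#' `group = "high"` when `score >= cutoff` (the 10-miRNA score uses
#' cutoff 6: low 0-5 vs high 6-10).
#'
#' @param scores [compute_scores()] result.
#' @param cutoff integer in `(0, k]`.
#' @return the input with a `group` column added.
#' @export
assign_groups <- function(scores, cutoff = 6L) {
  k <- attr(scores, "k") %||% max(scores$score)
  if (cutoff <= 0 || cutoff > k)
    stop("cutoff must be in (0, k]; k = ", k, call. = FALSE)
  scores$group <- ifelse(scores$score >= cutoff, "high", "low")
  scores
}

#' Association between score levels and mutation burden
#'
#' For each score level present, the median mutation count is computed;
#' the Spearman correlation is then taken over the (level, level median)
#' pairs (one point per level, not per sample), with average-rank tie
#' handling and an exact permutation p-value when there are at most 8
#' untied levels. `per_sample = TRUE` instead correlates scores and counts
#' across samples as a sensitivity analysis.
#'
#' @param scores [compute_scores()] result.
#' @param index instability index from [mutation_counts()].
#' @param per_sample correlate per sample instead of per level.
#' @return list with `levels`, `level_medians`, `rho`, `p_value` and a
#'   `degenerate` flag (constant medians give rho = 0, p = 1).
#' @export
score_instability_association <- function(scores, index, per_sample = FALSE) {
  shared <- intersect(scores$sample_id, index$sample_id)
  s <- scores$score[match(shared, scores$sample_id)]
  cnt <- index$mutation_count[match(shared, index$sample_id)]
  levels <- sort(unique(s))
  if (length(levels) < 3L)
    stop("need at least 3 distinct score levels", call. = FALSE)
  med <- vapply(levels, function(l) stats::median(cnt[s == l]), numeric(1))
  if (per_sample) {
    xx <- s; yy <- cnt
  } else {
    xx <- levels; yy <- med
  }
  if (stats::sd(yy) == 0) {
    return(list(levels = levels, level_medians = med, rho = 0, p_value = 1,
                degenerate = TRUE))
  }
  exact <- length(xx) <= 8L && !anyDuplicated(xx) && !anyDuplicated(yy)
  ct <- suppressWarnings(
    stats::cor.test(xx, yy, method = "spearman", exact = exact))
  list(levels = levels, level_medians = med, rho = unname(ct$estimate),
       p_value = ct$p.value, degenerate = FALSE)
}

#' Response-rate trend across score levels
#'
#' Fraction of outcome-positive samples (platinum sensitivity or complete
#' response) at each score level, correlated against the level (Pearson by
#' default). Levels with no non-missing outcome are excluded.
#'
#' @param scores [compute_scores()] result.
#' @param outcome logical vector named by sample id, or aligned with
#'   `scores`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `levels`, `rates`, `n_per_level`, `r`, `p_value`,
#'   `degenerate` flag.
#' @export
response_rate_trend <- function(scores, outcome,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(names(outcome))) outcome <- outcome[scores$sample_id]
  outcome <- as.logical(outcome)
  if (length(outcome) != nrow(scores))
    stop("outcome must align with scores", call. = FALSE)
  keep <- !is.na(outcome)
  s <- scores$score[keep]; o <- outcome[keep]
  levels <- sort(unique(s))
  if (length(levels) < 3L)
    stop("need at least 3 score levels with outcome data", call. = FALSE)
  rates <- vapply(levels, function(l) mean(o[s == l]), numeric(1))
  n_per <- vapply(levels, function(l) sum(s == l), integer(1))
  if (stats::sd(rates) == 0)
    return(list(levels = levels, rates = rates, n_per_level = n_per,
                r = 0, p_value = 1, degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(levels, rates, method = method))
  list(levels = levels, rates = rates, n_per_level = n_per,
       r = unname(ct$estimate), p_value = ct$p.value, degenerate = FALSE)
}

#' Compare tumour and normal-control scores
#'
#' Mann-Whitney comparison of k-miRNA scores between tumours and normal
#' controls (both scored against the same, typically pooled, medians).
#' `p_greater` tests tumours scoring higher than normals.
#'
#' @param scores_tumour,scores_normal integer score vectors (or
#'   `score_result` data.frames).
#' @return [mw_test()] result (`x` = tumours, `y` = normals).
#' @export
compare_tumour_normal_scores <- function(scores_tumour, scores_normal) {
  gv <- function(x) if (is.data.frame(x)) x$score else x
  mw_test(gv(scores_tumour), gv(scores_normal))
}
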