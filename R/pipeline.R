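# One-command orchestration of the full analysis sequence:
# screen -> signature -> score -> grouping -> instability association ->
# defect enrichment -> survival -> matched-group comparison.

.stage <- function(report, name, expr) {
  res <- tryCatch(list(status = "OK", value = expr),
                  error = function(e)
                    list(status = paste0("SKIPPED: ", conditionMessage(e)),
                         value = NULL))
  report$stages[[name]] <- res$status
  report[[name]] <- res$value
  report
}

#' Run the full analysis pipeline on a cohort bundle
#'
#' Executes, in order: the median-split screen (unless a fixed signature is
#' supplied), signature construction (screen hits, intersected with the
#' network when one is present), scoring and grouping, the score-level
#' instability association, response-rate trends, defect enrichment Fisher
#' tests, Kaplan-Meier / log-rank / Cox survival analyses, and the two
#' matched-group comparisons (score groups matched on mutation count, and
#' mutation groups matched on score). Optional stages missing their inputs
#' degrade gracefully with an explicit `SKIPPED` marker in `$stages`.
#'
#' @param bundle [assemble_cohort()] result.
#' @param signature optional fixed [signature_spec()]; when `NULL` the
#'   signature is derived from the screen.
#' @param alpha screen significance level (default 0.01).
#' @param cutoff score-group cutoff; default `floor(k/2) + 1`.
#' @param exclude_classes variant classes excluded from mutation counts.
#' @param covariates clinical covariates for the multivariate Cox model.
#' @return list of class `"report_bundle"` with one element per stage, a
#'   `$stages` status list and `$provenance` (config and input hashes).
#' @export
run_pipeline <- function(bundle, signature = NULL, alpha = 0.01,
                         cutoff = NULL, exclude_classes = NULL,
                         covariates = c("age", "figo_stage", "grade",
                                        "debulking")) {
  if (!inherits(bundle, "cohort_bundle"))
    stop("bundle must be a cohort_bundle", call. = FALSE)
  cfg <- list(signature = if (is.null(signature)) "derived" else
    signature[c("positive", "negative", "name")],
    alpha = alpha, cutoff = cutoff, exclude_classes = exclude_classes,
    covariates = covariates)
  report <- list(stages = list(), config = cfg)

  index <- mutation_counts(bundle$mutations, bundle$samples,
                           exclude_classes = exclude_classes)
  report$instability_index <- index

  if (is.null(signature)) {
    report <- .stage(report, "screen",
                     screen_mirnas(bundle$expression, index, alpha = alpha))
    if (!is.null(report$screen)) {
      sig_rows <- report$screen[report$screen$significant %in% TRUE, ]
      if (!is.null(bundle$network)) {
        members <- unique(normalize_mirna_id(bundle$network$mirna_id))
        in_net <- normalize_mirna_id(sig_rows$mirna_id) %in% members
        if (any(in_net)) sig_rows <- sig_rows[in_net, ]
      }
      if (nrow(sig_rows) > 0) {
        signature <- signature_spec(
          sig_rows$mirna_id[sig_rows$direction == "positive"],
          sig_rows$mirna_id[sig_rows$direction == "negative"],
          name = "screen-derived")
      }
    }
    if (!is.null(bundle$network) && !is.null(report$screen))
      report <- .stage(report, "network_enrichment",
                       network_enrichment(report$screen, bundle$network))
  } else {
    report$stages$screen <- "signature: fixed"
  }
  if (is.null(signature)) {
    report$stages$score <- "SKIPPED: no signature (no significant miRNAs)"
    report$provenance <- .provenance(bundle, cfg)
    class(report) <- "report_bundle"
    return(report)
  }
  report$signature <- signature
  if (is.null(cutoff)) cutoff <- floor(signature$k / 2) + 1L

  report <- .stage(report, "score", {
    sc <- compute_scores(bundle$expression, signature)
    assign_groups(sc, cutoff = cutoff)
  })
  if (is.null(report$score)) {
    report$provenance <- .provenance(bundle, cfg)
    class(report) <- "report_bundle"
    return(report)
  }
  scores <- report$score

  report <- .stage(report, "association",
                   score_instability_association(scores, index))

  cli <- bundle$clinical
  report <- .stage(report, "response_trends", {
    if (all(is.na(cli$platinum_sensitive)) &&
        all(is.na(cli$complete_response)))
      stop("no response labels available")
    list(platinum = if (!all(is.na(cli$platinum_sensitive)))
      response_rate_trend(scores, stats::setNames(
        cli$platinum_sensitive, cli$sample_id)) else NULL,
      complete_response = if (!all(is.na(cli$complete_response)))
        response_rate_trend(scores, stats::setNames(
          cli$complete_response, cli$sample_id)) else NULL)
  })

  report <- .stage(report, "defect_enrichment", {
    if (is.null(bundle$defects)) stop("no defect table available")
    def <- bundle$defects
    grp <- scores$group[match(def$sample_id, scores$sample_id)]
    tab_for <- function(flag) {
      a <- sum(flag & grp == "high", na.rm = TRUE)
      b <- sum(!flag & grp == "high", na.rm = TRUE)
      c_ <- sum(flag & grp == "low", na.rm = TRUE)
      d <- sum(!flag & grp == "low", na.rm = TRUE)
      fe <- fisher_exact_2x2(c(a, b, c_, d))
      list(table = fe$table, p_value = fe$p_value,
           odds_ratio = fe$odds_ratio,
           rate_high = a / (a + b), rate_low = c_ / (c_ + d))
    }
    list(hr_defect = tab_for(def$hr_defect),
         brca_defect = tab_for(def$brca_defect),
         emsy_pten = tab_for(def$emsy_amplified | def$pten_deleted))
  })

  report <- .stage(report, "survival", {
    ok <- !is.na(cli$os_time) & !is.na(cli$os_event)
    if (!any(ok)) stop("no usable survival data")
    d <- cli[ok, ]
    grp <- scores$group[match(d$sample_id, scores$sample_id)]
    km <- lapply(split(seq_len(nrow(d)), grp), function(i)
      km_estimate(d$os_time[i], d$os_event[i]))
    lr <- logrank_test(grp, d$os_time, d$os_event)
    uni <- cox_fit(data.frame(score_high = as.integer(grp == "high")),
                   d$os_time, d$os_event)
    multi <- tryCatch({
      cv <- d[, intersect(covariates, colnames(d)), drop = FALSE]
      if ("debulking" %in% colnames(cv))
        cv$debulking <- as.integer(cv$debulking == "suboptimal")
      keep <- stats::complete.cases(cv)
      cox_fit(cbind(score_high = as.integer(grp == "high")[keep],
                    cv[keep, , drop = FALSE]),
              d$os_time[keep], d$os_event[keep])
    }, error = function(e) NULL)
    list(km = km, logrank = lr, cox_univariate = uni,
         cox_multivariate = multi)
  })

  report <- .stage(report, "matching", {
    ok <- !is.na(cli$os_time) & !is.na(cli$os_event)
    d <- cli[ok, ]
    grp <- scores$group[match(d$sample_id, scores$sample_id)]
    cnt <- index$mutation_count[match(d$sample_id, index$sample_id)]
    # score groups matched on mutation burden
    m_score <- matched_group_selection(grp, cnt, sample_ids = d$sample_id)
    lr_score <- .matched_logrank(m_score, d)
    # mutation groups (median split of burden) matched on score
    mut_grp <- ifelse(cnt > stats::median(cnt), "high_mut", "low_mut")
    m_mut <- matched_group_selection(
      mut_grp, scores$score[match(d$sample_id, scores$sample_id)],
      sample_ids = d$sample_id)
    lr_mut <- .matched_logrank(m_mut, d)
    list(score_matched_on_mutations = m_score,
         score_matched_logrank = lr_score,
         mutations_matched_on_score = m_mut,
         mutations_matched_logrank = lr_mut)
  })

  report$provenance <- .provenance(bundle, cfg)
  class(report) <- "report_bundle"
  report
}

.matched_logrank <- function(m, clin) {
  kept <- c(m$kept_group_a, m$kept_group_b)
  if (length(kept) < 4L) return(NULL)
  lab <- c(rep("a", length(m$kept_group_a)),
           rep("b", length(m$kept_group_b)))
  i <- match(kept, clin$sample_id)
  logrank_test(lab, clin$os_time[i], clin$os_event[i])
}

.provenance <- function(bundle, cfg) {
  list(config_hash = .hash_object(cfg),
       input_hash = .hash_object(list(
         expression = unclass(bundle$expression),
         mutations = as.data.frame(bundle$mutations),
         clinical = as.data.frame(bundle$clinical),
         defects = if (!is.null(bundle$defects))
           as.data.frame(bundle$defects) else NULL,
         network = if (!is.null(bundle$network))
           as.data.frame(bundle$network) else NULL)),
       r_version = as.character(getRversion()),
       timestamp_free = TRUE)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Analysis report\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-20s %s\n", nm, x$stages[[nm]]))
  if (!is.null(x$association))
    cat(sprintf("  score-level Spearman rho = %.3f (p = %.3g)\n",
                x$association$rho, x$association$p_value))
  if (!is.null(x$survival))
    cat(sprintf("  log-rank p = %.3g; univariate HR(high score) = %.3f\n",
                x$survival$logrank$p_value,
                x$survival$cox_univariate$hazard_ratios[1]))
  invisible(x)
}
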