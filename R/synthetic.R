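# Synthetic cohort generator. Encodes the assumed causal chain: a latent
# per-sample DDR-deficiency variable D drives (i) signed expression shifts
# in a planted subset of miRNAs, (ii) over-dispersed somatic mutation
# counts, (iii) HR defect-evidence flags, (iv) proportional-hazards
# survival with better outcome for deficient tumours, and (v) platinum
# response labels. Normals are drawn at D = 0 with no mutations.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' 400 tumours and 8 normal controls, 100 miRNAs of which 6 positive and 4
#' negative are coupled to deficiency with a 1.0 SD expression shift,
#' Bernoulli(0.5) deficiency prevalence, negative-binomial mutation counts
#' with means spanning ~10 (intact) to ~60 (deficient) and dispersion 2,
#' exponential survival with baseline hazard 0.2/year and a protective
#' deficiency hazard ratio of 0.55, ~30% independent censoring, logistic
#' platinum-response and defect-evidence models.
#'
#' @param n_tumours,n_normals,n_mirnas cohort dimensions.
#' @param planted_positive,planted_negative numbers of positively /
#'   negatively coupled miRNAs.
#' @param effect_size_sd expression shift per unit deficiency (SD units).
#' @param deficiency_model `"bernoulli"` or `"beta"`.
#' @param deficiency_p Bernoulli prevalence of deficiency.
#' @param deficiency_shape length-2 Beta shape for the graded model.
#' @param mutation_mean_base,mutation_mean_slope negative-binomial mean =
#'   base + slope * D.
#' @param mutation_dispersion negative-binomial size parameter (> 0).
#' @param hazard_base baseline hazard (events per year).
#' @param log_hr_deficiency log hazard ratio per unit deficiency
#'   (negative = protective).
#' @param censor_rate target marginal censoring fraction.
#' @param response_intercept,response_slope logistic model for platinum
#'   sensitivity and complete response: P = plogis(intercept + slope * D).
#' @param defect_prob_intercept,defect_prob_slope logistic model for each
#'   of the six defect-evidence flags.
#' @param seed integer RNG seed.
#' @return validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_tumours = 400L, n_normals = 8L,
                              n_mirnas = 100L,
                              planted_positive = 6L, planted_negative = 4L,
                              effect_size_sd = 1.0,
                              deficiency_model = c("bernoulli", "beta"),
                              deficiency_p = 0.5,
                              deficiency_shape = c(2, 2),
                              mutation_mean_base = 10,
                              mutation_mean_slope = 50,
                              mutation_dispersion = 2,
                              hazard_base = 0.2,
                              log_hr_deficiency = log(0.55),
                              censor_rate = 0.3,
                              response_intercept = -1.5,
                              response_slope = 2,
                              defect_prob_intercept = -2.8,
                              defect_prob_slope = 1.2,
                              seed = 1L) {
  deficiency_model <- match.arg(deficiency_model)
  cfg <- as.list(environment())
  if (n_tumours < 4L || n_normals < 0L || n_mirnas < 1L)
    stop("invalid cohort dimensions", call. = FALSE)
  if (planted_positive < 0L || planted_negative < 0L ||
      planted_positive + planted_negative > n_mirnas)
    stop("planted miRNA counts exceed n_mirnas", call. = FALSE)
  if (mutation_dispersion <= 0) stop("mutation_dispersion must be > 0",
                                     call. = FALSE)
  if (hazard_base <= 0) stop("hazard_base must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  if (effect_size_sd < 0) stop("effect_size_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Simulate a cohort with known ground truth
#'
#' Deterministic given `config$seed`: the RNG stream is consumed in a fixed
#' order (deficiency, expression, mutations, defects, survival, response,
#' covariates, network). All tables come out in the same shapes the
#' `read_*` readers produce, assembled into a [assemble_cohort()] bundle.
#'
#' @param config [simulation_config()].
#' @return list of class `"simulated_cohort"`: `bundle` (tumours),
#'   `expression_full` and `clinical_full` (tumours + normals), `truth`
#'   (per-sample latent deficiency), `planted` (planted miRNA ids with
#'   signs), `signature` (the planted [signature_spec()]), `normal_ids`,
#'   `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  set.seed(config$seed)
  nt <- config$n_tumours; nn <- config$n_normals
  tum_ids <- sprintf("TUM-%04d", seq_len(nt))
  norm_ids <- if (nn > 0) sprintf("NORM-%02d", seq_len(nn)) else character(0)
  all_ids <- c(tum_ids, norm_ids)

  # latent deficiency; normals are intact by construction
  D <- switch(config$deficiency_model,
              bernoulli = stats::rbinom(nt, 1L, config$deficiency_p),
              beta = stats::rbeta(nt, config$deficiency_shape[1],
                                  config$deficiency_shape[2]))
  Dall <- c(D, rep(0, nn))

  # expression: planted rows get a signed shift of effect_size_sd * D
  np <- config$planted_positive; nq <- config$planted_negative
  pos_ids <- if (np > 0) sprintf("mir-p%02d", seq_len(np)) else character(0)
  neg_ids <- if (nq > 0) sprintf("mir-n%02d", seq_len(nq)) else character(0)
  noise_ids <- sprintf("mir-x%03d", seq_len(config$n_mirnas - np - nq))
  mirna_ids <- c(pos_ids, neg_ids, noise_ids)
  expr <- matrix(stats::rnorm(config$n_mirnas * length(all_ids)),
                 nrow = config$n_mirnas,
                 dimnames = list(mirna_ids, all_ids))
  for (m in pos_ids)
    expr[m, ] <- expr[m, ] + config$effect_size_sd * Dall
  for (m in neg_ids)
    expr[m, ] <- expr[m, ] - config$effect_size_sd * Dall
  class(expr) <- c("expression_matrix", class(expr))

  # over-dispersed mutation counts, expanded to MAF-lite records
  mu <- config$mutation_mean_base + config$mutation_mean_slope * D
  counts <- stats::rnbinom(nt, size = config$mutation_dispersion, mu = mu)
  gene_pool <- sprintf("GENE%03d", seq_len(200L))
  classes <- c("missense", "silent", "nonsense", "indel")
  total <- sum(counts)
  rec_sample <- rep(tum_ids, counts)
  muts <- data.frame(
    sample_id = rec_sample,
    gene_symbol = sample(gene_pool, total, replace = TRUE),
    chromosome = as.character(sample.int(22L, total, replace = TRUE)),
    # positions unique within each sample so dedup never collapses records
    position = unlist(lapply(counts, function(k)
      if (k > 0) sort(sample.int(1e8L, k)) else integer(0)),
      use.names = FALSE),
    ref_allele = sample(c("A", "C", "G", "T"), total, replace = TRUE),
    alt_allele = sample(c("A", "C", "G", "T"), total, replace = TRUE),
    variant_class = sample(classes, total, replace = TRUE,
                           prob = c(0.55, 0.30, 0.10, 0.05)),
    stringsAsFactors = FALSE)
  class(muts) <- c("mutation_table", "data.frame")

  # defect-evidence flags: six independent logistic flags per tumour
  pdef <- stats::plogis(config$defect_prob_intercept +
                          config$defect_prob_slope * D)
  flag <- function() stats::rbinom(nt, 1L, pdef) == 1L
  defects <- data.frame(sample_id = tum_ids,
                        brca1_mutated = flag(), brca1_methylated = flag(),
                        brca2_mutated = flag(), emsy_amplified = flag(),
                        pten_deleted = flag(), core_hr_altered = flag(),
                        stringsAsFactors = FALSE)
  defects$brca_defect <- defects$brca1_mutated | defects$brca1_methylated |
    defects$brca2_mutated
  defects$hr_defect <- defects$brca_defect | defects$emsy_amplified |
    defects$pten_deleted | defects$core_hr_altered
  class(defects) <- c("defect_table", "data.frame")

  # survival: exponential with log-hazard log(hazard_base) + log_hr * D,
  # independent exponential censoring tuned to the target marginal rate
  haz <- config$hazard_base * exp(config$log_hr_deficiency * D)
  t_event <- stats::rexp(nt, haz)
  cr <- config$censor_rate
  os_time <- t_event
  os_event <- rep(TRUE, nt)
  if (cr > 0) {
    cens_rate <- config$hazard_base * cr / (1 - cr)
    t_cens <- stats::rexp(nt, cens_rate)
    os_time <- pmin(t_event, t_cens)
    os_event <- t_event <= t_cens
  }

  # platinum response labels
  presp <- stats::plogis(config$response_intercept +
                           config$response_slope * D)
  platinum <- stats::rbinom(nt, 1L, presp) == 1L
  cresp <- stats::rbinom(nt, 1L, presp) == 1L

  clinical <- data.frame(
    sample_id = all_ids,
    os_time = c(os_time, rep(NA_real_, nn)),
    os_event = c(os_event, rep(NA, nn)),
    pfs_time = NA_real_, pfs_event = NA,
    age = c(round(stats::rnorm(nt, 60, 10)), rep(NA_real_, nn)),
    figo_stage = c(sample(2:4, nt, replace = TRUE,
                          prob = c(0.15, 0.6, 0.25)), rep(NA_integer_, nn)),
    grade = c(sample(1:3, nt, replace = TRUE, prob = c(0.1, 0.35, 0.55)),
              rep(NA_integer_, nn)),
    debulking = c(sample(c("optimal", "suboptimal"), nt, replace = TRUE,
                         prob = c(0.6, 0.4)), rep("unknown", nn)),
    platinum_sensitive = c(platinum, rep(NA, nn)),
    complete_response = c(cresp, rep(NA, nn)),
    is_tumour = c(rep(TRUE, nt), rep(FALSE, nn)),
    stringsAsFactors = FALSE)
  class(clinical) <- c("clinical_table", "data.frame")

  # curated-network stand-in: planted miRNAs plus ~10% of the noise pool
  ddr_genes <- data.frame(
    gene = c("BRCA1", "BRCA2", "RAD51", "ATM", "ATR", "CHEK1", "CHEK2",
             "H2AX", "RAD17", "RAD9A", "PTEN", "TP53", "MDM2", "XRCC4",
             "MSH2", "MLH1", "ERCC1", "XPA", "OGG1", "APEX1"),
    pathway = c("HR", "HR", "HR", "DDS", "DDS", "DDS", "DDS", "DDS",
                "DDS", "DDS", "HR", "DDS", "DDS", "NHEJ", "MMR", "MMR",
                "NER", "NER", "BER", "BER"),
    stringsAsFactors = FALSE)
  n_extra <- max(0L, round(0.1 * length(noise_ids)))
  members <- c(pos_ids, neg_ids,
               if (n_extra > 0) sample(noise_ids, n_extra) else character(0))
  if (length(members)) {
    n_tgt <- sample(1:3, length(members), replace = TRUE)
    edges <- do.call(rbind, lapply(seq_along(members), function(i) {
      gi <- sample.int(nrow(ddr_genes), n_tgt[i])
      data.frame(mirna_id = members[i], target_gene = ddr_genes$gene[gi],
                 pathway_class = ddr_genes$pathway[gi],
                 evidence = "synthetic", stringsAsFactors = FALSE)
    }))
    edges <- edges[!duplicated(edges[c("mirna_id", "target_gene")]), ,
                   drop = FALSE]
    rownames(edges) <- NULL
    attr(edges, "summary") <- list(
      n_edges = nrow(edges), n_mirnas = length(unique(edges$mirna_id)),
      n_genes = length(unique(edges$target_gene)))
    class(edges) <- c("network_edges", "data.frame")
  } else edges <- NULL

  sig <- if (np + nq > 0)
    signature_spec(pos_ids, neg_ids, name = "planted") else NULL
  truth <- data.frame(sample_id = tum_ids, deficiency = D,
                      stringsAsFactors = FALSE)
  planted <- data.frame(
    mirna_id = c(pos_ids, neg_ids),
    sign = c(rep("positive", np), rep("negative", nq)),
    stringsAsFactors = FALSE)

  bundle <- assemble_cohort(expr[, tum_ids, drop = FALSE], muts,
                            clinical[clinical$is_tumour %in% TRUE, ,
                                     drop = FALSE],
                            defects = defects, network = edges)
  structure(list(bundle = bundle, expression_full = expr,
                 clinical_full = clinical, truth = truth,
                 planted = planted, signature = sig,
                 normal_ids = norm_ids, config = config),
            class = "simulated_cohort")
}

#' Write a simulated cohort to TSV files
#'
#' Emits `expr.tsv`, `muts.tsv`, `clin.tsv`, `defects.tsv`, `truth.tsv`,
#' `signature.tsv` and (when present) `network.tsv` in the formats the
#' `read_*` readers consume. Byte-identical for identical seeds.
#'
#' @param cohort [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression_matrix(cohort$expression_full, p("expr.tsv"))
  .write_tsv(cohort$bundle$mutations, p("muts.tsv"))
  .write_tsv(cohort$clinical_full, p("clin.tsv"))
  .write_tsv(cohort$bundle$defects, p("defects.tsv"))
  .write_tsv(cohort$truth, p("truth.tsv"))
  if (!is.null(cohort$signature)) {
    sig <- cohort$signature
    .write_tsv(data.frame(mirna = c(sig$positive, sig$negative),
                          direction = c(rep("+", length(sig$positive)),
                                        rep("-", length(sig$negative)))),
               p("signature.tsv"))
  }
  if (!is.null(cohort$bundle$network)) {
    nw <- cohort$bundle$network
    .write_tsv(data.frame(mirna = nw$mirna_id, gene = nw$target_gene,
                          pathway = nw$pathway_class,
                          evidence = nw$evidence), p("network.tsv"))
  }
  invisible(list.files(dir, full.names = TRUE))
}

#' Recovery metrics of pipeline outputs against simulation truth
#'
#' @param cohort [simulate_cohort()] result.
#' @param screened optional [screen_mirnas()] result on this cohort.
#' @param scores optional [compute_scores()] result on this cohort.
#' @param cox optional [cox_fit()] of the score-group indicator.
#' @param matched optional [matched_group_selection()] result.
#' @return list of recovery metrics: screen `sensitivity`, `specificity`
#'   and `sign_accuracy`; per-sample `score_deficiency_spearman`;
#'   `cox_hr`, the misclassification-attenuated expectation
#'   `cox_hr_expected = exp(log_hr_deficiency * (E[D|high] - E[D|low]))`
#'   and their ratio `cox_hr_bias`; `matched_balance_p`.
#' @export
truth_report <- function(cohort, screened = NULL, scores = NULL,
                         cox = NULL, matched = NULL) {
  out <- list()
  planted <- cohort$planted
  if (!is.null(screened)) {
    if (!all(planted$mirna_id %in% screened$mirna_id) &&
        nrow(planted) > 0)
      stop("screen results do not cover the planted miRNAs", call. = FALSE)
    hit <- merge(planted, screened, by = "mirna_id")
    correct <- hit$significant %in% TRUE & hit$direction == hit$sign
    out$sensitivity <- if (nrow(planted)) mean(correct) else NA_real_
    out$sign_accuracy <- if (any(hit$significant %in% TRUE))
      mean(hit$direction[hit$significant] == hit$sign[hit$significant])
      else NA_real_
    nonpl <- screened[!screened$mirna_id %in% planted$mirna_id, ]
    out$specificity <- mean(!(nonpl$significant %in% TRUE))
  }
  if (!is.null(scores)) {
    shared <- intersect(scores$sample_id, cohort$truth$sample_id)
    if (!length(shared)) stop("score/truth sample universes do not match",
                              call. = FALSE)
    s <- scores$score[match(shared, scores$sample_id)]
    d <- cohort$truth$deficiency[match(shared, cohort$truth$sample_id)]
    out$score_deficiency_spearman <-
      suppressWarnings(stats::cor(s, d, method = "spearman"))
    if (!is.null(cox)) {
      grp <- assign_groups(scores, cutoff = floor(
        (attr(scores, "k") %||% max(s)) / 2) + 1L)
      hi <- grp$group[match(shared, grp$sample_id)] == "high"
      delta_d <- mean(d[hi]) - mean(d[!hi])
      expected <- exp(cohort$config$log_hr_deficiency * delta_d)
      hr <- unname(cox$hazard_ratios[1])
      out$cox_hr <- hr
      out$cox_hr_expected <- expected
      out$cox_hr_bias <- hr / expected
    }
  }
  if (!is.null(matched)) out$matched_balance_p <- matched$balance_p
  out
}
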