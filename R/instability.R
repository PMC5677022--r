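# Genome-instability index (somatic mutation burden) and HR-deficiency
# evidence annotation, including the epigenetic-silencing consensus caller.

#' Default core homologous-recombination gene set
#'
#' Used by [annotate_defects()] to derive the `core_hr_altered` flag.
#' @return character vector of gene symbols.
#' @export
core_hr_genes_default <- function() {
  c("BRCA1", "BRCA2", "RAD51", "RAD51C", "RAD51D", "BRIP1", "PALB2",
    "ATM", "ATR", "CHEK1", "CHEK2",
    "FANCA", "FANCB", "FANCC", "FANCD2", "FANCE", "FANCF", "FANCG",
    "FANCI", "FANCL", "FANCM")
}

#' Per-sample somatic mutation counts
#'
#' The genome-instability index: the number of distinct somatic mutations
#' per sample. Duplicate records (same sample, chromosome, position and alt
#' allele) are counted once. Every sample in the universe receives a count;
#' samples absent from the mutation table count 0. By default all variant
#' classes are counted; `exclude_classes` drops e.g. silent variants.
#'
#' @param mutations mutation table ([read_maf_lite()]).
#' @param samples sample universe (character vector, non-empty).
#' @param exclude_classes variant classes to exclude (case-insensitive).
#' @return data.frame with columns `sample_id`, `mutation_count`.
#' @export
mutation_counts <- function(mutations, samples, exclude_classes = NULL) {
  if (!length(samples)) stop("sample universe is empty", call. = FALSE)
  m <- mutations
  if (length(exclude_classes))
    m <- m[!tolower(m$variant_class) %in% tolower(exclude_classes), ,
           drop = FALSE]
  key <- paste(m$sample_id, m$chromosome, m$position, m$alt_allele,
               sep = "\r")
  m <- m[!duplicated(key), , drop = FALSE]
  tab <- table(factor(m$sample_id, levels = samples))
  data.frame(sample_id = samples,
             mutation_count = as.integer(tab[samples]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare mutation burden between defect-flagged and unflagged samples
#'
#' Mann-Whitney U test of the instability index between samples with and
#' without a boolean defect flag, via the shared [mw_test()] machinery
#' (exact tie-aware enumeration for small groups).
#'
#' @param index data.frame from [mutation_counts()].
#' @param flags named logical vector (names = sample ids) or logical vector
#'   aligned with `index`.
#' @return [mw_test()] result, with group medians in `median_x` (flagged)
#'   and `median_y` (unflagged).
#' @export
compare_defect_instability <- function(index, flags) {
  if (!is.null(names(flags)))
    flags <- flags[index$sample_id]
  flags <- as.logical(flags)
  if (length(flags) != nrow(index))
    stop("flags must align with the instability index", call. = FALSE)
  x <- index$mutation_count[flags %in% TRUE]
  y <- index$mutation_count[flags %in% FALSE]
  if (!length(x) || !length(y))
    stop("both defect groups must be non-empty", call. = FALSE)
  mw_test(x, y)
}

#' Call epigenetic silencing of a gene by methylation/expression consensus
#'
#' Z-scores promoter methylation (beta values) and matched gene expression,
#' runs 2-means clustering with `restarts` random initializations (seeded),
#' and takes the majority assignment over restarts. The consensus cluster
#' with higher mean methylation AND lower mean expression is labelled
#' silenced; if no cluster satisfies both, all calls are false. A silenced
#' call additionally requires the sample itself to be hyper-methylated
#' (methylation z > 0) and down-regulated (expression z < 0).
#'
#' @param methylation per-sample beta values for one gene (named or aligned
#'   with `expression`).
#' @param expression per-sample expression for the same gene.
#' @param restarts number of random k-means initializations (default 25).
#' @param seed RNG seed for the restarts.
#' @param sample_ids optional sample identifiers.
#' @return data.frame with `sample_id`, `silenced`, `methylation_z`,
#'   `expression_z`.
#' @export
call_epigenetic_silencing <- function(methylation, expression, restarts = 25L,
                                      seed = 1L, sample_ids = NULL) {
  if (length(methylation) != length(expression))
    stop("methylation and expression must cover the same samples",
         call. = FALSE)
  n <- length(methylation)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  if (is.null(sample_ids))
    sample_ids <- names(methylation) %||% paste0("S", seq_len(n))
  res <- data.frame(sample_id = sample_ids, silenced = FALSE,
                    methylation_z = NA_real_, expression_z = NA_real_,
                    stringsAsFactors = FALSE)
  if (stats::sd(methylation) == 0 || stats::sd(expression) == 0) {
    warning("constant input vector; no silencing calls made", call. = FALSE)
    res$methylation_z <- if (stats::sd(methylation) == 0) 0 else
      scale(methylation)[, 1]
    res$expression_z <- if (stats::sd(expression) == 0) 0 else
      scale(expression)[, 1]
    return(res)
  }
  mz <- scale(methylation)[, 1]
  ez <- scale(expression)[, 1]
  res$methylation_z <- mz
  res$expression_z <- ez
  feat <- cbind(mz, ez)
  if (nrow(unique(feat)) < 2L) {
    warning("fewer than two distinct feature points; no silencing calls",
            call. = FALSE)
    return(res)
  }
  set.seed(seed)
  # votes for membership in the "high-methylation" cluster, one per restart
  votes <- integer(n)
  for (r in seq_len(restarts)) {
    km <- stats::kmeans(feat, centers = 2L, nstart = 1L)
    high_meth <- which.max(km$centers[, 1])
    votes <- votes + (km$cluster == high_meth)
  }
  in_high <- votes > restarts / 2
  if (!any(in_high) || all(in_high)) return(res)
  mean_m <- tapply(mz, in_high, mean)
  mean_e <- tapply(ez, in_high, mean)
  # silenced cluster must be hyper-methylated AND down-regulated
  if (mean_m[["TRUE"]] > mean_m[["FALSE"]] &&
      mean_e[["TRUE"]] < mean_e[["FALSE"]]) {
    res$silenced <- in_high & mz > 0 & ez < 0
  }
  res
}

.cn_vocab <- c("amp", "neutral", "homodel")

#' Annotate per-sample HR-deficiency evidence
#'
#' Combines gene-level mutation flags, copy-number calls and BRCA1
#' silencing calls into the defect table used to stratify score groups.
#' Derived flags:
#' `brca_defect = brca1_mutated | brca1_methylated | brca2_mutated` (the
#' canonical BRCA1/2 deficiency definition) and
#' `hr_defect = brca_defect | emsy_amplified | pten_deleted |
#' core_hr_altered`.
#'
#' @param gene_mutations data.frame (sample, gene, flag) of gene-level
#'   somatic mutation flags.
#' @param copy_number_calls data.frame (sample, gene, call) with call in
#'   `{amp, neutral, homodel}`.
#' @param silencing BRCA1 silencing calls from
#'   [call_epigenetic_silencing()], or `NULL`.
#' @param samples sample universe.
#' @param core_hr_genes gene set defining `core_hr_altered`
#'   (default [core_hr_genes_default()]); a sample is core-HR altered when
#'   any of these genes is mutated or carries a non-neutral copy-number
#'   call.
#' @return data.frame of class `"defect_table"` with one row per sample and
#'   the boolean evidence and derived flags.
#' @export
annotate_defects <- function(gene_mutations, copy_number_calls,
                             silencing = NULL, samples,
                             core_hr_genes = core_hr_genes_default()) {
  if (!length(samples)) stop("sample universe is empty", call. = FALSE)
  gm <- gene_mutations
  colnames(gm)[1:2] <- c("sample", "gene")
  if (!"flag" %in% colnames(gm)) gm$flag <- TRUE
  gm$flag <- as.logical(gm$flag)
  gm$gene <- toupper(gm$gene)
  cn <- copy_number_calls
  colnames(cn)[1:3] <- c("sample", "gene", "call")
  cn$gene <- toupper(cn$gene)
  cn$call <- tolower(trimws(as.character(cn$call)))
  bad <- setdiff(unique(cn$call), .cn_vocab)
  if (length(bad))
    stop("unknown copy-number category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  mut_flag <- function(gene) {
    hit <- gm$sample[gm$gene == gene & gm$flag %in% TRUE]
    samples %in% hit
  }
  cn_flag <- function(gene, call) {
    hit <- cn$sample[cn$gene == gene & cn$call == call]
    samples %in% hit
  }
  sil <- rep(FALSE, length(samples))
  if (!is.null(silencing))
    sil <- samples %in% silencing$sample_id[silencing$silenced %in% TRUE]
  core <- setdiff(toupper(core_hr_genes), c("BRCA1", "BRCA2"))
  core_mut <- samples %in% gm$sample[gm$gene %in% core & gm$flag %in% TRUE]
  core_cn <- samples %in% cn$sample[cn$gene %in% core & cn$call != "neutral"]
  out <- data.frame(
    sample_id = samples,
    brca1_mutated = mut_flag("BRCA1"),
    brca1_methylated = sil,
    brca2_mutated = mut_flag("BRCA2"),
    emsy_amplified = cn_flag("EMSY", "amp"),
    pten_deleted = cn_flag("PTEN", "homodel"),
    core_hr_altered = core_mut | core_cn,
    stringsAsFactors = FALSE)
  out$brca_defect <- out$brca1_mutated | out$brca1_methylated |
    out$brca2_mutated
  out$hr_defect <- out$brca_defect | out$emsy_amplified | out$pten_deleted |
    out$core_hr_altered
  structure(out, class = c("defect_table", "data.frame"))
}
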