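# Readers, writers and the cohort data model. All files are UTF-8,
# tab-separated, with "#" comment lines ignored; every reader accepts "-"
# for stdin.

.pathway_vocab <- c("HR", "NHEJ", "MMR", "NER", "BER", "DDS", "other")

#' Read a miRNA-by-sample expression matrix
#'
#' The first column holds miRNA identifiers; the header row holds sample
#' identifiers. Cells must be numeric; `NA` (or empty) cells are recorded as
#' missing, never as zero.
#'
#' @param path TSV file path, or `"-"` for stdin.
#' @param normalize_ids normalize sample (see [normalize_sample_id()]) and
#'   miRNA (see [normalize_mirna_id()]) identifiers.
#' @return numeric matrix (miRNAs x samples) with identifier dimnames,
#'   class `"expression_matrix"`.
#' @export
read_expression_matrix <- function(path, normalize_ids = TRUE) {
  raw <- .read_tsv(path, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression matrix needs >= 1 sample column",
                           call. = FALSE)
  mirnas <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (normalize_ids) {
    mirnas <- normalize_mirna_id(mirnas)
    samples <- normalize_sample_id(samples)
  }
  dup_m <- unique(mirnas[duplicated(mirnas)])
  if (length(dup_m))
    stop("duplicated miRNA identifier(s): ", paste(dup_m, collapse = ", "),
         call. = FALSE)
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s))
    stop("duplicated sample identifier(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  vals <- matrix(NA_real_, nrow = length(mirnas), ncol = length(samples),
                 dimnames = list(mirnas, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric expression cell at row %d (miRNA %s), column %s: '%s'",
                   bad[1L], mirnas[bad[1L]], samples[j], col[bad[1L]]),
           call. = FALSE)
    vals[, j] <- num
  }
  structure(vals, class = c("expression_matrix", class(vals)))
}

#' Write an expression matrix back to TSV
#'
#' Inverse of [read_expression_matrix()]: re-reading the written file yields
#' an identical matrix.
#'
#' @param x expression matrix.
#' @param path output file.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(mirna = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

.maf_aliases <- list(
  sample_id    = c("Tumor_Sample_Barcode", "sample", "sample_id"),
  gene_symbol  = c("Hugo_Symbol", "gene", "gene_symbol"),
  chromosome   = c("Chromosome", "chromosome", "chrom", "chr"),
  position     = c("Start_Position", "Start_position", "position", "pos"),
  ref_allele   = c("Reference_Allele", "ref", "ref_allele"),
  alt_allele   = c("Tumor_Seq_Allele2", "alt", "alt_allele"),
  variant_class = c("Variant_Classification", "class", "variant_class")
)

#' Read a MAF-lite somatic mutation table
#'
#' Tab-separated with at least sample, gene, chromosome, position and
#' variant-classification columns; standard MAF column names and short
#' aliases are both accepted (`aliases` overrides). Rows failing coercion
#' (non-numeric or non-positive position, empty sample) are routed to a
#' reject report attached as `attr(, "rejects")`, never silently dropped.
#' Ref/alt allele columns are optional.
#'
#' @param path TSV file path, or `"-"` for stdin.
#' @param aliases named list extending the default column-name aliases.
#' @param normalize_ids normalize sample identifiers.
#' @return data.frame of mutation records (class `"mutation_table"`) with
#'   columns sample_id, gene_symbol, chromosome, position, ref_allele,
#'   alt_allele, variant_class; rejected rows in `attr(, "rejects")`.
#' @export
read_maf_lite <- function(path, aliases = list(), normalize_ids = TRUE) {
  al <- .maf_aliases
  for (nm in names(aliases)) al[[nm]] <- unique(c(aliases[[nm]], al[[nm]]))
  raw <- .read_tsv(path, colClasses = "character")
  pick <- function(field, required = TRUE) {
    hit <- intersect(al[[field]], colnames(raw))
    if (!length(hit)) {
      if (required)
        stop(sprintf("MAF-lite is missing a '%s' column (accepted aliases: %s)",
                     field, paste(al[[field]], collapse = ", ")),
             call. = FALSE)
      return(rep(NA_character_, nrow(raw)))
    }
    raw[[hit[1L]]]
  }
  df <- data.frame(
    sample_id = pick("sample_id"),
    gene_symbol = pick("gene_symbol"),
    chromosome = pick("chromosome"),
    position_raw = pick("position"),
    ref_allele = pick("ref_allele", required = FALSE),
    alt_allele = pick("alt_allele", required = FALSE),
    variant_class = pick("variant_class"),
    stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.numeric(df$position_raw))
  ok <- !is.na(pos) & pos >= 1 & abs(pos - round(pos)) < 1e-8 &
    !is.na(df$sample_id) & nzchar(trimws(df$sample_id))
  rejects <- df[!ok, , drop = FALSE]
  out <- df[ok, , drop = FALSE]
  out$position <- as.integer(round(pos[ok]))
  out$position_raw <- NULL
  if (normalize_ids) out$sample_id <- normalize_sample_id(out$sample_id)
  rownames(out) <- NULL
  out <- out[, c("sample_id", "gene_symbol", "chromosome", "position",
                 "ref_allele", "alt_allele", "variant_class")]
  structure(out, rejects = rejects,
            class = c("mutation_table", "data.frame"))
}

.clinical_map_default <- list(
  sample_id = "sample_id", os_time = "os_time", os_event = "os_event",
  pfs_time = "pfs_time", pfs_event = "pfs_event", age = "age",
  figo_stage = "figo_stage", grade = "grade", debulking = "debulking",
  platinum_sensitive = "platinum_sensitive",
  complete_response = "complete_response", is_tumour = "is_tumour")

.debulking_vocab <- c("optimal", "suboptimal", "unknown")

.as_bool <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Read a clinical table
#'
#' TSV with a declared column map (defaults to the canonical column names).
#' Survival times are in years. Categorical vocabularies are normalized
#' case-insensitively; categories outside the vocabulary are mapped to
#' `"unknown"` with a warning reporting the count. Optional columns
#' (pfs_time/pfs_event, platinum_sensitive, complete_response, is_tumour)
#' may be absent; `is_tumour` defaults to `TRUE`.
#'
#' @param path TSV file path, or `"-"` for stdin.
#' @param column_map named list mapping canonical field names to the file's
#'   column names (merged over the defaults).
#' @param normalize_ids normalize sample identifiers.
#' @return data.frame of clinical records, class `"clinical_table"`.
#' @export
read_clinical <- function(path, column_map = list(), normalize_ids = TRUE) {
  map <- .clinical_map_default
  for (nm in names(column_map)) map[[nm]] <- column_map[[nm]]
  raw <- .read_tsv(path)
  get <- function(field, required = FALSE) {
    col <- map[[field]]
    if (!col %in% colnames(raw)) {
      if (required) stop("clinical table is missing column '", col, "' (",
                         field, ")", call. = FALSE)
      return(NULL)
    }
    raw[[col]]
  }
  n <- nrow(raw)
  out <- data.frame(sample_id = as.character(get("sample_id", TRUE)),
                    stringsAsFactors = FALSE)
  if (normalize_ids) out$sample_id <- normalize_sample_id(out$sample_id)
  out$os_time <- as.numeric(get("os_time", TRUE))
  if (any(!is.na(out$os_time) & out$os_time < 0))
    stop("negative survival time (os_time) in clinical table", call. = FALSE)
  out$os_event <- .as_bool(get("os_event", TRUE))
  pt <- get("pfs_time"); out$pfs_time <- if (is.null(pt)) NA_real_ else as.numeric(pt)
  if (any(!is.na(out$pfs_time) & out$pfs_time < 0))
    stop("negative survival time (pfs_time) in clinical table", call. = FALSE)
  pe <- get("pfs_event"); out$pfs_event <- if (is.null(pe)) NA else .as_bool(pe)
  out$age <- if (is.null(get("age"))) NA_real_ else as.numeric(get("age"))
  out$figo_stage <- if (is.null(get("figo_stage"))) NA_integer_ else
    as.integer(get("figo_stage"))
  out$grade <- if (is.null(get("grade"))) NA_integer_ else
    as.integer(get("grade"))
  deb <- get("debulking")
  if (is.null(deb)) {
    out$debulking <- "unknown"
  } else {
    d <- tolower(trimws(as.character(deb)))
    d[is.na(d) | !nzchar(d)] <- "unknown"
    n_bad <- sum(!d %in% .debulking_vocab)
    if (n_bad > 0) {
      warning(n_bad, " debulking value(s) outside {",
              paste(.debulking_vocab, collapse = ", "),
              "} mapped to 'unknown'", call. = FALSE)
      d[!d %in% .debulking_vocab] <- "unknown"
    }
    out$debulking <- d
  }
  ps <- get("platinum_sensitive")
  out$platinum_sensitive <- if (is.null(ps)) NA else .as_bool(ps)
  cr <- get("complete_response")
  out$complete_response <- if (is.null(cr)) NA else .as_bool(cr)
  it <- get("is_tumour")
  out$is_tumour <- if (is.null(it)) rep(TRUE, n) else .as_bool(it)
  structure(out, class = c("clinical_table", "data.frame"))
}

#' Read a miRNA-target network edge list
#'
#' TSV with columns `mirna`, `gene`, `pathway` (DNA-repair pathway class of
#' the target gene) and optionally `evidence`. Edges are deduplicated on
#' (mirna, gene); pathway labels must belong to
#' `{HR, NHEJ, MMR, NER, BER, DDS, other}` (case-insensitive).
#'
#' @param path TSV file path, or `"-"` for stdin.
#' @param normalize_ids normalize miRNA identifiers.
#' @return data.frame of edges (class `"network_edges"`) with a `summary`
#'   attribute listing `n_edges`, `n_mirnas`, `n_genes`.
#' @export
read_network_edges <- function(path, normalize_ids = TRUE) {
  raw <- .read_tsv(path)
  need <- c("mirna", "gene", "pathway")
  miss <- setdiff(need, colnames(raw))
  if (length(miss))
    stop("network edge list is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(
    mirna_id = if (normalize_ids) normalize_mirna_id(raw$mirna) else
      as.character(raw$mirna),
    target_gene = toupper(trimws(as.character(raw$gene))),
    pathway_class = trimws(as.character(raw$pathway)),
    evidence = if ("evidence" %in% colnames(raw))
      as.character(raw$evidence) else NA_character_,
    stringsAsFactors = FALSE)
  idx <- match(toupper(out$pathway_class), toupper(.pathway_vocab))
  if (anyNA(idx))
    stop("pathway label(s) outside vocabulary: ",
         paste(unique(out$pathway_class[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  out$pathway_class <- .pathway_vocab[idx]
  out <- out[!duplicated(out[c("mirna_id", "target_gene")]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            summary = list(n_edges = nrow(out),
                           n_mirnas = length(unique(out$mirna_id)),
                           n_genes = length(unique(out$target_gene))),
            class = c("network_edges", "data.frame"))
}

#' Assemble aligned cohort inputs into one bundle
#'
#' The analysis sample universe is the intersection of the sample
#' identifiers present in expression, mutations and clinical, ordered
#' lexicographically; per-source dropped-sample counts are recorded.
#'
#' @param expression expression matrix ([read_expression_matrix()]).
#' @param mutations mutation table ([read_maf_lite()]).
#' @param clinical clinical table ([read_clinical()]).
#' @param defects optional per-sample HR-defect table ([annotate_defects()]).
#' @param network optional network edge list ([read_network_edges()]).
#' @return list of class `"cohort_bundle"` with elements `expression`
#'   (columns restricted to the universe), `mutations`, `clinical` (rows
#'   restricted and ordered), `defects`, `network`, `samples` and `dropped`.
#' @export
assemble_cohort <- function(expression, mutations, clinical,
                            defects = NULL, network = NULL) {
  s_expr <- colnames(expression)
  s_mut <- unique(mutations$sample_id)
  s_cli <- unique(clinical$sample_id)
  universe <- sort(Reduce(intersect, list(s_expr, s_mut, s_cli)))
  if (!length(universe))
    stop("empty sample universe: expression, mutation and clinical tables ",
         "share no sample identifiers", call. = FALSE)
  dropped <- list(expression = setdiff(s_expr, universe),
                  mutations = setdiff(s_mut, universe),
                  clinical = setdiff(s_cli, universe))
  cli <- clinical[match(universe, clinical$sample_id), , drop = FALSE]
  rownames(cli) <- NULL
  out <- list(expression = expression[, universe, drop = FALSE],
              mutations = mutations[mutations$sample_id %in% universe, ,
                                    drop = FALSE],
              clinical = cli,
              defects = if (!is.null(defects))
                defects[defects$sample_id %in% universe, , drop = FALSE]
              else NULL,
              network = network,
              samples = universe,
              dropped = dropped)
  class(out) <- "cohort_bundle"
  out
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", length(x$samples), "samples in universe\n")
  cat("  expression:", nrow(x$expression), "miRNAs\n")
  cat("  mutations:", nrow(x$mutations), "records\n")
  cat("  dropped (not in universe): expression",
      length(x$dropped$expression), "| mutations",
      length(x$dropped$mutations), "| clinical",
      length(x$dropped$clinical), "\n")
  if (!is.null(x$network))
    cat("  network:", nrow(x$network), "edges\n")
  invisible(x)
}
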