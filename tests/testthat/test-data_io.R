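test_that("expression matrix reader validates identifiers and missing cells", {
  f <- tempfile(fileext = ".tsv")
  m <- matrix(1:12, 3, 4, dimnames = list(c("miR-1", "miR-2", "miR-3"),
                                          paste0("S", 1:4)))
  make_expr_tsv(f, m)
  x <- read_expression_matrix(f)
  expect_equal(dim(x), c(3L, 4L))
  expect_equal(rownames(x), c("mir-1", "mir-2", "mir-3"))

  writeLines(c("mirna\tS1\tS2", "miR-21\t1\t2", "miR-21\t3\t4"), f)
  expect_error(read_expression_matrix(f), "mir-21")

  writeLines(c("mirna\tS1\tS2", "miR-1\tNA\t2", "miR-2\t3\t4"), f)
  x <- read_expression_matrix(f)
  expect_true(is.na(x["mir-1", "S1"]))
  expect_equal(sum(is.na(x)), 1L)

  writeLines(c("mirna\tS1\tS2", "miR-1\tabc\t2"), f)
  expect_error(read_expression_matrix(f), "non-numeric")
})

test_that("MAF-lite reader accepts aliases and routes bad rows to the reject report", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(Tumor_Sample_Barcode = c("S1", "S1", "S2", "S3"),
                   Hugo_Symbol = c("TP53", "BRCA1", "PTEN", "ATM"),
                   Chromosome = c("17", "17", "10", "11"),
                   Start_Position = c(100, 200, 300, 400),
                   Variant_Classification = "missense")
  make_maf_tsv(f, df)
  rec <- read_maf_lite(f)
  expect_equal(nrow(rec), 4L)
  expect_equal(nrow(attr(rec, "rejects")), 0L)

  df$Start_Position <- c("100", "x", "300", "400")
  make_maf_tsv(f, df)
  rec <- read_maf_lite(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(nrow(attr(rec, "rejects")), 1L)
  # accepted + rejected = input rows
  expect_equal(nrow(rec) + nrow(attr(rec, "rejects")), 4L)

  make_maf_tsv(f, df[0, ])
  expect_equal(nrow(read_maf_lite(f)), 0L)

  make_maf_tsv(f, df[, -1])
  expect_error(read_maf_lite(f), "Tumor_Sample_Barcode")
})

test_that("clinical reader normalizes vocabularies and rejects negative times", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = paste0("S", 1:5), os_time = c(1, 2, 3, 4, 5),
                   os_event = c("TRUE", "FALSE", "1", "0", "yes"),
                   debulking = c("OPTIMAL", "suboptimal", "weird", "", NA))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- suppressWarnings(read_clinical(f))
  expect_equal(nrow(cl), 5L)
  expect_equal(cl$debulking[1], "optimal")
  expect_equal(cl$debulking[3], "unknown")
  expect_warning(read_clinical(f), "unknown")
  expect_equal(cl$os_event, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_true(all(cl$is_tumour))

  df$os_time[2] <- -1
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressWarnings(read_clinical(f)), "negative")
})

test_that("packaged network fixture contains the documented interactions", {
  f <- system.file("extdata", "ddr_network_synthetic.tsv", package = "mirgi")
  nw <- read_network_edges(f)
  s <- attr(nw, "summary")
  expect_equal(s$n_edges, nrow(nw))
  expect_true(all(c("mir-24", "mir-421", "mir-146", "mir-151", "mir-505*",
                    "mir-324", "let-7a*", "mir-320") %in% nw$mirna_id))
  # RAD17 regulated by three miRNAs, RAD9A by two
  expect_setequal(nw$mirna_id[nw$target_gene == "RAD17"],
                  c("mir-421", "mir-505*", "mir-324"))
  expect_setequal(nw$mirna_id[nw$target_gene == "RAD9A"],
                  c("let-7a*", "mir-320"))
})

test_that("network reader deduplicates and enforces the pathway vocabulary", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("mirna\tgene\tpathway", "miR-1\tBRCA1\tHR",
               "miR-1\tBRCA1\thr", "miR-2\tATM\tDDS"), f)
  nw <- read_network_edges(f)
  expect_equal(nrow(nw), 2L)
  expect_equal(attr(nw, "summary")$n_mirnas, 2L)

  writeLines(c("mirna\tgene\tpathway", "miR-1\tBRCA1\tXYZ"), f)
  expect_error(read_network_edges(f), "XYZ")
})

test_that("cohort assembly intersects sample universes deterministically", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("mir-", 1:3), c("A", "B", "C", "E")))
  class(m) <- c("expression_matrix", class(m))
  muts <- data.frame(sample_id = c("B", "C", "D"), gene_symbol = "TP53",
                     chromosome = "17", position = 1:3, ref_allele = "A",
                     alt_allele = "T", variant_class = "missense")
  cli <- data.frame(sample_id = c("A", "B", "C", "D"), os_time = 1,
                    os_event = TRUE)
  b <- assemble_cohort(m, muts, cli)
  expect_equal(b$samples, c("B", "C"))
  expect_equal(length(b$dropped$expression), 2L)

  # order-independence: permuting input rows yields the same bundle
  b2 <- assemble_cohort(m[, c(3, 1, 4, 2)], muts[3:1, ], cli[4:1, ])
  expect_equal(b2$samples, b$samples)
  expect_equal(b2$expression, b$expression)
  expect_equal(b2$clinical$sample_id, b$clinical$sample_id)

  cli_bad <- data.frame(sample_id = c("X", "Y"), os_time = 1,
                        os_event = TRUE)
  expect_error(assemble_cohort(m, muts, cli_bad), "empty sample universe")
})

test_that("parsed tables round-trip through TSV unchanged", {
  f <- tempfile(fileext = ".tsv")
  m <- matrix(c(1.5, NA, 3, 4, 5, 6), 2, 3,
              dimnames = list(c("mir-a", "mir-b"), c("S1", "S2", "S3")))
  class(m) <- c("expression_matrix", class(m))
  write_expression_matrix(m, f)
  expect_equal(read_expression_matrix(f), m)

  maf <- data.frame(sample_id = c("S1", "S2"), gene_symbol = c("TP53", "ATM"),
                    chromosome = c("17", "11"), position = c(10L, 20L),
                    ref_allele = c("A", "C"), alt_allele = c("T", "G"),
                    variant_class = c("missense", "silent"))
  write.table(maf, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_maf_lite(f)
  expect_equal(as.data.frame(back), maf, ignore_attr = TRUE)
})

test_that("sample and miRNA identifier normalization follows the conventions", {
  expect_equal(normalize_sample_id(" tcga-ab-1234-01a-11r "),
               "TCGA-AB-1234-01")
  expect_equal(normalize_sample_id("TCGA-AB-1234-01"), "TCGA-AB-1234-01")
  expect_equal(normalize_sample_id("s1 "), "S1")
  expect_equal(normalize_mirna_id(c("miR-505*", " Let-7a* ")),
               c("mir-505*", "let-7a*"))
})
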