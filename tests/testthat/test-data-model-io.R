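# Reading, writing, cleaning and promoter mapping of beta matrices.

test_that("beta matrix round-trips through delimited text", {
  beta <- beta_fixture(c(0.1, 0.9, NA, 0.33, 0.5, 0.77, 0, 1,
                         0.25, 0.5, 0.125, NA, 0.6, 0.2, 0.8, 0.4,
                         0.15, 0.95, 0.45, 0.05), 5, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(beta, path)
  back <- read_beta_matrix(path)
  expect_identical(dimnames(back), dimnames(beta))
  expect_equal(back, beta)
  expect_identical(is.na(back), is.na(beta))

  # NA token is configurable
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_beta_matrix(beta, path2, delimiter = ",", na = "missing")
  back2 <- read_beta_matrix(path2, delimiter = ",", na = "missing")
  expect_equal(back2, beta)
})

test_that("read_beta_matrix rejects malformed input with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "g1\t0.2\t1.3", "g2\t0.1\t0.4"), path)
  expect_error(read_beta_matrix(path), "g1.*s2|s2.*g1")

  writeLines(c("feature_id\ts1\ts2", "g1\t0.2\t0.3", "g1\t0.1\t0.4"), path)
  expect_error(read_beta_matrix(path), "duplicate")

  writeLines(c("feature_id\ts1\ts2", "g1\t0.2\tx", "g2\t0.1\t0.4"), path)
  expect_error(read_beta_matrix(path), "non-numeric")

  expect_error(read_beta_matrix(file.path(tempdir(), "absent.tsv")), "not found")
})

test_that("batch assignment reading validates coverage and uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tbatch_id", "s1\tA", "s2\tA", "s3\tB"), path)
  batches <- read_batch_assignment(path)
  expect_identical(batches$batch_id, c("A", "A", "B"))

  beta <- beta_fixture(runif(8), 2, 4)
  expect_error(validate_batch_assignment(batches, beta), "no batch")

  writeLines(c("sample_id\tbatch_id", "s1\tA", "s1\tB"), path)
  expect_error(read_batch_assignment(path), "more than one batch")
})

test_that("clean_entries drops missing/indistinct gene names and is idempotent", {
  beta <- beta_fixture(runif(12), 6, 2)
  ann <- data.frame(
    probe_id = paste0("f", 1:6),
    chromosome = "chr1", position = 1:6 * 100,
    gene_name = c("GENE1", "", "GENE2;GENE3", "NA", "GENE4", "GENE5"),
    stringsAsFactors = FALSE)
  beta["f6", ] <- NA  # all-missing row

  res <- suppressMessages(clean_entries(beta, ann))
  expect_identical(rownames(res$beta), c("f1", "f5"))
  expect_identical(res$annotation$gene_name, c("GENE1", "GENE4"))
  expect_equal(res$beta, beta[c("f1", "f5"), ])

  # idempotent: a second pass changes nothing
  res2 <- suppressMessages(clean_entries(res$beta, res$annotation))
  expect_identical(res2$beta, res$beta)
  expect_equal(res2$n_dropped, 0)

  # comma separator also counts as indistinct; unannotated features dropped
  ann3 <- data.frame(probe_id = "f1", chromosome = "chr1", position = 10,
                     gene_name = "A,B", stringsAsFactors = FALSE)
  res3 <- suppressMessages(clean_entries(beta[1:2, ], ann3))
  expect_equal(nrow(res3$beta), 0)
})

test_that("promoter mapping uses an inclusive +/- window on matching gene and chromosome", {
  tss <- data.frame(gene_name = c("G1", "G2"), chromosome = c("chr1", "chr2"),
                    tss_position = c(1000L, 5000L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  probes <- data.frame(
    probe_id = c("p_in_edge", "p_out_edge", "p_wrong_chr", "p_minus", "p_nogene"),
    chromosome = c("chr1", "chr1", "chr2", "chr2", "chr3"),
    position = c(3000L, 3001L, 1000L, 4000L, 1000L),
    gene_name = c("G1", "G1", "G1", "G2", "G9"),
    stringsAsFactors = FALSE)

  kept <- map_probes_to_promoters(probes, tss, window_bp = 2000)
  expect_setequal(kept, c("p_in_edge", "p_minus"))  # 2000 bp away inclusive; wrong chr excluded

  # idempotence: restricting to kept probes returns the same set
  kept2 <- map_probes_to_promoters(probes[probes$probe_id %in% kept, ], tss)
  expect_setequal(kept2, kept)

  expect_error(map_probes_to_promoters(probes, tss, window_bp = 0), "positive")
})

test_that("TSS annotation reads both the named table and BED6 layouts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chromosome\ttss_position\tstrand\tgene_name",
               "chr1\t1000\t+\tG1"), path)
  tab <- read_tss_annotation(path)
  expect_identical(tab$tss_position, 1000L)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t1300\tG1\t0\t+", "chr2\t4000\t5000\tG2\t0\t-"), bed)
  tab2 <- read_tss_annotation(bed, format = "bed6")
  expect_identical(tab2$tss_position, c(1000L, 5000L))  # start+1 on +, end on -
})

test_that("probe-to-gene aggregation takes the mean of non-missing probes", {
  beta <- beta_fixture(c(0.2, 0.1, 0.4, NA, 0.7, 0.9), 3, 2)
  map <- c(f1 = "GENE_A", f2 = "GENE_A", f3 = "GENE_B")

  agg <- aggregate_probes_to_genes(beta, map)
  expect_equal(agg["GENE_A", "s1"], 0.3)     # mean(0.2, 0.4)
  expect_equal(agg["GENE_A", "s2"], 0.1)     # NA ignored, not propagated
  expect_equal(agg["GENE_B", ], c(s1 = 0.7, s2 = 0.9))  # single probe passes through
  expect_identical(colnames(agg), colnames(beta))

  # aggregated values never leave the range of contributing probes
  set.seed(42)
  big <- beta_fixture(runif(60), 12, 5)
  gmap <- stats::setNames(rep(c("A", "B", "C"), each = 4), rownames(big))
  agg2 <- aggregate_probes_to_genes(big, gmap)
  for (g in c("A", "B", "C")) {
    rows <- big[names(gmap)[gmap == g], ]
    expect_true(all(agg2[g, ] >= apply(rows, 2, min) - 1e-12))
    expect_true(all(agg2[g, ] <= apply(rows, 2, max) + 1e-12))
  }

  # entry missing only when every probe is missing
  beta2 <- beta_fixture(c(NA, 0.4, NA, NA), 2, 2)
  agg3 <- aggregate_probes_to_genes(beta2, c(f1 = "G", f2 = "G"))
  expect_true(is.na(agg3["G", "s1"]))   # both probes missing
  expect_equal(agg3["G", "s2"], 0.4)

  expect_error(aggregate_probes_to_genes(beta, character(0)), "empty")
  expect_error(aggregate_probes_to_genes(beta, c(f1 = "A")), "no gene mapping")
})
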