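test_that("mutation tables parse, derive VAF and report bad rows", {
  dir <- write_fixture_tables()
  muts <- read_mutation_table(file.path(dir, "muts.tsv"))
  expect_equal(nrow(muts), 3)
  expect_equal(muts$vaf, c(0.30, 0.0, 0.5))

  # precomputed vaf column is honored
  writeLines(c("sample\tchrom\tpos\tref\talt\tvaf", "S1\t1\t10\tA\tT\t0.25"),
             file.path(dir, "v.tsv"))
  expect_equal(read_mutation_table(file.path(dir, "v.tsv"))$vaf, 0.25)

  # missing required column is a format error
  writeLines(c("sample\tchrom\tref\talt\tvaf", "S1\t1\tA\tT\t0.2"),
             file.path(dir, "bad.tsv"))
  expect_error(read_mutation_table(file.path(dir, "bad.tsv")), "missing required")

  # non-numeric counts are dropped with a line-numbered warning
  writeLines(c("sample\tchrom\tpos\tref\talt\talt_count\tref_count",
               "S1\t1\t10\tA\tT\t5\t95",
               "S1\t1\t20\tA\tT\txx\t95",
               "S1\t1\t30\tA\tT\t0\t0"),
             file.path(dir, "rows.tsv"))
  expect_warning(out <- read_mutation_table(file.path(dir, "rows.tsv")),
                 "2 malformed.*3, 4")
  expect_equal(nrow(out), 1)
})

test_that("MAF dialect column names are mapped", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "Hugo_Symbol\tTumor_Sample_Barcode\tChromosome\tStart_Position\tReference_Allele\tTumor_Seq_Allele2\tt_alt_count\tt_ref_count",
    "BRAF\tS1\t7\t140753336\tA\tT\t40\t60"
  ), file.path(dir, "maf.tsv"))
  muts <- read_mutation_table(file.path(dir, "maf.tsv"), dialect = "maf")
  expect_equal(muts$gene, "BRAF")
  expect_equal(muts$vaf, 0.4)
})

test_that("SEG files parse, sort, and reject inverted intervals", {
  dir <- write_fixture_tables()
  segs <- read_seg_file(file.path(dir, "segs.seg"))
  expect_equal(segs$chrom, c("1", "7"))  # sorted by (sample, chrom, start)
  expect_equal(segs$seg_mean, c(0.0, 1.0))

  writeLines(c("sample\tchrom\tstart\tend\tseg_mean",
               "S1\t1\t100\t50\t0.3", "S1\t1\t1\t10\t0.1"),
             file.path(dir, "inv.seg"))
  expect_warning(out <- read_seg_file(file.path(dir, "inv.seg")), "start > end")
  expect_equal(nrow(out), 1)

  # overlapping segments: both retained, warning logged
  writeLines(c("sample\tchrom\tstart\tend\tseg_mean",
               "S1\t1\t1\t100\t0.0", "S1\t1\t50\t200\t1.0"),
             file.path(dir, "ovl.seg"))
  expect_warning(out <- read_seg_file(file.path(dir, "ovl.seg")), "overlap")
  expect_equal(nrow(out), 2)
})

test_that("purity tables validate the (0, 1] domain", {
  dir <- withr::local_tempdir()
  writeLines(c("sample\tpurity", "S1\t0.8", "S2\t1.0"), file.path(dir, "p.tsv"))
  p <- read_purity_table(file.path(dir, "p.tsv"))
  expect_equal(p[["S1"]], 0.8)
  expect_equal(p[["S2"]], 1.0)  # boundary accepted
  writeLines(c("sample\tpurity", "S1\t0"), file.path(dir, "p0.tsv"))
  expect_error(read_purity_table(file.path(dir, "p0.tsv")), "\\(0, 1\\]")
})

test_that("readers accept gzip-compressed files and round-trip field-for-field", {
  dir <- write_fixture_tables()
  muts <- read_mutation_table(file.path(dir, "muts.tsv"))
  gz <- file.path(dir, "muts2.tsv.gz")
  write_mutation_table(muts, gz)
  expect_equal(as.data.frame(read_mutation_table(gz)), as.data.frame(muts))

  segs <- read_seg_file(file.path(dir, "segs.seg"))
  write_seg_file(segs, file.path(dir, "segs2.seg.gz"))
  expect_equal(as.data.frame(read_seg_file(file.path(dir, "segs2.seg.gz"))),
               as.data.frame(segs))

  p <- read_purity_table(file.path(dir, "purity.tsv"))
  write_purity_table(p, file.path(dir, "p2.tsv"))
  expect_equal(read_purity_table(file.path(dir, "p2.tsv")), p)
})

test_that("assembly assigns by closed-interval containment and never drops mutations", {
  dir <- write_fixture_tables()
  muts <- read_mutation_table(file.path(dir, "muts.tsv"))
  segs <- read_seg_file(file.path(dir, "segs.seg"))
  ts <- assemble_tumor_sample(muts, segs, 0.8, "S1")
  expect_s3_class(ts, "tumor_sample")
  expect_equal(nrow(ts$mutations), nrow(muts))  # count in == count out
  # pos 1000 and 140753336 inside segments; pos 5000 beyond chr1 segment end 2000
  expect_equal(ts$mutations$assigned, c(TRUE, TRUE, FALSE))
  expect_true(is.na(ts$mutations$seg_mean[3]))

  # boundary: end is inclusive, end + 1 is out
  m2 <- tibble::tibble(sample_id = "S1", chrom = "1", pos = c(2000L, 2001L),
                       ref = "A", alt = "T", gene = NA_character_,
                       alt_count = c(10, 10), ref_count = c(90, 90),
                       vaf = 0.1)
  ts2 <- assemble_tumor_sample(m2, segs, 0.8, "S1")
  expect_equal(ts2$mutations$assigned, c(TRUE, FALSE))
})

test_that("nested overlapping segments resolve to the smallest interval", {
  segs <- tibble::tibble(sample_id = "S1", chrom = "1",
                         start = c(1L, 100L), end = c(10000L, 200L),
                         num_probes = NA_real_, seg_mean = c(0, 1), ccf_cnv = 1)
  m <- tibble::tibble(sample_id = "S1", chrom = "1", pos = 150L, ref = "A",
                      alt = "T", gene = NA_character_, alt_count = 10,
                      ref_count = 90, vaf = 0.1)
  expect_message(ts <- assemble_tumor_sample(m, segs, 1, "S1"), "multiple segments")
  expect_equal(ts$mutations$seg_mean, 1)  # the narrow [100,200] segment
})

test_that("clone trees validate structure and round-trip through JSON", {
  single <- clone_tree(tibble::tibble(node_id = 1, parent_id = NA,
                                      n_mutations = 5, prevalence = 1))
  expect_s3_class(single, "clone_tree")

  chain <- clone_tree(tibble::tibble(node_id = 0:2, parent_id = c(NA, 0, 1),
                                     n_mutations = c(3, 2, 1),
                                     prevalence = c(1, 0.6, 0.3)))
  expect_equal(nrow(chain$nodes), 3)

  # self-parent is a cycle
  expect_error(clone_tree(tibble::tibble(node_id = c(1, 2), parent_id = c(NA, 2),
                                         n_mutations = 1, prevalence = c(1, 0.5))),
               "cycle")
  # two roots
  expect_error(clone_tree(tibble::tibble(node_id = c(1, 2), parent_id = c(NA, NA),
                                         n_mutations = 1, prevalence = 1)),
               "exactly one root")
  # child prevalence above parent violates the pigeonhole invariant
  expect_error(clone_tree(tibble::tibble(node_id = c(1, 2), parent_id = c(NA, 1),
                                         n_mutations = 1, prevalence = c(0.5, 0.9))),
               "prevalence")

  dir <- withr::local_tempdir()
  trees <- simulate_clone_trees("RANDOM", 5, n_trees = 4, seed = 31)
  trees <- Map(function(tr, ll) { tr$log_likelihood <- ll; tr },
               trees, c(-2, -9, -4, -9))
  path <- file.path(dir, "trees.json")
  write_clone_trees(trees, path)
  back <- read_clone_trees(path)
  expect_length(back, 4)  # ordering preserved
  for (i in seq_along(trees)) {
    expect_equal(back[[i]]$nodes, trees[[i]]$nodes)
    expect_equal(back[[i]]$log_likelihood, trees[[i]]$log_likelihood)
  }
})
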