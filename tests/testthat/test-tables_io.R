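test_that("TSV parsing validates counts and reports the offending cell", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tr1\tr2", "ta\t3\t0", "tb\t1\t2"), p)
  tt <- read_taxon_table(p)
  expect_equal(unname(replicate_depths(tt)), c(4, 2))
  expect_equal(rownames(tt$counts), c("ta", "tb"))

  writeLines("taxon_id\tr1\tr2", p)
  empty <- read_taxon_table(p)
  expect_equal(nrow(empty$counts), 0)

  writeLines(c("taxon_id\tr1\tr2", "ta\t3.5\t0"), p)
  expect_error(read_taxon_table(p), "3\\.5.*ta.*r1")
  writeLines(c("taxon_id\tr1\tr2", "ta\t-1\t0"), p)
  expect_error(read_taxon_table(p), "ta")
})

test_that("duplicate labels are rejected", {
  m <- matrix(1L, 2, 2, dimnames = list(c("a", "a"), c("r1", "r2")))
  expect_error(taxon_table(m), "duplicate taxon")
  m2 <- matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("r1", "r1")))
  expect_error(taxon_table(m2), "duplicate replicate")
})

test_that("write/read round-trips counts, labels, and lineage in both formats", {
  tt <- tiny_table()
  for (fmt in c("tsv", "biom_json")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_taxon_table(tt, p, format = fmt)
    back <- read_taxon_table(p, format = fmt)
    expect_identical(back$counts, tt$counts, label = fmt)
    expect_identical(back$lineage, tt$lineage, label = fmt)
  }
  # tables without lineage round-trip too
  tt2 <- random_table()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_taxon_table(tt2, p)
  expect_identical(read_taxon_table(p)$counts, tt2$counts)
})

test_that("the JSON-BIOM subset is readable by an independent BIOM parser", {
  skip_if_not_installed("biomformat")
  tt <- tiny_table()
  p <- withr::local_tempfile(fileext = ".biom")
  write_taxon_table(tt, p, format = "biom_json")
  b <- biomformat::read_biom(p)
  m <- as.matrix(biomformat::biom_data(b))
  expect_equal(m[rownames(tt$counts), colnames(tt$counts)],
               matrix(as.numeric(tt$counts), nrow(tt$counts),
                      dimnames = dimnames(tt$counts)))
})

test_that("aggregate_by_rank sums within rank and conserves column totals", {
  tt <- tiny_table()
  fam <- aggregate_by_rank(tt, "family")
  expect_equal(fam$counts["Poaceae", ], tt$counts["sp1", ] + tt$counts["sp2", ])
  expect_equal(fam$counts["unassigned", ], tt$counts["sp4", ])
  expect_equal(colSums(fam$counts), colSums(tt$counts))

  top <- aggregate_by_rank(tt, "family", top_k = 1)
  expect_setequal(rownames(top$counts), c("Poaceae", "other"))
  expect_equal(colSums(top$counts), colSums(tt$counts))
  expect_equal(top$counts["other", ],
               tt$counts["sp3", ] + tt$counts["sp4", ])

  expect_error(aggregate_by_rank(tt, "phylum"), "unknown rank")

  # no lineage at all: everything pools into one unassigned row
  bare <- random_table()
  agg <- aggregate_by_rank(bare, "family")
  expect_equal(nrow(agg$counts), 1)
  expect_equal(unname(agg$counts[1, ]), unname(colSums(bare$counts)))
})

test_that("prune_empty removes zero rows and, on request, zero columns", {
  m <- matrix(c(0L, 1L, 0L, 0L, 1L, 0L), 3,
              dimnames = list(c("a", "b", "c"), c("r1", "r2")))
  tt <- taxon_table(m)
  pr <- prune_empty(tt)
  expect_equal(rownames(pr$counts), "b")
  expect_identical(prune_empty(tiny_table())$counts, tiny_table()$counts)
  allzero <- taxon_table(matrix(0L, 2, 2,
                                dimnames = list(c("a", "b"), c("r1", "r2"))))
  expect_equal(nrow(prune_empty(allzero)$counts), 0)
  m2 <- matrix(c(1L, 0L), 1, 2, dimnames = list("a", c("r1", "r2")))
  expect_equal(ncol(prune_empty(taxon_table(m2),
                                drop_empty_replicates = TRUE)$counts), 1)
})

test_that("replicate metadata round-trips and is validated against tables", {
  meta <- replicate_metadata(c("r1", "r2", "r3"), c("E1", "E1", "control"),
                             "PITS", c("sample", "sample", "pcr_control"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_replicate_metadata(meta, p)
  expect_equal(as.data.frame(read_replicate_metadata(p)), as.data.frame(meta))
  expect_error(replicate_metadata("r1", "E1", "PITS", "blank"), "sample_type")
  expect_error(replicate_metadata(c("r1", "r1"), "E1", "PITS", "sample"),
               "duplicate")
  tt <- tiny_table()
  expect_error(prevalence_scores(tt, meta[1:2, ]), "missing from metadata")
})
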