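test_that("readTetradVcf filters by contig and keeps sample order", {
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"), c(
    "MT\t100\t.\tA\tG\t2000\t.\t.\tGT:RO:AO\t0:450:3\t1:2:380",
    "MT\t250\t.\tC\tT\t900\t.\t.\tGT:RO:AO\t0:100:5\t1:1:99",
    "MT\t400\t.\tT\tC\t800\t.\t.\tGT:RO:AO\t0:300:1\t0:200:0",
    "I\t55\t.\tG\tC\t800\t.\t.\tGT:RO:AO\t0:3:0\t1:0:4",
    "I\t90\t.\tG\tA\t700\t.\t.\tGT:RO:AO\t0:2:0\t1:0:5"))
  x <- suppressMessages(readTetradVcf(vcf, contig = "MT"))
  expect_equal(nrow(x), 3L)
  # oracle: non-header line count for the filtered contig
  expect_equal(nrow(x),
               sum(grepl("^MT\t", readLines(vcf))))
  expect_equal(colnames(x), c("s1", "s2"))
  expect_equal(GenomicRanges::start(rowRanges(x)), c(100L, 250L, 400L))
  xall <- suppressMessages(readTetradVcf(vcf))
  expect_equal(nrow(xall), 5L)
  expect_equal(unname(roCounts(x)[1, ]), c(450L, 2L))
  expect_equal(unname(calledAllele(x)[1, ]), c(0L, 1L))
})

test_that("a FORMAT without AO is a hard error naming the field", {
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"),
                     "MT\t100\t.\tA\tG\t2000\t.\t.\tGT:RO\t0:450\t1:2",
                     format = "GT:RO")
  expect_error(suppressMessages(readTetradVcf(vcf)), "AO")
})

test_that("unsorted VCF records are sorted with a warning", {
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"), c(
    "MT\t400\t.\tT\tC\t800\t.\t.\tGT:RO:AO\t0:300:1\t0:200:0",
    "MT\t100\t.\tA\tG\t2000\t.\t.\tGT:RO:AO\t0:450:3\t1:2:380"))
  expect_warning(x <- suppressMessages(readTetradVcf(vcf)), "sort")
  expect_equal(GenomicRanges::start(rowRanges(x)), c(100L, 400L))
})

test_that("emitDataset output round-trips through readTetradVcf", {
  cfg <- simConfig(n_tetrads = 2, seed = 11)
  out <- suppressMessages(emitDataset(cfg, tempfile("rt")))
  sim <- out$sim
  x <- suppressMessages(readTetradVcf(out$vcf))
  o <- order(factor(sim$sites$contig, levels = c("MT", "I")),
             sim$sites$pos)
  expect_equal(as.character(GenomeInfoDb::seqnames(rowRanges(x))),
               sim$sites$contig[o])
  expect_equal(GenomicRanges::start(rowRanges(x)), sim$sites$pos[o])
  expect_equal(rowData(x)$ref, sim$sites$ref[o])
  expect_equal(unlist(rowData(x)$alt, use.names = FALSE), sim$sites$alt[o])
  expect_equal(unname(roCounts(x)), unname(sim$RO[o, ]))
  expect_equal(unname(altObsCounts(x)),
               matrix(vapply(sim$AO[o, ], `[`, integer(1), 1L),
                      nrow = length(o)))
  expect_equal(unname(calledAllele(x)), unname(sim$GT[o, ]))
})

test_that("sample metadata parses, deduplicates crosses, and validates", {
  meta <- tempfile(fileext = ".tsv")
  df <- data.frame(
    sample_id = c("ctrl_P1", "ctrl_P2", "sp1", "sp2", "sp3", "sp4"),
    role = c("parent", "parent", rep("spore", 4)),
    strain_or_cross = c("P1", "P2", rep("X1", 4)),
    tetrad_id = c(NA, NA, rep("T1", 4)),
    spore_index = c(NA, NA, 1:4),
    parent1 = c(NA, NA, rep("P1", 4)),
    parent2 = c(NA, NA, rep("P2", 4)))
  write.table(df, meta, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  m <- suppressMessages(readSampleMetadata(meta))
  expect_equal(nrow(m$samples), 6L)
  expect_equal(m$crosses,
               data.frame(cross_id = "X1", parent1_strain = "P1",
                          parent2_strain = "P2"))

  df2 <- df; df2$spore_index[c(4, 5)] <- 2          # duplicate (T1, 2)
  write.table(df2, meta, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  expect_error(suppressMessages(readSampleMetadata(meta)), "duplicate")
})

test_that("metadata naming a sample absent from the VCF is rejected", {
  x <- makeCrossExperiment(pos = c(100, 200),
                           p1_allele = c("reference", "reference"),
                           spore_ro = matrix(10L, 2, 2),
                           spore_ao = matrix(0L, 2, 2))
  meta <- list(samples = S4Vectors::DataFrame(
    role = "spore", strain_or_cross = "X1", tetrad_id = "T9",
    spore_index = 1L, excluded = FALSE, exclusion_reason = NA_character_,
    row.names = "ghost_sample"), crosses = NULL)
  expect_error(addSampleMetadata(x, meta), "ghost_sample")
})

test_that("a cross without parental controls in the VCF is rejected", {
  x <- makeCrossExperiment(pos = c(100, 200),
                           p1_allele = c("reference", "reference"),
                           spore_ro = matrix(10L, 2, 2),
                           spore_ao = matrix(0L, 2, 2))
  cd <- colData(x)
  meta <- list(samples = cd,
               crosses = data.frame(cross_id = "X1",
                                    parent1_strain = "P1",
                                    parent2_strain = "P9"))
  expect_error(addSampleMetadata(x, meta), "P9")
})

test_that("the genotype table is long-format, byte-stable and round-trips", {
  x <- makeCrossExperiment(pos = c(100, 200),
                           p1_allele = c("reference", "alternate"),
                           spore_ro = matrix(c(10L, 0L), 2, 1),
                           spore_ao = matrix(c(0L, 12L), 2, 1))
  tb <- genotypeTable(x)
  expect_equal(nrow(tb), 2L * 3L)                     # sites x samples
  expect_setequal(unique(tb$called_allele), c("reference", "alternate"))
  f1 <- tempfile(); f2 <- tempfile()
  writeGenotypeTable(x, f1)
  writeGenotypeTable(x, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read.delim(f1)
  expect_equal(nrow(back), nrow(tb))
  expect_equal(back$ro, tb$ro)
  expect_equal(back$called_allele, tb$called_allele)

  # degenerate input: zero sites still writes a header-only file
  writeGenotypeTable(x[0, ], f1)
  expect_length(readLines(f1), 1L)
})
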