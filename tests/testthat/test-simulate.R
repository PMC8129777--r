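test_that("simulated markers are sorted, distinct and reproducible", {
  cfg <- simConfig()
  set.seed(10); m1 <- simulateMarkers(cfg)
  set.seed(10); m2 <- simulateMarkers(cfg)
  expect_length(m1$positions, 8L)
  expect_false(is.unsorted(m1$positions, strictly = TRUE))
  expect_identical(m1, m2)
  expect_true(all(m1$ref != m1$alt))
  # every marker segregates in >=1 cross; every cross has >=2 markers
  seg <- sapply(seq_len(nrow(cfg$crosses)), function(i)
    m1$carriers[cfg$crosses$parent1_strain[i], ] !=
      m1$carriers[cfg$crosses$parent2_strain[i], ])
  expect_true(all(rowSums(seg) >= 1))
  expect_true(all(colSums(seg) >= 2))
  expect_error(simulateMarkers(simConfig(genome_length = 20000,
                                         n_markers = 20001)),
               "genome_length")
})

test_that("tetrad ground truth respects the tethering limit cases", {
  cfg0 <- simConfig(p_mix = 0, p_self_mating = 0, p_spore_death = 0,
                    min_viable_spores = 0)
  set.seed(20)
  mk <- simulateMarkers(cfg0)
  tt <- simulateTetrad(cfg0, mk)
  fr <- t(vapply(tt$spores, `[[`, numeric(cfg0$n_markers), "p1frac"))
  expect_true(all(fr %in% c(0, 1)))
  expect_equal(unname(rowMeans(fr)), c(1, 1, 0, 0))   # 2:2 tethering
  expect_true(all(vapply(tt$spores, `[[`, logical(1), "viable")))

  # forced heavy mixing without crossover: frequencies near 1/2 everywhere
  cfg5 <- simConfig(p_mix = 1, mix_beta = c(1e6, 1e6), p_crossover = 0,
                    p_self_mating = 0)
  set.seed(21)
  mk5 <- simulateMarkers(cfg5)
  tt5 <- simulateTetrad(cfg5, mk5)
  fr5 <- unlist(lapply(tt5$spores, `[[`, "p1frac"))
  expect_true(all(abs(fr5 - 0.5) < 0.005))

  # self-mating: all four spores identical and pure
  cfgS <- simConfig(p_self_mating = 1)
  set.seed(22)
  mkS <- simulateMarkers(cfgS)
  ttS <- simulateTetrad(cfgS, mkS)
  frS <- t(vapply(ttS$spores, `[[`, numeric(cfgS$n_markers), "p1frac"))
  expect_equal(nrow(unique(frS)), 1L)
  expect_true(all(frS %in% c(0, 1)))
  expect_true(all(vapply(ttS$spores, `[[`, character(1), "source") == "self"))
})

test_that("mixed spores carry recombinant minor haplotypes with breakpoints", {
  cfg <- simConfig(p_mix = 1, p_crossover = 1, p_self_mating = 0,
                   crossover_count_mean = 1)
  set.seed(23)
  mk <- simulateMarkers(cfg)
  tt <- simulateTetrad(cfg, mk)
  for (sp in tt$spores) {
    expect_equal(sp$source, "mixed")
    expect_gte(length(sp$breakpoints), 1L)
    expect_true(all(sp$breakpoints > 1 & sp$breakpoints < cfg$genome_length))
    expect_false(is.unsorted(sp$breakpoints, strictly = TRUE))
    expect_true(all(sp$p1frac >= 0 & sp$p1frac <= 1))
  }
})

test_that("read simulation matches its binomial noise model", {
  cfg <- simConfig(fixed_depth = TRUE, depth_mean = 500, seq_error = 0)
  set.seed(30)
  r <- simulateReads(c(1, 0), cfg)
  expect_equal(r$ao, c(500L, 0L))
  expect_equal(r$ro, c(0L, 500L))

  # f = 0.5 at depth 1e6: observed fraction within 4 binomial SEs
  cfg2 <- simConfig(fixed_depth = TRUE, depth_mean = 1e6, seq_error = 0)
  r2 <- simulateReads(0.5, cfg2)
  expect_lt(abs(r2$ao / 1e6 - 0.5), 0.002)

  # f = 0 with error 1e-3 at depth 1e5: minor fraction within 4 SEs of e
  cfg3 <- simConfig(fixed_depth = TRUE, depth_mean = 1e5, seq_error = 0.001)
  r3 <- simulateReads(0, cfg3)
  se <- sqrt(0.001 * 0.999 / 1e5)
  expect_lt(abs(r3$ao / 1e5 - 0.001), 4 * se)
})

test_that("negative-binomial depth spans the intended coverage range", {
  cfg <- simConfig()
  q <- qnbinom(c(0.025, 0.975), size = cfg$depth_dispersion,
               mu = cfg$depth_mean)
  expect_lt(q[1], 250)
  expect_gt(q[1], 100)
  expect_gt(q[2], 900)
  expect_lt(q[2], 1400)
})

test_that("emitted dataset is consistent with truth and seed-reproducible", {
  cfg <- simConfig(n_tetrads = 2, seed = 77)
  d1 <- tempfile("em1"); d2 <- tempfile("em2")
  o1 <- suppressMessages(emitDataset(cfg, d1))
  o2 <- suppressMessages(emitDataset(cfg, d2))
  truth <- read.delim(o1$truth_spores)
  meta <- read.delim(o1$metadata)
  n_strain <- length(unique(c(cfg$crosses$parent1_strain,
                              cfg$crosses$parent2_strain)))
  expect_equal(sum(meta$role == "spore"), sum(truth$viable))
  expect_equal(nrow(meta), n_strain + sum(truth$viable))
  vcf_samples <- strsplit(grep("^#CHROM", readLines(o1$vcf), value = TRUE),
                          "\t")[[1]][-(1:9)]
  expect_setequal(vcf_samples, meta$sample_id)
  for (f in c("sim.vcf", "metadata.tsv", "truth_spores.tsv",
              "truth_markers.tsv", "truth_freq.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("a zero-tetrad dataset contains parental controls only", {
  out <- suppressMessages(emitDataset(simConfig(n_tetrads = 0, seed = 3),
                                      tempfile("em0")))
  meta <- read.delim(out$metadata)
  expect_true(all(meta$role == "parent"))
  expect_gt(nrow(meta), 0L)
})
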