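test_that("marker orientation follows the parental control calls", {
  # site 1: P1 reference / P2 alternate -> parent1_allele reference
  # site 2: P1 alternate / P2 reference -> parent1_allele alternate
  x <- makeCrossExperiment(pos = c(100, 5000),
                           p1_allele = c("reference", "alternate"),
                           spore_ro = matrix(c(10L, 0L), 2, 1),
                           spore_ao = matrix(c(0L, 12L), 2, 1))
  mk <- suppressMessages(deriveMarkers(x))
  expect_equal(nrow(mk), 2L)
  expect_equal(mk$parent1_allele, c("reference", "alternate"))
  expect_equal(mk$parent2_allele, c("alternate", "reference"))
  expect_equal(mk$pos, c(100L, 5000L))
})

test_that("non-segregating sites yield no marker; impure parents are skipped", {
  # both parents reference at site 1; P1 impure (300:100) at site 2
  ids <- c("ctrl_P1", "ctrl_P2", "sp1")
  RO <- matrix(c(400L, 350L, 20L,
                 300L, 0L, 5L), 2, 3, byrow = TRUE,
               dimnames = list(NULL, ids))
  AO <- matrix(list(0L, 0L, 0L,
                    100L, 380L, 15L), 2, 3, byrow = TRUE,
               dimnames = list(NULL, ids))
  GT <- matrix(c(0L, 0L, 0L, 0L, 1L, 1L), 2, 3, byrow = TRUE,
               dimnames = list(NULL, ids))
  cd <- S4Vectors::DataFrame(
    role = c("parent", "parent", "spore"),
    strain_or_cross = c("P1", "P2", "X1"),
    tetrad_id = c(NA, NA, "T1"), spore_index = c(NA, NA, 1L),
    excluded = FALSE, exclusion_reason = NA_character_,
    row.names = ids)
  x <- makeExperiment("MT", c(100, 200), c("A", "C"), list("G", "T"),
                      c(999, 999), GT, RO, AO, samples = cd,
                      crosses = data.frame(cross_id = "X1",
                                           parent1_strain = "P1",
                                           parent2_strain = "P2"))
  expect_warning(mk <- suppressMessages(deriveMarkers(x)),
                 "contamination")
  expect_equal(nrow(mk), 0L)       # site 1 non-segregating, site 2 impure
  # at purity 0.7 the 0.75-major-fraction parent is accepted, and its
  # major allele (reference) fixes the orientation
  mk2 <- suppressMessages(deriveMarkers(x, purity = 0.7))
  expect_equal(mk2$pos, 200L)
  expect_equal(mk2$parent1_allele, "reference")
})

test_that("a cross with controls uncalled everywhere is a hard error", {
  x <- makeCrossExperiment(pos = c(100, 200),
                           p1_allele = c("reference", "reference"),
                           spore_ro = matrix(10L, 2, 1),
                           spore_ao = matrix(0L, 2, 1),
                           parent_depth = 0L)
  expect_error(suppressMessages(deriveMarkers(x)), "X1")
})

test_that("derived markers match simulator truth exactly without noise", {
  cfg <- simConfig(n_tetrads = 3, seq_error = 0, fixed_depth = TRUE,
                   depth_mean = 1000, seed = 5)
  sim <- suppressMessages(simulateDataset(cfg))
  x <- asExperiment(sim)
  xf <- suppressMessages(filterSites(x))
  mito <- xf[as.character(GenomeInfoDb::seqnames(rowRanges(xf))) == "MT", ]
  mk <- suppressMessages(deriveMarkers(mito))
  want <- sim$truth$markers[, c("cross_id", "pos", "parent1_allele")]
  got <- mk[, c("cross_id", "pos", "parent1_allele")]
  o1 <- order(want$cross_id, want$pos); o2 <- order(got$cross_id, got$pos)
  expect_equal(got[o2, ], want[o1, ], ignore_attr = TRUE)
})

test_that("self-mated tetrads are flagged and excluded; 2:2 tetrads are not", {
  # one tetrad uniformly parent1 at 12 nuclear sites, one split 2:2
  n <- 12
  mkNuc <- function(sp_from_p1) {
    # parent1 carries alt everywhere
    ids <- c("ctrl_P1", "ctrl_P2", colnames(sp_from_p1))
    ro <- ao <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
    ao[, 1] <- 6L; ro[, 2] <- 6L
    for (j in seq_len(ncol(sp_from_p1))) {
      ao[, 2 + j] <- ifelse(sp_from_p1[, j], 5L, 0L)
      ro[, 2 + j] <- ifelse(sp_from_p1[, j], 0L, 5L)
    }
    gt <- matrix(NA_integer_, n, length(ids), dimnames = list(NULL, ids))
    dep <- ro + ao
    gt[dep > 0] <- as.integer(ao[dep > 0] > ro[dep > 0])
    cd <- rbind(
      S4Vectors::DataFrame(role = "parent",
                           strain_or_cross = c("P1", "P2"),
                           tetrad_id = NA_character_,
                           spore_index = NA_integer_, excluded = FALSE,
                           exclusion_reason = NA_character_,
                           row.names = c("ctrl_P1", "ctrl_P2")),
      S4Vectors::DataFrame(role = "spore", strain_or_cross = "X1",
                           tetrad_id = sub("_s.*", "", colnames(sp_from_p1)),
                           spore_index = rep(1:4, 2), excluded = FALSE,
                           exclusion_reason = NA_character_,
                           row.names = colnames(sp_from_p1)))
    makeExperiment("I", seq(1000, by = 1000, length.out = n),
                   rep("A", n), as.list(rep("G", n)), rep(999, n),
                   gt, ro, ao, samples = cd,
                   crosses = data.frame(cross_id = "X1",
                                        parent1_strain = "P1",
                                        parent2_strain = "P2"))
  }
  sp <- matrix(c(rep(TRUE, 4), rep(c(TRUE, TRUE, FALSE, FALSE), each = 1)),
               nrow = n, ncol = 8, byrow = TRUE)
  # first 4 columns: tetrad Tself, all parent1; last 4: T22, split 2:2
  sp[, 1:4] <- TRUE
  sp[, 5:8] <- matrix(rep(c(TRUE, TRUE, FALSE, FALSE), each = n), n, 4)
  colnames(sp) <- c(paste0("Tself_s", 1:4), paste0("T22_s", 1:4))
  x <- mkNuc(sp)
  nm <- suppressMessages(deriveMarkers(x))
  x2 <- suppressMessages(flagSelfMating(x, nm, min_informative = 10))
  fl <- metadata(x2)$selfMating
  expect_true(fl$self_mated[fl$tetrad_id == "Tself"])
  expect_false(fl$self_mated[fl$tetrad_id == "T22"])
  cd <- colData(x2)
  expect_true(all(cd[paste0("Tself_s", 1:4), "excluded"]))
  expect_equal(unique(cd[paste0("Tself_s", 1:4), "exclusion_reason"]),
               "self-mating")
  expect_false(any(cd[paste0("T22_s", 1:4), "excluded"]))
})

test_that("too few informative nuclear calls leaves a tetrad unassessed", {
  x <- makeCrossExperiment(pos = c(100, 200, 300, 400),
                           p1_allele = rep("alternate", 4),
                           spore_ro = matrix(0L, 4, 1),
                           spore_ao = matrix(8L, 4, 1),
                           contig = "I")
  nm <- suppressMessages(deriveMarkers(x))
  expect_warning(x2 <- suppressMessages(flagSelfMating(x, nm,
                                                       min_informative = 10)),
                 "informative")
  expect_false(metadata(x2)$selfMating$self_mated)
  expect_false(any(colData(x2)$excluded))
})
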