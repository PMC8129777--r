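#' Simulation configuration for tethered mitochondrial inheritance
#'
#' Parameters of the ground-truthed tetrad-sequencing generator. Defaults
#' describe a study-scale experiment: three crosses sharing one wild
#' strain, 11 tetrads each, 8 biallelic mitochondrial markers, mean
#' mitochondrial coverage 500x with negative-binomial dispersion giving a
#' central 95% depth range of roughly 200-1000x, and tetrads selected for
#' at least three viable spores (as in dissection practice).
#'
#' The inheritance model: spores 1-2 of a tetrad inherit parent 1's
#' mitochondria and spores 3-4 parent 2's (tethered 2:2 baseline).
#' Independently per spore, with probability `p_mix` the spore instead
#' carries a mixed mitochondrial population whose minor-parent genome
#' fraction is Beta(`mix_beta`)-distributed, and with probability
#' `p_crossover` that minor contribution is a recombinant haplotype with
#' `K ~ Poisson(crossover_count_mean)` breakpoints (`K >= 1` enforced by
#' resampling, breakpoints uniform on the genome). With probability
#' `p_clean_recombinant` a spore's *entire* population carries a
#' recombinant haplotype instead. Whole tetrads are self-mated with
#' probability `p_self_mating` (all spores then carry one uniformly chosen
#' parent's alleles at every mitochondrial and nuclear site). A small panel
#' of 2:2-segregating nuclear marker sites is generated alongside, at low
#' nuclear coverage, to exercise self-mating detection.
#'
#' @param genome_length mitochondrial genome length in bp (default 20000).
#' @param n_markers number of biallelic mitochondrial SNP markers
#'   (default 8).
#' @param crosses cross design `data.frame` (`cross_id`, `parent1_strain`,
#'   `parent2_strain`); default three crosses sharing wild strain `wildA`.
#' @param n_tetrads tetrads per cross (default 11).
#' @param depth_mean expected mitochondrial coverage (default 500).
#' @param depth_dispersion negative-binomial size parameter (default 6;
#'   `Inf` gives Poisson depth).
#' @param fixed_depth when `TRUE`, every call gets exactly the mean depth.
#' @param seq_error per-read allele misassignment probability
#'   (default 0.001).
#' @param p_mix probability a spore carries a mixed population
#'   (default 0.15).
#' @param mix_beta Beta shape parameters for the minor-parent fraction
#'   (default `c(1.5, 4.5)`).
#' @param p_crossover probability the minor contribution of a mixed spore
#'   is recombinant (default 1).
#' @param crossover_count_mean Poisson mean for breakpoints (default 1).
#' @param p_clean_recombinant probability of an unmixed fully recombinant
#'   spore (default 0).
#' @param p_spore_death per-spore inviability probability (default 0.35).
#' @param min_viable_spores tetrads are redrawn until at least this many
#'   spores are viable (default 3, emulating dissection selection; 0
#'   disables).
#' @param p_self_mating per-tetrad self-mating probability (default 0.09).
#' @param n_nuclear_markers nuclear marker sites (default 12).
#' @param nuclear_depth_mean expected nuclear coverage (default 5).
#' @param nuclear_genome_length nuclear contig length (default 100000).
#' @param mito_contig,nuclear_contig contig names (defaults `"MT"`, `"I"`).
#' @param seed integer RNG seed (default 1).
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(genome_length = 20000, n_markers = 8,
                      crosses = NULL, n_tetrads = 11,
                      depth_mean = 500, depth_dispersion = 6,
                      fixed_depth = FALSE, seq_error = 0.001,
                      p_mix = 0.15, mix_beta = c(1.5, 4.5),
                      p_crossover = 1, crossover_count_mean = 1,
                      p_clean_recombinant = 0,
                      p_spore_death = 0.35, min_viable_spores = 3,
                      p_self_mating = 0.09,
                      n_nuclear_markers = 12, nuclear_depth_mean = 5,
                      nuclear_genome_length = 100000,
                      mito_contig = "MT", nuclear_contig = "I",
                      seed = 1) {
  if (is.null(crosses))
    crosses <- data.frame(
      cross_id = c("wildAxlabA", "wildAxlabB", "wildAxwildB"),
      parent1_strain = "wildA",
      parent2_strain = c("labA", "labB", "wildB"),
      stringsAsFactors = FALSE)
  cfg <- list(genome_length = genome_length, n_markers = n_markers,
              crosses = crosses, n_tetrads = n_tetrads,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              fixed_depth = fixed_depth, seq_error = seq_error,
              p_mix = p_mix, mix_beta = mix_beta,
              p_crossover = p_crossover,
              crossover_count_mean = crossover_count_mean,
              p_clean_recombinant = p_clean_recombinant,
              p_spore_death = p_spore_death,
              min_viable_spores = min_viable_spores,
              p_self_mating = p_self_mating,
              n_nuclear_markers = n_nuclear_markers,
              nuclear_depth_mean = nuclear_depth_mean,
              nuclear_genome_length = nuclear_genome_length,
              mito_contig = mito_contig, nuclear_contig = nuclear_contig,
              seed = seed)
  probs <- c(cfg$seq_error, cfg$p_mix, cfg$p_crossover,
             cfg$p_clean_recombinant, cfg$p_spore_death, cfg$p_self_mating)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (cfg$n_markers < 2) stop("n_markers must be >= 2")
  if (cfg$n_markers > cfg$genome_length)
    stop("n_markers exceeds genome_length")
  if (cfg$depth_mean <= 0) stop("depth_mean must be > 0")
  if (cfg$p_spore_death >= 1 && cfg$min_viable_spores > 0)
    stop("p_spore_death = 1 is incompatible with min_viable_spores > 0")
  if (any(cfg$crosses$parent1_strain == cfg$crosses$parent2_strain))
    stop("each cross needs two distinct parental strains")
  structure(cfg, class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", nrow(x$crosses), "crosses x", x$n_tetrads, "tetrads;",
      x$n_markers, "mito markers on", x$mito_contig,
      sprintf("(L=%d)", x$genome_length), "\n")
  cat(sprintf("  depth %g (NB size %g%s), seq_error %g\n", x$depth_mean,
              x$depth_dispersion, if (x$fixed_depth) ", fixed" else "",
              x$seq_error))
  cat(sprintf("  p_mix %g Beta(%g,%g), p_crossover %g, p_spore_death %g, p_self_mating %g, seed %d\n",
              x$p_mix, x$mix_beta[1], x$mix_beta[2], x$p_crossover,
              x$p_spore_death, x$p_self_mating, x$seed))
  invisible(x)
}

.randomBases <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  list(ref = ref, alt = alt)
}

# carrier matrix (strains x markers, TRUE = alternate allele) such that
# every marker segregates in >=1 cross and every cross has >= min_seg
# segregating markers
.sampleCarriers <- function(strains, n_markers, crosses, min_seg,
                            max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    carriers <- matrix(stats::runif(length(strains) * n_markers) < 0.5,
                       nrow = length(strains),
                       dimnames = list(strains, NULL))
    seg <- sapply(seq_len(nrow(crosses)), function(ci) {
      carriers[crosses$parent1_strain[ci], ] !=
        carriers[crosses$parent2_strain[ci], ]
    })                                      # markers x crosses
    seg <- matrix(seg, nrow = n_markers)
    if (all(rowSums(seg) >= 1) && all(colSums(seg) >= min_seg))
      return(carriers)
  }
  stop("could not sample a marker carrier configuration; ",
       "check crosses/n_markers")
}

#' Simulate parental mitochondrial marker haplotypes
#'
#' Draws `n_markers` distinct positions uniformly without replacement
#' (sorted), assigns ref/alt nucleotides, and assigns each marker's
#' alternate allele to a subset of parental strains such that every marker
#' segregates in at least one cross and every cross segregates at two or
#' more markers.
#'
#' @param config a [simConfig()] object. Uses the current RNG state; seed
#'   it with `set.seed()` or use [simulateDataset()].
#' @return a list: `positions`, `ref`, `alt`, `carriers` (strains x markers
#'   logical matrix, `TRUE` = strain carries the alternate allele).
#' @export
simulateMarkers <- function(config) {
  if (config$n_markers > config$genome_length)
    stop("n_markers exceeds genome_length")
  pos <- sort(sample.int(config$genome_length, config$n_markers))
  bases <- .randomBases(config$n_markers)
  strains <- unique(c(config$crosses$parent1_strain,
                      config$crosses$parent2_strain))
  carriers <- .sampleCarriers(strains, config$n_markers, config$crosses,
                              min_seg = 2L)
  list(positions = pos, ref = bases$ref, alt = bases$alt,
       carriers = carriers)
}

# expected marker table per cross (the generator's ground truth for
# deriveMarkers recovery): segregating sites only, with orientation
markerTruthTable <- function(markers, crosses, contig) {
  out <- lapply(seq_len(nrow(crosses)), function(ci) {
    p1 <- markers$carriers[crosses$parent1_strain[ci], ]
    p2 <- markers$carriers[crosses$parent2_strain[ci], ]
    seg <- which(p1 != p2)
    data.frame(cross_id = rep(crosses$cross_id[ci], length(seg)),
               contig = rep(contig, length(seg)),
               pos = markers$positions[seg], ref = markers$ref[seg],
               alt = markers$alt[seg],
               parent1_allele = ifelse(p1[seg], "alternate", "reference"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# haplotype parentage of a recombinant chromosome at each marker: starts
# at `start_parent` on the left, switches at each breakpoint
.segmentParent <- function(positions, breakpoints, start_parent, other_parent) {
  nsw <- vapply(positions, function(p) sum(breakpoints < p), integer(1))
  ifelse(nsw %% 2L == 0L, start_parent, other_parent)
}

#' Simulate the ground truth of one tetrad
#'
#' Applies the tethered-inheritance model (see [simConfig()]) to one
#' tetrad of one cross and returns the per-spore ground truth. Uses the
#' current RNG state.
#'
#' @param config a [simConfig()] object.
#' @param markers marker haplotypes from [simulateMarkers()].
#' @param cross_ix row index into `config$crosses`.
#' @return a list of 4 spores; each has `source` (`"parent1"`,
#'   `"parent2"`, `"mixed"`, `"self"`), `minor_fraction`, `breakpoints`
#'   (numeric, possibly empty), `viable`, and `p1frac` — the true fraction
#'   of parent-1 genomes at each marker. The tetrad-level element
#'   `self_parent` is 0 for a genuine cross, otherwise the selfed parent
#'   index.
#' @export
simulateTetrad <- function(config, markers, cross_ix = 1L) {
  n <- config$n_markers
  self <- stats::runif(1) < config$p_self_mating
  self_parent <- if (self) sample(1:2, 1) else 0L
  spores <- vector("list", 4L)
  for (k in 1:4) {
    if (self) {
      sp <- list(source = "self", minor_fraction = 0,
                 breakpoints = numeric(0),
                 p1frac = rep(if (self_parent == 1L) 1 else 0, n))
    } else {
      base_p1 <- k <= 2L                      # tethered 2:2 baseline
      mixed <- stats::runif(1) < config$p_mix
      clean_rec <- !mixed && config$p_clean_recombinant > 0 &&
        stats::runif(1) < config$p_clean_recombinant
      if (mixed) {
        m <- stats::rbeta(1, config$mix_beta[1], config$mix_beta[2])
        rec <- stats::runif(1) < config$p_crossover
        bp <- numeric(0)
        # minor-parent fraction of parent-1 genomes at each marker
        if (rec) {
          K <- 0L
          while (K < 1L) K <- stats::rpois(1, config$crossover_count_mean)
          bp <- sort(stats::runif(K, 1, config$genome_length))
          seg_p1 <- .segmentParent(markers$positions, bp,
                                   start_parent = !base_p1,
                                   other_parent = base_p1)
        } else {
          seg_p1 <- rep(!base_p1, n)
        }
        p1frac <- (1 - m) * as.numeric(base_p1) + m * as.numeric(seg_p1)
        sp <- list(source = "mixed", minor_fraction = m, breakpoints = bp,
                   p1frac = p1frac)
      } else if (clean_rec) {
        K <- 0L
        while (K < 1L) K <- stats::rpois(1, config$crossover_count_mean)
        bp <- sort(stats::runif(K, 1, config$genome_length))
        seg_p1 <- .segmentParent(markers$positions, bp,
                                 start_parent = base_p1,
                                 other_parent = !base_p1)
        sp <- list(source = "mixed", minor_fraction = 0, breakpoints = bp,
                   p1frac = as.numeric(seg_p1))
      } else {
        sp <- list(source = if (base_p1) "parent1" else "parent2",
                   minor_fraction = 0, breakpoints = numeric(0),
                   p1frac = rep(as.numeric(base_p1), n))
      }
    }
    sp$viable <- TRUE
    spores[[k]] <- sp
  }
  # inviability, with dissection-style selection for viable tetrads
  repeat {
    viable <- stats::runif(4) >= config$p_spore_death
    if (sum(viable) >= config$min_viable_spores) break
  }
  for (k in 1:4) spores[[k]]$viable <- viable[k]
  list(spores = spores, self_parent = self_parent)
}

#' Simulate observation counts from true allele frequencies
#'
#' Sequencing depth is negative-binomial with the configured mean and
#' dispersion (Poisson when dispersion is infinite; exactly the mean when
#' `fixed_depth`). The alternate-allele read count is binomial with
#' success probability `q(1-e) + (1-q)e` where `q` is the true alternate
#' frequency and `e` the per-read error.
#'
#' @param q true alternate-allele frequencies (vector).
#' @param config a [simConfig()] object.
#' @param depth_mean override for the expected depth (defaults to
#'   `config$depth_mean`; the nuclear panel uses
#'   `config$nuclear_depth_mean`).
#' @return a list of integer vectors `ro`, `ao`.
#' @export
simulateReads <- function(q, config, depth_mean = config$depth_mean) {
  stopifnot(all(q >= 0 & q <= 1))
  n <- length(q)
  d <- if (config$fixed_depth) {
    rep(as.integer(round(depth_mean)), n)
  } else if (is.infinite(config$depth_dispersion)) {
    stats::rpois(n, depth_mean)
  } else {
    stats::rnbinom(n, size = config$depth_dispersion, mu = depth_mean)
  }
  e <- config$seq_error
  p <- q * (1 - e) + (1 - q) * e
  ao <- stats::rbinom(n, d, p)
  list(ro = as.integer(d - ao), ao = as.integer(ao))
}

#' Simulate a complete tetrad-sequencing dataset in memory
#'
#' Seeds the RNG from `config$seed` and generates, in a fixed documented
#' order (mitochondrial markers, nuclear markers, site qualities, per-tetrad
#' ground truth, then per-sample read counts in final sample order), the
#' parental-control and viable-spore genotype calls plus full ground truth.
#'
#' @param config a [simConfig()] object.
#' @return a list: `sites` (site table: `contig`, `pos`, `ref`, `alt`,
#'   `qual`), `GT`/`RO`/`AO` matrices (sites x samples; `AO` a list-matrix),
#'   `samples` (metadata `data.frame` matching [readSampleMetadata()]'s
#'   schema), `truth` (list of `spores`, `markers`, `nuclear_markers`,
#'   `freq` tables), and `config`.
#' @export
simulateDataset <- function(config) {
  set.seed(config$seed)
  crosses <- config$crosses
  strains <- unique(c(crosses$parent1_strain, crosses$parent2_strain))

  mito <- simulateMarkers(config)
  # nuclear panel: every cross segregates at every site
  nuc_pos <- sort(sample.int(config$nuclear_genome_length,
                             config$n_nuclear_markers))
  nuc_bases <- .randomBases(config$n_nuclear_markers)
  nuc_carriers <- matrix(FALSE, length(strains), config$n_nuclear_markers,
                         dimnames = list(strains, NULL))
  for (j in seq_len(config$n_nuclear_markers)) {
    repeat {
      cj <- stats::setNames(stats::runif(length(strains)) < 0.5, strains)
      seg <- all(cj[crosses$parent1_strain] != cj[crosses$parent2_strain])
      if (seg) break
    }
    nuc_carriers[, j] <- cj
  }
  nuc <- list(positions = nuc_pos, ref = nuc_bases$ref, alt = nuc_bases$alt,
              carriers = nuc_carriers)

  n_mito <- config$n_markers
  n_nuc <- config$n_nuclear_markers
  qual <- round(stats::runif(n_mito + n_nuc, 300, 4000), 1)

  # ground truth for every tetrad
  truth_spores <- list(); truth_freq <- list()
  spore_meta <- list()
  qs_mito <- list(); qs_nuc <- list()           # per viable spore
  for (ci in seq_len(nrow(crosses))) {
    cid <- crosses$cross_id[ci]
    p1 <- crosses$parent1_strain[ci]; p2 <- crosses$parent2_strain[ci]
    alt1 <- mito$carriers[p1, ]; alt2 <- mito$carriers[p2, ]
    nalt1 <- nuc$carriers[p1, ]; nalt2 <- nuc$carriers[p2, ]
    for (t in seq_len(config$n_tetrads)) {
      tid <- sprintf("%s_T%02d", cid, t)
      tt <- simulateTetrad(config, mito, ci)
      # nuclear 2:2 assignment per site (TRUE = parent1 allele)
      nuc_from_p1 <- matrix(FALSE, 4, n_nuc)
      if (tt$self_parent > 0L) {
        nuc_from_p1[] <- tt$self_parent == 1L
      } else {
        for (j in seq_len(n_nuc))
          nuc_from_p1[, j] <- sample(c(TRUE, TRUE, FALSE, FALSE))
      }
      for (k in 1:4) {
        sp <- tt$spores[[k]]
        sid <- if (sp$viable) sprintf("%s_S%d", tid, k) else NA_character_
        truth_spores[[length(truth_spores) + 1L]] <- data.frame(
          cross_id = cid, tetrad_id = tid, spore_index = k,
          sample_id = sid, source = sp$source,
          minor_fraction = sp$minor_fraction,
          breakpoints = paste(round(sp$breakpoints, 1), collapse = ","),
          viable = sp$viable, stringsAsFactors = FALSE)
        truth_freq[[length(truth_freq) + 1L]] <- data.frame(
          tetrad_id = tid, spore_index = k, pos = mito$positions,
          parent1_genome_fraction = sp$p1frac,
          alt_freq = sp$p1frac * as.numeric(alt1) +
            (1 - sp$p1frac) * as.numeric(alt2),
          stringsAsFactors = FALSE)
        if (sp$viable) {
          spore_meta[[length(spore_meta) + 1L]] <- data.frame(
            sample_id = sid, role = "spore", strain_or_cross = cid,
            tetrad_id = tid, spore_index = k,
            parent1 = p1, parent2 = p2, stringsAsFactors = FALSE)
          qs_mito[[sid]] <- sp$p1frac * as.numeric(alt1) +
            (1 - sp$p1frac) * as.numeric(alt2)
          qs_nuc[[sid]] <- ifelse(nuc_from_p1[k, ], as.numeric(nalt1),
                                  as.numeric(nalt2))
        }
      }
    }
  }

  if (!length(truth_spores)) {
    truth_spores <- list(data.frame(
      cross_id = character(), tetrad_id = character(),
      spore_index = integer(), sample_id = character(),
      source = character(), minor_fraction = numeric(),
      breakpoints = character(), viable = logical()))
    truth_freq <- list(data.frame(
      tetrad_id = character(), spore_index = integer(), pos = integer(),
      parent1_genome_fraction = numeric(), alt_freq = numeric()))
  }
  ctrl_meta <- data.frame(sample_id = paste0("ctrl_", strains),
                          role = "parent", strain_or_cross = strains,
                          tetrad_id = NA_character_, spore_index = NA_integer_,
                          parent1 = NA_character_, parent2 = NA_character_,
                          stringsAsFactors = FALSE)
  spore_meta <- if (length(spore_meta)) do.call(rbind, spore_meta) else
    ctrl_meta[0, , drop = FALSE]
  samples <- rbind(ctrl_meta, spore_meta)

  # read counts, sample-major in final column order
  n_site <- n_mito + n_nuc
  RO <- AOv <- matrix(0L, n_site, nrow(samples),
                      dimnames = list(NULL, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    if (samples$role[s] == "parent") {
      st <- samples$strain_or_cross[s]
      qm <- as.numeric(mito$carriers[st, ])
      qn <- as.numeric(nuc$carriers[st, ])
    } else {
      qm <- qs_mito[[sid]]; qn <- qs_nuc[[sid]]
    }
    rm_ <- simulateReads(qm, config)
    rn_ <- simulateReads(qn, config, depth_mean = config$nuclear_depth_mean)
    RO[, s] <- c(rm_$ro, rn_$ro)
    AOv[, s] <- c(rm_$ao, rn_$ao)
  }
  depth <- RO + AOv
  GT <- matrix(NA_integer_, n_site, nrow(samples),
               dimnames = dimnames(RO))
  GT[depth > 0] <- as.integer(AOv[depth > 0] > RO[depth > 0])
  AO <- matrix(lapply(as.vector(AOv), identity), n_site,
               dimnames = dimnames(RO))

  sites <- data.frame(
    contig = c(rep(config$mito_contig, n_mito),
               rep(config$nuclear_contig, n_nuc)),
    pos = c(mito$positions, nuc$positions),
    ref = c(mito$ref, nuc$ref), alt = c(mito$alt, nuc$alt),
    qual = qual, stringsAsFactors = FALSE)

  truth <- list(
    spores = do.call(rbind, truth_spores),
    markers = markerTruthTable(mito, crosses, config$mito_contig),
    nuclear_markers = markerTruthTable(nuc, crosses, config$nuclear_contig),
    freq = do.call(rbind, truth_freq))
  logStage("simulate", crosses = nrow(crosses),
           tetrads = nrow(crosses) * config$n_tetrads,
           viable_spores = nrow(spore_meta), sites = n_site)
  list(sites = sites, GT = GT, RO = RO, AO = AO, samples = samples,
       truth = truth, config = config)
}

#' Convert an in-memory simulation to a MitoTetradExperiment
#'
#' @param sim output of [simulateDataset()].
#' @return a [MitoTetradExperiment] with metadata attached, equivalent to
#'   writing the dataset out with [emitDataset()] and reading it back.
#' @export
asExperiment <- function(sim) {
  sites <- sim$sites
  rr <- GRanges(sites$contig, IRanges::IRanges(sites$pos, sites$pos))
  mcols(rr) <- S4Vectors::DataFrame(
    ref = sites$ref,
    alt = methods::as(as.list(sites$alt), "CharacterList"),
    qual = sites$qual,
    varClass = "SNP")
  cd <- S4Vectors::DataFrame(
    role = sim$samples$role,
    strain_or_cross = sim$samples$strain_or_cross,
    tetrad_id = sim$samples$tetrad_id,
    spore_index = sim$samples$spore_index,
    excluded = FALSE, exclusion_reason = NA_character_,
    row.names = sim$samples$sample_id)
  x <- MitoTetradExperiment(rr, sim$GT, sim$RO, sim$AO, colData = cd,
                            crosses = sim$config$crosses)
  o <- order(factor(sites$contig,
                    levels = c(sim$config$mito_contig,
                               sim$config$nuclear_contig)),
             sites$pos)
  x[o, ]
}

#' Write a simulated dataset to disk as VCF + TSV files
#'
#' Emits a VCF 4.2 with per-sample `GT:RO:AO` fields (parental controls
#' and viable spores), the colony metadata TSV, and the ground-truth
#' tables. Identical seeds give byte-identical files.
#'
#' @param config a [simConfig()] object.
#' @param outdir output directory (created if needed).
#' @return (invisibly) a list of file paths plus the in-memory simulation
#'   (`sim`).
#' @export
emitDataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateDataset(config)
  vcf_path <- file.path(outdir, "sim.vcf")
  meta_path <- file.path(outdir, "metadata.tsv")

  o <- order(factor(sim$sites$contig,
                    levels = c(config$mito_contig, config$nuclear_contig)),
             sim$sites$pos)
  sites <- sim$sites[o, , drop = FALSE]
  GT <- sim$GT[o, , drop = FALSE]
  RO <- sim$RO[o, , drop = FALSE]
  AOv <- matrix(vapply(sim$AO[o, , drop = FALSE], `[`, integer(1), 1L),
                nrow = length(o), dimnames = dimnames(RO))
  gt_chr <- ifelse(is.na(GT), ".", as.character(GT))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    calls <- sprintf("%s:%d:%d", gt_chr[i, ], RO[i, ], AOv[i, ])
    paste(c(sites$contig[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            format(sites$qual[i], trim = TRUE), ".", ".", "GT:RO:AO", calls),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mitotetrad-simulator",
    sprintf("##contig=<ID=%s,length=%d>", config$mito_contig,
            config$genome_length),
    sprintf("##contig=<ID=%s,length=%d>", config$nuclear_contig,
            config$nuclear_genome_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"Reference allele observation count\">",
    "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observation count\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(GT)), collapse = "\t"))
  writeLines(c(header, body), vcf_path)
  writeTsv(sim$samples, meta_path)
  paths <- list(
    vcf = vcf_path, metadata = meta_path,
    truth_spores = writeTsv(sim$truth$spores,
                            file.path(outdir, "truth_spores.tsv")),
    truth_markers = writeTsv(sim$truth$markers,
                             file.path(outdir, "truth_markers.tsv")),
    truth_nuclear_markers = writeTsv(
      sim$truth$nuclear_markers,
      file.path(outdir, "truth_nuclear_markers.tsv")),
    truth_freq = writeTsv(sim$truth$freq,
                          file.path(outdir, "truth_freq.tsv")))
  logStage("emit_dataset", dir = outdir,
           samples = ncol(GT), sites = nrow(sites))
  invisible(c(paths, list(dir = outdir, sim = sim)))
}
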