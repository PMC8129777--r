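# programmatic fixtures; no files are shipped

# build a MitoTetradExperiment directly from plain vectors
makeExperiment <- function(contig, pos, ref, alt, qual, GT, RO, AO,
                           samples = NULL, crosses = NULL) {
  n <- length(pos)
  stopifnot(is.list(alt))
  rr <- GenomicRanges::GRanges(
    contig, IRanges::IRanges(pos, pos + nchar(ref) - 1L))
  S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
    ref = ref, alt = methods::as(alt, "CharacterList"), qual = qual,
    varClass = vapply(seq_len(n),
                      function(i) mitotetrad:::classifyVariant(ref[i], alt[[i]]),
                      character(1)))
  if (!is.list(AO)) AO <- matrix(lapply(AO, identity), nrow = nrow(RO),
                                 dimnames = dimnames(RO))
  MitoTetradExperiment(rr, GT, RO, AO, colData = samples, crosses = crosses)
}

# random biallelic-heavy experiment for filter property tests
randomExperiment <- function(n_sites = 20, n_samples = 6) {
  pos <- sort(sample.int(5000, n_sites))
  kinds <- sample(c("snp", "indel", "multi"), n_sites, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1))
  ref <- ifelse(kinds == "indel", "ATT", "A")
  alt <- lapply(kinds, function(k)
    switch(k, snp = "G", indel = "A", multi = c("G", "T")))
  qual <- round(stats::runif(n_sites, 0, 100), 1)
  sid <- sprintf("s%02d", seq_len(n_samples))
  RO <- matrix(stats::rpois(n_sites * n_samples, 20), n_sites,
               dimnames = list(NULL, sid))
  AOv <- matrix(stats::rpois(n_sites * n_samples, 5), n_sites,
                dimnames = list(NULL, sid))
  AO <- matrix(vector("list", n_sites * n_samples), n_sites,
               dimnames = list(NULL, sid))
  for (i in seq_len(n_sites))
    for (j in seq_len(n_samples))
      AO[[i, j]] <- if (kinds[i] == "multi")
        c(AOv[i, j], stats::rpois(1, 2)) else AOv[i, j]
  GT <- matrix(sample(c(0L, 1L, NA), n_sites * n_samples, replace = TRUE,
                      prob = c(0.5, 0.4, 0.1)),
               n_sites, dimnames = list(NULL, sid))
  storage.mode(RO) <- "integer"
  makeExperiment("MT", pos, ref, alt, qual, GT, RO, AO)
}

# two-parent / one-cross experiment with explicit spore calls at marker
# sites; ro/ao are sites x samples matrices
makeCrossExperiment <- function(pos, p1_allele, spore_ro, spore_ao,
                                spore_meta = NULL,
                                parent_depth = 400L, contig = "MT") {
  n <- length(pos)
  n_spore <- ncol(spore_ro)
  ids <- c("ctrl_P1", "ctrl_P2",
           if (is.null(spore_meta)) sprintf("sp%d", seq_len(n_spore))
           else rownames(spore_meta))
  ro <- ao <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  p1_ref <- p1_allele == "reference"
  ro[, 1] <- ifelse(p1_ref, parent_depth, 0L)
  ao[, 1] <- ifelse(p1_ref, 0L, parent_depth)
  ro[, 2] <- ifelse(p1_ref, 0L, parent_depth)
  ao[, 2] <- ifelse(p1_ref, parent_depth, 0L)
  ro[, -(1:2)] <- spore_ro
  ao[, -(1:2)] <- spore_ao
  GT <- matrix(NA_integer_, n, length(ids), dimnames = list(NULL, ids))
  dep <- ro + ao
  GT[dep > 0] <- as.integer(ao[dep > 0] > ro[dep > 0])
  if (is.null(spore_meta)) {
    spore_meta <- S4Vectors::DataFrame(
      role = "spore", strain_or_cross = "X1", tetrad_id = "T1",
      spore_index = seq_len(n_spore), excluded = FALSE,
      exclusion_reason = NA_character_,
      row.names = sprintf("sp%d", seq_len(n_spore)))
  }
  cd <- rbind(S4Vectors::DataFrame(
    role = "parent", strain_or_cross = c("P1", "P2"),
    tetrad_id = NA_character_, spore_index = NA_integer_,
    excluded = FALSE, exclusion_reason = NA_character_,
    row.names = c("ctrl_P1", "ctrl_P2")), spore_meta)
  makeExperiment(contig, pos, rep("A", n), as.list(rep("G", n)),
                 rep(1000, n), GT, ro, ao, samples = cd,
                 crosses = data.frame(cross_id = "X1",
                                      parent1_strain = "P1",
                                      parent2_strain = "P2"))
}

# minimal VCF text writer for I/O contract tests
writeToyVcf <- function(path, records, samples = c("s1", "s2"),
                        format = "GT:RO:AO") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=MT,length=20000>",
    "##contig=<ID=I,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"Ref obs\">",
    if (grepl("AO", format))
      "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alt obs\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}
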