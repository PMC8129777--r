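#' Summarize spore colonies into predominant-parent assignments
#'
#' The per-colony mean parent-1 fraction is the unweighted mean over
#' non-missing markers. The predominant parent is parent 1 when the mean
#' strictly exceeds 0.5, parent 2 when strictly below, and `unassigned` at
#' exactly 0.5 or with zero informative markers.
#'
#' @param profiles table from [fractionProfiles()].
#' @param recombinants optional table from [classifyRecombinants()]; when
#'   given, the `is_recombinant` flag is joined in.
#' @return a `data.frame`: `sample_id`, `cross_id`, `tetrad_id`,
#'   `spore_index`, `mean_parent1_fraction`, `n_informative_markers`,
#'   `predominant_parent`, `is_recombinant`.
#' @export
summarizeSpores <- function(profiles, recombinants = NULL) {
  ids <- unique(profiles$sample_id)
  res <- lapply(ids, function(id) {
    pr <- profiles[profiles$sample_id == id, , drop = FALSE]
    f <- pr$parent1_fraction
    n_inf <- sum(!is.na(f))
    m <- if (n_inf) mean(f, na.rm = TRUE) else NA_real_
    pred <- if (n_inf == 0L) {
      message("sample ", id, ": no informative markers; unassigned")
      "unassigned"
    } else if (m > 0.5) "parent1" else if (m < 0.5) "parent2" else "unassigned"
    data.frame(sample_id = id, cross_id = pr$cross_id[1],
               tetrad_id = pr$tetrad_id[1], spore_index = pr$spore_index[1],
               mean_parent1_fraction = m, n_informative_markers = n_inf,
               predominant_parent = pred, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$is_recombinant <- if (!is.null(recombinants))
    recombinants$is_recombinant[match(out$sample_id, recombinants$sample_id)]
  else NA
  rownames(out) <- NULL
  out
}

#' Classify tetrad segregation patterns
#'
#' Under tethered uniparental inheritance each parent supplies its
#' mitochondrial genome to exactly two of the four spores, so a complete
#' tetrad should segregate 2:2. A tetrad deviates when at least three of
#' its assigned spores share the same predominant parent — a rule that also
#' applies to 3-spore tetrads; tetrads with fewer than three assigned
#' spores never deviate.
#'
#' @param spores table from [summarizeSpores()].
#' @param selfMating optional per-tetrad flag table from
#'   [flagSelfMating()] (recorded in `metadata()$selfMating`).
#' @return a `data.frame`: `tetrad_id`, `cross_id`, `n_viable_spores`,
#'   `n_parent1`, `n_parent2`, `pattern` (e.g. `"2:2"`), `deviates_2_2`,
#'   `n_recombinant`, `self_mated`.
#' @export
classifyTetrads <- function(spores, selfMating = NULL) {
  tets <- unique(spores[, c("tetrad_id", "cross_id")])
  res <- lapply(seq_len(nrow(tets)), function(i) {
    sp <- spores[spores$tetrad_id == tets$tetrad_id[i], , drop = FALSE]
    n1 <- sum(sp$predominant_parent == "parent1")
    n2 <- sum(sp$predominant_parent == "parent2")
    data.frame(tetrad_id = tets$tetrad_id[i], cross_id = tets$cross_id[i],
               n_viable_spores = nrow(sp), n_parent1 = n1, n_parent2 = n2,
               pattern = sprintf("%d:%d", n1, n2),
               deviates_2_2 = max(n1, n2) >= 3L,
               n_recombinant = sum(sp$is_recombinant, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(tetrad_id = character(), cross_id = character(),
                      n_viable_spores = integer(), n_parent1 = integer(),
                      n_parent2 = integer(), pattern = character(),
                      deviates_2_2 = logical(), n_recombinant = integer())
  out$self_mated <- if (!is.null(selfMating))
    selfMating$self_mated[match(out$tetrad_id, selfMating$tetrad_id)]
  else FALSE
  out$self_mated[is.na(out$self_mated)] <- FALSE
  rownames(out) <- NULL
  out
}

#' Per-cross transmission-bias summary
#'
#' For each cross, the fraction of assigned spore colonies predominantly
#' inheriting each parent's mitochondrial genome, the recombinant count,
#' and an exact two-sided binomial test of the parent-1 count against the
#' unbiased 1/2 expectation (two-sidedness by summing the probabilities of
#' all outcomes no more likely than the observed one). The same fractions
#' are also reported restricted to spores from complete (4-viable-spore)
#' tetrads, since both denominators are of interest.
#'
#' @param spores table from [summarizeSpores()].
#' @param tetrads optional table from [classifyTetrads()] (needed for the
#'   complete-tetrad denominator).
#' @return a `data.frame`, one row per cross: `cross_id`,
#'   `n_spores_analyzed`, `n_parent1`, `n_parent2`, `fraction_from_parent1`,
#'   `fraction_from_parent2`, `n_recombinant`, `binomial_p_two_sided`,
#'   `n_assigned_complete_tetrads`, `fraction_from_parent1_complete`.
#' @export
summarizeCrosses <- function(spores, tetrads = NULL) {
  crosses <- unique(spores$cross_id)
  res <- lapply(crosses, function(cid) {
    sp <- spores[spores$cross_id == cid, , drop = FALSE]
    asg <- sp[sp$predominant_parent %in% c("parent1", "parent2"), , drop = FALSE]
    if (!nrow(asg)) stop("cross ", cid, " has no assigned spores")
    n1 <- sum(asg$predominant_parent == "parent1")
    n <- nrow(asg)
    pval <- stats::binom.test(n1, n, p = 0.5)$p.value
    n_complete <- f1_complete <- NA
    if (!is.null(tetrads)) {
      full <- tetrads$tetrad_id[tetrads$cross_id == cid &
                                  tetrads$n_viable_spores == 4L]
      ac <- asg[asg$tetrad_id %in% full, , drop = FALSE]
      n_complete <- nrow(ac)
      f1_complete <- if (n_complete)
        sum(ac$predominant_parent == "parent1") / n_complete else NA_real_
    }
    data.frame(cross_id = cid, n_spores_analyzed = n,
               n_parent1 = n1, n_parent2 = n - n1,
               fraction_from_parent1 = n1 / n,
               fraction_from_parent2 = (n - n1) / n,
               n_recombinant = sum(asg$is_recombinant, na.rm = TRUE),
               binomial_p_two_sided = pval,
               n_assigned_complete_tetrads = n_complete,
               fraction_from_parent1_complete = f1_complete,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
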