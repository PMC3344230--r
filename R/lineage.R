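#' Clone set for one individual and marker
#'
#' @param individual_id individual label.
#' @param marker `"nuclear"` or `"chloroplast"`.
#' @param clones named character vector of aligned clone sequences.
#' @return an object of class `clone_set`.
#' @export
clone_set <- function(individual_id, marker = c("nuclear", "chloroplast"), clones) {
  marker <- match.arg(marker)
  clones <- unlist(clones)
  if (!length(clones)) stopf("a clone set needs at least one clone")
  if (is.null(names(clones)))
    names(clones) <- paste0(individual_id, "|c", seq_along(clones))
  if (length(unique(nchar(clones))) != 1L)
    stopf("clones must be aligned to a common reference (equal length)")
  structure(list(individual_id = individual_id, marker = marker,
                 clones = clones), class = "clone_set")
}

# Pairwise clone distance: substitution mismatches where both clones carry
# a base. Gaps are compared as coded extents, not per column: clones whose
# gap-run architectures differ are treated as different alleles (infinite
# distance), while a shared deletion does not separate clones. Polymerase
# point errors therefore drive linkage; slippage indels disqualify it.
clone_distance <- function(a, b) {
  av <- to_residues(a); bv <- to_residues(b)
  runs <- function(v) {
    r <- rle(v == "-")
    if (!any(r$values)) return(character(0))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sprintf("%d-%d", starts[r$values], ends[r$values])
  }
  ra <- runs(av); rb <- runs(bv)
  if (!setequal(ra, rb)) return(Inf)
  ok <- av %in% DNA_BASES & bv %in% DNA_BASES
  sum(av[ok] != bv[ok])
}

#' Collapse clone sequences into allele calls
#'
#' Single-linkage clustering of clones at a small substitution distance
#' (absorbing PCR/cloning point errors), followed by per-cluster
#' majority-rule consensus. Clusters below `min_support` are flagged as
#' putative PCR or cloning artefacts: the sequencing protocol accepts an
#' allele only once captured more than once, so singletons are excluded
#' from genotyping by default but persisted for audit.
#'
#' @param cs a [clone_set()] (or named character vector of aligned clones).
#' @param max_error_mismatches link clones at up to this many substitution
#'   differences (default 2).
#' @param min_support minimum clone support for an accepted allele
#'   (default 2).
#' @return data.frame with columns `allele_id`, `consensus`, `support`,
#'   `flagged_singleton`, ordered by decreasing support then sequence.
#'   Result is invariant to clone input order.
#' @export
collapse_clones <- function(cs, max_error_mismatches = 2, min_support = 2) {
  clones <- if (inherits(cs, "clone_set")) cs$clones else unlist(cs)
  ind <- if (inherits(cs, "clone_set")) cs$individual_id else "ind"
  if (length(unique(nchar(clones))) != 1L)
    stopf("clones must be aligned (equal length)")
  # order-invariance: work on a deterministically sorted copy
  clones <- clones[order(unname(clones), names(clones))]
  n <- length(clones)
  comp <- seq_len(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (clone_distance(clones[i], clones[j]) <= max_error_mismatches) {
        old <- comp[j]; comp[comp == old] <- comp[i]
      }
    }
  }
  groups <- split(seq_len(n), comp)
  calls <- lapply(groups, function(ix) {
    mat <- do.call(rbind, lapply(clones[ix], to_residues))
    cons <- apply(mat, 2, function(col) {
      tab <- sort(table(col), decreasing = TRUE)
      nm <- names(tab)[tab == max(tab)]
      sort(nm)[1]  # deterministic tie-break
    })
    data.frame(consensus = paste(cons, collapse = ""),
               support = length(ix), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out <- out[order(-out$support, out$consensus), , drop = FALSE]
  out$allele_id <- sprintf("%s_a%d", ind, seq_len(nrow(out)))
  out$flagged_singleton <- out$support < min_support
  rownames(out) <- NULL
  out[, c("allele_id", "consensus", "support", "flagged_singleton")]
}

#' Assign an allele to a lineage group
#'
#' Major-clade membership (X vs Y style) is decided by the diagnostic
#' indel; the subgroup within the major clade is the nearest exemplar by
#' p-distance, with a separation margin: when the nearest and second
#' nearest exemplars differ by less than `margin` the call is
#' `"unassigned"` rather than forced.
#'
#' @param consensus allele consensus sequence, aligned to the exemplar
#'   alignment.
#' @param references an [alignment()] of per-group exemplars (names are the
#'   group labels, e.g. X1..X4, Y).
#' @param diagnostic `c(start, end)` columns (0-based half-open) of the
#'   major-clade diagnostic indel.
#' @param margin minimum p-distance separation between nearest and second
#'   nearest exemplar (default 0.005).
#' @param min_reciprocal_overlap passed to [detect_diagnostic_indel()].
#' @return group label, or `"unassigned"`.
#' @export
assign_allele_group <- function(consensus, references, diagnostic,
                                margin = 0.005, min_reciprocal_overlap = 0.8) {
  stopifnot(inherits(references, "alignment"))
  if (nchar(consensus) != references$length)
    stopf("allele must be aligned to the reference alignment")
  all_seqs <- c(aln_strings(references), query = consensus)
  aln <- alignment(all_seqs)
  status <- detect_diagnostic_indel("query", aln, diagnostic,
                                    min_reciprocal_overlap)
  ref_status <- vapply(references$ids, detect_diagnostic_indel, character(1),
                       aln = aln, diagnostic = diagnostic,
                       min_reciprocal_overlap = min_reciprocal_overlap)
  cand <- if (status == "ambiguous") references$ids
          else references$ids[ref_status == status]
  if (!length(cand)) return("unassigned")
  d <- vapply(cand, function(id)
    p_distance(aln_row(aln, "query"), aln_row(aln, id)), numeric(1))
  d <- sort(d)
  if (length(d) >= 2L && (d[2] - d[1]) < margin) return("unassigned")
  names(d)[1]
}

#' Infer a dosage-ambiguous genotype from observed allele groups
#'
#' Clone presence/absence cannot reveal allele dosage in polyploids, so the
#' genotype is the set of all multisets of size `ploidy` containing every
#' observed group at least once. The star label marks unresolved dosage
#' (e.g. `X3*Y` stands for X3X3Y or X3YY).
#'
#' @param groups character vector of observed allele groups.
#' @param ploidy integer ploidy (2, 3 or 4).
#' @return list of class `genotype` with `candidates` (list of sorted
#'   character vectors), `label`, `groups`, `ploidy`.
#' @export
infer_genotype <- function(groups, ploidy) {
  groups <- ms_sort(unique(as.character(groups)))
  if (!length(groups)) stopf("no observed allele groups")
  if (!ploidy %in% 2:4) stopf("ploidy must be 2, 3 or 4")
  k <- length(groups)
  if (k > ploidy)
    stopf("more alleles (%d) than genome copies (%d)", k, ploidy)
  extra <- ploidy - k
  fills <- ms_subsets(rep(groups, each = extra), extra)
  candidates <- unique(lapply(fills, function(f) ms_sort(c(groups, f))))
  candidates <- candidates[order(vapply(candidates, ms_label, character(1)))]
  label <- if (length(candidates) == 1L) ms_label(candidates[[1]])
  else paste0(paste(groups[-k], collapse = ""), "*", groups[k])
  structure(list(candidates = candidates, label = label, groups = groups,
                 ploidy = as.integer(ploidy)), class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf("genotype %s (ploidy %d, %d candidate%s)\n", x$label, x$ploidy,
              length(x$candidates), if (length(x$candidates) > 1) "s" else ""))
  invisible(x)
}

#' Group chloroplast haplotypes into deep clusters
#'
#' Hierarchical clustering on p-distance, cut at the midpoint of the
#' largest gap in merge heights — deep, mutually exclusive haplotype
#' clades separate cleanly there. Group labels (alpha, beta, ...) are
#' assigned by decreasing group size with a lexicographic tie-break on the
#' earliest member.
#'
#' @param seqs an [alignment()] or named character vector of aligned cpDNA
#'   haplotype sequences (at least 2).
#' @param linkage `"average"` (default) or `"single"`.
#' @return list of class `haplotype_grouping` with `groups` (named label
#'   vector), `threshold`, `tree` (hclust), `n_groups`.
#' @export
group_haplotypes <- function(seqs, linkage = c("average", "single")) {
  linkage <- match.arg(linkage)
  seqs <- if (inherits(seqs, "alignment")) aln_strings(seqs) else unlist(seqs)
  if (length(seqs) < 2L) stopf("need at least 2 haplotype sequences")
  d <- p_distance_matrix(seqs)
  hc <- hclust(as.dist(d), method = if (linkage == "average") "average" else "single")
  h <- sort(hc$height)
  gaps <- diff(c(0, h))
  if (max(h) <= 1e-12) {
    members <- setNames(rep(1L, length(seqs)), names(seqs))
    threshold <- 0
  } else {
    g <- which.max(gaps)
    threshold <- (c(0, h)[g] + h[g]) / 2
    members <- cutree(hc, h = threshold)
  }
  # label groups by decreasing size, tie-break on earliest member name
  sizes <- table(members)
  first <- vapply(names(sizes), function(k)
    sort(names(members)[members == as.integer(k)])[1], character(1))
  ord <- order(-as.integer(sizes), first)
  labels <- setNames(GREEK_LABELS[seq_along(ord)], names(sizes)[ord])
  groups <- setNames(unname(labels[as.character(members)]), names(members))
  structure(list(groups = groups, threshold = threshold, tree = hc,
                 n_groups = length(sizes)), class = "haplotype_grouping")
}

GREEK_LABELS <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                  "eta", "theta", "iota", "kappa", "lambda", "mu")

#' One observed taxon of the complex
#'
#' @param taxon_id label (e.g. morph plus cytotype).
#' @param ploidy 2, 3 or 4.
#' @param alleles observed allele groups (character vector).
#' @param haplotype chloroplast haplotype group label or `NA`.
#' @param reproduction `"apogamous"` or `"sexual"`.
#' @param region character vector of region labels.
#' @param phenology `"evergreen"`, `"deciduous"` or `"unknown"`.
#' @param genotype optional precomputed [infer_genotype()] result.
#' @return an object of class `taxon_observation`.
#' @export
taxon_observation <- function(taxon_id, ploidy, alleles, haplotype = NA,
                              reproduction = c("apogamous", "sexual"),
                              region = character(0),
                              phenology = "unknown", genotype = NULL) {
  reproduction <- match.arg(reproduction)
  if (is.null(genotype)) genotype <- infer_genotype(alleles, ploidy)
  stopifnot(all(lengths(genotype$candidates) == ploidy))
  structure(list(taxon_id = as.character(taxon_id), ploidy = as.integer(ploidy),
                 alleles = ms_sort(unique(alleles)), genotype = genotype,
                 haplotype = as.character(haplotype),
                 reproduction = reproduction, region = as.character(region),
                 phenology = phenology),
            class = "taxon_observation")
}

#' Infer the allele-to-haplotype maternal map
#'
#' Chloroplasts are maternally inherited, so an allele whose carriers all
#' share one haplotype group marks a maternal lineage. The map is built by
#' deterministic rounds of elimination: an allele is mapped when (i) its
#' carriers not yet explained by another mapped allele share one haplotype
#' and (ii) in at least one such carrier it is the strictly preferred
#' candidate (smallest raw haplotype spread among co-candidates). Remaining
#' ambiguity is reported, never guessed; carriers contradicting an
#' otherwise-consistent allele produce conflict records.
#'
#' @param observations list of [taxon_observation()].
#' @param exempt taxon ids excluded from map building (taxa whose
#'   nuclear/chloroplast signal is known to disagree).
#' @return list of class `allele_haplotype_map` with `map` (named vector,
#'   allele -> haplotype), `conflicts` (data.frame taxon/allele/expected/
#'   observed), `ambiguous` (data.frame taxon/candidates).
#' @export
infer_allele_haplotype_map <- function(observations, exempt = character(0)) {
  obs <- Filter(function(o) !(o$taxon_id %in% exempt) && !is.na(o$haplotype),
                observations)
  alleles <- ms_sort(unique(unlist(lapply(obs, `[[`, "alleles"))))
  hap_of <- vapply(obs, `[[`, character(1), "haplotype")
  names(hap_of) <- vapply(obs, `[[`, character(1), "taxon_id")
  carriers <- lapply(setNames(alleles, alleles), function(a)
    names(hap_of)[vapply(obs, function(o) a %in% o$alleles, logical(1))])
  rawH <- lapply(carriers, function(tt) unique(hap_of[tt]))
  genotype_of <- setNames(lapply(obs, `[[`, "alleles"), names(hap_of))

  mapped <- character(0)  # named: allele -> haplotype
  repeat {
    # carriers not yet explained by a mapped co-allele
    E <- lapply(setNames(alleles, alleles), function(a) {
      if (a %in% names(mapped)) return(character(0))
      Filter(function(t) {
        others <- setdiff(genotype_of[[t]], a)
        !any(mapped[others] == hap_of[[t]], na.rm = TRUE)
      }, carriers[[a]])
    })
    Hp <- lapply(E, function(tt) unique(hap_of[tt]))
    # additions are decided against the round-start map and applied together,
    # so within-round order cannot promote a weaker candidate
    mapped0 <- names(mapped)
    newly <- character(0)
    for (a in setdiff(alleles, mapped0)) {
      if (length(Hp[[a]]) != 1L) next
      ok <- any(vapply(E[[a]], function(t) {
        others <- setdiff(genotype_of[[t]], c(a, mapped0))
        all(lengths(rawH[others]) > length(rawH[[a]]))
      }, logical(1)))
      if (ok) newly[a] <- Hp[[a]]
    }
    if (!length(newly)) break
    mapped <- c(mapped, newly)
  }

  # post-fixpoint diagnostics
  E <- lapply(setNames(alleles, alleles), function(a) {
    if (a %in% names(mapped)) return(character(0))
    Filter(function(t) {
      others <- setdiff(genotype_of[[t]], a)
      !any(mapped[others] == hap_of[[t]], na.rm = TRUE)
    }, carriers[[a]])
  })
  conflicts <- list()
  ambiguous <- list()
  for (a in setdiff(alleles, names(mapped))) {
    tt <- E[[a]]
    if (!length(tt)) next  # fully explained elsewhere: benign unmapped
    haps <- hap_of[tt]
    preferred <- vapply(tt, function(t) {
      others <- setdiff(genotype_of[[t]], c(a, names(mapped)))
      all(lengths(rawH[others]) >= length(rawH[[a]]))
    }, logical(1))
    if (length(unique(haps)) >= 2L && any(preferred)) {
      expected <- names(sort(table(haps), decreasing = TRUE))[1]
      bad <- tt[haps != expected]
      for (t in bad)
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          taxon = t, allele = a, expected = expected,
          observed = hap_of[[t]], stringsAsFactors = FALSE)
    } else if (length(unique(haps)) == 1L) {
      for (t in tt)
        ambiguous[[length(ambiguous) + 1L]] <- data.frame(
          taxon = t, allele = a, haplotype = unname(hap_of[[t]]),
          stringsAsFactors = FALSE)
    }
  }
  empty_df <- function(...) {
    nm <- c(...)
    as.data.frame(setNames(rep(list(character(0)), length(nm)), nm))
  }
  structure(list(
    map = mapped,
    conflicts = if (length(conflicts)) do.call(rbind, conflicts)
                else empty_df("taxon", "allele", "expected", "observed"),
    ambiguous = if (length(ambiguous)) do.call(rbind, ambiguous)
                else empty_df("taxon", "allele", "haplotype")),
    class = "allele_haplotype_map")
}
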