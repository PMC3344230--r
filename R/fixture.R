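#' The Pteris cadieri complex observation table
#'
#' Deterministic transcription of the field observations for the eleven
#' (morph, cytotype) taxa of the P. cadieri complex from Hainan and
#' Taiwan: ploidy from flow cytometry, nuclear allele content and
#' dosage-ambiguous genotypes, chloroplast haplotype groups (alpha, beta,
#' gamma), regions and phenology. All members of the complex are
#' apogamous. The haplotype of the triploid morph 6 is not directly
#' reported and is inferred from its maternal allele (X2, an alpha
#' lineage); the cell is flagged accordingly.
#'
#' @return list with `observations` (list of [taxon_observation()]),
#'   `exempt` (taxa whose nuclear and chloroplast signals disagree and
#'   which are excluded from maternal-map building: morphs 5 and 6),
#'   `inferred_cells` (data.frame of cells inferred rather than observed).
#' @export
cadieri_observations <- function() {
  tx <- function(id, ploidy, alleles, hap, region, phen)
    taxon_observation(id, ploidy, alleles, hap, "apogamous", region, phen)
  observations <- list(
    tx("morph1_2x",  2L, c("X2", "Y"),       "alpha", c("Hainan", "Taiwan"), "deciduous"),
    tx("morph2_2x",  2L, c("X4", "Y"),       "beta",  "Hainan",              "unknown"),
    tx("morph2_4x",  4L, c("X2", "X4", "Y"), "beta",  "Hainan",              "evergreen"),
    tx("morph3_2x",  2L, c("X3", "Y"),       "gamma", "Taiwan",              "evergreen"),
    tx("morph4_2x",  2L, c("X3", "Y"),       "gamma", c("Hainan", "Taiwan"), "evergreen"),
    tx("morph5_3x",  3L, c("X3", "Y"),       "alpha", "Taiwan",              "evergreen"),
    tx("morph6_3x",  3L, c("X2", "X3", "Y"), "alpha", "Taiwan",              "evergreen"),
    tx("morph7_2x",  2L, c("X3", "Y"),       "gamma", "Taiwan",              "evergreen"),
    tx("morph8_2x",  2L, c("X1", "Y"),       "alpha", c("Hainan", "Taiwan"), "deciduous"),
    tx("morph8_3x",  3L, c("X1", "Y"),       "alpha", "Taiwan",              "deciduous"),
    tx("morph8_4x",  4L, c("X2", "X4", "Y"), "beta",  "Hainan",              "evergreen"))
  names(observations) <- vapply(observations, `[[`, character(1), "taxon_id")
  list(observations = observations,
       exempt = c("morph5_3x", "morph6_3x"),
       inferred_cells = data.frame(taxon = "morph6_3x", field = "haplotype",
                                   value = "alpha",
                                   basis = "maternal allele X2 is an alpha lineage",
                                   stringsAsFactors = FALSE))
}

#' Summary counts for an observation set
#'
#' @param observations list of [taxon_observation()].
#' @return list with `n_taxa`, `n_alleles`, `n_haplotype_groups`,
#'   `alleles`, `haplotype_groups`.
#' @export
observation_summary <- function(observations) {
  alleles <- ms_sort(unique(unlist(lapply(observations, `[[`, "alleles"))))
  haps <- sort(unique(stats::na.omit(vapply(observations, `[[`, character(1),
                                            "haplotype"))))
  list(n_taxa = length(observations), n_alleles = length(alleles),
       n_haplotype_groups = length(haps), alleles = alleles,
       haplotype_groups = haps)
}
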