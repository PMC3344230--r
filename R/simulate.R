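#' Configuration for the synthetic hybrid-complex generator
#'
#' Defaults emulate the statistical structure the analysis assumes: five
#' nuclear allele lineages in two deep clades separated by a 15-column
#' diagnostic deletion, three divergent chloroplast haplotype groups,
#' hybrids of ploidy 2-4 formed under the package's gamete rules, PCR bias
#' among alleles, cytometry peak ratios of 0.6 per genome copy, and the
#' 32-spore apogamous signature with occasional 16/28 counts.
#'
#' @param seed mandatory integer seed; every downstream draw derives from it.
#' @param alleles allele lineage names.
#' @param major_clade named vector assigning each allele to a deep clade;
#'   the clade listed last carries the diagnostic deletion.
#' @param diagnostic_indel_length columns of the diagnostic deletion.
#' @param haplotype_groups chloroplast group labels.
#' @param allele_haplotype named vector, allele -> maternal haplotype group
#'   of its progenitor.
#' @param seq_length alignment columns for both markers.
#' @param within_divergence,between_group_divergence,between_clade_divergence
#'   expected p-distances (must be increasing).
#' @param n_diploid_hybrids,n_triploid_hybrids,n_tetraploid_hybrids numbers
#'   of hybrid individuals when no explicit `events` table is given.
#' @param clones_per_individual clones sequenced per individual through the
#'   generic primer channel.
#' @param use_clade_channels also sample clade-specific channels emulating
#'   the bias-avoiding forward primers anchored on the diagnostic indel:
#'   each major clade present in a genotype is re-sampled separately.
#' @param channel_min,channel_patience,channel_max adaptive stopping for
#'   clade channels: sequence at least `channel_min` clones and continue
#'   until every observed allele type is captured more than once and
#'   `channel_patience` consecutive clones add no new type, up to
#'   `channel_max`.
#' @param pcr_bias_weights named per-allele sampling weights (default 1).
#' @param pcr_error_rate per-base error probability in cloned sequences
#'   (default 5e-4, the usual figure for proofreading-free Taq over a
#'   30-odd-cycle amplification).
#' @param histogram_cv coefficient of variation of cytometry peaks.
#' @param standard_channel G1 peak channel of the calibration standard.
#' @param n_cells events per peak in simulated histograms.
#' @param n_channels histogram bins.
#' @param spore_atypical_prob probability an apogamous sporangium shows an
#'   atypical 16 or 28 count instead of 32.
#' @param regions region labels to sample from.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              alleles = c("X1", "X2", "X3", "X4", "Y"),
                              major_clade = c(X1 = "X", X2 = "X", X3 = "X",
                                              X4 = "X", Y = "Y"),
                              diagnostic_indel_length = 15L,
                              haplotype_groups = c("alpha", "beta", "gamma"),
                              allele_haplotype = c(X1 = "alpha", X2 = "alpha",
                                                   X3 = "gamma", X4 = "beta",
                                                   Y = "beta"),
                              seq_length = 600L,
                              within_divergence = 0.005,
                              between_group_divergence = 0.04,
                              between_clade_divergence = 0.08,
                              n_diploid_hybrids = 3L,
                              n_triploid_hybrids = 2L,
                              n_tetraploid_hybrids = 1L,
                              clones_per_individual = 8L,
                              use_clade_channels = TRUE,
                              channel_min = 6L,
                              channel_patience = 8L,
                              channel_max = 16L,
                              pcr_bias_weights = NULL,
                              pcr_error_rate = 5e-4,
                              histogram_cv = 0.03,
                              standard_channel = 200,
                              n_cells = 4000L,
                              n_channels = 1024L,
                              spore_atypical_prob = 0.1,
                              regions = c("Hainan", "Taiwan")) {
  if (missing(seed)) stopf("a seed is mandatory")
  if (!(within_divergence < between_group_divergence &&
        between_group_divergence < between_clade_divergence))
    stopf("divergences must satisfy within < between-group < between-clade")
  if (is.null(major_clade) || !all(alleles %in% names(major_clade))) {
    # custom allele sets: last lineage forms the deletion clade
    major_clade <- setNames(c(rep("X", length(alleles) - 1L), "Y"), alleles)
  }
  if (is.null(allele_haplotype) || !all(alleles %in% names(allele_haplotype))) {
    # conflict-free default: cycle lineages over the haplotype groups
    allele_haplotype <- setNames(
      rep(haplotype_groups, length.out = length(alleles)), alleles)
  }
  if (is.null(pcr_bias_weights))
    pcr_bias_weights <- setNames(rep(1, length(alleles)), alleles)
  if (!all(alleles %in% names(pcr_bias_weights)))
    stopf("pcr_bias_weights must cover every allele")
  if (any(pcr_bias_weights <= 0)) stopf("PCR bias weights must be positive")
  structure(as.list(environment()), class = "simulation_config")
}

# Mutate each A/C/G/T site independently with probability p to a different
# base; gaps are untouched.
mutate_seq <- function(res, p) {
  hit <- which(res %in% DNA_BASES & runif(length(res)) < p)
  for (i in hit) res[i] <- sample(setdiff(DNA_BASES, res[i]), 1L)
  res
}

#' Simulate reference (exemplar) alignments
#'
#' Star phylogeny with clades: a random root sequence diverges into the
#' major allele clades, then into allele exemplars; the diagnostic deletion
#' is inserted into every exemplar of the deletion clade. Haplotype
#' exemplars diverge from an independent root at the between-group level.
#' Deterministic for a given config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `allele_exemplars` and `haplotype_exemplars`
#'   ([alignment()]s) and `diagnostic` = `c(start, end)` columns (0-based
#'   half-open) of the deletion window.
#' @export
simulate_reference_sequences <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(child_seed(config$seed, 1L), {
    L <- config$seq_length
    root <- sample(DNA_BASES, L, replace = TRUE)
    clades <- unique(config$major_clade)
    # clade branches are shortened by the group step so that cross-clade
    # exemplar pairs sit near between_clade_divergence overall
    clade_anc <- lapply(setNames(clades, clades), function(cl)
      mutate_seq(root, (config$between_clade_divergence -
                          config$between_group_divergence) / 2))
    exemplars <- lapply(setNames(config$alleles, config$alleles), function(a) {
      anc <- clade_anc[[config$major_clade[[a]]]]
      mutate_seq(anc, config$between_group_divergence / 2)
    })
    del_clade <- clades[length(clades)]
    start <- L %/% 2L
    end <- start + config$diagnostic_indel_length
    for (a in config$alleles) {
      if (config$major_clade[[a]] == del_clade)
        exemplars[[a]][(start + 1L):end] <- "-"
    }
    hap_root <- sample(DNA_BASES, L, replace = TRUE)
    haps <- lapply(setNames(config$haplotype_groups, config$haplotype_groups),
                   function(h) mutate_seq(hap_root,
                                          config$between_group_divergence / 2))
    list(allele_exemplars = alignment(vapply(exemplars, paste, character(1),
                                             collapse = "")),
         haplotype_exemplars = alignment(vapply(haps, paste, character(1),
                                                collapse = "")),
         diagnostic = c(start, end))
  })
}

# Random event list obeying the gamete rules: diploid hybrids from
# progenitor crosses, triploids from progenitor mothers x unreduced
# apogamous diploid fathers, tetraploids from doubled-diploid mothers x
# unreduced apogamous diploid fathers.
random_events <- function(config) {
  alleles <- config$alleles
  ev <- list()
  dips <- list()  # apogamous diploid hybrids created so far
  k <- 0L
  for (i in seq_len(config$n_diploid_hybrids)) {
    ab <- sort(sample(alleles, 2L))
    k <- k + 1L
    id <- sprintf("H%02d_2x", k)
    ev[[id]] <- list(id = id, type = "cross", ploidy = 2L,
                     mother = c(ab[1], ab[1]), mother_gamete = ab[1],
                     father = c(ab[2], ab[2]), father_gamete = ab[2],
                     genotype = ab,
                     haplotype = config$allele_haplotype[[ab[1]]])
    dips[[id]] <- ev[[id]]
  }
  for (i in seq_len(config$n_triploid_hybrids)) {
    f <- dips[[sample(length(dips), 1L)]]
    a <- sample(alleles, 1L)
    k <- k + 1L
    id <- sprintf("H%02d_3x", k)
    ev[[id]] <- list(id = id, type = "cross", ploidy = 3L,
                     mother = c(a, a), mother_gamete = a,
                     father = f$genotype, father_gamete = f$genotype,
                     genotype = ms_sort(c(a, f$genotype)),
                     haplotype = config$allele_haplotype[[a]])
  }
  for (i in seq_len(config$n_tetraploid_hybrids)) {
    src <- dips[[sample(length(dips), 1L)]]
    f <- dips[[sample(length(dips), 1L)]]
    k <- k + 1L
    id <- sprintf("H%02d_4x", k)
    ev[[id]] <- list(id = id, type = "cross", ploidy = 4L,
                     mother = rep(src$genotype, each = 2L),
                     mother_gamete = src$genotype,
                     father = f$genotype, father_gamete = f$genotype,
                     genotype = ms_sort(c(src$genotype, f$genotype)),
                     haplotype = src$haplotype,
                     doubling_source = src$genotype)
  }
  ev
}

#' Simulate a complete hybrid-complex dataset with ground truth
#'
#' Executes the event list (crosses and doublings) and emits, per hybrid
#' individual, every observation the analysis consumes: a nuclear clone
#' set (allele copies sampled proportionally to dosage times PCR bias
#' weight, with per-base PCR errors), a chloroplast sequence from the
#' maternal lineage with within-group variation, a two-peak cytometry
#' histogram (sample/standard ratio 0.6 per genome copy, Gaussian spread),
#' spore counts, and region/phenology labels.
#'
#' @param config a [simulation_config()].
#' @param events optional explicit event list (as built by the random
#'   generator); by default events are drawn from the config counts.
#' @return list of class `simulated_complex` with `individuals` (named
#'   list of observation bundles), `truth` (progenitors, events, and a
#'   per-individual data.frame of latent ploidy, genotype label and
#'   haplotype), `references`, `config`.
#' @export
simulate_complex <- function(config, events = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  refs <- simulate_reference_sequences(config)
  if (is.null(events))
    events <- with_seed(child_seed(config$seed, 2L), random_events(config))
  bias <- config$pcr_bias_weights
  individuals <- list()
  truth_rows <- list()
  with_seed(child_seed(config$seed, 3L), {
    for (evi in seq_along(events)) {
      e <- events[[evi]]
      stopifnot(ms_equal(e$genotype, c(e$mother_gamete, e$father_gamete)))
      id <- e$id
      dosage <- table(e$genotype)
      w <- as.numeric(dosage) * bias[names(dosage)]
      names(w) <- names(dosage)
      draw_one <- function(sub) {
        if (length(sub) == 1L) sub else
          sample(sub, 1L, prob = w[sub] / sum(w[sub]))
      }
      # generic primer channel: fixed depth over all alleles
      picked <- vapply(seq_len(config$clones_per_individual), function(i)
        draw_one(names(w)), character(1))
      # clade-specific channels (bias-avoiding primers): sequence until all
      # observed types are captured more than once and the observed set is
      # stable, within the configured effort bounds
      if (config$use_clade_channels) {
        for (cl in unique(config$major_clade[names(w)])) {
          sub <- names(w)[config$major_clade[names(w)] == cl]
          got <- character(0)
          since_new <- 0L
          while (length(got) < config$channel_max) {
            a <- draw_one(sub)
            since_new <- if (a %in% got) since_new + 1L else 0L
            got <- c(got, a)
            tab <- table(got)
            if (length(got) >= config$channel_min && all(tab >= 2L) &&
                since_new >= config$channel_patience) break
          }
          picked <- c(picked, got)
        }
      }
      clones <- vapply(picked, function(a) {
        s <- aln_row(refs$allele_exemplars, a)
        paste(mutate_seq(s, config$pcr_error_rate), collapse = "")
      }, character(1))
      names(clones) <- sprintf("%s|c%d", id, seq_along(clones))
      hap <- e$haplotype
      cp <- paste(mutate_seq(aln_row(refs$haplotype_exemplars, hap),
                             config$within_divergence / 2), collapse = "")
      ratio <- 0.6 * e$ploidy
      std_mu <- config$standard_channel
      smp_mu <- std_mu * ratio
      draws <- c(rnorm(config$n_cells, std_mu, config$histogram_cv * std_mu),
                 rnorm(config$n_cells, smp_mu, config$histogram_cv * smp_mu))
      bins <- pmin(pmax(round(draws), 1L), config$n_channels)
      hist <- fluorescence_histogram(id, seq_len(config$n_channels),
                                     tabulate(bins, config$n_channels))
      spores <- vapply(seq_len(5L), function(i)
        if (runif(1) < config$spore_atypical_prob) sample(c(16L, 28L), 1L)
        else 32L, integer(1))
      region <- sample(config$regions, 1L)
      phen <- sample(c("evergreen", "deciduous"), 1L)
      individuals[[id]] <- list(
        id = id, clones = clones, cpdna = cp, histogram = hist,
        spore_counts = spores, region = region, phenology = phen)
      truth_rows[[id]] <- data.frame(
        id = id, ploidy = e$ploidy,
        genotype_label = infer_genotype(unique(e$genotype), e$ploidy)$label,
        genotype = ms_label(e$genotype), haplotype = hap,
        reproduction = "apogamous", region = region,
        stringsAsFactors = FALSE)
    }
  })
  progenitors <- lapply(setNames(config$alleles, config$alleles), function(a)
    parent_taxon(c(a, a), "sexual", config$allele_haplotype[[a]], "presumed"))
  structure(list(individuals = individuals,
                 truth = list(progenitors = progenitors, events = events,
                              individuals = do.call(rbind, truth_rows)),
                 references = refs, config = config),
            class = "simulated_complex")
}

#' Write a simulated complex to disk in the pipeline's input formats
#'
#' Emits per-individual nuclear clone FASTAs, a cpDNA FASTA, histogram
#' CSVs, a spore-count TSV, a sample sheet TSV, the exemplar reference
#' FASTAs, and a JSON-lines ground-truth file.
#'
#' @param sim a [simulate_complex()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_complex"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "clones"), showWarnings = FALSE)
  dir.create(file.path(dir, "histograms"), showWarnings = FALSE)
  cp <- vapply(sim$individuals, `[[`, character(1), "cpdna")
  write_fasta_alignment(cp, file.path(dir, "cpdna.fasta"))
  write_fasta_alignment(sim$references$allele_exemplars,
                        file.path(dir, "allele_exemplars.fasta"))
  write_fasta_alignment(sim$references$haplotype_exemplars,
                        file.path(dir, "haplotype_exemplars.fasta"))
  rows <- list()
  for (ind in sim$individuals) {
    write_fasta_alignment(ind$clones,
                          file.path(dir, "clones", paste0(ind$id, ".fasta")))
    write_histogram_csv(ind$histogram,
                        file.path(dir, "histograms", paste0(ind$id, ".csv")))
    rows[[ind$id]] <- data.frame(
      sample_id = ind$id,
      clone_fasta = file.path("clones", paste0(ind$id, ".fasta")),
      histogram_csv = file.path("histograms", paste0(ind$id, ".csv")),
      spore_counts = paste(ind$spore_counts, collapse = ","),
      region = ind$region, phenology = ind$phenology,
      stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, rows)
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "truth.jsonl"), "w")
  on.exit(close(con))
  tr <- sim$truth$individuals
  for (i in seq_len(nrow(tr)))
    writeLines(jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE), con)
  writeLines(jsonlite::toJSON(list(
    diagnostic = sim$references$diagnostic,
    alleles = sim$config$alleles,
    allele_haplotype = as.list(sim$config$allele_haplotype)),
    auto_unbox = TRUE), con)
  invisible(dir)
}
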