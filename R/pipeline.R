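#' Read a written complex back into memory
#'
#' Reads the directory layout produced by [write_simulation()]: sample
#' sheet, clone FASTAs, histograms, cpDNA FASTA and exemplar references.
#' The ground-truth file is deliberately not read.
#'
#' @param dir input directory.
#' @return list with `individuals`, `references` (exemplar alignments and
#'   the diagnostic window recovered from the exemplars themselves).
#' @export
read_complex <- function(dir) {
  sheet_path <- file.path(dir, "samples.tsv")
  if (!file.exists(sheet_path)) stopf("no sample sheet at %s", sheet_path)
  sheet <- read.delim(sheet_path, stringsAsFactors = FALSE)
  if (!nrow(sheet)) stopf("empty sample sheet: %s", sheet_path)
  cp <- aln_strings(read_fasta_alignment(file.path(dir, "cpdna.fasta")))
  refs <- list(
    allele_exemplars = read_fasta_alignment(file.path(dir, "allele_exemplars.fasta")),
    haplotype_exemplars = read_fasta_alignment(file.path(dir, "haplotype_exemplars.fasta")))
  refs$diagnostic <- infer_diagnostic_window(refs$allele_exemplars)
  individuals <- lapply(seq_len(nrow(sheet)), function(i) {
    id <- sheet$sample_id[i]
    clones <- aln_strings(read_fasta_alignment(file.path(dir, sheet$clone_fasta[i])))
    hist <- read_histogram_csv(file.path(dir, sheet$histogram_csv[i]),
                               sample_id = id)
    list(id = id, clones = clones, cpdna = unname(cp[id]), histogram = hist,
         spore_counts = as.integer(strsplit(sheet$spore_counts[i], ",")[[1]]),
         region = sheet$region[i], phenology = sheet$phenology[i])
  })
  names(individuals) <- sheet$sample_id
  list(individuals = individuals, references = refs)
}

#' Recover the diagnostic indel window from exemplar references
#'
#' The major-clade diagnostic deletion is the most frequent shared gap
#' extent among the exemplars carrying it (ties resolved toward the
#' longest, then leftmost).
#'
#' @param references exemplar [alignment()].
#' @return `c(start, end)` (0-based half-open), or `NULL` when the
#'   exemplars are gap-free.
#' @export
infer_diagnostic_window <- function(references) {
  runs <- find_gap_runs(references)
  runs <- runs[!runs$terminal, , drop = FALSE]
  if (!nrow(runs)) return(NULL)
  key <- paste(runs$start, runs$end)
  tab <- table(key)
  lens <- runs$end - runs$start
  best <- names(tab)[order(-as.integer(tab),
                           -lens[match(names(tab), key)],
                           runs$start[match(names(tab), key)])][1]
  as.integer(strsplit(best, " ")[[1]])
}

#' Validate pipeline inputs
#'
#' Schema checks on a complex directory (sample sheet, referenced files,
#' spore counts, histograms). Returns issues instead of failing.
#'
#' @param dir input directory in the [write_simulation()] layout.
#' @return data.frame with columns `row`, `field`, `problem` (zero rows
#'   when everything is well-formed).
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  add <- function(row, field, problem)
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, field = field, problem = problem, stringsAsFactors = FALSE)
  sheet_path <- file.path(dir, "samples.tsv")
  if (!file.exists(sheet_path)) {
    add(0L, "samples.tsv", "sample sheet missing")
  } else {
    sheet <- read.delim(sheet_path, stringsAsFactors = FALSE)
    need <- c("sample_id", "clone_fasta", "histogram_csv", "spore_counts")
    for (col in setdiff(need, names(sheet)))
      add(0L, col, "required column missing")
    if ("sample_id" %in% names(sheet)) {
      dup <- which(duplicated(sheet$sample_id))
      for (i in dup) add(i, "sample_id",
                         sprintf("duplicate individual id '%s'", sheet$sample_id[i]))
    }
    if (all(need %in% names(sheet))) {
      for (i in seq_len(nrow(sheet))) {
        for (col in c("clone_fasta", "histogram_csv")) {
          f <- file.path(dir, sheet[[col]][i])
          if (!file.exists(f)) add(i, col, sprintf("file not found: %s", f))
        }
        sc <- suppressWarnings(as.integer(strsplit(sheet$spore_counts[i], ",")[[1]]))
        if (!length(sc) || anyNA(sc) || any(sc < 0))
          add(i, "spore_counts", "spore counts must be non-negative integers")
      }
    }
  }
  for (f in c("cpdna.fasta", "allele_exemplars.fasta")) {
    if (!file.exists(file.path(dir, f))) add(0L, f, "required FASTA missing")
  }
  if (!length(issues))
    return(data.frame(row = integer(0), field = character(0),
                      problem = character(0)))
  do.call(rbind, issues)
}

#' Validate an observation table
#'
#' @param df data.frame with columns `taxon_id`, `ploidy`, `alleles`
#'   (`+`-separated group labels), optionally `haplotype`.
#' @return issue data.frame as in [validate_inputs()].
#' @export
validate_observations <- function(df) {
  issues <- list()
  add <- function(row, field, problem)
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, field = field, problem = problem, stringsAsFactors = FALSE)
  dup <- which(duplicated(df$taxon_id))
  for (i in dup) add(i, "taxon_id",
                     sprintf("duplicate individual id '%s'", df$taxon_id[i]))
  for (i in seq_len(nrow(df))) {
    if (!df$ploidy[i] %in% 2:4) add(i, "ploidy", "ploidy out of range 2-4")
    groups <- strsplit(df$alleles[i], "+", fixed = TRUE)[[1]]
    if (df$ploidy[i] %in% 2:4 && length(unique(groups)) > df$ploidy[i])
      add(i, "alleles", "genotype/ploidy mismatch: more alleles than genome copies")
  }
  if (!length(issues))
    return(data.frame(row = integer(0), field = character(0),
                      problem = character(0)))
  do.call(rbind, issues)
}

#' Run the full inference pipeline
#'
#' Executes the stages in dependency order: cytometry and reproduction
#' typing, clone collapsing and allele-group assignment, genotype
#' inference, haplotype grouping, allele-to-haplotype mapping, network
#' reconstruction and regional partition. Any stage failure is recorded
#' and dependent stages are skipped with explicit status. Two runs on the
#' same input produce identical results.
#'
#' @param input a [simulate_complex()] result or a directory in the
#'   [write_simulation()] layout.
#' @param exempt taxon ids excluded from map building.
#' @param enforce_maternal_haplotype passed to [infer_network()].
#' @param min_support,max_error_mismatches clone-collapsing thresholds.
#' @param margin allele-group assignment separation margin.
#' @return list of class `pipeline_report`: `taxa` (per-individual table),
#'   `alleles` (allele call table), `haplotypes` (grouping), `map`,
#'   `network`, `regional`, `stages` (status and messages per stage).
#' @export
run_pipeline <- function(input, exempt = character(0),
                         enforce_maternal_haplotype = TRUE,
                         min_support = 2, max_error_mismatches = 2,
                         margin = 0.005) {
  data <- if (is.character(input)) read_complex(input) else input
  refs <- data$references
  diagnostic <- refs$diagnostic
  if (is.null(diagnostic))
    diagnostic <- infer_diagnostic_window(refs$allele_exemplars)
  stages <- list()
  note <- function(stage, status, msg = "")
    stages[[stage]] <<- list(status = status, message = msg)

  inds <- data$individuals
  # ---- cytometry + reproduction ----
  cyto <- lapply(inds, function(ind) {
    out <- tryCatch({
      pc <- call_ploidy_histogram(ind$histogram)
      rc <- classify_reproduction(ind$spore_counts)
      list(ratio = pc$ratio, genome_size_pg = pc$genome_size_pg,
           ploidy = pc$ploidy, mode = rc$mode, error = NA_character_)
    }, error = function(e) list(ratio = NA_real_, genome_size_pg = NA_real_,
                                ploidy = NA_integer_, mode = NA_character_,
                                error = conditionMessage(e)))
    out
  })
  note("cytometry", "ok",
       sprintf("%d/%d samples called",
               sum(vapply(cyto, function(x) !is.na(x$ploidy), logical(1))),
               length(inds)))

  # ---- clone typing ----
  allele_rows <- list()
  groups_of <- list()
  for (id in names(inds)) {
    calls <- collapse_clones(clone_set(id, "nuclear", inds[[id]]$clones),
                             max_error_mismatches, min_support)
    accepted <- calls[!calls$flagged_singleton, , drop = FALSE]
    grp <- vapply(seq_len(nrow(accepted)), function(i)
      assign_allele_group(accepted$consensus[i], refs$allele_exemplars,
                          diagnostic, margin), character(1))
    calls$group <- NA_character_
    calls$group[!calls$flagged_singleton] <- grp
    calls$individual <- id
    allele_rows[[id]] <- calls
    groups_of[[id]] <- ms_sort(unique(grp[grp != "unassigned"]))
  }
  alleles_tab <- do.call(rbind, allele_rows)
  rownames(alleles_tab) <- NULL
  note("alleles", "ok", sprintf("%d accepted allele calls",
                                sum(!alleles_tab$flagged_singleton)))

  # ---- haplotype grouping (individuals together with exemplars) ----
  hap_status <- "ok"
  hap_groups <- setNames(rep(NA_character_, length(inds)), names(inds))
  grouping <- NULL
  hap_try <- tryCatch({
    seqs <- c(vapply(inds, `[[`, character(1), "cpdna"),
              aln_strings(refs$haplotype_exemplars))
    grouping <- group_haplotypes(seqs)
    ex_ids <- refs$haplotype_exemplars$ids
    cluster_label <- vapply(unique(grouping$groups), function(g) {
      members <- names(grouping$groups)[grouping$groups == g]
      hit <- intersect(members, ex_ids)
      if (length(hit) == 1L) hit else NA_character_
    }, character(1))
    names(cluster_label) <- unique(grouping$groups)
    hap_groups[names(inds)] <- cluster_label[grouping$groups[names(inds)]]
    TRUE
  }, error = function(e) {
    hap_status <<- "failed"
    note("haplotypes", "failed", conditionMessage(e))
    FALSE
  })
  if (hap_status == "ok")
    note("haplotypes", "ok",
         sprintf("%d groups", length(unique(stats::na.omit(hap_groups)))))

  # ---- genotypes & observations ----
  taxa_rows <- list()
  observations <- list()
  for (id in names(inds)) {
    p <- cyto[[id]]$ploidy
    grp <- groups_of[[id]]
    status <- "typed"
    label <- NA_character_
    if (is.na(p)) {
      status <- "uncalled_ploidy"
    } else if (!length(grp)) {
      status <- "no_accepted_alleles"
    } else if (length(grp) > p) {
      status <- "genotype_ploidy_conflict"
    } else {
      gt <- infer_genotype(grp, p)
      label <- gt$label
      observations[[id]] <- taxon_observation(
        id, p, grp, hap_groups[[id]], "apogamous",
        region = inds[[id]]$region, phenology = inds[[id]]$phenology,
        genotype = gt)
    }
    taxa_rows[[id]] <- data.frame(
      taxon_id = id, ploidy = p, ratio = cyto[[id]]$ratio,
      genome_size_pg = round(cyto[[id]]$genome_size_pg),
      mode = cyto[[id]]$mode, alleles = paste(grp, collapse = "+"),
      genotype = label, haplotype = hap_groups[[id]],
      region = inds[[id]]$region, status = status, stringsAsFactors = FALSE)
  }
  taxa <- do.call(rbind, taxa_rows)
  rownames(taxa) <- NULL
  note("genotypes", "ok",
       sprintf("%d/%d taxa typed", sum(taxa$status == "typed"), nrow(taxa)))

  # ---- map + network + regional ----
  map <- NULL
  network <- NULL
  regional <- NULL
  if (length(observations)) {
    map <- infer_allele_haplotype_map(observations, exempt)
    note("map", "ok", sprintf("%d alleles mapped, %d conflicts",
                              length(map$map), nrow(map$conflicts)))
    network <- infer_network(observations, map, enforce_maternal_haplotype)
    note("network", "ok",
         sprintf("cost %d, %d unexplained", network$cost,
                 length(network$unexplained)))
    regional <- regional_partition(network, observations)
    note("regional", "ok", "")
  } else {
    note("map", "skipped", "no typed observations")
    note("network", "skipped", "no typed observations")
    note("regional", "skipped", "no typed observations")
  }
  structure(list(taxa = taxa, alleles = alleles_tab, haplotypes = grouping,
                 observations = observations, map = map, network = network,
                 regional = regional, stages = stages),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  for (s in names(x$stages))
    cat(sprintf("  %-10s %-8s %s\n", s, x$stages[[s]]$status,
                x$stages[[s]]$message))
  invisible(x)
}
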