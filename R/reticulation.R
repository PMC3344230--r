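#' A (possibly presumed) parent taxon
#'
#' @param genotype allele-group multiset (character vector); its size is
#'   the ploidy.
#' @param reproduction `"sexual"` or `"apogamous"`.
#' @param haplotype maternal haplotype group or `NA`.
#' @param status `"observed"` or `"presumed"`.
#' @param provenance optional character notes on how a presumed taxon can
#'   arise (doubling / genome addition sources).
#' @return an object of class `parent_taxon`; its `key` combines genotype
#'   and reproduction mode.
#' @export
parent_taxon <- function(genotype, reproduction = c("sexual", "apogamous"),
                         haplotype = NA, status = c("presumed", "observed"),
                         provenance = character(0)) {
  reproduction <- match.arg(reproduction)
  status <- match.arg(status)
  genotype <- ms_sort(genotype)
  structure(list(genotype = genotype, ploidy = length(genotype),
                 reproduction = reproduction,
                 haplotype = as.character(haplotype), status = status,
                 provenance = provenance,
                 key = paste0(ms_label(genotype), "/", reproduction)),
            class = "parent_taxon")
}

#' @export
print.parent_taxon <- function(x, ...) {
  cat(sprintf("%s %s (%s%s)\n", x$status, ms_label(x$genotype),
              x$reproduction,
              if (!is.na(x$haplotype)) paste0(", ", x$haplotype) else ""))
  invisible(x)
}

#' Hypothesize homozygous diploid progenitors (diploids-first)
#'
#' For every allele lineage, posits one sexual, homozygous diploid
#' progenitor; maternal haplotypes are attached from the allele-haplotype
#' map where available. Progenitors matching an observed sexual taxon are
#' marked observed, otherwise presumed.
#'
#' @param alleles character vector of allele groups.
#' @param map optional [infer_allele_haplotype_map()] result (or named
#'   vector allele -> haplotype).
#' @param observed optional list of observed [taxon_observation()] used to
#'   match progenitors to real taxa.
#' @return list of [parent_taxon()] (sorted by allele).
#' @export
hypothesize_progenitors <- function(alleles, map = NULL, observed = list()) {
  alleles <- ms_sort(unique(as.character(alleles)))
  if (!length(alleles)) return(list())
  hapmap <- if (inherits(map, "allele_haplotype_map")) map$map else map
  lapply(alleles, function(a) {
    g <- c(a, a)
    hit <- Filter(function(o) o$reproduction == "sexual" &&
                    ms_equal(o$genotype$candidates[[1]], g) &&
                    length(o$genotype$candidates) == 1L, observed)
    parent_taxon(g, "sexual",
                 haplotype = if (!is.null(hapmap) && a %in% names(hapmap))
                   hapmap[[a]] else NA,
                 status = if (length(hit)) "observed" else "presumed")
  })
}

#' Derive candidate sexual tetraploids
#'
#' Sexual tetraploids can arise by genome doubling of any diploid genotype
#' (g becomes g+g) or by genome addition between two sexual homozygous
#' diploids (aa x bb becomes aabb). Duplicate genotypes are merged with
#' multiple provenances.
#'
#' @param diploids list of [parent_taxon()] of ploidy 2 (sexual).
#' @param apogamous_diploids list of [parent_taxon()] of ploidy 2
#'   (apogamous hybrids; doubling sources only).
#' @param mechanisms subset of `c("doubling", "genome_addition")`.
#' @param observed optional observed taxa for status matching.
#' @return list of [parent_taxon()] tetraploids.
#' @export
derive_sexual_tetraploids <- function(diploids, apogamous_diploids = list(),
                                      mechanisms = c("doubling", "genome_addition"),
                                      observed = list()) {
  out <- list()
  add <- function(genotype, haplotype, prov) {
    key <- ms_label(genotype)
    if (!is.null(out[[key]])) {
      prev <- out[[key]]
      prev$provenance <- unique(c(prev$provenance, prov))
      # a known haplotype (e.g. from a doubling source) survives an
      # unknown alternative provenance; two conflicting known haplotypes
      # leave the node's maternal lineage undetermined
      hs <- unique(stats::na.omit(c(prev$haplotype, haplotype)))
      prev$haplotype <- if (length(hs) == 1L) hs else NA_character_
      out[[key]] <<- prev
      return(invisible())
    }
    hit <- Filter(function(o) o$reproduction == "sexual" &&
                    length(o$genotype$candidates) == 1L &&
                    ms_equal(o$genotype$candidates[[1]], genotype), observed)
    out[[key]] <<- parent_taxon(genotype, "sexual", haplotype,
                                status = if (length(hit)) "observed" else "presumed",
                                provenance = prov)
  }
  if ("doubling" %in% mechanisms) {
    for (p in c(diploids, apogamous_diploids)) {
      stopifnot(p$ploidy == 2L)
      add(c(p$genotype, p$genotype), p$haplotype,
          sprintf("doubling of %s", ms_label(p$genotype)))
    }
  }
  if ("genome_addition" %in% mechanisms) {
    sex <- Filter(function(p) p$reproduction == "sexual", diploids)
    if (length(sex) >= 2) {
      for (i in seq_len(length(sex) - 1)) for (j in (i + 1):length(sex)) {
        a <- sex[[i]]; b <- sex[[j]]
        add(c(a$genotype, b$genotype), NA_character_,
            sprintf("genome addition %s x %s",
                    ms_label(a$genotype), ms_label(b$genotype)))
      }
    }
  }
  unname(out[order(names(out))])
}

#' Enumerate crosses compatible with an observed offspring
#'
#' Gamete rules: a sexual parent of even ploidy p contributes any
#' size-(p/2) sub-multiset of its genotype (tetrasomic segregation for
#' tetraploids); an apogamous parent contributes its full genotype
#' unreduced and acts only as father. A cross is emitted when the two
#' gametes sum to an offspring genotype candidate and, if enforced and
#' known, the mother's haplotype matches the offspring's. When the
#' maternal constraint is off (or the offspring haplotype unknown),
#' sexual-by-sexual crosses are reported as unordered parent pairs, since
#' nothing then distinguishes mother from father.
#'
#' @param offspring a [taxon_observation()] (apogamous).
#' @param parent_pool list of [parent_taxon()].
#' @param enforce_maternal_haplotype require mother haplotype = offspring
#'   haplotype when both are known (default TRUE).
#' @param allow_apogamous_mother permit apogamous maternal parents
#'   (exploratory; default FALSE).
#' @return data.frame with columns `offspring`, `mother`, `mother_gamete`,
#'   `father`, `father_gamete`, `mother_status`, `father_status`,
#'   `mother_key`, `father_key`; zero rows when no cross is feasible.
#' @export
enumerate_crosses <- function(offspring, parent_pool,
                              enforce_maternal_haplotype = TRUE,
                              allow_apogamous_mother = FALSE) {
  stopifnot(inherits(offspring, "taxon_observation"))
  if (!length(parent_pool)) stopf("parent pool is empty")
  hap_known <- !is.na(offspring$haplotype)
  constrain <- enforce_maternal_haplotype && hap_known
  rows <- list()
  seen <- character(0)
  for (cand in offspring$genotype$candidates) {
    p_off <- length(cand)
    for (m in parent_pool) {
      mother_ok <- m$reproduction == "sexual" ||
        (allow_apogamous_mother && m$reproduction == "apogamous")
      if (!mother_ok) next
      m_gams <- if (m$reproduction == "sexual") {
        if (m$ploidy %% 2L != 0L) next
        ms_subsets(m$genotype, m$ploidy %/% 2L)
      } else list(m$genotype)
      # strict maternal constraint: an offspring with a known haplotype can
      # only descend from a mother carrying that haplotype; mothers of
      # unknown haplotype are not admitted as maternal candidates, so taxa
      # without a compatible mother surface as unexplained rather than
      # being resolved arbitrarily
      if (constrain && (is.na(m$haplotype) ||
                        m$haplotype != offspring$haplotype)) next
      for (gm in m_gams) {
        need <- p_off - length(gm)
        if (need <= 0) next
        for (f in parent_pool) {
          f_gams <- if (f$reproduction == "sexual") {
            if (f$ploidy %% 2L != 0L) next
            if (f$ploidy %/% 2L != need) next
            ms_subsets(f$genotype, need)
          } else {
            if (f$ploidy != need) next
            list(f$genotype)
          }
          for (gf in f_gams) {
            if (!ms_equal(c(gm, gf), cand)) next
            sym <- !constrain && m$reproduction == "sexual" &&
              f$reproduction == "sexual"
            pair <- c(paste(m$key, ms_label(gm), sep = ":"),
                      paste(f$key, ms_label(gf), sep = ":"))
            key <- if (sym) paste(sort(pair), collapse = " x ")
                   else paste(pair, collapse = " -> ")
            if (key %in% seen) next
            seen <- c(seen, key)
            rows[[length(rows) + 1L]] <- data.frame(
              offspring = offspring$taxon_id,
              mother = ms_label(m$genotype), mother_gamete = ms_label(gm),
              father = ms_label(f$genotype), father_gamete = ms_label(gf),
              mother_status = m$status, father_status = f$status,
              mother_key = m$key, father_key = f$key,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(offspring = character(0), mother = character(0),
                      mother_gamete = character(0), father = character(0),
                      father_gamete = character(0), mother_status = character(0),
                      father_status = character(0), mother_key = character(0),
                      father_key = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$mother, out$father, out$mother_gamete, out$father_gamete), ,
      drop = FALSE]
}

# Build the full candidate parent pool for a set of observations.
build_parent_pool <- function(observations, map = NULL,
                              mechanisms = c("doubling", "genome_addition"),
                              max_intermediate_depth = 1L) {
  alleles <- ms_sort(unique(unlist(lapply(observations, `[[`, "alleles"))))
  progenitors <- hypothesize_progenitors(alleles, map, observations)
  pool <- progenitors
  # observed taxa as apogamous fathers (one entry per genotype candidate)
  for (o in observations) {
    if (o$reproduction != "apogamous") next
    for (cand in o$genotype$candidates)
      pool[[length(pool) + 1L]] <- parent_taxon(cand, "apogamous",
                                                o$haplotype, "observed")
  }
  # presumed apogamous diploid intermediates (depth-1 hybrids of progenitors)
  if (max_intermediate_depth >= 1L && length(alleles) >= 2L) {
    observed_dips <- unique(unlist(lapply(Filter(function(o)
      o$reproduction == "apogamous" && o$ploidy == 2L, observations),
      function(o) vapply(o$genotype$candidates, ms_label, character(1)))))
    for (i in seq_len(length(alleles) - 1L)) for (j in (i + 1L):length(alleles)) {
      g <- ms_sort(c(alleles[i], alleles[j]))
      if (ms_label(g) %in% observed_dips) next  # already in pool as observed
      pool[[length(pool) + 1L]] <- parent_taxon(g, "apogamous", NA, "presumed")
    }
  }
  # candidate sexual tetraploids from all diploid genotypes in play
  dip_sources <- list()
  for (p in pool) if (p$ploidy == 2L) dip_sources[[p$key]] <- p
  sex_dips <- Filter(function(p) p$reproduction == "sexual", dip_sources)
  apo_dips <- Filter(function(p) p$reproduction == "apogamous", dip_sources)
  tets <- derive_sexual_tetraploids(unname(sex_dips), unname(apo_dips),
                                    mechanisms, observations)
  pool <- c(pool, tets)
  # deduplicate by key; observed status wins over presumed
  uniq <- list()
  for (p in pool) {
    k <- p$key
    if (is.null(uniq[[k]]) || (uniq[[k]]$status == "presumed" &&
                               p$status == "observed")) uniq[[k]] <- p
  }
  list(pool = unname(uniq[order(names(uniq))]), progenitors = progenitors)
}

#' Infer a minimal reticulate origin network
#'
#' Searches over one originating cross per observed apogamous taxon,
#' drawing parents from observed taxa, hypothesized diploid progenitors,
#' derived sexual tetraploids and depth-limited apogamous intermediates.
#' The objective is the diploids-first parsimony criterion: minimise the
#' number of presumed (unobserved) taxa used, with ties broken by fewer
#' distinct parent nodes overall and then deterministic lexicographic
#' order. The search is exhaustive branch-and-bound at the scale of a
#' species complex (about 15 taxa, 8 alleles); all co-optimal networks are
#' retained.
#'
#' @param observations list of [taxon_observation()] (apogamous taxa are
#'   explained; sexual taxa only serve as parents).
#' @param map optional [infer_allele_haplotype_map()] result.
#' @param enforce_maternal_haplotype require maternal haplotype match
#'   (default TRUE).
#' @param mechanisms tetraploid-formation mechanisms allowed. Triploid
#'   "ploidy reduction" is deliberately not an event type.
#' @param max_co_optimal cap on retained co-optimal networks.
#' @return list of class `reticulate_network`: `crosses` (edge table of
#'   the first optimal network), `cost` (number of presumed nodes used),
#'   `presumed_nodes`, `progenitors`, `co_optimal` (list of alternative
#'   edge tables at equal cost), `unexplained` (taxon ids with no feasible
#'   cross), `pool` (the candidate parent list).
#' @export
infer_network <- function(observations, map = NULL,
                          enforce_maternal_haplotype = TRUE,
                          mechanisms = c("doubling", "genome_addition"),
                          max_co_optimal = 64L) {
  bp <- build_parent_pool(observations, map, mechanisms)
  pool <- bp$pool
  status_of <- setNames(vapply(pool, `[[`, character(1), "status"),
                        vapply(pool, `[[`, character(1), "key"))
  targets <- Filter(function(o) o$reproduction == "apogamous", observations)
  options <- list()
  unexplained <- character(0)
  for (o in targets) {
    cr <- enumerate_crosses(o, pool, enforce_maternal_haplotype)
    if (!nrow(cr)) {
      unexplained <- c(unexplained, o$taxon_id)
      next
    }
    # a cross may not use the offspring itself as a parent
    self_keys <- vapply(o$genotype$candidates, function(g)
      paste0(ms_label(g), "/apogamous"), character(1))
    cr <- cr[!(cr$mother_key %in% self_keys | cr$father_key %in% self_keys), ,
             drop = FALSE]
    if (!nrow(cr)) {
      unexplained <- c(unexplained, o$taxon_id)
      next
    }
    options[[o$taxon_id]] <- cr
  }
  ids <- names(options)
  # per-option presumed-node requirement sets
  reqs <- lapply(options, function(cr)
    lapply(seq_len(nrow(cr)), function(i) {
      ks <- c(cr$mother_key[i], cr$father_key[i])
      sort(unique(ks[status_of[ks] == "presumed"]))
    }))
  allnodes <- lapply(options, function(cr)
    lapply(seq_len(nrow(cr)), function(i)
      sort(unique(c(cr$mother_key[i], cr$father_key[i])))))
  # order taxa by fewest options first (tighter bounding)
  ord <- order(vapply(options, nrow, integer(1)))
  ids <- ids[ord]
  best_cost <- Inf
  best_nodes <- Inf
  solutions <- list()
  choice <- integer(length(ids))
  recurse <- function(k, used_presumed, used_nodes) {
    if (length(used_presumed) > best_cost) return()
    if (k > length(ids)) {
      cost <- length(used_presumed)
      nn <- length(used_nodes)
      if (cost < best_cost || (cost == best_cost && nn < best_nodes)) {
        best_cost <<- cost
        best_nodes <<- nn
        solutions <<- list(choice[seq_along(ids)])
      } else if (cost == best_cost && nn == best_nodes &&
                 length(solutions) < max_co_optimal) {
        solutions[[length(solutions) + 1L]] <<- choice[seq_along(ids)]
      }
      return()
    }
    id <- ids[k]
    for (i in seq_len(nrow(options[[id]]))) {
      choice[k] <<- i
      recurse(k + 1L, union(used_presumed, reqs[[id]][[i]]),
              union(used_nodes, allnodes[[id]][[i]]))
    }
  }
  if (length(ids)) recurse(1L, character(0), character(0)) else best_cost <- 0
  assemble <- function(sel) {
    do.call(rbind, lapply(seq_along(ids), function(k)
      options[[ids[k]]][sel[k], , drop = FALSE]))
  }
  empty_crosses <- data.frame(
    offspring = character(0), mother = character(0),
    mother_gamete = character(0), father = character(0),
    father_gamete = character(0), mother_status = character(0),
    father_status = character(0), mother_key = character(0),
    father_key = character(0))
  crosses <- if (length(solutions)) assemble(solutions[[1]]) else empty_crosses
  presumed <- if (length(solutions)) {
    ks <- unique(c(crosses$mother_key, crosses$father_key))
    sort(ks[status_of[ks] == "presumed"])
  } else character(0)
  structure(list(
    crosses = crosses,
    cost = if (is.finite(best_cost)) best_cost else 0L,
    presumed_nodes = presumed,
    progenitors = bp$progenitors,
    co_optimal = lapply(solutions, assemble),
    unexplained = unexplained,
    pool = pool), class = "reticulate_network")
}

#' @export
print.reticulate_network <- function(x, ...) {
  cat(sprintf("reticulate network: %d crosses, %d presumed taxa, %d co-optimal\n",
              nrow(x$crosses), x$cost, length(x$co_optimal)))
  if (length(x$unexplained))
    cat("unexplained:", paste(x$unexplained, collapse = ", "), "\n")
  invisible(x)
}

#' Partition a network and its observations by region
#'
#' @param network a [infer_network()] result.
#' @param observations the observations the network explains.
#' @return list with `regions` (per-region list holding `taxa` and the
#'   induced `crosses`), `alleles` / `haplotypes` / `cytotypes` inventory
#'   data.frames with private/shared flags, and `unplaced` taxa lacking a
#'   region label.
#' @export
regional_partition <- function(network, observations) {
  obs_regions <- lapply(observations, `[[`, "region")
  names(obs_regions) <- vapply(observations, `[[`, character(1), "taxon_id")
  unplaced <- names(obs_regions)[lengths(obs_regions) == 0L]
  regions <- sort(unique(unlist(obs_regions)))
  per_region <- lapply(setNames(regions, regions), function(r) {
    taxa <- names(obs_regions)[vapply(obs_regions, function(x) r %in% x, logical(1))]
    list(taxa = taxa,
         crosses = network$crosses[network$crosses$offspring %in% taxa, ,
                                   drop = FALSE])
  })
  inv <- function(feature) {
    vals <- lapply(observations, function(o) switch(feature,
      allele = o$alleles, haplotype = o$haplotype,
      cytotype = as.character(o$ploidy)))
    items <- sort(unique(stats::na.omit(unlist(vals))))
    do.call(rbind, lapply(items, function(it) {
      rr <- sort(unique(unlist(obs_regions[vapply(seq_along(vals), function(i)
        it %in% vals[[i]], logical(1))])))
      data.frame(item = it, regions = paste(rr, collapse = ","),
                 private = length(rr) == 1L, stringsAsFactors = FALSE)
    }))
  }
  list(regions = per_region, alleles = inv("allele"),
       haplotypes = inv("haplotype"), cytotypes = inv("cytotype"),
       unplaced = unplaced)
}
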