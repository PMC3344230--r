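test_that("diploids-first progenitors are one homozygous sexual diploid per allele", {
  pg <- hypothesize_progenitors(c("X1", "X2", "X3", "X4", "Y"))
  expect_length(pg, 5)
  labels <- vapply(pg, function(p) paste(p$genotype, collapse = ""), "")
  expect_equal(labels, c("X1X1", "X2X2", "X3X3", "X4X4", "YY"))
  expect_true(all(vapply(pg, `[[`, "", "reproduction") == "sexual"))
  expect_true(all(vapply(pg, `[[`, "", "status") == "presumed"))

  one <- hypothesize_progenitors("A")
  expect_equal(paste(one[[1]]$genotype, collapse = ""), "AA")
  expect_length(hypothesize_progenitors(character(0)), 0)
})

test_that("sexual tetraploids arise by doubling and genome addition", {
  x2y <- parent_taxon(c("X2", "Y"), "apogamous")
  x4y <- parent_taxon(c("X4", "Y"), "apogamous")
  x4x4 <- parent_taxon(c("X4", "X4"), "sexual")
  yy <- parent_taxon(c("Y", "Y"), "sexual")
  tets <- derive_sexual_tetraploids(list(x4x4, yy), list(x2y, x4y))
  labels <- vapply(tets, function(p) paste(p$genotype, collapse = ""), "")
  expect_true(all(c("X2X2YY", "X4X4YY", "X4X4X4X4", "YYYY") %in% labels))
  # X4X4YY is reachable both by doubling X4Y and by addition X4X4 x YY
  x4x4yy <- tets[[which(labels == "X4X4YY")]]
  expect_length(x4x4yy$provenance, 2)
  expect_true(any(grepl("doubling of X4Y", x4x4yy$provenance)))
  expect_true(any(grepl("genome addition", x4x4yy$provenance)))
})

test_that("the published three crosses for genotype X2X3Y are recovered exactly", {
  pool <- list(parent_taxon(c("X2", "X2"), "sexual"),
               parent_taxon(c("X3", "X3"), "sexual"),
               parent_taxon(c("Y", "Y"), "sexual"),
               parent_taxon(c("X2", "X2", "Y", "Y"), "sexual"),
               parent_taxon(c("X3", "X3", "Y", "Y"), "sexual"),
               parent_taxon(c("X3", "Y"), "apogamous"))
  off <- taxon_observation("morph6", 3, c("X2", "X3", "Y"))
  cr <- enumerate_crosses(off, pool, enforce_maternal_haplotype = FALSE)
  expect_equal(nrow(cr), 3)
  got <- sort(paste(cr$mother, cr$father, sep = " x "))
  expect_equal(got, sort(c("X2X2 x X3X3YY", "X3X3 x X2X2YY", "X2X2 x X3Y")))
})

test_that("the morph 1 cross is unique under the maternal constraint", {
  map <- c(X2 = "alpha")
  pool <- hypothesize_progenitors(c("X1", "X2", "X3", "X4", "Y"), map)
  off <- taxon_observation("morph1", 2, c("X2", "Y"), haplotype = "alpha")
  cr <- enumerate_crosses(off, pool, enforce_maternal_haplotype = TRUE)
  expect_equal(nrow(cr), 1)
  expect_equal(cr$mother, "X2X2")
  expect_equal(cr$father, "YY")
})

test_that("offspring alleles missing from the pool yield no crosses", {
  pool <- hypothesize_progenitors(c("A", "B"))
  off <- taxon_observation("t", 2, c("A", "Z"))
  expect_equal(nrow(enumerate_crosses(off, pool, FALSE)), 0)
})

test_that("every emitted cross conserves alleles and ploidy", {
  fx <- cadieri_observations()
  map <- infer_allele_haplotype_map(fx$observations, fx$exempt)
  net <- infer_network(fx$observations, map)
  expect_equal(nrow(net$crosses), 11)
  expect_length(net$unexplained, 0)
  # morph 5's maternal lineage stays ambiguous: several haplotype-compatible
  # mothers are feasible, none is singled out
  cr5 <- enumerate_crosses(fx$observations[["morph5_3x"]], net$pool,
                           enforce_maternal_haplotype = TRUE)
  expect_gte(length(unique(cr5$mother)), 2)
  obs_by_id <- fx$observations
  for (i in seq_len(nrow(net$crosses))) {
    row <- net$crosses[i, ]
    o <- obs_by_id[[row$offspring]]
    gametes <- c(parse_genotype_label(row$mother_gamete),
                 parse_genotype_label(row$father_gamete))
    hit <- any(vapply(o$genotype$candidates, function(cand)
      identical(sort(gametes), sort(cand)), logical(1)))
    expect_true(hit, info = row$offspring)
    expect_equal(length(gametes), o$ploidy, info = row$offspring)
  }
})

test_that("maternal haplotype propagates through every constrained cross", {
  fx <- cadieri_observations()
  map <- infer_allele_haplotype_map(fx$observations, fx$exempt)
  net <- infer_network(fx$observations, map, enforce_maternal_haplotype = TRUE)
  hap_of_node <- function(key) {
    p <- Filter(function(q) q$key == key, net$pool)[[1]]
    p$haplotype
  }
  for (i in seq_len(nrow(net$crosses))) {
    row <- net$crosses[i, ]
    mh <- hap_of_node(row$mother_key)
    oh <- fx$observations[[row$offspring]]$haplotype
    if (!is.na(mh) && !is.na(oh)) expect_equal(mh, oh, info = row$offspring)
  }
})

test_that("the fixture network presumes exactly the five diploid progenitors", {
  fx <- cadieri_observations()
  map <- infer_allele_haplotype_map(fx$observations, fx$exempt)
  net <- infer_network(fx$observations, map)
  pg <- vapply(net$progenitors, function(p) paste(p$genotype, collapse = ""), "")
  expect_equal(sort(pg), c("X1X1", "X2X2", "X3X3", "X4X4", "YY"))
  # all five progenitors appear as parents in the optimal network
  used <- unique(c(net$crosses$mother_key, net$crosses$father_key))
  expect_true(all(paste0(pg, "/sexual") %in% used))
})

test_that("a single hybrid diploid costs its two presumed progenitors", {
  obs <- list(taxon_observation("h1", 2, c("A", "B"), haplotype = "h1"))
  map <- structure(list(map = c(A = "h1"), conflicts = NULL, ambiguous = NULL),
                   class = "allele_haplotype_map")
  net <- infer_network(obs, map)
  expect_equal(net$cost, 2)
  expect_equal(nrow(net$crosses), 1)
  expect_equal(net$crosses$mother, "AA")
  expect_equal(net$crosses$father, "BB")
})

test_that("network cost matches a brute-force assignment oracle on small instances", {
  set.seed(51)
  for (rep in 1:20) {
    alleles <- LETTERS[1:3]
    n_obs <- sample(2:4, 1)
    obs <- lapply(seq_len(n_obs), function(i) {
      p <- sample(2:3, 1)
      al <- sample(alleles, sample(2:min(p, 3), 1))
      taxon_observation(paste0("t", i), p, al)
    })
    names(obs) <- vapply(obs, `[[`, "", "taxon_id")
    net <- infer_network(obs, NULL, enforce_maternal_haplotype = FALSE)
    explained <- setdiff(names(obs), net$unexplained)
    # oracle: exhaustively combine per-taxon cross options
    bp_pool <- net$pool
    status_of <- setNames(vapply(bp_pool, `[[`, "", "status"),
                          vapply(bp_pool, `[[`, "", "key"))
    opts <- lapply(obs[explained], function(o)
      enumerate_crosses(o, bp_pool, FALSE))
    opts <- lapply(names(opts), function(id) {
      cr <- opts[[id]]
      self_keys <- vapply(obs[[id]]$genotype$candidates, function(g)
        paste0(paste(sort(g), collapse = ""), "/apogamous"), "")
      cr[!(cr$mother_key %in% self_keys | cr$father_key %in% self_keys), ,
         drop = FALSE]
    })
    if (!length(opts) || any(vapply(opts, nrow, 1L) == 0)) next
    grid <- expand.grid(lapply(opts, function(cr) seq_len(nrow(cr))))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      used <- character(0)
      for (j in seq_along(opts)) {
        row <- opts[[j]][grid[g, j], ]
        used <- union(used, c(row$mother_key, row$father_key))
      }
      cost <- sum(status_of[used] == "presumed")
      if (cost < best) best <- cost
    }
    expect_equal(net$cost, best, info = paste("instance", rep))
  }
})

test_that("observing a sexual taxon matching a presumed node never raises cost", {
  obs <- list(taxon_observation("h1", 2, c("A", "B"), haplotype = "hA"),
              taxon_observation("h2", 3, c("A", "B")))
  base <- infer_network(obs, NULL, enforce_maternal_haplotype = FALSE)
  obs2 <- c(obs, list(taxon_observation("pA", 2, "A", haplotype = "hA",
                                        reproduction = "sexual")))
  with_sex <- infer_network(obs2, NULL, enforce_maternal_haplotype = FALSE)
  expect_lte(with_sex$cost, base$cost)
})

test_that("regional partition flags private alleles and unplaced taxa", {
  fx <- cadieri_observations()
  map <- infer_allele_haplotype_map(fx$observations, fx$exempt)
  net <- infer_network(fx$observations, map)
  rp <- regional_partition(net, fx$observations)
  x4 <- rp$alleles[rp$alleles$item == "X4", ]
  expect_true(x4$private)
  expect_equal(x4$regions, "Hainan")
  # triploid cytotype is confined to Taiwan
  t3 <- rp$cytotypes[rp$cytotypes$item == "3", ]
  expect_equal(t3$regions, "Taiwan")
  expect_length(rp$unplaced, 0)
  # dropping a region label routes the taxon to unplaced
  obs2 <- fx$observations
  obs2[["morph1_2x"]]$region <- character(0)
  rp2 <- regional_partition(net, obs2)
  expect_equal(rp2$unplaced, "morph1_2x")
  # single-region data collapse to one subnetwork equal to the input
  one <- lapply(fx$observations, function(o) { o$region <- "Taiwan"; o })
  rp3 <- regional_partition(net, one)
  expect_length(rp3$regions, 1)
  expect_equal(nrow(rp3$regions$Taiwan$crosses), nrow(net$crosses))
})
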