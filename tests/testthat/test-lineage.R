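# Tiny aligned clone fabric: a base sequence with controlled substitutions.
mkseq <- function(base, subs = integer(0)) {
  v <- strsplit(base, "")[[1]]
  for (pos in subs) v[pos] <- setdiff(c("A", "C", "G", "T"), v[pos])[1]
  paste(v, collapse = "")
}

test_that("clone collapsing separates alleles and absorbs PCR errors", {
  a <- strrep("ACGTT", 8)   # 40 bp allele a
  b <- mkseq(a, c(3, 9, 15, 22, 30))  # clearly distinct allele b
  clones <- c(c1 = a, c2 = a, c3 = a, c4 = mkseq(a, 5), c5 = b, c6 = b)
  calls <- collapse_clones(clone_set("ind1", "nuclear", clones))
  accepted <- calls[!calls$flagged_singleton, ]
  expect_equal(nrow(accepted), 2)
  expect_setequal(accepted$support, c(4, 2))
  expect_equal(accepted$consensus[accepted$support == 4], a)

  one <- collapse_clones(clone_set("ind2", "nuclear", c(c1 = a)))
  expect_true(one$flagged_singleton)
  expect_equal(nrow(one), 1)

  four <- collapse_clones(clone_set("ind3", "nuclear", setNames(rep(a, 4), paste0("c", 1:4))))
  expect_equal(four$support, 4)
  expect_false(four$flagged_singleton)
})

test_that("clone collapsing is invariant to input order", {
  set.seed(41)
  a <- strrep("ACGTAGGT", 6)
  b <- mkseq(a, c(2, 11, 20, 29, 38))
  clones <- c(a, mkseq(a, 7), b, b, mkseq(b, 13), a)
  names(clones) <- paste0("c", 1:6)
  ref <- collapse_clones(clones)[, c("consensus", "support")]
  for (i in 1:5) {
    shuf <- sample(clones)
    got <- collapse_clones(shuf)[, c("consensus", "support")]
    expect_equal(got, ref)
  }
})

test_that("shared deletions do not split clones but extent differences count", {
  base <- strrep("ACGTT", 6)
  del <- paste0(substr(base, 1, 10), strrep("-", 5), substr(base, 16, 30))
  calls <- collapse_clones(c(c1 = del, c2 = del, c3 = base, c4 = base))
  expect_equal(nrow(calls), 2)
  expect_equal(calls$support, c(2, 2))
})

test_that("allele group assignment honours the diagnostic indel and margin", {
  set.seed(42)
  cfg <- simulation_config(seed = 7)
  refs <- simulate_reference_sequences(cfg)
  ex <- refs$allele_exemplars
  # a Y-clade query is called Y regardless of subgroup distances
  yq <- paste(aln_row(ex, "Y"), collapse = "")
  expect_equal(assign_allele_group(yq, ex, refs$diagnostic), "Y")
  x3 <- paste(aln_row(ex, "X3"), collapse = "")
  expect_equal(assign_allele_group(x3, ex, refs$diagnostic), "X3")
  # a query equidistant from two exemplars stays unassigned: take the
  # midpoint between X1 and X2 (alternate their private differences)
  r1 <- aln_row(ex, "X1"); r2 <- aln_row(ex, "X2")
  diff_at <- which(r1 != r2 & r1 %in% c("A", "C", "G", "T") &
                     r2 %in% c("A", "C", "G", "T"))
  mid <- r1
  take2 <- diff_at[seq(1, length(diff_at), by = 2)]
  mid[take2] <- r2[take2]
  expect_equal(assign_allele_group(paste(mid, collapse = ""), ex,
                                   refs$diagnostic), "unassigned")
})

test_that("genotype candidates enumerate dosage ambiguity with star labels", {
  g <- infer_genotype(c("X2", "Y"), 2)
  expect_equal(g$label, "X2Y")
  expect_length(g$candidates, 1)

  g3 <- infer_genotype(c("X3", "Y"), 3)
  expect_equal(g3$label, "X3*Y")
  expect_setequal(vapply(g3$candidates, paste, "", collapse = ""),
                  c("X3X3Y", "X3YY"))

  g33 <- infer_genotype(c("X2", "X3", "Y"), 3)
  expect_equal(g33$label, "X2X3Y")
  expect_length(g33$candidates, 1)

  g4 <- infer_genotype(c("X2", "X4", "Y"), 4)
  expect_setequal(vapply(g4$candidates, paste, "", collapse = ""),
                  c("X2X2X4Y", "X2X4X4Y", "X2X4YY"))

  expect_error(infer_genotype(c("A", "B", "C"), 2), "more alleles")
})

test_that("candidate counts equal compositions of ploidy over groups", {
  for (p in 2:4) {
    for (k in 1:p) {
      groups <- paste0("g", seq_len(k))
      got <- length(infer_genotype(groups, p)$candidates)
      expect_equal(got, choose(p - 1, k - 1),
                   info = sprintf("p=%d k=%d", p, k))
    }
  }
})

test_that("haplotype grouping recovers simulated deep clusters exactly", {
  set.seed(43)
  base <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  centers <- lapply(1:3, function(i) {
    v <- base
    flip <- sample(400, 16)  # ~4% between groups
    for (p in flip) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    v
  })
  seqs <- character(0)
  truth <- character(0)
  for (i in 1:3) for (j in 1:4) {
    v <- centers[[i]]
    flip <- sample(400, 2)  # ~0.5% within groups
    for (p in flip) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    id <- sprintf("g%d_s%d", i, j)
    seqs[id] <- paste(v, collapse = "")
    truth[id] <- as.character(i)
  }
  hg <- group_haplotypes(seqs)
  expect_equal(hg$n_groups, 3)
  # exact partition match (adjusted Rand 1): groups refine truth and back
  tab <- table(hg$groups, truth)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("identical haplotypes collapse to one group", {
  hg <- group_haplotypes(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(hg$n_groups, 1)
  hg2 <- group_haplotypes(c(a = "ACGTACGT", b = "ACGTACGA"))
  expect_equal(hg2$n_groups, 2)
})

test_that("the complex fixture carries three haplotype groups and five alleles", {
  fx <- cadieri_observations()
  s <- observation_summary(fx$observations)
  expect_equal(s$n_haplotype_groups, 3)
  expect_equal(s$n_alleles, 5)
})

test_that("the maternal map reproduces the published allele-haplotype table", {
  fx <- cadieri_observations()
  m <- infer_allele_haplotype_map(fx$observations, fx$exempt)
  expect_equal(m$map[["X1"]], "alpha")
  expect_equal(m$map[["X2"]], "alpha")
  expect_equal(m$map[["X3"]], "gamma")
  expect_equal(m$map[["X4"]], "beta")
  expect_false("Y" %in% names(m$map))
  expect_equal(nrow(m$conflicts), 0)
})

test_that("an underdetermined single taxon reports candidates, not a guess", {
  obs <- list(taxon_observation("t1", 2, c("X1", "Y"), "alpha"))
  m <- infer_allele_haplotype_map(obs)
  expect_length(m$map, 0)
  expect_setequal(m$ambiguous$allele, c("X1", "Y"))
  expect_equal(nrow(m$conflicts), 0)
})

test_that("haplotype disagreement among carriers yields a conflict record", {
  obs <- list(taxon_observation("t1", 2, c("X3", "Y"), "alpha"),
              taxon_observation("t2", 2, c("X3", "Y"), "gamma"))
  m <- infer_allele_haplotype_map(obs)
  expect_false("X3" %in% names(m$map))
  expect_true("X3" %in% m$conflicts$allele)
})
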