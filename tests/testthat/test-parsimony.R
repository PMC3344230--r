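cm4 <- function(states) {
  m <- matrix(states, 4, 1, dimnames = list(c("A", "B", "C", "D"), NULL))
  character_matrix(m)
}

test_that("Fitch length matches hand counts on four taxa", {
  cm <- cm4(c("0", "0", "1", "1"))
  expect_equal(fitch_length(ape::read.tree(text = "((A,B),(C,D));"), cm), 1)
  expect_equal(fitch_length(ape::read.tree(text = "((A,C),(B,D));"), cm), 2)
  # all-missing characters contribute nothing
  cm2 <- cm4(c("?", "?", "?", "?"))
  expect_equal(fitch_length(ape::read.tree(text = "((A,B),(C,D));"), cm2), 0)
  expect_error(fitch_length(ape::read.tree(text = "((A,B),(C,E));"), cm),
               "leaf without")
})

test_that("per-character bounds count states and majorities", {
  m <- matrix(c("A", "A", "C", "C", "C"), 5, 1,
              dimnames = list(paste0("t", 1:5), NULL))
  b <- fitch_bounds(character_matrix(m))
  expect_equal(c(b$m, b$g), c(1L, 2L))
  m2 <- matrix(c("A", "A", "A"), 3, 1, dimnames = list(paste0("t", 1:3), NULL))
  expect_equal(unlist(fitch_bounds(character_matrix(m2))), c(m = 0L, g = 0L))
  m3 <- matrix(c("A", "C", "G", "T"), 4, 1,
               dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(unlist(fitch_bounds(character_matrix(m3))), c(m = 3L, g = 3L))
})

test_that("exhaustive search finds the compatible tree with CI 1", {
  taxa <- c("A", "B", "C", "D")
  m <- split_matrix(taxa, c("A", "B"), 4)
  ex <- exhaustive_mp(character_matrix(m))
  expect_equal(ex$n_topologies, 3)
  expect_equal(length(ex$trees), 1)
  expect_equal(ex$score$length, 4)
  expect_equal(ex$score$ci, 1)
  expect_true(ape::is.monophyletic(ape::root(ex$trees[[1]], "D"), c("A", "B")))
})

test_that("invariant matrices tie every topology at length zero", {
  m <- matrix("A", 5, 3, dimnames = list(paste0("t", 1:5), NULL))
  ex <- exhaustive_mp(character_matrix(m))
  expect_equal(ex$score$length, 0)
  expect_equal(length(ex$trees), 15)
  h <- heuristic_mp(character_matrix(m), n_random_addition = 3, seed = 1)
  expect_equal(h$score$length, 0)
})

test_that("heuristic search matches the exhaustive oracle on 6-taxon data", {
  set.seed(31)
  for (i in 1:10) {
    cm <- character_matrix(random_binary_matrix(6, 20))
    ex <- exhaustive_mp(cm)
    h <- heuristic_mp(cm, n_random_addition = 5, seed = i)
    expect_equal(h$score$length, ex$score$length, info = paste("case", i))
  }
})

test_that("Fitch equals brute-force minimisation and phangorn on small trees", {
  set.seed(32)
  skip_if_not_installed("phangorn")
  for (i in 1:40) {
    n <- sample(4:6, 1)
    taxa <- paste0("t", 1:n)
    m <- matrix(sample(c("A", "C", "G", "T", "?"), n * 3, replace = TRUE,
                       prob = c(rep(0.22, 4), 0.12)), n, 3,
                dimnames = list(taxa, NULL))
    cm <- character_matrix(m, alphabet = "dna")
    tr <- ape::unroot(ape::rtree(n, tip.label = sample(taxa)))
    L <- fitch_length(tr, cm)
    expect_equal(L, brute_fitch(tr, m, c("A", "C", "G", "T")),
                 info = paste("brute case", i))
    pd <- phangorn::phyDat(m, type = "DNA")
    expect_equal(L, phangorn::parsimony(tr, pd), info = paste("phangorn", i))
  }
})

test_that("scores are invariant under consistent taxon relabeling", {
  set.seed(33)
  m <- random_binary_matrix(7, 25)
  cm <- character_matrix(m)
  h <- heuristic_mp(cm, n_random_addition = 5, seed = 1)
  tr <- h$trees[[1]]
  sc <- tree_score(tr, cm)
  perm <- sample(rownames(m))
  m2 <- m[perm, , drop = FALSE]
  sc2 <- tree_score(tr, character_matrix(m2))
  expect_equal(sc2, sc)
})

test_that("a duplicated taxon does not change the best length", {
  set.seed(34)
  m <- random_binary_matrix(6, 20)
  base <- exhaustive_mp(character_matrix(m))$score$length
  m2 <- rbind(m, twin = m["t1", ])
  rownames(m2)[7] <- "twin"
  got <- heuristic_mp(character_matrix(m2), n_random_addition = 8,
                      seed = 2)$score$length
  expect_equal(got, base)
})

test_that("CI and RI stay within their defined ranges", {
  set.seed(35)
  for (i in 1:15) {
    cm <- character_matrix(random_binary_matrix(sample(5:8, 1), 15))
    h <- heuristic_mp(cm, n_random_addition = 3, seed = i)
    b <- fitch_bounds(cm)
    expect_gte(h$score$length, sum(b$m))
    expect_lte(h$score$length, sum(b$g) + sum(b$m))
    if (h$score$length > 0) {
      expect_gt(h$score$ci, 0)
      expect_lte(h$score$ci, 1)
    }
    if (!is.na(h$score$ri)) {
      expect_gte(h$score$ri, 0)
      expect_lte(h$score$ri, 1)
    }
  }
})

test_that("bootstrap support is high for a unanimous split and balanced under conflict", {
  taxa <- c("A", "B", "C", "D")
  strong <- character_matrix(split_matrix(taxa, c("A", "B"), 20))
  set.seed(36)
  bs <- bootstrap_support(strong, n_reps = 200, seed = 5)
  expect_gte(split_support(bs, c("A", "B"), taxa), 0.99)

  single <- character_matrix(split_matrix(taxa, c("A", "C"), 1))
  bs1 <- bootstrap_support(single, n_reps = 50, seed = 6)
  expect_equal(split_support(bs1, c("A", "C"), taxa), 1)

  mixed <- character_matrix(cbind(split_matrix(taxa, c("A", "B"), 10),
                                  split_matrix(taxa, c("A", "C"), 10)))
  bs2 <- bootstrap_support(mixed, n_reps = 400, seed = 7)
  s <- split_support(bs2, c("A", "B"), taxa)
  expect_gte(s, 0.35)
  expect_lte(s, 0.65)
})

test_that("majority-rule consensus reflects shared structure", {
  m <- split_matrix(paste0("t", 1:5), c("t1", "t2"), 5)
  h <- heuristic_mp(character_matrix(m), n_random_addition = 5, seed = 3)
  cons <- mp_consensus(h$trees)
  expect_s3_class(cons, "phylo")
  expect_setequal(cons$tip.label, paste0("t", 1:5))
})

test_that("ILD on identical partitions is never significant", {
  set.seed(37)
  p1 <- character_matrix(random_binary_matrix(6, 15))
  r <- ild_test(p1, p1, n_reps = 99, seed = 1)
  expect_equal(r$D_obs, 0)
  expect_gt(r$p_value, 0.5)
})

test_that("ILD p-value is invariant to partition order", {
  set.seed(38)
  parts <- conflicting_partition_matrices(12)
  p1 <- character_matrix(parts$p1)
  p2 <- character_matrix(parts$p2)
  a <- ild_test(p1, p2, n_reps = 99, seed = 4)
  b <- ild_test(p2, p1, n_reps = 99, seed = 4)
  expect_equal(a$D_obs, b$D_obs)
  expect_equal(a$p_value, b$p_value, tolerance = 0.06)
  expect_lte(a$p_value, 0.05)  # maximal conflict should register
})

test_that("trees round-trip through Newick text", {
  set.seed(39)
  m <- random_binary_matrix(6, 12)
  h <- heuristic_mp(character_matrix(m), n_random_addition = 3, seed = 9)
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(h$trees[[1]], f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(h$trees[[1]])), 0,
               ignore_attr = TRUE)
})
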