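IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
                `-` = 15L, `?` = 15L)
DNA_MISSING <- c("-", "?", "N")

#' Character matrix for parsimony analysis
#'
#' Wraps a taxa-by-characters symbol matrix with the bitmask encoding used
#' by the Fitch engine. Missing symbols (`?`, and for DNA also `-` and `N`)
#' are encoded as full-alphabet ambiguity. All characters are unordered and
#' equally weighted unless `weights` is given.
#'
#' @param x character matrix of single symbols with taxa as rownames.
#' @param alphabet `"dna"`, `"binary"`, `"standard"` (arbitrary symbols) or
#'   `"auto"` (binary if symbols are 0/1/?, else DNA if they are IUPAC,
#'   else standard).
#' @param weights positive per-character weights (default 1).
#' @return an object of class `character_matrix`.
#' @export
character_matrix <- function(x, alphabet = c("auto", "dna", "binary", "standard"),
                             weights = NULL) {
  alphabet <- match.arg(alphabet)
  if (inherits(x, "alignment")) x <- x$rows
  if (!is.matrix(x)) stopf("`x` must be a symbol matrix or alignment")
  if (is.null(rownames(x))) stopf("`x` needs taxa as rownames")
  x[] <- toupper(x)
  syms <- setdiff(unique(as.vector(x)), c("?", NA))
  if (alphabet == "auto") {
    alphabet <- if (all(syms %in% c("0", "1", "-"))) "binary"
    else if (all(syms %in% names(IUPAC_MASK))) "dna"
    else "standard"
  }
  n <- nrow(x); k <- ncol(x)
  if (alphabet == "dna") {
    masks <- matrix(IUPAC_MASK[as.vector(x)], n, k)
    if (anyNA(masks)) stopf("symbols outside the IUPAC DNA alphabet")
    missing <- matrix(as.vector(x) %in% DNA_MISSING |
                        !(as.vector(x) %in% DNA_BASES), n, k)
  } else if (alphabet == "binary") {
    lut <- c(`0` = 1L, `1` = 2L, `?` = 3L, `-` = 3L)
    masks <- matrix(lut[as.vector(x)], n, k)
    if (anyNA(masks)) stopf("binary characters allow symbols 0, 1, ?, -")
    missing <- matrix(as.vector(x) %in% c("?", "-"), n, k)
  } else {
    lev <- sort(setdiff(syms, c("-", "?")))
    if (length(lev) > 30L) stopf("too many states for a standard character")
    full <- bitwShiftL(1L, length(lev)) - 1L
    lut <- setNames(bitwShiftL(1L, seq_along(lev) - 1L), lev)
    lut <- c(lut, `-` = full, `?` = full)
    masks <- matrix(lut[as.vector(x)], n, k)
    if (anyNA(masks)) stopf("unexpected symbol in standard character matrix")
    missing <- matrix(as.vector(x) %in% c("?", "-"), n, k)
  }
  dimnames(masks) <- dimnames(missing) <- dimnames(x)
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k || any(weights <= 0))
    stopf("weights must be positive, one per character")
  structure(list(taxa = rownames(x), symbols = x, masks = masks,
                 missing = missing, weights = as.numeric(weights),
                 alphabet = rep(alphabet, k)),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters (%s)\n",
              length(x$taxa), ncol(x$masks),
              paste(unique(x$alphabet), collapse = "+")))
  invisible(x)
}

#' Binary character matrix from coded indels
#'
#' @param chars an `indel_characters` table from [simple_indel_coding()].
#' @return a binary [character_matrix()] (taxa = sequence ids).
#' @export
indel_character_matrix <- function(chars) {
  ids <- setdiff(names(chars), c("start", "end"))
  m <- matrix("?", length(ids), nrow(chars), dimnames = list(ids, NULL))
  for (id in ids) m[id, ] <- as.character(chars[[id]])
  character_matrix(m, alphabet = "binary")
}

#' Concatenate character matrices over the same taxa
#'
#' Supports mixed blocks (DNA plus binary indel characters) with per-block
#' alphabets, as used when combining sequence and coded-gap data.
#'
#' @param ... `character_matrix` objects sharing one taxon set.
#' @return the combined `character_matrix`.
#' @export
bind_characters <- function(...) {
  cms <- list(...)
  stopifnot(length(cms) >= 1L, all(vapply(cms, inherits, TRUE, "character_matrix")))
  taxa <- cms[[1]]$taxa
  for (cm in cms) {
    if (!setequal(cm$taxa, taxa)) stopf("taxon sets differ between blocks")
  }
  ord <- lapply(cms, function(cm) match(taxa, cm$taxa))
  out <- cms[[1]]
  out$symbols <- do.call(cbind, Map(function(cm, o) cm$symbols[o, , drop = FALSE], cms, ord))
  out$masks <- do.call(cbind, Map(function(cm, o) cm$masks[o, , drop = FALSE], cms, ord))
  out$missing <- do.call(cbind, Map(function(cm, o) cm$missing[o, , drop = FALSE], cms, ord))
  out$weights <- unlist(lapply(cms, `[[`, "weights"))
  out$alphabet <- unlist(lapply(cms, `[[`, "alphabet"))
  rownames(out$symbols) <- rownames(out$masks) <- rownames(out$missing) <- taxa
  out
}

# Subset characters (columns) of a character_matrix.
cm_subset <- function(cm, cols) {
  cm$symbols <- cm$symbols[, cols, drop = FALSE]
  cm$masks <- cm$masks[, cols, drop = FALSE]
  cm$missing <- cm$missing[, cols, drop = FALSE]
  cm$weights <- cm$weights[cols]
  cm$alphabet <- cm$alphabet[cols]
  cm
}

# ---- tree conversions ------------------------------------------------------

# ape::phylo -> 0-based edge matrix over `taxa` row order.
phylo_to_edges0 <- function(phy, taxa) {
  if (!inherits(phy, "phylo")) stopf("`tree` must be an ape phylo object")
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  if (!all(phy$tip.label %in% taxa))
    stopf("tree leaf without a data row: %s",
          paste(setdiff(phy$tip.label, taxa), collapse = ", "))
  tipmap <- match(phy$tip.label, taxa) - 1L
  mapnode <- function(v) ifelse(v <= n, tipmap[v], v - 1L)
  E <- cbind(mapnode(phy$edge[, 1]), mapnode(phy$edge[, 2]))
  storage.mode(E) <- "integer"
  E
}

# 0-based edge matrix (leaves = seq_along(taxa) - 1) -> ape::phylo.
edges0_to_phylo <- function(E, taxa) {
  n <- length(taxa)
  adj <- vector("list", 2L * n - 2L)
  for (i in seq_len(nrow(E))) {
    a <- E[i, 1] + 1L; b <- E[i, 2] + 1L
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  lab <- function(v, parent) {
    if (v <= n) return(taxa[v])
    kids <- setdiff(adj[[v]], parent)
    paste0("(", paste(vapply(kids, lab, character(1), parent = v), collapse = ","), ")")
  }
  root <- n + 1L
  ape::read.tree(text = paste0(lab(root, -1L), ";"))
}

# ---- scores ----------------------------------------------------------------

#' Fitch parsimony length of a tree
#'
#' Minimum number of state changes (weighted sum over characters) required
#' on an unrooted binary tree for unordered characters; missing states are
#' full-alphabet ambiguities.
#'
#' @param tree an `ape::phylo` (rooted trees are unrooted first); leaves
#'   must be a subset of the matrix taxa.
#' @param cm a [character_matrix()].
#' @return numeric tree length.
#' @export
fitch_length <- function(tree, cm) {
  stopifnot(inherits(cm, "character_matrix"))
  taxa <- tree$tip.label
  if (!all(taxa %in% cm$taxa)) stopf("tree leaf without a data row")
  S <- cm$masks[match(taxa, cm$taxa), , drop = FALSE]
  cpp_tree_length(S, cm$weights, phylo_to_edges0(tree, taxa))
}

#' Per-character parsimony bounds
#'
#' For each character, `m` is the minimum steps on any tree (distinct
#' observed states minus one) and `g` the maximum (non-missing taxa minus
#' the largest single-state count). Ambiguity codes are treated as missing
#' for bound counting. These bounds define CI = sum(m)/L and
#' RI = (sum(g) - L)/(sum(g) - sum(m)).
#'
#' @param cm a [character_matrix()].
#' @return data.frame with columns `m` and `g`.
#' @export
fitch_bounds <- function(cm) {
  stopifnot(inherits(cm, "character_matrix"))
  k <- ncol(cm$symbols)
  m <- g <- integer(k)
  for (j in seq_len(k)) {
    obs <- cm$symbols[!cm$missing[, j], j]
    if (!length(obs)) { m[j] <- 0L; g[j] <- 0L; next }
    tab <- table(obs)
    m[j] <- length(tab) - 1L
    g[j] <- length(obs) - max(tab)
  }
  data.frame(m = m, g = g)
}

#' Tree length with consistency and retention indices
#'
#' @inheritParams fitch_length
#' @return list with `length`, `ci`, `ri` (NA where undefined: CI for a
#'   zero-length tree, RI when no character has homoplasy headroom).
#' @export
tree_score <- function(tree, cm) {
  L <- fitch_length(tree, cm)
  b <- fitch_bounds(cm)
  M <- sum(b$m * cm$weights); G <- sum(b$g * cm$weights)
  ci <- if (L > 0) M / L else NA_real_
  ri <- if (G > M) (G - L) / (G - M) else NA_real_
  list(length = L, ci = ci, ri = ri)
}

#' Parsimony-informative characters
#'
#' A character is parsimony-informative when at least two states each occur
#' in at least two taxa (among non-missing entries).
#'
#' @param cm a [character_matrix()].
#' @return logical vector, one entry per character.
#' @export
pars_informative <- function(cm) {
  vapply(seq_len(ncol(cm$symbols)), function(j) {
    obs <- cm$symbols[!cm$missing[, j], j]
    sum(table(obs) >= 2L) >= 2L
  }, logical(1))
}

# ---- searches --------------------------------------------------------------

#' Exhaustive maximum-parsimony search
#'
#' Enumerates all (2n-5)!! unrooted binary topologies (4 to 9 taxa) and
#' returns every minimum-length tree. Serves as the exact oracle for the
#' heuristic search.
#'
#' @param cm a [character_matrix()].
#' @param maxtrees cap on retained co-optimal trees.
#' @return list with `trees` (multiPhylo), `score` (length/ci/ri),
#'   `n_topologies`.
#' @export
exhaustive_mp <- function(cm, maxtrees = 10000) {
  stopifnot(inherits(cm, "character_matrix"))
  res <- cpp_exhaustive_mp(cm$masks, cm$weights, maxtrees)
  trees <- lapply(res$trees, edges0_to_phylo, taxa = cm$taxa)
  class(trees) <- "multiPhylo"
  b <- fitch_bounds(cm)
  M <- sum(b$m * cm$weights); G <- sum(b$g * cm$weights)
  L <- res$length
  list(trees = trees,
       score = list(length = L, ci = if (L > 0) M / L else NA_real_,
                    ri = if (G > M) (G - L) / (G - M) else NA_real_),
       n_topologies = res$n_topologies)
}

#' Heuristic maximum-parsimony search
#'
#' Random-addition stepwise starts followed by branch swapping (SPR by
#' default, NNI optional) to convergence; all equally best trees found are
#' retained (MULTREES semantics). Deterministic given `seed`.
#'
#' @param cm a [character_matrix()].
#' @param n_random_addition number of random addition-sequence replicates.
#' @param swapper `"SPR"` or `"NNI"`.
#' @param seed integer seed for the search RNG.
#' @param collect_trees keep the co-optimal topologies (disable when only
#'   the length is needed, e.g. inside permutation loops).
#' @param maxtrees cap on retained trees.
#' @return list with `trees` (multiPhylo), `score` (length/ci/ri).
#' @export
heuristic_mp <- function(cm, n_random_addition = 100,
                         swapper = c("SPR", "NNI"), seed = 1,
                         collect_trees = TRUE, maxtrees = 1000) {
  stopifnot(inherits(cm, "character_matrix"))
  swapper <- match.arg(swapper)
  res <- cpp_heuristic_mp(cm$masks, cm$weights, as.integer(n_random_addition),
                          swapper == "SPR", as.integer(seed %% 2147483647),
                          collect_trees, maxtrees)
  trees <- lapply(res$trees, edges0_to_phylo, taxa = cm$taxa)
  class(trees) <- "multiPhylo"
  b <- fitch_bounds(cm)
  M <- sum(b$m * cm$weights); G <- sum(b$g * cm$weights)
  L <- res$length
  list(trees = trees,
       score = list(length = L, ci = if (L > 0) M / L else NA_real_,
                    ri = if (G > M) (G - L) / (G - M) else NA_real_))
}

# Canonical split mask (double) for a taxon subset; complement so that
# taxon 1 is always outside the mask.
split_mask <- function(cm_taxa, subset) {
  idx <- match(subset, cm_taxa)
  if (anyNA(idx)) stopf("unknown taxa in split")
  mk <- sum(2^(idx - 1))
  full <- 2^length(cm_taxa) - 1
  if (idx_contains_first(idx)) full - mk else mk
}
idx_contains_first <- function(idx) 1L %in% idx

split_label <- function(mask, taxa) {
  idx <- which(bitwAnd_double(mask, 2^(seq_along(taxa) - 1)) > 0)
  paste(taxa[idx], collapse = ",")
}
bitwAnd_double <- function(a, b) {
  # exact for masks below 2^53
  floor(a / b) %% 2 * b
}

#' Nonparametric bootstrap support for splits
#'
#' Resamples characters with replacement, runs a reduced heuristic search
#' per replicate, and tabulates split frequencies. A replicate contributes
#' to a split in proportion to the fraction of its equally best trees
#' containing the split.
#'
#' @param cm a [character_matrix()] (at most 53 taxa).
#' @param n_reps bootstrap replicates.
#' @param seed integer seed.
#' @param n_random_addition addition replicates per bootstrap replicate.
#' @param swapper `"SPR"` or `"NNI"`.
#' @return data.frame with columns `split` (taxon labels on one side),
#'   `support` (fraction in `[0, 1]`), sorted by decreasing support.
#' @export
bootstrap_support <- function(cm, n_reps = 1000, seed = 1,
                              n_random_addition = 2, swapper = c("SPR", "NNI")) {
  stopifnot(inherits(cm, "character_matrix"))
  swapper <- match.arg(swapper)
  if (length(cm$taxa) > 53L) stopf("bootstrap supports at most 53 taxa")
  k <- ncol(cm$masks)
  acc <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      counts <- tabulate(sample.int(k, k, replace = TRUE), nbins = k)
      w <- counts * cm$weights
      keep <- w > 0
      res <- cpp_heuristic_mp(cm$masks[, keep, drop = FALSE], w[keep],
                              as.integer(n_random_addition), swapper == "SPR",
                              child_seed(seed, r), TRUE, 64L)
      trees <- res$trees
      if (!length(trees)) next
      wt <- 1 / length(trees)
      for (tr in trees) {
        for (mk in cpp_tree_splits(tr, length(cm$taxa))) {
          key <- sprintf("%.0f", mk)
          acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + wt
        }
      }
    }
  })
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(split = character(0), support = numeric(0)))
  masks <- as.numeric(keys)
  support <- vapply(keys, function(kk) acc[[kk]], numeric(1)) / n_reps
  out <- data.frame(split = vapply(masks, split_label, character(1), taxa = cm$taxa),
                    support = unname(support), stringsAsFactors = FALSE)
  out[order(-out$support, out$split), , drop = FALSE]
}

#' Support for one named split
#'
#' @param bs result of [bootstrap_support()].
#' @param subset character vector of taxa on one side of the split.
#' @param taxa the full taxon set of the analysis.
#' @return support fraction (0 if the split never appeared).
#' @export
split_support <- function(bs, subset, taxa) {
  side <- if (taxa[1] %in% subset) setdiff(taxa, subset) else subset
  lab <- paste(taxa[sort(match(side, taxa))], collapse = ",")
  hit <- bs$support[bs$split == lab]
  if (length(hit)) hit[1] else 0
}

#' Majority-rule consensus of parsimony trees
#'
#' @param trees a `multiPhylo` set.
#' @param p minimum split frequency (default 0.5 majority rule).
#' @return an `ape::phylo` consensus tree.
#' @export
mp_consensus <- function(trees, p = 0.5) {
  ape::consensus(trees, p = p, check.labels = TRUE)
}

#' Incongruence length difference (partition homogeneity) test
#'
#' D = L(combined) - L(part1) - L(part2) with parsimony lengths from the
#' heuristic search; characters are randomly reassigned between two
#' pseudo-partitions of the original sizes, and the p-value is the
#' add-one-corrected fraction of permutations with D at least the observed
#' value. By default only parsimony-informative characters enter the test.
#'
#' @param part1,part2 `character_matrix` objects over one taxon set.
#' @param n_reps permutation replicates.
#' @param seed integer seed.
#' @param informative_only restrict to parsimony-informative characters.
#' @param n_random_addition,swapper search settings per length evaluation.
#' @return list with `D_obs`, `p_value`, `D_perm` (numeric vector), and the
#'   partition sizes used.
#' @export
ild_test <- function(part1, part2, n_reps = 1000, seed = 1,
                     informative_only = TRUE, n_random_addition = 2,
                     swapper = c("SPR", "NNI")) {
  stopifnot(inherits(part1, "character_matrix"),
            inherits(part2, "character_matrix"))
  swapper <- match.arg(swapper)
  if (!setequal(part1$taxa, part2$taxa))
    stopf("partitions must share one taxon set")
  if (informative_only) {
    part1 <- cm_subset(part1, which(pars_informative(part1)))
    part2 <- cm_subset(part2, which(pars_informative(part2)))
  }
  k1 <- ncol(part1$masks); k2 <- ncol(part2$masks)
  if (k1 == 0L || k2 == 0L)
    return(list(D_obs = 0, p_value = 1, D_perm = numeric(0), n1 = k1, n2 = k2))
  comb <- bind_characters(part1, part2)
  spr <- swapper == "SPR"
  len <- function(cols, sd) {
    cpp_heuristic_mp(comb$masks[, cols, drop = FALSE], comb$weights[cols],
                     as.integer(n_random_addition), spr, sd, FALSE, 1L)$length
  }
  Lc <- len(seq_len(k1 + k2), child_seed(seed, 0))
  L1 <- len(seq_len(k1), child_seed(seed, 1))
  L2 <- len(k1 + seq_len(k2), child_seed(seed, 2))
  D_obs <- Lc - L1 - L2
  D_perm <- numeric(n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      i1 <- sample.int(k1 + k2, k1)
      i2 <- setdiff(seq_len(k1 + k2), i1)
      D_perm[r] <- Lc - len(i1, child_seed(seed, 2L * r + 1L)) -
        len(i2, child_seed(seed, 2L * r + 2L))
    }
  })
  p <- (1 + sum(D_perm >= D_obs - 1e-9)) / (n_reps + 1)
  list(D_obs = D_obs, p_value = p, D_perm = D_perm, n1 = k1, n2 = k2)
}
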