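# Independent oracles and small random-input generators used across tests.
# These deliberately take different code paths from the package internals.

# Brute-force parsimony length: minimise over all internal-node labelings
# (and ambiguous-leaf resolutions) the number of mismatched edges.
brute_fitch <- function(tree, symbols, alphabet) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  nodes <- sort(unique(as.vector(tree$edge)))
  internals <- setdiff(nodes, seq_len(n))
  k <- length(alphabet)
  total <- 0
  for (j in seq_len(ncol(symbols))) {
    allowed <- lapply(tree$tip.label, function(tx) {
      s <- symbols[tx, j]
      if (s %in% alphabet) s else alphabet  # missing = any state
    })
    names(allowed) <- tree$tip.label
    grid <- as.matrix(expand.grid(rep(list(alphabet), length(internals)),
                                  stringsAsFactors = FALSE))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      lab <- stats::setNames(grid[g, ], internals)
      cost <- 0
      for (e in seq_len(nrow(tree$edge))) {
        a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
        sa <- lab[[as.character(a)]]
        if (b <= n) {
          if (!(sa %in% allowed[[tree$tip.label[b]]])) cost <- cost + 1
        } else if (sa != lab[[as.character(b)]]) cost <- cost + 1
      }
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

# Column-wise simple-indel-coding oracle: classify every sequence against
# every distinct internal gap extent directly from alignment columns.
indel_oracle <- function(seqs) {
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  L <- ncol(mat)
  runs_of <- function(v) {
    gap <- v == "-"
    if (!any(gap)) return(NULL)
    idx <- which(gap)
    brk <- cumsum(c(1L, diff(idx) != 1L))
    do.call(rbind, lapply(split(idx, brk), function(ix)
      c(start = min(ix) - 1L, end = max(ix))))
  }
  allruns <- lapply(rownames(mat), function(id) runs_of(mat[id, ]))
  names(allruns) <- rownames(mat)
  internal <- do.call(rbind, lapply(allruns, function(r) {
    if (is.null(r)) return(NULL)
    r[r[, "start"] > 0L & r[, "end"] < L, , drop = FALSE]
  }))
  if (is.null(internal) || !nrow(internal)) {
    out <- data.frame(start = integer(0), end = integer(0))
    for (id in rownames(mat)) out[[id]] <- character(0)
    return(out)
  }
  ext <- unique(as.data.frame(internal))
  ext <- ext[order(ext$start, ext$end), , drop = FALSE]
  out <- data.frame(start = ext$start, end = ext$end)
  for (id in rownames(mat)) {
    st <- character(nrow(ext))
    for (i in seq_len(nrow(ext))) {
      s <- ext$start[i]; e <- ext$end[i]
      win <- mat[id, (s + 1L):e]
      exact <- all(win == "-") &&
        (s == 0L || mat[id, s] != "-") &&
        (e == L || mat[id, e + 1L] != "-") &&
        s > 0L && e < L
      st[i] <- if (exact) "1" else if (!any(win == "-")) "0" else "?"
    }
    out[[id]] <- st
  }
  rownames(out) <- NULL
  out
}

# Random gappy alignment (ids t1.., <= 8 sequences, <= 60 columns).
random_gappy_alignment <- function(nseq, ncol, gap_prob = 0.25) {
  seqs <- vapply(seq_len(nseq), function(i) {
    res <- sample(c("A", "C", "G", "T"), ncol, replace = TRUE)
    ngap <- stats::rpois(1, gap_prob * 4)
    for (g in seq_len(ngap)) {
      len <- sample(1:6, 1)
      s <- sample(ncol - len + 1, 1)
      res[s:(s + len - 1)] <- "-"
    }
    paste(res, collapse = "")
  }, character(1))
  names(seqs) <- paste0("t", seq_len(nseq))
  seqs
}

# Random binary matrix for parsimony tests.
random_binary_matrix <- function(ntaxa, nchar) {
  m <- matrix(sample(c("0", "1"), ntaxa * nchar, replace = TRUE), ntaxa, nchar)
  rownames(m) <- paste0("t", seq_len(ntaxa))
  m
}

# Matrix whose characters all support one split of the taxa.
split_matrix <- function(taxa, side, nchar) {
  m <- matrix("0", length(taxa), nchar, dimnames = list(taxa, NULL))
  m[side, ] <- "1"
  m
}

# Characters simulated on a fixed tree: pick an internal edge split at
# random and emit its indicator, with a little noise.
tree_signal_matrix <- function(splits, nchar, noise = 0) {
  taxa <- colnames(splits)
  m <- matrix("0", length(taxa), nchar, dimnames = list(taxa, NULL))
  for (j in seq_len(nchar)) {
    sp <- splits[sample(nrow(splits), 1), ]
    if (noise > 0) {
      flip <- stats::runif(length(sp)) < noise
      sp[flip] <- !sp[flip]
    }
    m[, j] <- ifelse(sp, "1", "0")
  }
  m
}

# Internal splits of a caterpillar tree in the given leaf order (prefixes
# of size 2..n-2), as indicator rows over the sorted taxa.
caterpillar_splits <- function(order) {
  taxa <- sort(order)
  n <- length(order)
  do.call(rbind, lapply(2:(n - 2), function(k) {
    stats::setNames(taxa %in% order[seq_len(k)], taxa)
  }))
}

# Two maximally conflicting 6-taxon tree signals: caterpillars in orders
# whose every informative split conflicts pairwise.
conflicting_partition_matrices <- function(nchar_each) {
  sp1 <- caterpillar_splits(paste0("t", c(1, 2, 3, 4, 5, 6)))
  sp2 <- caterpillar_splits(paste0("t", c(2, 5, 4, 3, 1, 6)))
  list(p1 = tree_signal_matrix(sp1, nchar_each),
       p2 = tree_signal_matrix(sp2, nchar_each))
}
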