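#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' functions never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Deterministic child seed derivation (keeps values < 2^31).
child_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12347L) %% 2147480017L
}

#' Proportion of differing sites between two aligned sequences
#'
#' Compares only columns where both sequences carry an unambiguous base
#' (A, C, G or T); gaps and missing symbols are skipped.
#'
#' @param a,b aligned sequences as single strings or character vectors of
#'   single residues.
#' @return p-distance in `[0, 1]`; `NA` if no comparable site exists.
#' @export
p_distance <- function(a, b) {
  av <- to_residues(a); bv <- to_residues(b)
  if (length(av) != length(bv)) stop("sequences must be aligned (equal length)")
  ok <- av %in% DNA_BASES & bv %in% DNA_BASES
  if (!any(ok)) return(NA_real_)
  mean(av[ok] != bv[ok])
}

DNA_BASES <- c("A", "C", "G", "T")

# Coerce a sequence to an uppercase vector of single residues.
to_residues <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  toupper(as.character(x))
}

# Pairwise p-distance matrix over a named list/vector of aligned sequences.
p_distance_matrix <- function(seqs) {
  n <- length(seqs)
  res <- lapply(seqs, to_residues)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- res[[i]] %in% DNA_BASES & res[[j]] %in% DNA_BASES
    d[i, j] <- d[j, i] <- if (any(ok)) mean(res[[i]][ok] != res[[j]][ok]) else NA_real_
  }
  d
}

# Multiset helpers: genotypes are sorted character vectors of allele groups.
ms_sort <- function(x) sort(as.character(x), method = "radix")
ms_label <- function(x) paste(ms_sort(x), collapse = "")
ms_equal <- function(a, b) identical(ms_sort(a), ms_sort(b))
ms_union <- function(a, b) ms_sort(c(a, b))

# All distinct sub-multisets of size k of multiset x (sorted vectors).
ms_subsets <- function(x, k) {
  x <- ms_sort(x)
  if (k == 0) return(list(character(0)))
  if (k > length(x)) return(list())
  idx <- combn(seq_along(x), k, simplify = FALSE)
  out <- unique(lapply(idx, function(i) x[i]))
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Parse a concatenated genotype or gamete label into allele tokens
#'
#' Splits labels such as `"X2X2YY"` into `c("X2","X2","Y","Y")`; an allele
#' token is an upper-case letter followed by optional digits.
#'
#' @param label genotype label string.
#' @return character vector of allele tokens (sorted).
#' @export
parse_genotype_label <- function(label) {
  ms_sort(regmatches(label, gregexpr("[A-Z][0-9]*", label))[[1]])
}
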