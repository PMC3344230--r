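#' Find maximal gap runs per sequence
#'
#' Reports every maximal run of `-` in every sequence, with 0-based
#' half-open column coordinates (converters to 1-based inclusive exist only
#' at I/O boundaries). Runs touching either alignment end are flagged
#' `terminal`.
#'
#' @param aln an [alignment()].
#' @return data.frame with columns `seq_id`, `start`, `end`, `terminal`.
#' @export
find_gap_runs <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  out <- list()
  for (id in aln$ids) {
    g <- aln$rows[id, ] == "-"
    if (!any(g)) next
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    for (k in gi) {
      out[[length(out) + 1L]] <- data.frame(
        seq_id = id, start = starts[k] - 1L, end = ends[k],
        terminal = (starts[k] == 1L || ends[k] == aln$length),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), terminal = logical(0)))
  do.call(rbind, out)
}

#' Simple indel coding of alignment gaps
#'
#' Codes each distinct internal gap extent present in at least one sequence
#' as one binary character: a sequence scores 1 if it carries a gap run
#' with exactly that extent, 0 if it has no gap overlapping the extent, and
#' missing (`?`) if an overlapping gap run has a different extent (the gap
#' neither confirms nor excludes the event). Terminal gaps usually reflect
#' incomplete sequencing of primer-bounded fragments, so by default they
#' are not coded and score missing for characters they overlap.
#'
#' @param aln an [alignment()].
#' @param treat_terminal_gaps_as `"missing"` (default: terminal runs are
#'   not coded; they blank overlapping characters) or `"coded"` (terminal
#'   runs are treated like internal ones).
#' @return data.frame of class `indel_characters`: columns `start`, `end`
#'   (0-based half-open) followed by one column per sequence holding
#'   `"0"`, `"1"` or `"?"`; characters ordered by `(start, end)`.
#' @export
simple_indel_coding <- function(aln, treat_terminal_gaps_as = c("missing", "coded")) {
  treat_terminal_gaps_as <- match.arg(treat_terminal_gaps_as)
  runs <- find_gap_runs(aln)
  codable <- if (treat_terminal_gaps_as == "coded") runs
             else runs[!runs$terminal, , drop = FALSE]
  if (!nrow(codable)) {
    out <- data.frame(start = integer(0), end = integer(0))
    for (id in aln$ids) out[[id]] <- character(0)
    class(out) <- c("indel_characters", class(out))
    return(out)
  }
  ext <- unique(codable[, c("start", "end")])
  ext <- ext[order(ext$start, ext$end), , drop = FALSE]
  states <- matrix("0", nrow(ext), length(aln$ids),
                   dimnames = list(NULL, aln$ids))
  for (id in aln$ids) {
    rr <- runs[runs$seq_id == id, , drop = FALSE]
    if (!nrow(rr)) next
    for (i in seq_len(nrow(ext))) {
      s <- ext$start[i]; e <- ext$end[i]
      overlaps <- rr$start < e & rr$end > s
      if (!any(overlaps)) next
      exact <- any(rr$start == s & rr$end == e &
                     (treat_terminal_gaps_as == "coded" | !rr$terminal))
      states[i, id] <- if (exact) "1" else "?"
    }
  }
  out <- cbind(data.frame(start = ext$start, end = ext$end, row.names = NULL),
               as.data.frame(states, stringsAsFactors = FALSE))
  class(out) <- c("indel_characters", class(out))
  out
}

#' Classify a sequence against a diagnostic indel window
#'
#' Determines whether a sequence carries a diagnostic deletion (such as the
#' 15 bp deletion separating the two deep nuclear allele clades): carrier
#' if it has a gap run whose reciprocal overlap with the diagnostic window
#' meets the threshold, non-carrier if no gap overlaps the window,
#' ambiguous otherwise.
#'
#' @param seq_id sequence label.
#' @param aln an [alignment()].
#' @param diagnostic integer `c(start, end)` window, 0-based half-open.
#' @param min_reciprocal_overlap minimum overlap fraction required in both
#'   directions (default 0.8).
#' @return `"carrier"`, `"non_carrier"` or `"ambiguous"`.
#' @export
detect_diagnostic_indel <- function(seq_id, aln, diagnostic,
                                    min_reciprocal_overlap = 0.8) {
  stopifnot(inherits(aln, "alignment"), length(diagnostic) == 2L)
  s <- as.integer(diagnostic[1]); e <- as.integer(diagnostic[2])
  if (s < 0L || e > aln$length || s >= e)
    stopf("diagnostic window outside alignment bounds")
  if (!seq_id %in% aln$ids) stopf("unknown sequence id '%s'", seq_id)
  runs <- find_gap_runs(aln)
  rr <- runs[runs$seq_id == seq_id, , drop = FALSE]
  if (!nrow(rr)) return("non_carrier")
  ov_len <- pmax(0L, pmin(rr$end, e) - pmax(rr$start, s))
  if (all(ov_len == 0L)) return("non_carrier")
  frac_run <- ov_len / (rr$end - rr$start)
  frac_win <- ov_len / (e - s)
  if (any(frac_run >= min_reciprocal_overlap &
          frac_win >= min_reciprocal_overlap)) "carrier" else "ambiguous"
}

#' Write coded indel characters as TSV or NEXUS-style binary matrix
#'
#' @param chars an `indel_characters` table from [simple_indel_coding()].
#' @param path output file.
#' @param format `"tsv"` (start/end in 1-based inclusive coordinates plus
#'   per-sequence states) or `"nexus"` (binary matrix, missing `?`).
#' @export
write_indel_matrix <- function(chars, path, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  ids <- setdiff(names(chars), c("start", "end"))
  if (format == "tsv") {
    out <- chars
    # 0-based half-open -> 1-based inclusive at the I/O boundary
    out$start <- out$start + 1L
    out$end <- out$end
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    mat <- vapply(ids, function(id) paste(chars[[id]], collapse = ""), character(1))
    lines <- c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(ids), nrow(chars)),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "  MATRIX",
               sprintf("    %s %s", format(ids, width = max(nchar(ids))), mat),
               "  ;", "END;")
    writeLines(lines, path)
  }
  invisible(path)
}
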