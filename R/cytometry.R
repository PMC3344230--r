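#' Flow-cytometry histogram container
#'
#' A fluorescence-intensity histogram for one sample co-run with (or paired
#' to) a calibration standard, as read off a flow cytometer.
#'
#' @param sample_id sample label.
#' @param channels strictly increasing numeric bin centres (fluorescence
#'   intensity, arbitrary units).
#' @param counts non-negative integer event counts per bin.
#' @param standard_id label of the calibration standard.
#' @return an object of class `fluorescence_histogram`.
#' @export
fluorescence_histogram <- function(sample_id, channels, counts,
                                   standard_id = "standard") {
  channels <- as.numeric(channels)
  counts <- as.numeric(counts)
  if (length(channels) != length(counts))
    stopf("channels and counts differ in length")
  if (any(diff(channels) <= 0)) stopf("channels must be strictly increasing")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (sum(counts) <= 0) stopf("histogram is empty")
  structure(list(sample_id = as.character(sample_id), channels = channels,
                 counts = counts, standard_id = as.character(standard_id)),
            class = "fluorescence_histogram")
}

#' Read a histogram from a `channel,count` CSV file
#'
#' @param path CSV file with header `channel,count`.
#' @param sample_id,standard_id labels; `sample_id` defaults to the file name.
#' @return a [fluorescence_histogram()].
#' @export
read_histogram_csv <- function(path, sample_id = NULL, standard_id = "standard") {
  x <- read.csv(path)
  if (!all(c("channel", "count") %in% names(x)))
    stopf("%s: expected columns 'channel' and 'count'", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.csv$", "", basename(path))
  fluorescence_histogram(sample_id, x$channel, x$count, standard_id)
}

#' Write a histogram to CSV
#' @param hist a [fluorescence_histogram()].
#' @param path output file.
#' @export
write_histogram_csv <- function(hist, path) {
  write.csv(data.frame(channel = hist$channels, count = hist$counts),
            path, row.names = FALSE, quote = FALSE)
}

#' Detect G1 peaks in a fluorescence histogram
#'
#' Smooths the histogram with a moving average and reports local maxima
#' exceeding a height threshold relative to the global maximum. Peak
#' positions are refined by an intensity-weighted centroid over the
#' smoothing window, so positions are not limited to bin centres.
#'
#' @param hist a [fluorescence_histogram()].
#' @param smoothing_window moving-average window (bins, odd; default 5).
#' @param min_prominence_fraction minimum peak height as a fraction of the
#'   maximum smoothed count (default 0.10).
#' @return numeric vector of peak channel positions, sorted by channel.
#' @export
detect_g1_peaks <- function(hist, smoothing_window = 5,
                            min_prominence_fraction = 0.10) {
  stopifnot(inherits(hist, "fluorescence_histogram"))
  y <- hist$counts
  w <- max(1L, as.integer(smoothing_window))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  sm <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- 0
  n <- length(sm)
  thr <- min_prominence_fraction * max(sm)
  # candidate local maxima (right edge of any plateau)
  cand <- which(diff(c(-Inf, sm)) >= 0 & diff(c(sm, -Inf)) < 0)
  # prominence: height above the higher of the two valley minima on the
  # paths to the nearest higher terrain (or the histogram ends)
  prominence <- vapply(cand, function(i) {
    lo <- i; left_min <- sm[i]
    while (lo > 1L && sm[lo - 1L] <= sm[i]) {
      lo <- lo - 1L
      left_min <- min(left_min, sm[lo])
    }
    hi <- i; right_min <- sm[i]
    while (hi < n && sm[hi + 1L] <= sm[i]) {
      hi <- hi + 1L
      right_min <- min(right_min, sm[hi])
    }
    sm[i] - max(left_min, right_min)
  }, numeric(1))
  keep <- cand[prominence >= thr]
  peaks <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    ww <- y[lo:hi]
    if (sum(ww) > 0) sum(hist$channels[lo:hi] * ww) / sum(ww)
    else hist$channels[i]
  }, numeric(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) < 2L)
    stopf("unresolvable histogram: fewer than 2 peaks (standard + sample) found")
  peaks
}

#' Reference peak ratios for ploidy calling
#'
#' Sample-to-standard genome ratios observed for diploid, triploid and
#' tetraploid members of the complex against the Nicotiana tabacum 4X
#' standard (0.6 per genome copy).
#' @export
PLOIDY_REFERENCE_RATIOS <- c(`2` = 1.2, `3` = 1.8, `4` = 2.4)

#' Call ploidy and genome size from peak positions
#'
#' The sample/standard peak ratio is compared with the reference ratios
#' 1.2, 1.8 and 2.4 (diploid, triploid, tetraploid); genome size is the
#' ratio times the standard genome size (N. tabacum 4X, 20.08 pg).
#'
#' @param sample_peak,standard_peak positive peak channel positions.
#' @param standard_genome_pg standard genome size in picograms.
#' @param reference_ratios named vector mapping ploidy to expected ratio.
#' @param tolerance maximal |ratio - reference| for a call (default 0.15,
#'   half the spacing between adjacent references).
#' @return a list of class `ploidy_call` with elements `ratio`,
#'   `genome_size_pg`, `ploidy` (integer or `NA` when uncalled),
#'   `sample_peak`, `standard_peak`, `standard_genome_pg`.
#' @export
call_ploidy <- function(sample_peak, standard_peak, standard_genome_pg = 20.08,
                        reference_ratios = PLOIDY_REFERENCE_RATIOS,
                        tolerance = 0.15) {
  if (!is.finite(sample_peak) || !is.finite(standard_peak) ||
      sample_peak <= 0 || standard_peak <= 0)
    stopf("peak positions must be positive")
  ratio <- sample_peak / standard_peak
  d <- abs(reference_ratios - ratio)
  k <- which.min(d)
  ploidy <- if (d[k] <= tolerance) as.integer(names(reference_ratios)[k]) else NA_integer_
  structure(list(ratio = ratio, genome_size_pg = ratio * standard_genome_pg,
                 ploidy = ploidy, sample_peak = sample_peak,
                 standard_peak = standard_peak,
                 standard_genome_pg = standard_genome_pg),
            class = "ploidy_call")
}

#' Call ploidy directly from a histogram
#'
#' Detects peaks and takes the lowest-channel qualifying peak as the
#' co-run standard (the N. tabacum standard sits below all sample peaks
#' given reference ratios of at least 1.2), unless `standard_peak` is
#' supplied explicitly.
#'
#' @inheritParams detect_g1_peaks
#' @inheritParams call_ploidy
#' @param standard_peak optional explicit standard peak channel.
#' @return a `ploidy_call`.
#' @export
call_ploidy_histogram <- function(hist, standard_peak = NULL,
                                  smoothing_window = 5,
                                  min_prominence_fraction = 0.10, ...) {
  peaks <- detect_g1_peaks(hist, smoothing_window, min_prominence_fraction)
  if (is.null(standard_peak)) {
    standard_peak <- peaks[1]
    sample_peak <- peaks[2]
  } else {
    above <- peaks[peaks > standard_peak * 1.02]
    if (length(above)) sample_peak <- above[1]
    else {
      below <- peaks[peaks < standard_peak * 0.98]
      if (!length(below)) stopf("no sample peak distinct from the standard")
      sample_peak <- below[length(below)]
    }
  }
  call_ploidy(sample_peak, standard_peak, ...)
}

#' Classify reproduction mode from spore counts
#'
#' Sexual ferns produce 64 spores per sporangium; apogamous ferns 32 or
#' fewer (occasionally 16 or 28). Counts strictly between 32 and 64 are
#' never observed in practice and are labelled indeterminate rather than
#' forced. The plant-level mode is the plurality of per-sporangium labels,
#' with ties indeterminate.
#'
#' @param spore_counts integer spores per sporangium (the field protocol
#'   scores 5 sporangia per plant).
#' @param sexual_slack tolerated deviation from 64 still scored sexual
#'   (debris allowance; default 0).
#' @return a list of class `reproduction_call` with `mode` (one of
#'   `"sexual"`, `"apogamous"`, `"indeterminate"`), `labels` and
#'   `spore_counts`.
#' @export
classify_reproduction <- function(spore_counts, sexual_slack = 0) {
  if (!length(spore_counts)) stopf("empty spore count list")
  spore_counts <- as.numeric(spore_counts)
  if (any(!is.finite(spore_counts)) || any(spore_counts < 0))
    stopf("spore counts must be non-negative numbers")
  labels <- ifelse(abs(spore_counts - 64) <= sexual_slack, "sexual",
            ifelse(spore_counts <= 32, "apogamous", "indeterminate"))
  tab <- table(factor(labels, levels = c("sexual", "apogamous", "indeterminate")))
  top <- tab[tab == max(tab)]
  mode <- if (length(top) > 1L) "indeterminate" else names(top)
  structure(list(mode = mode, labels = labels, spore_counts = spore_counts),
            class = "reproduction_call")
}

#' Cytometry and reproduction summary table
#'
#' Runs ploidy calling on a list of histograms and reproduction typing on
#' matching spore counts, returning the combined per-sample table.
#'
#' @param histograms list of [fluorescence_histogram()].
#' @param spore_counts named list of per-sporangium counts (names =
#'   sample ids); entries may be missing.
#' @param ... passed to [call_ploidy_histogram()].
#' @return data.frame with columns `sample_id`, `ratio`, `genome_size_pg`,
#'   `ploidy`, `mode`.
#' @export
cytometry_table <- function(histograms, spore_counts = list(), ...) {
  rows <- lapply(histograms, function(h) {
    pc <- call_ploidy_histogram(h, ...)
    sc <- spore_counts[[h$sample_id]]
    mode <- if (is.null(sc)) NA_character_ else classify_reproduction(sc)$mode
    data.frame(sample_id = h$sample_id, ratio = pc$ratio,
               genome_size_pg = pc$genome_size_pg, ploidy = pc$ploidy,
               mode = mode, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
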