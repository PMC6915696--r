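#' Fragment-analysis peak trace
#'
#' PCR amplification across an unstable CAG tract yields a cluster of
#' products differing by single repeat units; capillary electrophoresis
#' renders them as peaks whose heights reflect molecule abundance. A trace
#' holds the (repeat length, height) peaks for one sample, optionally with
#' explicit per-allele repeat-length windows.
#'
#' @param sample_id text label.
#' @param repeat_length positive integer CAG repeat lengths, unique within
#'   the trace (duplicates are merged by summing heights).
#' @param height peak heights (fluorescence units), finite and > 0.
#' @param allele_windows optional list of two numeric length-2 intervals
#'   (disjoint) assigning repeat lengths to alleles.
#' @return object of class `"peak_trace"`: a data frame with columns
#'   `repeat_length`, `height`, sorted by repeat length.
#' @export
peak_trace <- function(sample_id, repeat_length, height, allele_windows = NULL) {
  rl <- as.numeric(repeat_length); h <- as.numeric(height)
  if (length(rl) == 0L) stop("trace has no peaks", call. = FALSE)
  if (length(rl) != length(h)) stop("misaligned peak columns", call. = FALSE)
  if (any(rl < 1) || any(rl != round(rl))) {
    stop("repeat lengths must be positive integers", call. = FALSE)
  }
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("peak heights must be finite and > 0", call. = FALSE)
  }
  if (anyDuplicated(rl)) {  # merge identical repeat lengths
    agg <- tapply(h, rl, sum)
    rl <- as.numeric(names(agg))
    h <- as.numeric(agg)
  }
  ord <- order(rl)
  if (!is.null(allele_windows)) {
    if (length(allele_windows) != 2L) {
      stop("`allele_windows` must be a list of two intervals", call. = FALSE)
    }
    w1 <- sort(as.numeric(allele_windows[[1]]))
    w2 <- sort(as.numeric(allele_windows[[2]]))
    if (max(min(w1), min(w2)) <= min(max(w1), max(w2))) {
      stop("allele windows must be disjoint", call. = FALSE)
    }
    allele_windows <- list(w1, w2)
  }
  structure(data.frame(repeat_length = as.integer(rl[ord]), height = h[ord]),
            sample_id = as.character(sample_id)[1],
            allele_windows = allele_windows,
            class = c("peak_trace", "data.frame"))
}

#' @export
print.peak_trace <- function(x, ...) {
  cat(sprintf("Peak trace '%s': %d peaks, repeats %d-%d\n",
              attr(x, "sample_id"), nrow(x),
              min(x$repeat_length), max(x$repeat_length)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Apply the relative peak-height threshold
#'
#' Peaks lower than `threshold_factor` times the highest peak in the group
#' (default 5%) are excluded from quantification; the threshold is computed
#' within the peak group supplied (i.e. per allele when called after
#' [split_alleles()]).
#'
#' @param peaks data frame with `repeat_length` and `height` columns.
#' @param threshold_factor fraction of the maximum height, in (0, 1).
#' @return list with `peaks` (survivors) and `threshold` (height cut-off).
#' @export
apply_peak_threshold <- function(peaks, threshold_factor = 0.05) {
  if (nrow(peaks) == 0L) stop("no peaks to threshold", call. = FALSE)
  if (threshold_factor <= 0 || threshold_factor >= 1) {
    stop("`threshold_factor` must lie in (0, 1)", call. = FALSE)
  }
  thr <- threshold_factor * max(peaks$height)
  list(peaks = peaks[peaks$height >= thr, , drop = FALSE], threshold = thr)
}

#' Height-weighted average CAG repeat length for one allele
#'
#' The six-step average-repeat procedure for one allele's peak cluster:
#' threshold at `threshold_factor` of the tallest peak, normalise surviving
#' heights to sum to 1, multiply each normalised height by its repeat length
#' and sum.
#'
#' @param peaks data frame with `repeat_length` and `height`.
#' @param threshold_factor relative height threshold; `NULL` disables
#'   thresholding.
#' @return average CAG repeat length (real-valued).
#' @export
allele_average_cag <- function(peaks, threshold_factor = 0.05) {
  if (nrow(peaks) == 0L) stop("no peaks in allele group", call. = FALSE)
  if (!is.null(threshold_factor)) {
    peaks <- apply_peak_threshold(peaks, threshold_factor)$peaks
  }
  stopifnot(nrow(peaks) >= 1L)  # the tallest peak always survives
  w <- peaks$height / sum(peaks$height)
  sum(w * peaks$repeat_length)
}

#' Combine per-allele averages
#'
#' Arithmetic mean of the one or two allele averages; a single allele
#' (e.g. a homozygous knock-in) passes through unchanged.
#'
#' @param allele_avgs numeric vector of length 1 or 2.
#' @return combined average CAG repeat length.
#' @export
combined_average_cag <- function(allele_avgs) {
  if (length(allele_avgs) < 1L) stop("no allele averages supplied", call. = FALSE)
  if (length(allele_avgs) > 2L) stop("at most two alleles expected", call. = FALSE)
  mean(allele_avgs)
}

#' Split a trace into two allele peak groups
#'
#' When explicit `allele_windows` are attached to the trace, peaks are
#' assigned by window membership. Otherwise the trace is split at the
#' largest gap between consecutive peak repeat lengths — unambiguous in
#' practice because wild-type and expanded alleles sit far apart.
#'
#' @param trace a [peak_trace()].
#' @param min_gap smallest repeat-length gap (exclusive) accepted as an
#'   allele boundary when splitting by gap.
#' @return list of two data frames (`allele1`, `allele2`), ordered by
#'   repeat length.
#' @export
split_alleles <- function(trace, min_gap = 2L) {
  peaks <- as.data.frame(trace)
  windows <- attr(trace, "allele_windows")
  if (!is.null(windows)) {
    in1 <- peaks$repeat_length >= windows[[1]][1] & peaks$repeat_length <= windows[[1]][2]
    in2 <- peaks$repeat_length >= windows[[2]][1] & peaks$repeat_length <= windows[[2]][2]
    g1 <- peaks[in1, , drop = FALSE]; g2 <- peaks[in2, , drop = FALSE]
    if (nrow(g1) == 0L || nrow(g2) == 0L) {
      stop("an allele window contains no peaks", call. = FALSE)
    }
    if (windows[[1]][1] > windows[[2]][1]) { tmp <- g1; g1 <- g2; g2 <- tmp }
    return(list(allele1 = g1, allele2 = g2))
  }
  if (nrow(peaks) < 2L) stop("need >= 2 peaks to split into two alleles", call. = FALSE)
  gaps <- diff(peaks$repeat_length)
  if (max(gaps) < min_gap) {
    stop("ambiguous split: no gap of >= ", min_gap,
         " repeats between peak clusters", call. = FALSE)
  }
  cut <- which.max(gaps)
  list(allele1 = peaks[seq_len(cut), , drop = FALSE],
       allele2 = peaks[(cut + 1L):nrow(peaks), , drop = FALSE])
}

#' Average CAG repeat length for a whole trace
#'
#' Orchestrates the per-trace computation: optionally split into alleles,
#' threshold per allele group (default) or globally, average each allele,
#' then average the alleles.
#'
#' @param trace a [peak_trace()].
#' @param two_alleles logical; split into two alleles first (default `TRUE`
#'   when the trace has allele windows or a clear gap, `FALSE` analyses the
#'   whole trace as one allele).
#' @param threshold_factor relative height threshold (default 0.05).
#' @param threshold_scope `"per_allele"` (default) or `"global"`.
#' @return object of class `"average_cag_result"`: `allele_averages`,
#'   `combined_average`, `threshold_used`, `n_peaks_used`.
#' @export
average_cag <- function(trace, two_alleles = TRUE, threshold_factor = 0.05,
                        threshold_scope = c("per_allele", "global")) {
  threshold_scope <- match.arg(threshold_scope)
  groups <- if (two_alleles) split_alleles(trace) else list(as.data.frame(trace))
  if (threshold_scope == "global") {
    thr <- apply_peak_threshold(as.data.frame(trace), threshold_factor)$threshold
    groups <- lapply(groups, function(g) g[g$height >= thr, , drop = FALSE])
    groups <- Filter(function(g) nrow(g) > 0L, groups)
    avgs <- vapply(groups, function(g) allele_average_cag(g, NULL), numeric(1))
    thr_used <- thr
    n_used <- sum(vapply(groups, nrow, integer(1)))
  } else {
    kept <- lapply(groups, function(g) apply_peak_threshold(g, threshold_factor))
    avgs <- vapply(kept, function(k) allele_average_cag(k$peaks, NULL), numeric(1))
    thr_used <- vapply(kept, function(k) k$threshold, numeric(1))
    n_used <- sum(vapply(kept, function(k) nrow(k$peaks), integer(1)))
  }
  structure(list(allele_averages = unname(avgs),
                 combined_average = combined_average_cag(unname(avgs)),
                 threshold_used = unname(thr_used),
                 n_peaks_used = n_used,
                 sample_id = attr(trace, "sample_id")),
            class = "average_cag_result")
}

#' @export
print.average_cag_result <- function(x, ...) {
  cat(sprintf("Average CAG for '%s': %.2f (alleles: %s; %d peaks used)\n",
              x$sample_id, x$combined_average,
              paste(sprintf("%.2f", x$allele_averages), collapse = ", "),
              x$n_peaks_used))
  invisible(x)
}

#' Read fragment-analysis peak tables
#'
#' Reads a delimited text export with columns `sample_id`, optional `allele`,
#' and either `repeat_length` or `size_bp` (fragment size in bases, converted
#' via `repeat = round((size_bp - flank_length_bp) / 3)`), plus `height`.
#' Peaks mapping to the same repeat length are merged by summing heights.
#'
#' @param path CSV file path.
#' @param flank_length_bp constant flanking-sequence length used for
#'   size-to-repeat conversion (required when the file gives `size_bp`).
#' @return named list of [peak_trace()] objects, one per sample.
#' @export
read_peak_table <- function(path, flank_length_bp = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"repeat_length" %in% names(df)) {
    if (!"size_bp" %in% names(df)) {
      stop("peak table needs a `repeat_length` or `size_bp` column", call. = FALSE)
    }
    if (is.null(flank_length_bp)) {
      stop("`flank_length_bp` is required to convert `size_bp` to repeats",
           call. = FALSE)
    }
    df$repeat_length <- round((df$size_bp - flank_length_bp) / 3)
  }
  if (!all(c("sample_id", "height") %in% names(df))) {
    stop("peak table needs `sample_id` and `height` columns", call. = FALSE)
  }
  ids <- unique(df$sample_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$sample_id == id, , drop = FALSE]
    peak_trace(id, sub$repeat_length, sub$height)
  })
  names(out) <- ids
  out
}
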