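# GC-content anomaly of cluster regions relative to the genome background.
# Altered GC is an indicator of horizontal acquisition; regions are profiled
# with a sliding window and compared to background windows with a z-test
# (the test choice is this package's own — see the methods vignette).

#' GC content of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`; ambiguous `N` bases are excluded from both
#' numerator and denominator. Reverse-complement invariant.
#'
#' @param seq Sequence over A/C/G/T/N (case-insensitive).
#' @return GC fraction; `NaN` when no unambiguous base remains.
#' @export
gc_content <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(chars, c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("illegal nucleotide(s): ", paste(unique(bad), collapse = ", "))
  }
  n_gc <- sum(chars %in% c("G", "C"))
  n_eff <- sum(chars != "N")
  if (n_eff == 0L) return(NaN)
  n_gc / n_eff
}

#' Sliding-window GC content
#'
#' Half-open windows `[i, i + window)` for `i = 0, step, 2 step, ...` while
#' the window fits; a final partial window is appended when the remainder is
#' longer than half a window. A window wider than the sequence degrades to a
#' single whole-sequence window with a warning.
#'
#' @param seq Nucleotide sequence.
#' @param window Window width, bp.
#' @param step Stride, bp (>= 1).
#' @return A `data.frame` with 0-based half-open `start`, `end` and `gc`.
#' @export
window_gc <- function(seq, window = 500L, step = 250L) {
  L <- nchar(seq)
  stopifnot(step >= 1L, window >= 1L)
  if (window > L) {
    warning("window (", window, " bp) exceeds sequence length (", L,
            " bp); using a single whole-sequence window")
    return(data.frame(start = 0L, end = L, gc = gc_content(seq)))
  }
  starts <- seq(0L, L - window, by = step)
  ends <- starts + window
  nxt <- starts[length(starts)] + step
  if (nxt < L && (L - nxt) > window / 2) {
    starts <- c(starts, nxt); ends <- c(ends, L)
  }
  gc <- vapply(seq_along(starts), function(i) {
    gc_content(substr(seq, starts[i] + 1L, ends[i]))
  }, 0)
  data.frame(start = as.integer(starts), end = as.integer(ends), gc = gc)
}

#' GC profile of a cluster region
#'
#' Window track plus the three summary numbers used to annotate regions:
#' maximum, mean and minimum window GC. The mean is weighted by window
#' length, so it equals the whole-region GC when windows tile exactly.
#'
#' @inheritParams window_gc
#' @return A `gc_profile` list: `windows`, `region_max`, `region_mean`,
#'   `region_min`, `n_windows`.
#' @export
gc_profile <- function(seq, window = 500L, step = 250L) {
  w <- window_gc(seq, window, step)
  wt <- w$end - w$start
  structure(list(windows = w,
                 region_max = max(w$gc),
                 region_mean = sum(w$gc * wt) / sum(wt),
                 region_min = min(w$gc),
                 n_windows = nrow(w)),
            class = "gc_profile")
}

#' Test a region's GC against the genome background
#'
#' z-test of the region mean against background window GC values:
#' `z = (region_mean - genome_mean) / (genome_sd / sqrt(n_region_windows))`,
#' with a two-sided normal p-value; the region is flagged anomalous when
#' `p < alpha`. The background is either an empirical sample of at least 5
#' genome windows, or a parametric background (`genome_mean`, `genome_sd`)
#' such as the binomial window model derived from a genome-wide GC fraction.
#'
#' @param region_profile A [gc_profile()].
#' @param genome_windows Numeric vector of background window GC fractions
#'   (>= 5 values), or `NULL` when `genome_mean`/`genome_sd` are given.
#' @param genome_mean,genome_sd Parametric background, used when
#'   `genome_windows` is `NULL`.
#' @param alpha Significance level.
#' @return A list: `z`, `p_value`, `anomalous`, `degenerate`, `genome_mean`,
#'   `genome_sd`.
#' @export
gc_anomaly <- function(region_profile, genome_windows = NULL,
                       genome_mean = NULL, genome_sd = NULL, alpha = 0.05) {
  stopifnot(inherits(region_profile, "gc_profile"))
  if (!is.null(genome_windows)) {
    if (length(genome_windows) < 5L) {
      stop("need at least 5 genome background windows")
    }
    genome_mean <- mean(genome_windows)
    genome_sd <- sd(genome_windows)
  } else if (is.null(genome_mean) || is.null(genome_sd)) {
    stop("supply genome_windows or genome_mean + genome_sd")
  }
  if (genome_sd == 0) {
    return(list(z = NA_real_, p_value = NA_real_, anomalous = NA,
                degenerate = TRUE, genome_mean = genome_mean,
                genome_sd = genome_sd))
  }
  z <- (region_profile$region_mean - genome_mean) /
    (genome_sd / sqrt(region_profile$n_windows))
  p <- 2 * pnorm(-abs(z))
  list(z = z, p_value = p, anomalous = p < alpha, degenerate = FALSE,
       genome_mean = genome_mean, genome_sd = genome_sd)
}

#' Per-record GC anomaly report
#'
#' Profiles every record with non-overlapping windows and, where the record
#' carries a genome GC fraction, tests the region against the binomial
#' parametric background (`mean = genome_gc`,
#' `sd = sqrt(gc (1 - gc) / window)`).
#'
#' @param records List of [bgc_record()] objects.
#' @param cfg A [pipeline_config()] (window, step and alpha are used).
#' @return A `data.frame`: record id, window max/mean/min GC, genome mean,
#'   z, p, anomaly flag.
#' @export
gc_report <- function(records, cfg = pipeline_config()) {
  rows <- lapply(records, function(r) {
    prof <- gc_profile(r$region_seq, cfg$gc_window, cfg$gc_step)
    # the z-test assumes independent windows: test on a non-overlapping tiling
    prof_test <- gc_profile(r$region_seq, cfg$gc_window, cfg$gc_window)
    if (!is.na(r$genome_gc)) {
      an <- gc_anomaly(prof_test, genome_mean = r$genome_gc,
                       genome_sd = sqrt(r$genome_gc * (1 - r$genome_gc) /
                                        cfg$gc_window),
                       alpha = cfg$alpha)
    } else {
      an <- list(z = NA_real_, p_value = NA_real_, anomalous = NA)
    }
    data.frame(record_id = r$record_id, gc_max = prof$region_max,
               gc_mean = prof$region_mean, gc_min = prof$region_min,
               genome_mean = r$genome_gc, z = an$z, p_value = an$p_value,
               anomalous = an$anomalous, stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(), gc_max = numeric(),
               gc_mean = numeric(), gc_min = numeric(),
               genome_mean = numeric(), z = numeric(), p_value = numeric(),
               anomalous = logical(), stringsAsFactors = FALSE)
}
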