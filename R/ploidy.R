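# Ploidy assignment from chromosome counts and flow-cytometry histograms.

#' Construct a ploidy call
#'
#' @param plant_id Plant identifier.
#' @param method `"counting"` or `"flow"`.
#' @param ploidy Integer x-multiplier (>= 1).
#' @param chromosome_number Modal chromosome count (counting method).
#' @param peak_channel Dominant sample peak channel (flow method).
#' @param ratio_to_control Peak channel divided by the control channel
#'   (flow method).
#' @return An object of class `ploidy_call`.
#' @export
ploidy_call <- function(plant_id, method = c("counting", "flow"), ploidy,
                        chromosome_number = NULL, peak_channel = NULL,
                        ratio_to_control = NULL) {
  method <- match.arg(method)
  md_check(is_string(plant_id), "`plant_id` must be a string")
  md_check(is_count(ploidy, min = 1L), "`ploidy` must be an integer >= 1")
  if (method == "counting") {
    md_check(is_count(chromosome_number, min = 1L),
             "counting calls need `chromosome_number`")
  } else {
    md_check(is_number(peak_channel) && is_number(ratio_to_control),
             "flow calls need `peak_channel` and `ratio_to_control`")
  }
  structure(list(plant_id = plant_id, method = method,
                 ploidy = as.integer(ploidy),
                 chromosome_number = chromosome_number,
                 peak_channel = peak_channel,
                 ratio_to_control = ratio_to_control),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  evid <- if (x$method == "counting")
    sprintf("2n = %d chromosomes", x$chromosome_number)
  else
    sprintf("peak at channel %.1f, ratio %.2f to control", x$peak_channel,
            x$ratio_to_control)
  cat(sprintf("Ploidy call '%s': %dx by %s (%s)\n", x$plant_id, x$ploidy,
              x$method, evid))
  invisible(x)
}

#' Call ploidy from metaphase chromosome counts
#'
#' Takes the modal chromosome count over a plant's metaphase cells (ties
#' resolved to the lower count, robust to occasional miscounted spreads)
#' and converts it to an x-multiplier of the basic chromosome number
#' (x = 11 for *Musa*, so 22 -> 2x and 33 -> 3x). If the modal count is not
#' within `tolerance` of any multiple of the basic number the call is
#' refused with an `aneuploid-or-miscount` error rather than rounded.
#'
#' @param observation A list or data frame row with `plant_id` and
#'   `cell_counts` (integer vector of per-metaphase chromosome counts), or
#'   a data frame with columns `plant_id` and `chromosome_count` for a
#'   single plant.
#' @param basic_number Basic chromosome number x (default 11).
#' @param tolerance Maximum allowed deviation of the modal count from
#'   `ploidy * basic_number` (default 1).
#' @return A [ploidy_call()] with `method = "counting"`.
#' @examples
#' count_to_ploidy(list(plant_id = "p1", cell_counts = rep(33, 10)))
#' @export
count_to_ploidy <- function(observation, basic_number = 11L, tolerance = 1L) {
  md_check(is_count(basic_number, min = 1L), "`basic_number` must be >= 1")
  md_check(is_count(tolerance, min = 0L), "`tolerance` must be >= 0")
  if (is.data.frame(observation)) {
    md_check(all(c("plant_id", "chromosome_count") %in% names(observation)) &&
               length(unique(observation$plant_id)) == 1L,
             "`observation` data frame needs one plant's chromosome_count rows")
    observation <- list(plant_id = observation$plant_id[1L],
                        cell_counts = observation$chromosome_count)
  }
  md_check(is.list(observation) &&
             all(c("plant_id", "cell_counts") %in% names(observation)),
           "`observation` needs plant_id and cell_counts")
  counts <- observation$cell_counts
  md_check(is.numeric(counts) && length(counts) >= 1L && all(counts > 0),
           "`cell_counts` must be positive integers")
  tab <- table(counts)
  modal <- min(as.integer(names(tab)[tab == max(tab)])) # ties -> lower
  ploidy <- round(modal / basic_number)
  if (ploidy < 1L || abs(modal - ploidy * basic_number) > tolerance) {
    md_stop(sprintf(
      "modal count %d is not within %d of any multiple of x = %d: aneuploid or miscount",
      modal, tolerance, basic_number),
      "musadicho_aneuploid")
  }
  ploidy_call(observation$plant_id, "counting", ploidy,
              chromosome_number = modal)
}

# Moving-average smoothing with shrinking windows at the edges.
.smooth_counts <- function(counts, window) {
  n <- length(counts)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(counts[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# Local maxima (plateau centres; histogram ends never qualify) with their
# topographic prominence: peak height minus the higher of the deepest
# saddles separating it from higher terrain on each side.
.find_peaks <- function(channels, smoothed) {
  n <- length(smoothed)
  if (n < 3L) return(data.frame(channel = numeric(), height = numeric(),
                                prominence = numeric()))
  peaks <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (smoothed[i] > smoothed[i - 1L]) {
      j <- i
      while (j < n && smoothed[j + 1L] == smoothed[i]) j <- j + 1L
      if (j < n && smoothed[j + 1L] < smoothed[i]) {
        peaks <- c(peaks, (i + j) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  prom <- vapply(peaks, function(p) {
    h <- smoothed[p]
    left <- smoothed[seq_len(p - 1L)]
    right <- smoothed[(p + 1L):n]
    higher_l <- which(left >= h)
    sad_l <- if (length(higher_l)) min(left[(max(higher_l)):(p - 1L)]) else min(left)
    higher_r <- which(right >= h)
    sad_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
    h - max(sad_l, sad_r)
  }, numeric(1))
  data.frame(channel = channels[peaks], height = smoothed[peaks],
             prominence = prom)
}

#' Detect fluorescence peaks in a DNA-content histogram
#'
#' Counts are moving-average smoothed (shrinking windows at the edges),
#' then local maxima are kept when their topographic prominence is at least
#' `min_prominence_frac` times the maximum smoothed count. Returns the peak
#' channels sorted ascending; signals a `no-peaks` error when the
#' histogram is empty of structure.
#'
#' @param histogram A [flow_histogram()].
#' @param smooth_window Odd moving-average window (default 5 channels).
#' @param min_prominence_frac Minimum prominence as a fraction of the
#'   maximum smoothed count (default 0.05).
#' @return Numeric vector of peak channels, ascending.
#' @examples
#' h <- generate_flow_histogram(2, seed = 1)
#' detect_peaks(h)
#' @export
detect_peaks <- function(histogram, smooth_window = 5L,
                         min_prominence_frac = 0.05) {
  md_check(inherits(histogram, "flow_histogram"),
           "`histogram` must be a flow_histogram")
  md_check(is_count(smooth_window, min = 1L) && smooth_window %% 2L == 1L,
           "`smooth_window` must be an odd positive integer")
  md_check(is_number(min_prominence_frac) && min_prominence_frac >= 0,
           "`min_prominence_frac` must be non-negative")
  if (all(histogram$counts == 0)) {
    md_stop("histogram holds no counts: no peaks", "musadicho_no_peaks")
  }
  sm <- .smooth_counts(histogram$counts, smooth_window)
  pk <- .find_peaks(histogram$channels, sm)
  pk <- pk[pk$prominence >= min_prominence_frac * max(sm), , drop = FALSE]
  if (!nrow(pk)) {
    md_stop("no peak exceeds the prominence threshold", "musadicho_no_peaks")
  }
  sort(pk$channel)
}

#' Call ploidy from a flow histogram against an internal standard
#'
#' Detects peaks, discards those within the control tolerance band around
#' `control_channel`, and converts the dominant remaining sample peak `p`
#' to a ploidy by rounding `control_ploidy * p / control_channel`. If only
#' the control-band peak exists the sample shares the control's ploidy (the
#' merged-peak case). The call is refused with an `unresolved-ploidy` error
#' when the peak deviates from the nearest ploidy position by more than
#' `max_rel_deviation`.
#'
#' @param histogram A [flow_histogram()].
#' @param control_channel Channel of the internal standard's peak (must be
#'   supplied per run; the channel scale is instrument-dependent).
#' @param control_ploidy Ploidy of the internal standard (default 3).
#' @param max_rel_deviation Maximum relative deviation of the peak from its
#'   implied ploidy position (default 0.2).
#' @param control_band Relative half-width of the band around
#'   `control_channel` treated as the control peak (default 0.1).
#' @param smooth_window,min_prominence_frac Passed to [detect_peaks()].
#' @return A [ploidy_call()] with `method = "flow"`.
#' @examples
#' h <- generate_flow_histogram(2, control_channel = 75, seed = 1)
#' call_ploidy_flow(h, control_channel = 75)
#' @export
call_ploidy_flow <- function(histogram, control_channel,
                             control_ploidy = 3L, max_rel_deviation = 0.2,
                             control_band = 0.1, smooth_window = 5L,
                             min_prominence_frac = 0.05) {
  md_check(is_number(control_channel) && control_channel > 0,
           "`control_channel` must be positive")
  md_check(is_count(control_ploidy, min = 1L),
           "`control_ploidy` must be an integer >= 1")
  md_check(is_number(max_rel_deviation) && max_rel_deviation > 0,
           "`max_rel_deviation` must be positive")
  peaks <- detect_peaks(histogram, smooth_window, min_prominence_frac)
  sm <- .smooth_counts(histogram$counts, smooth_window)
  height <- sm[match(peaks, histogram$channels)]
  in_band <- abs(peaks / control_channel - 1) <= control_band
  sample_peaks <- peaks[!in_band]
  if (!length(sample_peaks)) {
    p <- peaks[which.max(height)]
    return(ploidy_call(histogram$plant_id, "flow", control_ploidy,
                       peak_channel = p,
                       ratio_to_control = p / control_channel))
  }
  p <- sample_peaks[which.max(height[!in_band])]
  ploidy <- round(control_ploidy * p / control_channel)
  expected <- ploidy * control_channel / control_ploidy
  if (ploidy < 1L || abs(p - expected) / expected > max_rel_deviation) {
    md_stop(sprintf(
      "peak at channel %.1f deviates by more than %.0f%% from any ploidy position",
      p, 100 * max_rel_deviation),
      "musadicho_unresolved_ploidy")
  }
  ploidy_call(histogram$plant_id, "flow", ploidy, peak_channel = p,
              ratio_to_control = p / control_channel)
}

#' Call ploidy for every histogram of a cohort
#'
#' Convenience wrapper applying [call_ploidy_flow()] to each histogram;
#' refused calls (errors) are captured as condition objects in the result
#' rather than aborting the cohort.
#'
#' @param histograms List of [flow_histogram()] objects.
#' @param ... Passed to [call_ploidy_flow()].
#' @return List whose elements are [ploidy_call()] objects or captured
#'   error conditions, suitable for [summarize_cohort()].
#' @export
call_cohort <- function(histograms, ...) {
  lapply(histograms, function(h) {
    tryCatch(call_ploidy_flow(h, ...), musadicho_error = function(e) e)
  })
}

#' Summarise ploidy calls for a cohort
#'
#' Tallies calls by ploidy; refused or failed calls are listed separately,
#' never silently dropped.
#'
#' @param calls List of [ploidy_call()] objects and/or captured error
#'   conditions (as produced by [call_cohort()]).
#' @return An object of class `cohort_summary`: a list with `tally` (named
#'   integer vector, names are ploidies) and `refused` (list of error
#'   conditions).
#' @examples
#' coh <- generate_cohort(data.frame(ploidy = c(2, 4), count = c(9, 1)),
#'                        seed = 1)
#' summarize_cohort(call_cohort(coh$histograms, control_channel = 75))
#' @export
summarize_cohort <- function(calls) {
  md_check(is.list(calls), "`calls` must be a list")
  ok <- vapply(calls, inherits, logical(1), "ploidy_call")
  bad <- vapply(calls, inherits, logical(1), "condition")
  md_check(all(ok | bad),
           "`calls` elements must be ploidy_call objects or conditions")
  ploidies <- vapply(calls[ok], `[[`, integer(1), "ploidy")
  tally <- if (length(ploidies)) {
    tab <- table(ploidies)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(), character())
  }
  structure(list(tally = tally, refused = calls[bad]),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  n <- sum(x$tally) + length(x$refused)
  cat(sprintf("Cohort of %d plants:", n))
  for (k in names(x$tally)) cat(sprintf(" %sx: %d;", k, x$tally[[k]]))
  cat(sprintf(" refused: %d\n", length(x$refused)))
  invisible(x)
}

#' Side-by-side counting and flow ploidy table
#'
#' Joins per-plant counting and flow calls into the study's reporting
#' format, with the flow call in parentheses next to the counting call.
#' Disagreements between the two methods are observed data and are reported
#' side by side, never reconciled.
#'
#' @param counting_calls,flow_calls Lists of [ploidy_call()] objects (or
#'   captured conditions, shown as `"?"`), matched by `plant_id`.
#' @return Data frame with columns `plant_id`, `counting`, `flow`,
#'   `display` (e.g. `"2x (4x)"`).
#' @export
ploidy_table <- function(counting_calls, flow_calls) {
  fmt <- function(x) {
    if (inherits(x, "ploidy_call")) sprintf("%dx", x$ploidy) else "?"
  }
  id_of <- function(x) if (inherits(x, "ploidy_call")) x$plant_id else NA_character_
  cids <- vapply(counting_calls, id_of, character(1))
  fids <- vapply(flow_calls, id_of, character(1))
  ids <- unique(c(cids[!is.na(cids)], fids[!is.na(fids)]))
  rows <- lapply(ids, function(pid) {
    cc <- counting_calls[match(pid, cids)][[1]]
    fc <- flow_calls[match(pid, fids)][[1]]
    data.frame(plant_id = pid, counting = fmt(cc), flow = fmt(fc),
               display = sprintf("%s (%s)", fmt(cc), fmt(fc)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
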