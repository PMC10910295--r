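#' Stimulus protocol for a flash-response recording
#'
#' Describes the timing layout of one recording block: a pre-stimulus
#' baseline interval, the flash itself, and a post-offset interval in which
#' OFF responses are measured. Spike times are expressed in seconds relative
#' to stimulus onset, so the analysed window is
#' `[-pre_window, stim_duration + post_window]`.
#'
#' The defaults describe a 1-s flash repeated 40 times per condition with
#' 1-s baseline and post-offset windows and 25-ms PSTH bins, i.e. 120 bins
#' over the 3-s window.
#'
#' @param stim_duration Flash duration in seconds.
#' @param pre_window Baseline interval before onset, seconds.
#' @param post_window Interval after offset used for OFF responses, seconds.
#' @param n_trials Number of repetitions per stimulation condition.
#' @param bin_width PSTH bin width in seconds; must divide the total window
#'   into an integer number of bins.
#' @param conditions Ordered labels of the three stimulation conditions.
#' @return An object of class `stim_protocol`.
#' @examples
#' p <- stim_protocol()
#' n_bins(p)
#' @export
stim_protocol <- function(stim_duration = 1.0,
                          pre_window = 1.0,
                          post_window = 1.0,
                          n_trials = 40L,
                          bin_width = 0.025,
                          conditions = c("contra", "ipsi", "bilateral")) {
  stopifnot(is.numeric(stim_duration), is.numeric(pre_window),
            is.numeric(post_window), is.numeric(bin_width))
  if (stim_duration <= 0 || pre_window <= 0 || post_window <= 0 ||
      bin_width <= 0) {
    stop("all protocol durations must be positive", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 2L) {
    stop("n_trials must be an integer >= 2", call. = FALSE)
  }
  total <- pre_window + stim_duration + post_window
  nb <- total / bin_width
  if (abs(nb - round(nb)) > 1e-8) {
    stop("bin_width must divide the total analysis window ",
         "(pre + stim + post = ", total, " s) into an integer number of bins",
         call. = FALSE)
  }
  conditions <- as.character(conditions)
  if (length(conditions) != 3L || anyDuplicated(conditions)) {
    stop("conditions must be three distinct labels", call. = FALSE)
  }
  structure(
    list(stim_duration = stim_duration,
         pre_window = pre_window,
         post_window = post_window,
         n_trials = n_trials,
         bin_width = bin_width,
         conditions = conditions),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol>\n")
  cat(sprintf("  window: [%g, %g] s (stim %g s), %d bins of %g s\n",
              -x$pre_window, x$stim_duration + x$post_window,
              x$stim_duration, n_bins(x), x$bin_width))
  cat(sprintf("  %d trials x conditions: %s\n",
              x$n_trials, paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Number of PSTH bins implied by a protocol
#' @param protocol A [stim_protocol()].
#' @return Integer bin count.
#' @export
n_bins <- function(protocol) {
  as.integer(round((protocol$pre_window + protocol$stim_duration +
                      protocol$post_window) / protocol$bin_width))
}

#' Bin edges of the PSTH time axis
#' @param protocol A [stim_protocol()].
#' @return Numeric vector of length `n_bins(protocol) + 1`, half-open bins,
#'   starting at `-pre_window`.
#' @export
bin_edges <- function(protocol) {
  -protocol$pre_window + protocol$bin_width * seq(0L, n_bins(protocol))
}

# Bin index (1-based) of each spike time; the closed upper end of the window
# folds into the last bin so that boundary spikes are never dropped.
time_to_bin <- function(t, protocol) {
  b <- floor((t + protocol$pre_window) / protocol$bin_width) + 1L
  pmin(as.integer(b), n_bins(protocol))
}

# Logical masks selecting bins whose left edge falls in each analysis window.
window_bins <- function(protocol, window = c("baseline", "on", "off")) {
  window <- match.arg(window)
  left <- bin_edges(protocol)[-(n_bins(protocol) + 1L)]
  eps <- 1e-9
  switch(window,
         baseline = left < -eps,
         on = left >= -eps & left < protocol$stim_duration - eps,
         off = left >= protocol$stim_duration - eps)
}

window_duration <- function(protocol, window = c("baseline", "on", "off")) {
  window <- match.arg(window)
  switch(window,
         baseline = protocol$pre_window,
         on = protocol$stim_duration,
         off = protocol$post_window)
}

#' Read or write a stimulus protocol as YAML
#'
#' The on-disk form is a flat YAML mapping of the [stim_protocol()] fields;
#' unknown extra keys (e.g. classifier thresholds stored in the same config
#' file) are ignored on read.
#'
#' @param path File path.
#' @return `read_protocol()` returns a validated `stim_protocol`.
#' @export
read_protocol <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("stim_duration", "pre_window", "post_window", "n_trials",
            "bin_width", "conditions")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    stop("protocol file is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stim_protocol(stim_duration = doc$stim_duration,
                pre_window = doc$pre_window,
                post_window = doc$post_window,
                n_trials = doc$n_trials,
                bin_width = doc$bin_width,
                conditions = unlist(doc$conditions))
}

#' @rdname read_protocol
#' @param protocol A [stim_protocol()] to serialise.
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(unclass(protocol), path)
  invisible(path)
}
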