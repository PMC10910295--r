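#' Trial-aligned spike dataset
#'
#' Container tying together a [stim_protocol()], per-unit metadata, and spike
#' timestamps. Spikes are stored long-format, one row per spike, with times in
#' seconds relative to stimulus onset (negative = baseline). Construction
#' validates every invariant the downstream analysis relies on:
#' * spike times inside `[-pre_window, stim_duration + post_window]`,
#' * trial indices in `[0, n_trials)`,
#' * strictly increasing times within a trial (duplicates rejected),
#' * conditions drawn from the protocol's labels,
#' * treatment in `{dark, light}`, hemisphere in `{left, right}`,
#' * every spike's `unit_id` declared in the metadata.
#'
#' Units with no spikes at all are valid; the analysis treats them as silent.
#'
#' @param protocol A [stim_protocol()].
#' @param units Data frame with columns `unit_id`, `subject_id`, `treatment`,
#'   `hemisphere` and optionally `ground_truth` (simulator archetype label).
#' @param spikes Data frame with columns `unit_id`, `condition`, `trial`
#'   (0-based), `spike_time_s`. May have zero rows.
#' @return An object of class `spike_dataset`.
#' @export
spike_dataset <- function(protocol, units, spikes) {
  stopifnot(inherits(protocol, "stim_protocol"))
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  spikes <- as.data.frame(spikes, stringsAsFactors = FALSE)

  need_meta <- c("unit_id", "subject_id", "treatment", "hemisphere")
  for (col in need_meta) {
    if (!col %in% names(units)) {
      stop("unit metadata is missing column '", col, "'", call. = FALSE)
    }
  }
  if (!"ground_truth" %in% names(units)) units$ground_truth <- NA_character_
  units <- units[c(need_meta, "ground_truth")]
  units$unit_id <- as.character(units$unit_id)
  if (anyDuplicated(units$unit_id)) {
    stop("duplicate unit_id in metadata: ",
         units$unit_id[duplicated(units$unit_id)][1L], call. = FALSE)
  }
  bad_tr <- setdiff(unique(units$treatment), c("dark", "light"))
  if (length(bad_tr)) {
    stop("unknown treatment level '", bad_tr[1L],
         "' (expected dark/light)", call. = FALSE)
  }
  bad_hemi <- setdiff(unique(units$hemisphere), c("left", "right"))
  if (length(bad_hemi)) {
    stop("unknown hemisphere level '", bad_hemi[1L],
         "' (expected left/right)", call. = FALSE)
  }

  need_sp <- c("unit_id", "condition", "trial", "spike_time_s")
  for (col in need_sp) {
    if (!col %in% names(spikes)) {
      stop("spike table is missing column '", col, "'", call. = FALSE)
    }
  }
  spikes <- spikes[need_sp]
  spikes$unit_id <- as.character(spikes$unit_id)
  spikes$condition <- as.character(spikes$condition)
  spikes$trial <- as.integer(spikes$trial)
  spikes$spike_time_s <- as.numeric(spikes$spike_time_s)

  if (nrow(spikes)) {
    unknown <- setdiff(unique(spikes$unit_id), units$unit_id)
    if (length(unknown)) {
      stop("spike table references undeclared unit '", unknown[1L], "'",
           call. = FALSE)
    }
    bad_cond <- setdiff(unique(spikes$condition), protocol$conditions)
    if (length(bad_cond)) {
      stop("unknown condition label '", bad_cond[1L], "'", call. = FALSE)
    }
    bad_trial <- spikes$trial < 0L | spikes$trial >= protocol$n_trials |
      is.na(spikes$trial)
    if (any(bad_trial)) {
      i <- which(bad_trial)[1L]
      stop("trial index out of range for unit ", spikes$unit_id[i],
           " (trial ", spikes$trial[i], ")", call. = FALSE)
    }
    lo <- -protocol$pre_window
    hi <- protocol$stim_duration + protocol$post_window
    bad_t <- is.na(spikes$spike_time_s) | spikes$spike_time_s < lo |
      spikes$spike_time_s > hi
    if (any(bad_t)) {
      i <- which(bad_t)[1L]
      stop("spike time ", spikes$spike_time_s[i], " outside [", lo, ", ", hi,
           "] for unit ", spikes$unit_id[i], ", trial ", spikes$trial[i],
           call. = FALSE)
    }
    ord <- order(spikes$unit_id, match(spikes$condition, protocol$conditions),
                 spikes$trial, spikes$spike_time_s)
    spikes <- spikes[ord, , drop = FALSE]
    rownames(spikes) <- NULL
    key <- paste(spikes$unit_id, spikes$condition, spikes$trial)
    same <- key[-1L] == key[-length(key)] &
      spikes$spike_time_s[-1L] == spikes$spike_time_s[-nrow(spikes)]
    if (nrow(spikes) > 1L && any(same)) {
      i <- which(same)[1L] + 1L
      stop("duplicate spike time ", spikes$spike_time_s[i], " for unit ",
           spikes$unit_id[i], ", trial ", spikes$trial[i], call. = FALSE)
    }
  }
  rownames(units) <- NULL
  structure(list(protocol = protocol, units = units, spikes = spikes),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat("<spike_dataset>", nrow(x$units), "units,", nrow(x$spikes), "spikes\n")
  print(x$protocol)
  invisible(x)
}

# Lightweight single-unit view of a dataset (no re-validation); used by the
# cohort-level loops to avoid rescanning the full spike table per unit.
split_by_unit <- function(dataset) {
  idx <- split(seq_len(nrow(dataset$spikes)),
               factor(dataset$spikes$unit_id,
                      levels = dataset$units$unit_id))
  out <- lapply(seq_len(nrow(dataset$units)), function(i) {
    structure(list(protocol = dataset$protocol,
                   units = dataset$units[i, , drop = FALSE],
                   spikes = dataset$spikes[idx[[i]], , drop = FALSE]),
              class = "spike_dataset")
  })
  names(out) <- dataset$units$unit_id
  out
}

# Spike times of one (unit, condition), as a list of length n_trials.
unit_trains <- function(dataset, unit_id, condition) {
  p <- dataset$protocol
  sel <- dataset$spikes$unit_id == unit_id &
    dataset$spikes$condition == condition
  t <- dataset$spikes$spike_time_s[sel]
  trial <- dataset$spikes$trial[sel]
  split(t, factor(trial, levels = seq_len(p$n_trials) - 1L))
}

#' Read a spike dataset from its three on-disk files
#'
#' The on-disk format is plain text: a spike CSV
#' (`unit_id,condition,trial,spike_time_s`, one row per spike), a metadata CSV
#' (`unit_id,subject_id,treatment,hemisphere[,ground_truth]`) and a YAML
#' protocol file (see [read_protocol()]). All dataset invariants are enforced
#' on read.
#'
#' @param spikes_path Path to the spike CSV.
#' @param meta_path Path to the unit-metadata CSV.
#' @param protocol_path Path to the protocol YAML.
#' @return A validated [spike_dataset()].
#' @export
read_spike_table <- function(spikes_path, meta_path, protocol_path) {
  protocol <- read_protocol(protocol_path)
  units <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if ("ground_truth" %in% names(units)) {
    units$ground_truth[units$ground_truth %in% c("", "NA")] <- NA_character_
  }
  spikes <- utils::read.csv(spikes_path, stringsAsFactors = FALSE)
  if (nrow(spikes) == 0L) {
    spikes <- data.frame(unit_id = character(), condition = character(),
                         trial = integer(), spike_time_s = numeric())
  }
  spike_dataset(protocol, units, spikes)
}

#' Write a spike dataset to disk
#'
#' Emits the three files read back by [read_spike_table()]. Rows are ordered
#' deterministically by (unit, condition, trial, time) and spike times are
#' written with enough digits to round-trip doubles exactly for analysis
#' purposes (15 significant digits).
#'
#' @param dataset A [spike_dataset()].
#' @param spikes_path,meta_path,protocol_path Output file paths.
#' @return Invisibly, the spike table path.
#' @export
write_spike_table <- function(dataset, spikes_path, meta_path = NULL,
                              protocol_path = NULL) {
  sp <- dataset$spikes
  out <- data.frame(unit_id = sp$unit_id,
                    condition = sp$condition,
                    trial = sp$trial,
                    spike_time_s = sprintf("%.15g", sp$spike_time_s),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, spikes_path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    utils::write.csv(dataset$units, meta_path, row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(protocol_path)) write_protocol(dataset$protocol, protocol_path)
  invisible(spikes_path)
}
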