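#' Safe-use exceedance filtering
#'
#' The extraction step of the screening pipeline: prescription records are
#' checked against the per-drug safe-use rules and every violation is
#' recorded as a flag with one of four reasons:
#'
#' * `DOSE` — the record's daily dose exceeds the drug's cap.
#' * `EPISODE` — a treatment episode's total days supplied exceeds the
#'   episode cap. Consecutive prescriptions for one patient-drug pair form
#'   one episode when the gap between a prescription's coverage end
#'   (date + days supplied) and the next prescription's date is at most
#'   `episode_gap_days` (persistence-window convention; default 7 days).
#'   Every record of a violating episode is flagged.
#' * `CUMULATIVE` — the summed days supplied of a patient-drug pair inside
#'   some rolling 90-day window exceeds the cumulative cap. Windows are
#'   closed on the left and open on the right; every record inside a
#'   violating window is flagged.
#' * `FREQUENCY` — the record is the (k+1)-th or later dispensing event for
#'   its patient-drug pair within a rolling 30-day window, where k is the
#'   drug's event cap.
#'
#' A flag is a screening signal, not a clinical judgment: a prescriber may
#' exceed the standards for legitimate medical reasons.
#'
#' @name narcscreen-ssun
NULL

#' Flag records exceeding the safe-use rules
#'
#' @param records Validated record data frame.
#' @param rules Rule set from [default_ssun_rules()] or [read_ssun_rules()].
#' @param episode_gap_days Maximum coverage gap (days) joining two
#'   prescriptions into one treatment episode.
#' @return Data frame of flags: `record_index` (row in `records`),
#'   `patient_id`, `hospital_id`, `drug`, `reason`. A record may carry
#'   several flags with distinct reasons.
#' @export
flag_exceedances <- function(records, rules = default_ssun_rules(),
                             episode_gap_days = 7) {
  validate_rules(rules)
  no_rule <- setdiff(unique(records$drug), names(rules))
  if (length(no_rule) > 0) {
    stop("no safe-use rule for drug(s): ", paste(no_rule, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(records)
  if (n == 0) return(empty_flags())

  idx_out <- integer(0); reason_out <- character(0)
  add <- function(idx, reason) {
    idx_out <<- c(idx_out, idx)
    reason_out <<- c(reason_out, rep(reason, length(idx)))
  }

  # DOSE: per-prescription check
  caps <- vapply(rules, `[[`, numeric(1), "max_daily_dose_mg")[records$drug]
  add(which(records$daily_dose_mg > caps), "DOSE")

  # window-based checks per patient-drug pair
  key <- paste(records$patient_id, records$drug, sep = "\r")
  for (rows in split(seq_len(n), key)) {
    drug <- records$drug[rows[1]]
    rule <- rules[[drug]]
    ord <- rows[order(records$date[rows], rows)]
    d <- as.numeric(records$date[ord])
    supplied <- records$days_supplied[ord]

    if (is.finite(rule$max_episode_days)) {
      # split into episodes at coverage gaps > episode_gap_days
      cover_end <- cummax_by_episode(d, supplied, episode_gap_days)
      ep <- cover_end$episode
      tot <- tapply(supplied, ep, sum)
      bad_ep <- as.integer(names(tot)[tot > rule$max_episode_days])
      if (length(bad_ep) > 0) add(ord[ep %in% bad_ep], "EPISODE")
    }

    if (is.finite(rule$max_cumulative_days)) {
      flagged <- rep(FALSE, length(ord))
      for (i in seq_along(ord)) {
        inside <- d >= d[i] & d < d[i] + 90
        if (sum(supplied[inside]) > rule$max_cumulative_days) {
          flagged <- flagged | inside
        }
      }
      if (any(flagged)) add(ord[flagged], "CUMULATIVE")
    }

    if (is.finite(rule$max_events_per_30_days)) {
      k <- rule$max_events_per_30_days
      pos <- seq_along(ord)
      hits <- vapply(pos, function(i) {
        sum(d[seq_len(i)] > d[i] - 30) > k
      }, logical(1))
      if (any(hits)) add(ord[hits], "FREQUENCY")
    }
  }

  if (length(idx_out) == 0) return(empty_flags())
  flags <- data.frame(
    record_index = idx_out,
    patient_id = records$patient_id[idx_out],
    hospital_id = records$hospital_id[idx_out],
    drug = records$drug[idx_out],
    reason = reason_out,
    stringsAsFactors = FALSE
  )
  flags <- unique(flags)
  flags <- flags[order(flags$record_index, flags$reason), , drop = FALSE]
  rownames(flags) <- NULL
  flags
}

empty_flags <- function() {
  data.frame(record_index = integer(0), patient_id = character(0),
             hospital_id = character(0), drug = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

# Assign episode ids by scanning records of one patient-drug pair in date
# order: a new episode starts when the record's date exceeds the running
# coverage end (max of date + days_supplied so far) by more than gap days.
cummax_by_episode <- function(dates, supplied, gap) {
  n <- length(dates)
  episode <- integer(n)
  ep <- 1L
  cover_end <- dates[1] + supplied[1]
  episode[1] <- ep
  if (n > 1) {
    for (i in 2:n) {
      if (dates[i] - cover_end > gap) {
        ep <- ep + 1L
        cover_end <- dates[i] + supplied[i]
      } else {
        cover_end <- max(cover_end, dates[i] + supplied[i])
      }
      episode[i] <- ep
    }
  }
  list(episode = episode)
}

#' Extract the flagged subset of records
#'
#' Returns every record belonging to a (patient, drug) pair with at least
#' one flag — the pair's whole prescription history, not only the violating
#' records — so the network reflects each flagged patient's full
#' prescription pattern for that drug. Set `whole_history = FALSE` to keep
#' only the violating records themselves.
#'
#' @param records Record data frame the flags were computed from.
#' @param flags Flag data frame from [flag_exceedances()].
#' @param whole_history Keep the full pair history (default) or only
#'   flagged records.
#' @return Subset of `records` (row order preserved).
#' @export
flagged_subset <- function(records, flags, whole_history = TRUE) {
  if (nrow(flags) == 0) return(records[0, , drop = FALSE])
  if (whole_history) {
    key <- paste(records$patient_id, records$drug, sep = "\r")
    flagged_key <- unique(paste(flags$patient_id, flags$drug, sep = "\r"))
    out <- records[key %in% flagged_key, , drop = FALSE]
  } else {
    out <- records[sort(unique(flags$record_index)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Summarize prescriptions per flagged patient
#'
#' For each drug, the mean and population standard deviation of the number
#' of records per patient within the flagged subset, and the number of
#' flagged patients. A strongly right-skewed distribution (SD much larger
#' than the mean) is itself a screening signal: a minority of patients
#' accumulating very many prescriptions.
#'
#' @param flagged Record data frame from [flagged_subset()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Data frame per drug: `drug`, `n_patients`, `mean_rx`, `sd_rx`.
#'   Drugs with no flagged patients get `n_patients = 0` and `NA` moments.
#' @export
summarize_exceedance <- function(flagged, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  out <- lapply(drug_classes(), function(drug) {
    sub <- flagged[flagged$drug == drug, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(data.frame(drug = drug, n_patients = 0L,
                        mean_rx = NA_real_, sd_rx = NA_real_,
                        stringsAsFactors = FALSE))
    }
    counts <- as.numeric(table(sub$patient_id))
    m <- mean(counts)
    v <- if (sd_type == "population") {
      mean((counts - m)^2)
    } else if (length(counts) > 1) stats::var(counts) else 0
    data.frame(drug = drug, n_patients = length(counts),
               mean_rx = m, sd_rx = sqrt(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write exceedance flags as delimited text
#' @param flags Flag data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flags <- function(flags, path) {
  utils::write.table(flags, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
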