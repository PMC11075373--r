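#' Drug classes, hospital attribute vocabularies, and safe-use rules
#'
#' The pipeline screens three classes of medical narcotics that are subject
#' to per-drug safe-use limits (daily dose, episode duration, cumulative
#' duration and prescribing frequency) under Korea's Standards for Safe Use
#' of Medical Narcotics.
#'
#' @name narcscreen-vocab
NULL

#' Recognized drug classes
#' @return Character vector of the three drug class codes.
#' @export
drug_classes <- function() {
  c("APPETITE_SUPPRESSANT", "ZOLPIDEM", "PROPOFOL")
}

#' Hospital size-category codes
#'
#' Ten institution types: general hospital (GH), psychiatric hospital (PH),
#' oriental medicine hospital (OMH), convalescent hospital (CH), dental
#' clinic (DC), public health center/clinic/unit (PHCE/PHCL/PHU), hospital
#' (HO) and clinic (CL).
#' @return Character vector of the ten size codes.
#' @export
size_categories <- function() {
  c("GH", "PH", "OMH", "CH", "DC", "PHCE", "PHCL", "PHU", "HO", "CL")
}

#' Region codes
#'
#' Sixteen first-level administrative regions of South Korea.
#' @return Character vector of the sixteen region codes.
#' @export
region_codes <- function() {
  c("SEL", "PUS", "TAE", "INC", "KWJ", "TAJ", "USN", "KYG",
    "KAW", "CCB", "CCN", "CLB", "CLN", "KSB", "KSN", "CHJ")
}

#' Construct a safe-use rule for one drug
#'
#' A rule caps any subset of: daily dose (mg/day), total days supplied in one
#' treatment episode, total days supplied in any rolling 90-day window, and
#' the number of dispensing events in any rolling 30-day window. `Inf` marks
#' an unlimited field.
#'
#' @param drug One of [drug_classes()].
#' @param max_daily_dose_mg Positive number or `Inf`.
#' @param max_episode_days Positive integer or `Inf`.
#' @param max_cumulative_days Positive integer or `Inf`.
#' @param max_events_per_30_days Positive integer or `Inf`.
#' @return A list of class `ssun_rule`.
#' @export
ssun_rule <- function(drug,
                      max_daily_dose_mg = Inf,
                      max_episode_days = Inf,
                      max_cumulative_days = Inf,
                      max_events_per_30_days = Inf) {
  drug <- match.arg(drug, drug_classes())
  stopifnot(max_daily_dose_mg > 0, max_episode_days > 0,
            max_cumulative_days > 0, max_events_per_30_days > 0)
  structure(
    list(drug = drug,
         max_daily_dose_mg = max_daily_dose_mg,
         max_episode_days = max_episode_days,
         max_cumulative_days = max_cumulative_days,
         max_events_per_30_days = max_events_per_30_days),
    class = "ssun_rule"
  )
}

#' Default safe-use rule set
#'
#' The default limits encode the published safe-use standards:
#' appetite suppressants restricted to treatment episodes of at most four
#' weeks (28 days) and at most three months (90 days) of supply in any
#' rolling 90-day window; zolpidem capped at 10 mg/day with episodes of at
#' most four weeks; propofol at most one dispensing event per rolling
#' 30-day window.
#'
#' Any field may be overridden through `overrides`, a named list of the form
#' `list(ZOLPIDEM = list(max_daily_dose_mg = 5))`.
#'
#' @param overrides Optional named list of per-drug field overrides.
#' @return Named list of three `ssun_rule` objects, one per drug class.
#' @examples
#' rules <- default_ssun_rules()
#' rules$ZOLPIDEM$max_daily_dose_mg  # 10
#' @export
default_ssun_rules <- function(overrides = NULL) {
  rules <- list(
    APPETITE_SUPPRESSANT = ssun_rule("APPETITE_SUPPRESSANT",
                                     max_episode_days = 28L,
                                     max_cumulative_days = 90L),
    ZOLPIDEM = ssun_rule("ZOLPIDEM",
                         max_daily_dose_mg = 10,
                         max_episode_days = 28L),
    PROPOFOL = ssun_rule("PROPOFOL",
                         max_events_per_30_days = 1L)
  )
  if (!is.null(overrides)) {
    for (drug in names(overrides)) {
      if (!drug %in% names(rules)) {
        stop("unknown drug in rule overrides: ", drug, call. = FALSE)
      }
      for (field in names(overrides[[drug]])) {
        if (!field %in% names(rules[[drug]])) {
          stop("unknown rule field: ", field, call. = FALSE)
        }
        rules[[drug]][[field]] <- overrides[[drug]][[field]]
      }
    }
  }
  rules
}

#' Read a rule set from a YAML file
#'
#' The file holds a mapping from drug class to rule fields; missing drugs
#' keep their defaults, missing fields keep the default field value, and the
#' string `"unlimited"` (or `.inf`) maps to `Inf`.
#'
#' @param path Path to a YAML rules file.
#' @return Named list of `ssun_rule` objects.
#' @export
read_ssun_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- lapply(raw, function(fields) {
    lapply(fields, function(v) if (identical(v, "unlimited")) Inf else v)
  })
  default_ssun_rules(overrides = raw)
}

validate_rules <- function(rules) {
  stopifnot(is.list(rules))
  for (nm in names(rules)) {
    r <- rules[[nm]]
    if (!inherits(r, "ssun_rule") || !identical(r$drug, nm)) {
      stop("invalid rule set entry for drug ", nm, call. = FALSE)
    }
  }
  invisible(rules)
}
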