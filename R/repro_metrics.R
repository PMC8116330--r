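# Per-female and cohort reproductive statistics over oviposition event logs.
#
# Conventions (all matching standard captive-breeding bookkeeping):
# * wind egg cases (no yolk) are excluded from every denominator;
# * fertility  = % of non-wind eggs that developed an embryo;
# * hatchability = % of non-wind eggs that hatched;
# * both are AI-adjusted by default: confirmed parthenotes are excluded from
#   the numerators so the rates reflect insemination success only;
# * fertility duration = last minus first AI-fertile lay day (0 when a single
#   fertile egg was laid, undefined when none).

FATES <- c("wind", "infertile", "embryo_death", "hatched")

#' Round half away from zero
#'
#' Reporting rounding for percentages: one decimal by default, ties away
#' from zero (so 26.25 -> 26.3), unlike R's banker's [round()].
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage with reporting rounding
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Decimal places (default 1).
#' @return `100 * num / den`, rounded half away from zero.
#' @export
as_pct <- function(num, den, digits = 1L) {
  if (any(den == 0)) stop("percentage undefined: zero denominator")
  round_half_up(100 * num / den, digits)
}

#' Validate an oviposition event log
#'
#' @param df Data frame with columns `female_id`, `day` (integer lay day or
#'   `Date`), `fate` (one of wind, infertile, embryo_death, hatched), and
#'   optionally `pair_id`, `offspring_id`, `parthenote` (logical).
#' @return The validated data frame with canonical columns; `Date` lay days
#'   are converted to integer day numbers.
#' @export
egg_events <- function(df) {
  need <- c("female_id", "day", "fate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event log lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (inherits(df$day, "Date")) df$day <- as.integer(df$day)
  df$day <- as.integer(df$day)
  df$fate <- tolower(as.character(df$fate))
  bad <- setdiff(unique(df$fate), FATES)
  if (length(bad)) stop("unknown fate(s): ", paste(bad, collapse = ", "))
  blank_to_na <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
    x
  }
  df$pair_id <- if (is.null(df$pair_id)) NA_character_ else
    blank_to_na(df$pair_id)
  df$offspring_id <- if (is.null(df$offspring_id)) NA_character_ else
    blank_to_na(df$offspring_id)
  if (is.null(df$parthenote)) df$parthenote <- NA
  df$parthenote <- as.logical(df$parthenote)
  wind <- df$fate == "wind"
  if (any(wind & (!is.na(df$offspring_id) | df$parthenote %in% TRUE)))
    stop("wind egg cases cannot carry an offspring_id or parthenote flag")
  if (any(df$parthenote %in% TRUE & !df$fate %in% c("embryo_death", "hatched")))
    stop("parthenote flag requires a developed egg (embryo_death or hatched)")
  df[c("female_id", "day", "pair_id", "fate", "offspring_id", "parthenote")]
}

#' Read an oviposition event log
#'
#' Delimited text (comma or tab, auto-detected) with columns `female_id`,
#' `lay_date` (ISO-8601 date or integer day index), optional `pair_id`,
#' `fate`, optional `offspring_id` and `parthenote`.
#'
#' @param path Path to the log.
#' @return Validated event data frame (see [egg_events()]).
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- detect_delim(readLines(path, n = 1L))
  # read everything as character: numeric coercion would strip leading zeros
  # from ids like "034"
  df <- utils::read.table(path, sep = sep, header = TRUE, strip.white = TRUE,
                          colClasses = "character")
  if ("lay_date" %in% names(df) && !"day" %in% names(df)) {
    ld <- df$lay_date
    df$day <- if (all(grepl("^-?[0-9]+$", ld))) as.integer(ld)
              else as.integer(as.Date(ld))
    df$lay_date <- NULL
  }
  df$female_id <- as.character(df$female_id)
  egg_events(df)
}

#' Summarise one female's reproductive outcome
#'
#' Eggs laid before `insemination_day` are excluded entirely; wind cases are
#' excluded from all denominators; parthenote-flagged eggs are excluded from
#' the AI fertility and hatchability numerators unless
#' `include_parthenotes = TRUE` (raw mode).
#'
#' @param events Event data frame ([egg_events()]) for a single female.
#' @param insemination_day Lay-day origin (same scale as `events$day`);
#'   default 0 when days are already post-insemination offsets.
#' @param include_parthenotes Count parthenote-flagged developed eggs in the
#'   fertility/hatchability numerators (default FALSE).
#' @return One-row data frame: `female_id`, `n_laid`, `n_eggs`,
#'   `n_fertile_ai`, `n_parthenote`, `n_hatched_ai`, `fertility_pct`,
#'   `hatchability_pct`, `first_fertile_day`, `last_fertile_day`,
#'   `fertility_duration_days` (days are post-insemination offsets).
#' @export
summarize_female <- function(events, insemination_day = 0L,
                             include_parthenotes = FALSE) {
  ev <- egg_events(events)
  if (length(unique(ev$female_id)) > 1L)
    stop("events mix several females: ",
         paste(unique(ev$female_id), collapse = ", "))
  if (inherits(insemination_day, "Date"))
    insemination_day <- as.integer(insemination_day)
  ev <- ev[ev$day >= insemination_day, , drop = FALSE]
  nonwind <- ev[ev$fate != "wind", , drop = FALSE]
  developed <- nonwind$fate %in% c("embryo_death", "hatched")
  parth <- nonwind$parthenote %in% TRUE
  n_eggs <- nrow(nonwind)
  n_fertile_ai <- sum(developed & !parth)
  n_hatched_ai <- sum(nonwind$fate == "hatched" & !parth)
  fert_num <- if (include_parthenotes) sum(developed) else n_fertile_ai
  hatch_num <- if (include_parthenotes) sum(nonwind$fate == "hatched")
               else n_hatched_ai
  fdays <- nonwind$day[developed & !parth] - insemination_day
  data.frame(
    female_id = if (nrow(ev)) ev$female_id[1] else unique(events$female_id)[1],
    n_laid = nrow(ev),
    n_eggs = n_eggs,
    n_fertile_ai = n_fertile_ai,
    n_parthenote = sum(parth),
    n_hatched_ai = n_hatched_ai,
    fertility_pct = if (n_eggs) as_pct(fert_num, n_eggs) else NA_real_,
    hatchability_pct = if (n_eggs) as_pct(hatch_num, n_eggs) else NA_real_,
    first_fertile_day = if (length(fdays)) min(fdays) else NA_integer_,
    last_fertile_day = if (length(fdays)) max(fdays) else NA_integer_,
    fertility_duration_days = if (length(fdays)) max(fdays) - min(fdays)
                              else NA_integer_,
    stringsAsFactors = FALSE)
}

#' Summarise every female in an event log
#'
#' @param events Event data frame covering one or more females.
#' @param inseminations Named vector or data frame (`female_id`, `day`)
#'   of insemination days; females absent from it get day 0.
#' @inheritParams summarize_female
#' @return Data frame with one [summarize_female()] row per female, ordered
#'   by female id.
#' @export
summarize_females <- function(events, inseminations = NULL,
                              include_parthenotes = FALSE) {
  ev <- egg_events(events)
  ins <- integer()
  if (is.data.frame(inseminations)) {
    ins <- stats::setNames(as.integer(inseminations$day),
                           as.character(inseminations$female_id))
  } else if (!is.null(inseminations)) {
    ins <- stats::setNames(as.integer(inseminations), names(inseminations))
  }
  ids <- sort(unique(ev$female_id))
  do.call(rbind, lapply(ids, function(f)
    summarize_female(ev[ev$female_id == f, , drop = FALSE],
                     insemination_day = if (f %in% names(ins)) ins[[f]] else 0L,
                     include_parthenotes = include_parthenotes)))
}

#' Cohort totals over female summaries
#'
#' Pooled fertility within each group label is computed from summed counts,
#' not by averaging the per-female percentages.
#'
#' @param summaries Data frame from [summarize_females()].
#' @param group_labels Named character vector mapping every `female_id` to a
#'   group label.
#' @return Data frame per label: `group`, `n_females`, `n_eggs`,
#'   `n_fertile_ai`, `n_hatched_ai`, `pooled_fertility_pct`.
#' @export
cohort_totals <- function(summaries, group_labels) {
  missing <- setdiff(summaries$female_id, names(group_labels))
  if (length(missing))
    stop("group_labels does not cover female(s): ",
         paste(missing, collapse = ", "))
  lab <- group_labels[summaries$female_id]
  out <- do.call(rbind, lapply(sort(unique(lab)), function(g) {
    s <- summaries[lab == g, , drop = FALSE]
    data.frame(group = g,
               n_females = nrow(s),
               n_eggs = sum(s$n_eggs),
               n_fertile_ai = sum(s$n_fertile_ai),
               n_hatched_ai = sum(s$n_hatched_ai),
               pooled_fertility_pct = if (sum(s$n_eggs))
                 as_pct(sum(s$n_fertile_ai), sum(s$n_eggs)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Parthenogenesis incidence rates
#'
#' Frequency of parthenogenesis as the ratio of confirmed parthenotes
#' (optionally including consistent-but-unconfirmed ones) to the total
#' number of non-wind eggs; the maximum rate additionally assumes every
#' ungenotyped developed egg was a parthenote; a third rate uses the total
#' number of fertile (developed) eggs as denominator.
#'
#' @param confirmed Count of confirmed parthenotes.
#' @param unconfirmed Count of consistent-but-unconfirmed parthenotes.
#' @param ungenotyped Developed eggs that could not be genotyped.
#' @param total_eggs Total non-wind eggs laid.
#' @param total_fertile Total developed (fertile) eggs.
#' @param include_unconfirmed Count unconfirmed parthenotes in the observed
#'   numerator (default TRUE, the conservative-inclusion convention).
#' @return List: `observed_pct`, `max_pct`, `pct_of_fertile` (one-decimal,
#'   half away from zero).
#' @export
incidence <- function(confirmed, unconfirmed = 0L, ungenotyped = 0L,
                      total_eggs, total_fertile = NA_integer_,
                      include_unconfirmed = TRUE) {
  counts <- c(confirmed, unconfirmed, ungenotyped, total_eggs)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (total_eggs == 0) stop("incidence undefined: zero total eggs")
  numer <- confirmed + if (include_unconfirmed) unconfirmed else 0L
  if (!is.na(total_fertile) &&
      (numer > total_fertile || total_fertile > total_eggs))
    stop("expected parthenotes <= total_fertile <= total_eggs")
  list(observed_pct = as_pct(numer, total_eggs),
       max_pct = as_pct(numer + ungenotyped, total_eggs),
       pct_of_fertile = if (is.na(total_fertile)) NA_real_
                        else as_pct(numer, total_fertile))
}

#' Sperm morphometrics summary
#'
#' Mean and standard error per component over all measured cells, plus the
#' per-cell total (head + midpiece + flagellum, the acrosome being part of
#' the head). By linearity the mean total equals the sum of the component
#' means on any input.
#'
#' @param measurements Data frame with numeric columns `head`, `midpiece`,
#'   `flagellum`, and optionally `acrosome` (lengths in micrometres), one row
#'   per cell; at least two rows.
#' @return Data frame `component`, `mean_um`, `se_um`, `n` with rows total,
#'   head, midpiece, flagellum (and acrosome when present).
#' @export
morphometrics_summary <- function(measurements) {
  need <- c("head", "midpiece", "flagellum")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("missing component column(s): ",
                         paste(miss, collapse = ", "))
  comps <- c(need, intersect("acrosome", names(measurements)))
  for (cc in comps)
    if (any(is.na(measurements[[cc]])))
      stop("missing ", cc, " measurement in some record")
  n <- nrow(measurements)
  if (n < 2L) stop("need at least two cells")
  tot <- measurements$head + measurements$midpiece + measurements$flagellum
  cols <- c(list(total = tot),
            stats::setNames(lapply(comps, function(cc) measurements[[cc]]),
                            comps))
  do.call(rbind, lapply(names(cols), function(nm) {
    v <- cols[[nm]]
    data.frame(component = nm, mean_um = mean(v),
               se_um = stats::sd(v) / sqrt(n), n = n)
  }))
}
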