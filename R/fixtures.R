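# Golden reference data shipped with the package:
# * habitat_genotypes(): 9-locus genotypes of 12 parthenote embryos/hatchlings
#   (ids P1..P12) collected from a 48-female, male-free habitat, plus the two
#   AI-trial dams (854, 307) and their three parthenote offspring
#   (AI-P1..AI-P3).
# * habitat_reconstructed_dams(): the four published maternal reconstructions
#   those parthenotes imply (wildcard slots printed "-").
# * ai_trial_counts() / ai_trial_events(): per-female outcome counts for the
#   20 artificial-insemination trials, and a deterministic expansion of those
#   counts into an egg-by-egg event log.
# * sperm_morphometrics(): a synthetic per-cell morphometry table whose
#   component means equal the published means (the per-cell values are
#   constructed, not measured).

ptx_extdata <- function(file) {
  p <- system.file("extdata", file, package = "parthenotrace")
  if (!nzchar(p)) stop("fixture not found: ", file)
  p
}

#' Golden genotype fixture: habitat parthenotes and AI-trial families
#'
#' @return Named list of [mlg()] objects (12 habitat parthenotes P1..P12 as
#'   offspring, dams 854 and 307, AI parthenotes AI-P1..AI-P3).
#' @export
habitat_genotypes <- function() {
  read_genotype_table(ptx_extdata("habitat_parthenote_genotypes.csv"))
}

#' Published maternal reconstructions for the habitat parthenotes
#'
#' The four reconstructed dams ("Female 1".."Female 4") with their member
#' parthenotes; wildcard (undetermined) slots are missing calls. P8, the
#' consistent-but-unconfirmed parthenote, is not a member of any published
#' reconstruction.
#'
#' @return Named list of [mlg()] objects with a `members` attribute (named
#'   list of member-id character vectors).
#' @export
habitat_reconstructed_dams <- function() {
  path <- ptx_extdata("habitat_reconstructed_dams.csv")
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  members <- strsplit(df$members, ";", fixed = TRUE)
  names(members) <- df$individual_id
  df$members <- NULL
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  out <- read_genotype_table(tmp)
  attr(out, "members") <- members
  out
}

#' AI-trial outcome counts (20 females)
#'
#' One row per inseminated female: egg cases laid (`n_laid`, wind cases
#' included), non-wind eggs (`n_eggs`), AI-fertile eggs, parthenotes, AI
#' hatchlings, first/last AI-fertile lay day (days post-insemination),
#' parthenote lay days, semen group (`fresh`, `cold24`, `cold48`), and the
#' published percentages/duration for cross-checking. `n_laid` and the
#' percentage-implied denominator `n_eggs` disagree for some females (e.g.
#' 793: 27 laid vs 23 implied); both are recorded.
#'
#' @return Data frame, one row per female.
#' @export
ai_trial_counts <- function() {
  df <- utils::read.csv(ptx_extdata("ai_trial_females.csv"),
                        colClasses = c(female_id = "character",
                                       parthenote_days = "character"))
  df
}

#' Expand AI-trial counts into an oviposition event log
#'
#' Deterministic (no randomness): AI-fertile lay days are spread evenly
#' between the recorded first and last fertile day, hatched eggs first;
#' parthenote eggs use their recorded lay days (fate hatched); infertile and
#' wind cases fill days 1 onward. Day 0 is the insemination day for every
#' female.
#'
#' @param counts Data frame from [ai_trial_counts()].
#' @return Event data frame ([egg_events()]) covering all females.
#' @export
ai_trial_events <- function(counts = ai_trial_counts()) {
  one <- function(r) {
    rows <- list()
    nf <- r$n_fertile_ai
    if (nf > 0) {
      fdays <- if (nf == 1L) r$first_fertile_day
               else round(seq(r$first_fertile_day, r$last_fertile_day,
                              length.out = nf))
      fdays[1] <- r$first_fertile_day
      fdays[nf] <- r$last_fertile_day
      fate <- c(rep("hatched", r$n_hatched_ai),
                rep("embryo_death", nf - r$n_hatched_ai))
      rows$fert <- data.frame(female_id = r$female_id, day = as.integer(fdays),
                              pair_id = NA_character_, fate = fate,
                              offspring_id = paste0(r$female_id, "-ai",
                                                    seq_len(nf)),
                              parthenote = FALSE)
    }
    if (r$n_parthenote > 0) {
      pdays <- as.integer(strsplit(r$parthenote_days, ";", fixed = TRUE)[[1]])
      if (length(pdays) != r$n_parthenote)
        stop("parthenote day list does not match count for ", r$female_id)
      rows$parth <- data.frame(female_id = r$female_id, day = pdays,
                               pair_id = NA_character_, fate = "hatched",
                               offspring_id = paste0(r$female_id, "-p",
                                                     seq_along(pdays)),
                               parthenote = TRUE)
    }
    n_inf <- r$n_eggs - r$n_fertile_ai - r$n_parthenote
    if (n_inf > 0)
      rows$inf <- data.frame(female_id = r$female_id, day = seq_len(n_inf),
                             pair_id = NA_character_, fate = "infertile",
                             offspring_id = NA_character_, parthenote = NA)
    n_wind <- r$n_laid - r$n_eggs
    if (n_wind > 0)
      rows$wind <- data.frame(female_id = r$female_id, day = seq_len(n_wind),
                              pair_id = NA_character_, fate = "wind",
                              offspring_id = NA_character_, parthenote = NA)
    do.call(rbind, rows)
  }
  ev <- do.call(rbind, lapply(seq_len(nrow(counts)),
                              function(i) one(counts[i, ])))
  rownames(ev) <- NULL
  egg_events(ev)
}

#' Semen-group labels for the AI-trial females
#'
#' @param counts Data frame from [ai_trial_counts()].
#' @return Named character vector female_id -> group (`fresh`, `cold24`,
#'   `cold48`).
#' @export
ai_trial_groups <- function(counts = ai_trial_counts()) {
  stats::setNames(counts$semen_group, counts$female_id)
}

#' Synthetic per-cell sperm morphometrics
#'
#' A constructed table of `n_sharks * n_per_shark` cells whose component
#' means equal the published population means (head 57.7, midpiece 19.9,
#' flagellum 100.7, acrosome 3.0 micrometres): each component carries a
#' deterministic zero-sum deviation pattern, so the data are synthetic
#' stand-ins for the unpublished per-cell measurements, exact in the mean
#' but not in higher moments.
#'
#' @param n_sharks,n_per_shark Numbers of sharks and cells per shark
#'   (defaults 5 and 10, the published design).
#' @return Data frame `shark`, `head`, `midpiece`, `flagellum`, `acrosome`.
#' @export
sperm_morphometrics <- function(n_sharks = 5L, n_per_shark = 10L) {
  n <- n_sharks * n_per_shark
  if (n %% 2L != 0L) stop("need an even total number of cells")
  half <- rep(c(-1, 1), n / 2)           # sums to exactly zero
  alt <- rep(c(-1, -1, 1, 1), length.out = n)
  if (sum(alt) != 0) alt <- half
  data.frame(shark = rep(paste0("shark_", seq_len(n_sharks)),
                         each = n_per_shark),
             head = 57.7 + 1.4 * half,
             midpiece = 19.9 + 1.1 * alt,
             flagellum = 100.7 + 4.2 * half,
             acrosome = 3.0 + 0.5 * alt)
}

#' Habitat egg-monitoring counts
#'
#' Census counts from the 48-female, male-free habitat whose parthenotes are
#' in [habitat_genotypes()]: non-wind eggs collected over the 105-day
#' monitoring window, developed (fertile) eggs, and developed eggs that
#' could not be genotyped. Inputs to [incidence()].
#'
#' @return List: `n_females`, `monitoring_days`, `total_eggs`,
#'   `total_fertile`, `ungenotyped`.
#' @export
habitat_egg_counts <- function() {
  list(n_females = 48L, monitoring_days = 105L, total_eggs = 1053L,
       total_fertile = 28L, ungenotyped = 14L)
}
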