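# Seeded generators for every input the pipeline consumes: Hardy-Weinberg
# multilocus genotypes, Mendelian sexual offspring, terminal-fusion
# automictic parthenotes, genotyping noise (failed loci, allelic dropout),
# and oviposition event logs with sperm-storage fertility decay.
#
# Automixis is modelled as terminal fusion only: the egg fuses with its
# meiotic sister product, so every locus ends homozygous for one maternal
# allele. Central fusion (which retains heterozygosity and would defeat a
# homozygosity-based classifier) is deliberately not modelled.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Define a locus allele-frequency model
#'
#' @param name Locus name.
#' @param lengths Distinct integer allele fragment lengths.
#' @param frequencies Allele frequencies, same length as `lengths`,
#'   non-negative, summing to 1 (default equifrequent).
#' @return An object of class `"locus_model"`.
#' @export
locus_model <- function(name, lengths,
                        frequencies = rep(1 / length(lengths),
                                          length(lengths))) {
  lengths <- vapply(lengths, as_allele, 0L)
  if (anyDuplicated(lengths)) stop("allele lengths must be distinct")
  if (length(frequencies) != length(lengths))
    stop("frequencies and lengths differ in length")
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-9)
    stop("frequencies must be non-negative and sum to 1")
  structure(list(name = name, lengths = lengths, frequencies = frequencies),
            class = "locus_model")
}

#' Default nine-locus synthetic panel
#'
#' Nine microsatellite loci with the marker names used for this species
#' (Cp1, Cpl80, ..., Cpl1141) and six equifrequent synthetic alleles each.
#' Allele frequencies are synthetic stand-ins (no published estimates
#' exist): with six equifrequent alleles the per-locus chance that a sexual
#' offspring is homozygous-maternal is 1/6, so a nine-locus false-positive
#' parthenote call has probability (1/6)^9 < 1e-6.
#'
#' @param n_loci Number of loci (default 9).
#' @param n_alleles Alleles per locus (default 6).
#' @return List of [locus_model()] objects.
#' @export
default_locus_models <- function(n_loci = 9L, n_alleles = 6L) {
  base_names <- c("Cp1", "Cpl80", "Cpl150", "Cpl471", "Cpl930",
                  "Cpl1163", "Cpl962", "Cpl1161", "Cpl1141")
  nm <- if (n_loci <= length(base_names)) base_names[seq_len(n_loci)]
        else c(base_names, paste0("L", seq_len(n_loci - length(base_names))))
  lapply(seq_len(n_loci), function(i)
    locus_model(nm[i], seq(150L + 10L * i, by = 4L, length.out = n_alleles)))
}

draw_mlg <- function(id, role, loci) {
  g <- lapply(loci, function(lm) {
    # sample over indices: sample(x, ...) misfires when x has length 1
    idx <- sample.int(length(lm$lengths), 2L, replace = TRUE,
                      prob = lm$frequencies)
    sort_geno(lm$lengths[idx])
  })
  names(g) <- vapply(loci, `[[`, "", "name")
  mlg(id, g, role = role)
}

#' Simulate a Hardy-Weinberg population
#'
#' Every individual draws two alleles per locus independently from the locus
#' frequencies. Reproducible: the same seed yields the same genotypes.
#'
#' @param n_dams,n_sires Numbers of dams and sires (ids `dam_1`, ...,
#'   `sire_1`, ...).
#' @param loci List of [locus_model()] objects (non-empty).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Named list of [mlg()] objects with the panel as attribute.
#' @export
simulate_population <- function(n_dams, n_sires,
                                loci = default_locus_models(), seed = NULL) {
  if (length(loci) == 0L) stop("empty locus list")
  stopifnot(n_dams >= 0L, n_sires >= 0L)
  with_seed(seed, {
    dams <- lapply(seq_len(n_dams), function(i)
      draw_mlg(paste0("dam_", i), "dam", loci))
    sires <- lapply(seq_len(n_sires), function(i)
      draw_mlg(paste0("sire_", i), "sire", loci))
    out <- c(dams, sires)
    names(out) <- vapply(out, `[[`, "", "id")
    structure(out, panel = vapply(loci, `[[`, "", "name"))
  })
}

#' Simulate a Mendelian sexual offspring
#'
#' At each locus the offspring receives one allele drawn uniformly from the
#' dam's pair and one from the sire's pair.
#'
#' @param dam,sire Parental [mlg()] objects with full genotypes, sharing a
#'   panel.
#' @param id Offspring id.
#' @param seed Integer seed or `NULL`.
#' @return Offspring [mlg()] with role `"offspring"`.
#' @export
simulate_offspring <- function(dam, sire, id = "offspring", seed = NULL) {
  panel <- check_shared_panel(list(dam, sire))
  with_seed(seed, {
    g <- lapply(panel, function(lc) {
      dg <- dam$loci[[lc]]; sg <- sire$loci[[lc]]
      if (anyNA(dg) || anyNA(sg))
        stop("parents must have full genotypes at every locus (", lc, ")")
      sort_geno(c(dg[sample.int(2L, 1L)], sg[sample.int(2L, 1L)]))
    })
    names(g) <- panel
    mlg(id, g, role = "offspring")
  })
}

#' Simulate a terminal-fusion automictic parthenote
#'
#' At each locus one maternal allele is chosen uniformly and duplicated, so
#' the offspring is homozygous everywhere.
#'
#' @param dam Maternal [mlg()] with a full genotype.
#' @param id Offspring id.
#' @param seed Integer seed or `NULL`.
#' @return Parthenote [mlg()] with role `"offspring"`.
#' @export
simulate_parthenote <- function(dam, id = "parthenote", seed = NULL) {
  with_seed(seed, {
    g <- lapply(dam$loci, function(dg) {
      if (anyNA(dg)) stop("dam must have a full genotype at every locus")
      a <- dg[sample.int(2L, 1L)]
      c(a, a)
    })
    mlg(id, g, role = "offspring")
  })
}

#' Apply genotyping noise to a multilocus genotype
#'
#' Each locus independently fails entirely with `locus_failure_rate`;
#' otherwise each allele call independently drops out (becomes the missing
#' slot of a half-missing genotype) with `allele_dropout_rate`.
#'
#' @param g An [mlg()] object.
#' @param locus_failure_rate,allele_dropout_rate Probabilities in \[0, 1\].
#' @param seed Integer seed or `NULL`.
#' @return The noised [mlg()].
#' @export
apply_genotyping_noise <- function(g, locus_failure_rate = 0,
                                   allele_dropout_rate = 0, seed = NULL) {
  stopifnot(locus_failure_rate >= 0, locus_failure_rate <= 1,
            allele_dropout_rate >= 0, allele_dropout_rate <= 1)
  with_seed(seed, {
    g$loci <- lapply(g$loci, function(lg) {
      if (stats::runif(1) < locus_failure_rate) return(geno())
      drop <- stats::runif(2) < allele_dropout_rate
      lg[drop] <- NA_integer_
      sort_geno(lg)
    })
    g
  })
}

#' Define an oviposition model
#'
#' Egg pairs are laid every `pair_interval_days` (default 6--7 days, the
#' natural cadence for this species) through a laying season. After an
#' insemination, per-egg fertilisation probability decays geometrically with
#' sperm-storage time: `initial_fertility * fertilization_decay^days`.
#'
#' @param pair_interval_days Integer range (length 2) of days between pairs.
#' @param season_length_days Length of the laying season.
#' @param wind_rate Probability an egg case is a yolkless wind case.
#' @param initial_fertility Fertilisation probability at insemination day.
#' @param fertilization_decay Per-day multiplicative survival of the
#'   fertilisation probability.
#' @param parthenote_rate Probability a non-wind egg develops
#'   parthenogenetically.
#' @param hatch_given_fertile Hatch probability for a developed egg.
#' @return An object of class `"oviposition_model"`.
#' @export
oviposition_model <- function(pair_interval_days = c(6L, 7L),
                              season_length_days = 105L,
                              wind_rate = 0.1,
                              initial_fertility = 0.6,
                              fertilization_decay = 0.99,
                              parthenote_rate = 0.011,
                              hatch_given_fertile = 0.85) {
  stopifnot(length(pair_interval_days) == 2L,
            all(pair_interval_days >= 1L),
            pair_interval_days[1] <= pair_interval_days[2],
            season_length_days >= 1L)
  probs <- c(wind_rate, initial_fertility, fertilization_decay,
             parthenote_rate, hatch_given_fertile)
  if (any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  structure(list(pair_interval_days = as.integer(pair_interval_days),
                 season_length_days = as.integer(season_length_days),
                 wind_rate = wind_rate,
                 initial_fertility = initial_fertility,
                 fertilization_decay = fertilization_decay,
                 parthenote_rate = parthenote_rate,
                 hatch_given_fertile = hatch_given_fertile),
            class = "oviposition_model")
}

#' Simulate one female's oviposition event log
#'
#' Egg pairs are laid at random intervals until the season ends. Each
#' non-wind egg is independently a parthenote with `parthenote_rate`; an
#' egg that is not a parthenote is fertilised with probability
#' `initial_fertility * fertilization_decay^(day - insemination_day)` when an
#' insemination day is given (0 otherwise, e.g. a female housed without
#' males); developed eggs hatch with `hatch_given_fertile`.
#'
#' @param female_id Female identifier.
#' @param model An [oviposition_model()].
#' @param insemination_day Day of artificial insemination (day 0 = season
#'   start), or `NA` for an uninseminated female.
#' @param seed Integer seed or `NULL`.
#' @return Event data frame ([egg_events()]), parthenote and AI-fertile eggs
#'   carrying generated `offspring_id`s.
#' @export
simulate_oviposition <- function(female_id, model = oviposition_model(),
                                 insemination_day = NA, seed = NULL) {
  stopifnot(inherits(model, "oviposition_model"))
  with_seed(seed, {
    days <- integer()
    gap <- function() {
      lo <- model$pair_interval_days[1]
      hi <- model$pair_interval_days[2]
      lo + sample.int(hi - lo + 1L, 1L) - 1L  # sample(seq(lo,hi),1) misfires when lo==hi
    }
    d <- gap()
    while (d <= model$season_length_days) {
      days <- c(days, d)
      d <- d + gap()
    }
    rows <- list()
    k <- 0L
    for (p in seq_along(days)) {
      for (side in 1:2) {
        k <- k + 1L
        day <- days[p]
        if (stats::runif(1) < model$wind_rate) {
          rows[[k]] <- data.frame(female_id = female_id, day = day,
                                  pair_id = paste0(female_id, "-p", p),
                                  fate = "wind", offspring_id = NA_character_,
                                  parthenote = NA)
          next
        }
        if (stats::runif(1) < model$parthenote_rate) {
          fate <- if (stats::runif(1) < model$hatch_given_fertile) "hatched"
                  else "embryo_death"
          rows[[k]] <- data.frame(female_id = female_id, day = day,
                                  pair_id = paste0(female_id, "-p", p),
                                  fate = fate,
                                  offspring_id = paste0(female_id, "-e", k),
                                  parthenote = TRUE)
          next
        }
        pfert <- if (is.na(insemination_day) || day < insemination_day) 0
                 else model$initial_fertility *
                      model$fertilization_decay^(day - insemination_day)
        if (stats::runif(1) < pfert) {
          fate <- if (stats::runif(1) < model$hatch_given_fertile) "hatched"
                  else "embryo_death"
          rows[[k]] <- data.frame(female_id = female_id, day = day,
                                  pair_id = paste0(female_id, "-p", p),
                                  fate = fate,
                                  offspring_id = paste0(female_id, "-e", k),
                                  parthenote = FALSE)
        } else {
          rows[[k]] <- data.frame(female_id = female_id, day = day,
                                  pair_id = paste0(female_id, "-p", p),
                                  fate = "infertile",
                                  offspring_id = NA_character_,
                                  parthenote = NA)
        }
      }
    }
    if (k == 0L)
      return(egg_events(data.frame(female_id = character(), day = integer(),
                                   pair_id = character(), fate = character(),
                                   offspring_id = character(),
                                   parthenote = logical())))
    egg_events(do.call(rbind, rows))
  })
}
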