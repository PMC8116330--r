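# Offspring classification against a putative dam (and optional sire).
#
# The decision rule is shaped by terminal-fusion automixis: a parthenote is
# homozygous for a maternal allele at every locus. A dam genotype with fewer
# than two known alleles carries a wildcard slot that matches any allele
# (needed when the dam itself was reconstructed from offspring).

VERDICTS <- c("PARTHENOTE", "SEXUAL", "CONSISTENT_UNCONFIRMED", "MISMATCH")

#' Per-locus parthenote evidence
#'
#' Compares an offspring's genotype at one locus with the putative dam's.
#'
#' @param off,dam Single-locus genotypes ([geno()]).
#' @return One of `"hom_maternal"` (offspring homozygous for an allele found
#'   in, or compatible with a wildcard slot of, the dam), `"non_maternal_allele"`
#'   (offspring carries an allele the dam demonstrably lacks),
#'   `"missing"` (offspring locus failed), or `"het"` otherwise.
#' @export
locus_parthenote_consistent <- function(off, dam) {
  off_known <- geno_alleles(off)
  if (length(off_known) == 0L) return("missing")
  dam_known <- geno_alleles(dam)
  wildcard <- length(dam_known) < 2L
  if (length(off_known) == 2L && off_known[1] == off_known[2] &&
      (wildcard || off_known[1] %in% dam_known))
    return("hom_maternal")
  if (!wildcard && any(!off_known %in% dam_known))
    return("non_maternal_allele")
  "het"
}

# Can (maternal, paternal) be assigned so that maternal comes from `dam` and
# paternal from `sire`? NULL sire = unknown father, matches anything. A
# missing offspring slot and a parental wildcard slot also match anything.
locus_explained <- function(off, dam, sire = NULL) {
  fits <- function(a, parent) {
    if (is.na(a)) return(TRUE)
    known <- geno_alleles(parent)
    length(known) < 2L || a %in% known
  }
  sire_fits <- function(a) is.null(sire) || fits(a, sire)
  (fits(off[1], dam) && sire_fits(off[2])) ||
    (fits(off[2], dam) && sire_fits(off[1]))
}

# Maternal side alone: can one offspring allele have come from the dam?
locus_dam_ok <- function(off, dam) locus_explained(off, dam, sire = NULL)

#' Classify an offspring against its putative dam (and optionally a sire)
#'
#' Verdicts:
#' * `PARTHENOTE`: every scored locus is homozygous for a maternal allele and
#'   at most `max_missing` loci failed.
#' * `CONSISTENT_UNCONFIRMED`: same evidence on the scored loci, but more than
#'   `max_missing` loci failed, so confirmation is withheld.
#' * `SEXUAL`: at least one scored locus is incompatible with parthenogenesis
#'   (heterozygous or carrying a non-maternal allele), and the genotype is
#'   explainable by the dam plus the tested sire (or an unknown father) with
#'   at most `tolerance` exception loci.
#' * `MISMATCH`: more than `tolerance` loci carry alleles explainable by
#'   neither parent.
#'
#' @param off,dam [mlg()] objects sharing a panel.
#' @param sire Optional [mlg()] candidate father; when supplied, loci whose
#'   non-maternal alleles cannot be drawn from the sire's known alleles are
#'   tagged `paternal_exclusion` and counted in `n_exclusions`.
#' @param tolerance Number of mismatching loci tolerated before declaring
#'   `MISMATCH` (default 0: no genotyping-error allowance).
#' @param max_missing Maximum number of failed offspring loci compatible with
#'   a confirmed `PARTHENOTE` verdict (default 1: a single routine dropout
#'   does not withhold confirmation, several failed loci do).
#' @return An object of class `"offspring_call"`: list with `offspring_id`,
#'   `verdict`, `per_locus` (named evidence tags), `n_scored`,
#'   `n_exclusions` (NA when no sire is tested), and `n_unexplained`.
#' @export
classify_offspring <- function(off, dam, sire = NULL, tolerance = 0L,
                               max_missing = 1L) {
  panel <- check_shared_panel(c(list(off, dam), if (!is.null(sire)) list(sire)))
  tags <- vapply(panel, function(lc)
    locus_parthenote_consistent(off$loci[[lc]], dam$loci[[lc]]), "")
  scored <- tags != "missing"
  n_scored <- sum(scored)
  n_missing <- length(panel) - n_scored

  all_hom <- n_scored > 0L && all(tags[scored] == "hom_maternal")
  explained <- vapply(panel, function(lc)
    locus_explained(off$loci[[lc]], dam$loci[[lc]],
                    if (is.null(sire)) NULL else sire$loci[[lc]]), NA)
  n_unexplained <- sum(!explained)

  n_exclusions <- NA_integer_
  if (!is.null(sire)) {
    # refine non-parthenote loci with paternal evidence
    for (lc in panel[tags %in% c("het", "non_maternal_allele")]) {
      o <- off$loci[[lc]]
      if (!locus_dam_ok(o, dam$loci[[lc]])) next  # dam-side failure, not sire's
      if (locus_explained(o, dam$loci[[lc]], sire$loci[[lc]])) {
        if (tags[lc] == "non_maternal_allele") tags[lc] <- "paternal_match"
      } else {
        tags[lc] <- "paternal_exclusion"
      }
    }
    n_exclusions <- sum(tags == "paternal_exclusion")
  }

  verdict <- if (all_hom || n_scored == 0L) {
    if (n_missing <= max_missing && n_scored > 0L) "PARTHENOTE"
    else "CONSISTENT_UNCONFIRMED"
  } else if (n_unexplained > tolerance) {
    "MISMATCH"
  } else {
    "SEXUAL"
  }

  structure(list(offspring_id = off$id, verdict = verdict, per_locus = tags,
                 n_scored = n_scored, n_exclusions = n_exclusions,
                 n_unexplained = n_unexplained),
            class = "offspring_call")
}

#' @export
print.offspring_call <- function(x, ...) {
  cat(sprintf("<offspring_call> %s: %s (scored %d, unexplained %d%s)\n",
              x$offspring_id, x$verdict, x$n_scored, x$n_unexplained,
              if (is.na(x$n_exclusions)) ""
              else sprintf(", sire exclusions %d", x$n_exclusions)))
  invisible(x)
}

#' Classify a batch of offspring against one dam
#'
#' @param offspring Named list of [mlg()] objects.
#' @inheritParams classify_offspring
#' @return Data frame with one row per offspring: `offspring_id`, `verdict`,
#'   `n_scored`, `n_exclusions`, `n_unexplained`, then one evidence-tag
#'   column per panel locus.
#' @export
classify_batch <- function(offspring, dam, sire = NULL, tolerance = 0L,
                           max_missing = 1L) {
  calls <- lapply(offspring, classify_offspring, dam = dam, sire = sire,
                  tolerance = tolerance, max_missing = max_missing)
  core <- data.frame(
    offspring_id = vapply(calls, `[[`, "", "offspring_id"),
    verdict = vapply(calls, `[[`, "", "verdict"),
    n_scored = vapply(calls, `[[`, 0L, "n_scored"),
    n_exclusions = vapply(calls, `[[`, NA_integer_, "n_exclusions"),
    n_unexplained = vapply(calls, `[[`, 0L, "n_unexplained"),
    row.names = NULL, check.names = FALSE)
  tagm <- t(vapply(calls, `[[`, character(length(mlg_panel(dam))), "per_locus"))
  cbind(core, as.data.frame(tagm, row.names = NULL))
}

#' Rank candidate sires by paternal exclusions
#'
#' For each candidate, counts loci at which the offspring's non-maternal
#' allele set cannot be drawn from the candidate's known alleles. Candidates
#' are ranked ascending by exclusion count, ties broken by sire id; a
#' candidate is accepted when its exclusion count is within `tolerance`.
#'
#' @param off,dam [mlg()] objects sharing a panel.
#' @param candidate_sires Non-empty named list of [mlg()] candidates.
#' @param tolerance Maximum exclusions for acceptance (default 0).
#' @return Data frame `sire_id`, `n_exclusions`, `accepted`, ranked.
#' @export
assign_paternity <- function(off, dam, candidate_sires, tolerance = 0L) {
  if (length(candidate_sires) == 0L) stop("empty candidate sire list")
  res <- do.call(rbind, lapply(candidate_sires, function(s) {
    call <- classify_offspring(off, dam, sire = s, tolerance = tolerance)
    data.frame(sire_id = s$id, n_exclusions = call$n_exclusions)
  }))
  res <- res[order(res$n_exclusions, res$sire_id), , drop = FALSE]
  res$accepted <- res$n_exclusions <= tolerance
  rownames(res) <- NULL
  res
}
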