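# End-to-end run: genotypes (+ optional event log) in, classification,
# maternal reconstruction, reproductive metrics and a machine-readable
# manifest out. All randomness flows through the single seed recorded in
# the manifest; re-running a config yields byte-identical reports.

#' Assemble a pipeline run configuration
#'
#' @param genotypes Path to a genotype table ([read_genotype_table()]).
#' @param out_dir Output directory (created if absent).
#' @param dam_map Optional path to (or data frame of) a two-column table
#'   `offspring_id,dam_id` naming the putative dam of each offspring;
#'   offspring without an entry are classified against an unknown dam
#'   (homozygosity-only rule).
#' @param events Optional path to an oviposition event log
#'   ([read_event_log()]).
#' @param inseminations Optional path to a table `female_id,day`.
#' @param groups Optional path to a table `female_id,group` for cohort
#'   totals.
#' @param counts Optional list for [incidence()]:
#'   `ungenotyped`, `total_eggs`, `total_fertile`.
#' @param tolerance,max_missing,include_unconfirmed See
#'   [classify_offspring()] and [incidence()].
#' @param seed Integer seed recorded in the manifest.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(genotypes, out_dir, dam_map = NULL, events = NULL,
                       inseminations = NULL, groups = NULL, counts = NULL,
                       tolerance = 0L, max_missing = 1L,
                       include_unconfirmed = TRUE, seed = 1L) {
  cfg <- list(genotypes = genotypes, out_dir = out_dir, dam_map = dam_map,
              events = events, inseminations = inseminations, groups = groups,
              counts = counts, tolerance = as.integer(tolerance),
              max_missing = as.integer(max_missing),
              include_unconfirmed = isTRUE(include_unconfirmed),
              seed = as.integer(seed))
  for (p in c("genotypes", "events", "inseminations", "groups")) {
    v <- cfg[[p]]
    if (!is.null(v) && is.character(v) && !file.exists(v))
      stop("config path does not exist: ", p, " = ", v)
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Relative paths in the file are resolved against the file's directory.
#'
#' @param path Path to a JSON file with [run_config()] fields.
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (p in c("genotypes", "events", "inseminations", "groups", "dam_map")) {
    if (!is.null(raw[[p]]) && !grepl("^/", raw[[p]]))
      raw[[p]] <- file.path(base, raw[[p]])
  }
  do.call(run_config, raw)
}

read_two_col <- function(x, cn) {
  if (is.null(x)) return(NULL)
  df <- if (is.data.frame(x)) x else {
    sep <- detect_delim(readLines(x, n = 1L))
    utils::read.table(x, sep = sep, header = TRUE, strip.white = TRUE,
                      colClasses = "character")
  }
  names(df)[1:2] <- cn
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full inference pipeline
#'
#' Stages, in order: read and validate genotypes; classify every offspring
#' against its putative dam (or by homozygosity alone when no dam is known);
#' reconstruct maternal genotypes and the minimum dam count from the
#' parthenote calls of offspring without a known dam; summarise the event
#' log per female and per cohort; compute incidence when census counts are
#' supplied. Writes `offspring_calls.tsv`, `matrilines.tsv`,
#' `reconstructed_dams.csv`, `female_summaries.tsv`, `cohort_totals.tsv`,
#' `incidence.json`, and `manifest.json` under `out_dir`.
#'
#' @param config A [run_config()] (or path to a JSON config file).
#' @return Invisibly, a list with all computed objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage ", sQuote(name), " failed: ",
           conditionMessage(e), call. = FALSE))
  }

  genos <- stage("genotypes", read_genotype_table(config$genotypes))
  panel <- attr(genos, "panel")
  roles <- vapply(genos, `[[`, "", "role")
  offspring <- genos[roles %in% c("offspring", "unknown")]
  dam_map <- stage("dam_map", read_two_col(config$dam_map,
                                           c("offspring_id", "dam_id")))

  unknown_dam <- mlg("<unknown>", stats::setNames(
    rep(list(geno()), length(panel)), panel), role = "dam")
  calls <- stage("classify", do.call(rbind, lapply(offspring, function(o) {
    dam_id <- if (!is.null(dam_map) && o$id %in% dam_map$offspring_id)
      dam_map$dam_id[match(o$id, dam_map$offspring_id)] else NA_character_
    dam <- if (is.na(dam_id)) unknown_dam else genos[[dam_id]]
    if (is.null(dam)) stop("dam ", dam_id, " absent from genotype table ",
                           "(offspring ", o$id, ")")
    cl <- classify_offspring(o, dam, tolerance = config$tolerance,
                             max_missing = config$max_missing)
    data.frame(offspring_id = cl$offspring_id, dam_id = dam_id,
               verdict = cl$verdict, n_scored = cl$n_scored,
               n_unexplained = cl$n_unexplained,
               t(cl$per_locus), check.names = FALSE)
  })))
  rownames(calls) <- NULL

  parth_verdicts <- c("PARTHENOTE",
                      if (config$include_unconfirmed) "CONSISTENT_UNCONFIRMED")
  orphan <- calls$offspring_id[is.na(calls$dam_id) &
                               calls$verdict %in% parth_verdicts]
  mm <- stage("matriline", min_mothers(genos[orphan]))
  recon_mlgs <- lapply(mm$reconstructions, reconstruction_to_mlg)
  names(recon_mlgs) <- vapply(mm$reconstructions, `[[`, "", "dam_label")
  mat_df <- data.frame(
    dam_label = names(recon_mlgs),
    members = vapply(mm$reconstructions, function(r)
      paste(r$members, collapse = ";"), ""))

  summaries <- NULL; totals <- NULL
  if (!is.null(config$events)) {
    ev <- stage("events", read_event_log(config$events))
    ins <- read_two_col(config$inseminations, c("female_id", "day"))
    summaries <- stage("summaries", summarize_females(ev, ins))
    grp <- read_two_col(config$groups, c("female_id", "group"))
    if (!is.null(grp))
      totals <- stage("cohort", cohort_totals(
        summaries, stats::setNames(grp$group, grp$female_id)))
  }

  inc <- NULL
  if (!is.null(config$counts)) {
    # census counts describe the monitored cohort: the offspring with no
    # mapped dam (AI-trial offspring with known dams are a different cohort)
    cohort <- is.na(calls$dam_id)
    cc <- config$counts
    inc <- stage("incidence", incidence(
      confirmed = sum(calls$verdict[cohort] == "PARTHENOTE"),
      unconfirmed = sum(calls$verdict[cohort] == "CONSISTENT_UNCONFIRMED"),
      ungenotyped = cc$ungenotyped %||% 0L,
      total_eggs = cc$total_eggs,
      total_fertile = cc$total_fertile %||% NA_integer_,
      include_unconfirmed = config$include_unconfirmed))
  }

  write_tsv(calls, file.path(config$out_dir, "offspring_calls.tsv"))
  write_tsv(mat_df, file.path(config$out_dir, "matrilines.tsv"))
  if (length(recon_mlgs))
    write_genotype_table(recon_mlgs,
                         file.path(config$out_dir, "reconstructed_dams.csv"),
                         role = FALSE)
  if (!is.null(summaries))
    write_tsv(summaries, file.path(config$out_dir, "female_summaries.tsv"))
  if (!is.null(totals))
    write_tsv(totals, file.path(config$out_dir, "cohort_totals.tsv"))
  if (!is.null(inc))
    jsonlite::write_json(inc, file.path(config$out_dir, "incidence.json"),
                         auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "parthenotrace",
    version = as.character(utils::packageVersion("parthenotrace")),
    seed = config$seed,
    n_dams_minimum = mm$n_dams,
    config = config[c("genotypes", "events", "tolerance", "max_missing",
                      "include_unconfirmed")])
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(calls = calls, min_mothers = mm, summaries = summaries,
                 totals = totals, incidence = inc, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
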