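# Single-locus genotypes are length-2 integer vectors of allele fragment
# lengths (base pairs), NA for a missing call, sorted ascending with NA last.
# A multilocus genotype ("mlg") wraps a named list of those over a panel.

MISSING_TOKENS <- c("-", "−", "–", ".", "")

#' Construct a single-locus genotype
#'
#' A genotype at one codominant microsatellite locus: an unordered pair of
#' allele calls, each an integer fragment length or `NA` for a failed call.
#' Alleles are stored sorted ascending with missing slots last, so two
#' genotypes with the same alleles compare equal regardless of input order.
#'
#' @param a1,a2 Allele calls: positive integers, or `NA` for a missing call.
#' @return An integer vector of length 2 (sorted, `NA` last).
#' @examples
#' geno(315, 289)   # same as geno(289, 315)
#' geno(194)        # half-missing call, "194/-"
#' geno()           # failed locus, "-/-"
#' @export
geno <- function(a1 = NA, a2 = NA) {
  sort_geno(c(as_allele(a1), as_allele(a2)))
}

as_allele <- function(x) {
  if (is.null(x) || length(x) != 1L) stop("allele must be a single value")
  if (is.na(x)) return(NA_integer_)
  xi <- suppressWarnings(as.integer(x))
  if (is.na(xi) || xi != as.numeric(x) || xi <= 0L)
    stop("allele must be a positive integer fragment length, got: ", x)
  xi
}

sort_geno <- function(al) {
  stopifnot(length(al) == 2L)
  as.integer(sort(al, na.last = TRUE))
}

#' State of a single-locus genotype
#'
#' @param g A genotype from [geno()].
#' @return `"full"` (both alleles called), `"half"` (one called), or
#'   `"missing"` (failed locus).
#' @export
geno_state <- function(g) {
  n <- sum(!is.na(g))
  c("missing", "half", "full")[n + 1L]
}

#' Known alleles of a single-locus genotype
#'
#' @param g A genotype from [geno()].
#' @return Integer vector of the called alleles (length 0, 1, or 2).
#' @export
geno_alleles <- function(g) g[!is.na(g)]

format_geno <- function(g) {
  tok <- ifelse(is.na(g), "-", as.character(g))
  paste(tok, collapse = "/")
}

parse_geno <- function(cell, where = "") {
  cell <- gsub("\\s+", "", cell)
  for (tk in c("−", "–", ".")) cell <- gsub(tk, "-", cell, fixed = TRUE)
  if (cell %in% c("", "-")) return(geno())
  parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, "-")
  if (length(parts) != 2L)
    stop("cannot parse genotype cell ", sQuote(cell), where)
  al <- lapply(parts, function(p) {
    if (p %in% c("", "-")) return(NA_integer_)
    if (!grepl("^[0-9]+$", p))
      stop("non-integer allele token ", sQuote(p), where)
    as_allele(p)
  })
  sort_geno(c(al[[1]], al[[2]]))
}

#' Construct a multilocus genotype
#'
#' @param id Individual identifier.
#' @param loci Named list of single-locus genotypes ([geno()]), one entry per
#'   panel locus; names define the panel order.
#' @param role One of `"dam"`, `"sire"`, `"offspring"`, `"unknown"`.
#' @return An object of class `"mlg"`.
#' @export
mlg <- function(id, loci, role = "unknown") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  role <- match.arg(role, c("dam", "sire", "offspring", "unknown"))
  if (!is.list(loci) || is.null(names(loci)) || any(!nzchar(names(loci))) ||
      anyDuplicated(names(loci)))
    stop("loci must be a named list with unique, non-empty names")
  loci <- lapply(loci, function(g) {
    if (length(g) != 2L) stop("each locus genotype must have two allele slots")
    sort_geno(as.integer(g))
  })
  structure(list(id = id, role = role, loci = loci), class = "mlg")
}

#' @export
print.mlg <- function(x, ...) {
  cat(sprintf("<mlg> %s (%s): %s\n", x$id, x$role,
              paste(sprintf("%s=%s", names(x$loci),
                            vapply(x$loci, format_geno, "")), collapse = " ")))
  invisible(x)
}

#' Panel (ordered locus names) of a multilocus genotype or collection
#'
#' @param x An `"mlg"` object or a list of them.
#' @return Character vector of locus names.
#' @export
mlg_panel <- function(x) {
  if (inherits(x, "mlg")) return(names(x$loci))
  if (length(x) == 0L) return(character())
  names(x[[1]]$loci)
}

check_shared_panel <- function(xs) {
  p <- mlg_panel(xs)
  for (x in xs)
    if (!identical(names(x$loci), p))
      stop("individuals do not share a common locus panel (", x$id, ")")
  p
}

detect_delim <- function(header_line) {
  if (grepl("\t", header_line)) "\t" else ","
}

#' Read a multilocus genotype table
#'
#' Reads a delimited text table (comma or tab, auto-detected) with a header
#' naming an identifier column, an optional `role` column, and one column per
#' locus. Cells use the syntax `"a1/a2"`; a dash (ASCII `-`, typographic
#' minus, or `.`) marks a missing allele call, so `"194/-"` is a half-missing
#' call and `"-/-"` a failed locus. Allele order within a cell is normalised
#' ascending on read.
#'
#' @param path Path to the table.
#' @param panel Optional character vector of expected locus names; loci in the
#'   header outside the panel raise a schema error, and column order is
#'   rearranged to the panel order.
#' @return A named list of [mlg()] objects (names are individual ids), with
#'   the panel as attribute `"panel"`.
#' @export
read_genotype_table <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file (missing header): ", path)
  sep <- detect_delim(first)
  df <- utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                          check.names = FALSE, strip.white = TRUE,
                          blank.lines.skip = TRUE, comment.char = "")
  if (ncol(df) < 2L) stop("genotype table needs an id column and >=1 locus")
  id_col <- names(df)[1]
  has_role <- ncol(df) >= 2L && tolower(names(df)[2]) == "role"
  locus_cols <- names(df)[-c(1L, if (has_role) 2L)]
  if (anyDuplicated(locus_cols)) stop("duplicate locus in header")
  if (!is.null(panel)) {
    unknown <- setdiff(locus_cols, panel)
    if (length(unknown))
      stop("unknown locus in header: ", paste(unknown, collapse = ", "))
    missing_loci <- setdiff(panel, locus_cols)
    if (length(missing_loci))
      stop("panel locus missing from header: ",
           paste(missing_loci, collapse = ", "))
    locus_cols <- panel
  }
  if (anyDuplicated(df[[id_col]]))
    stop("duplicate individual id: ",
         paste(unique(df[[id_col]][duplicated(df[[id_col]])]), collapse = ", "))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    id <- df[[id_col]][i]
    role <- if (has_role) df[["role"]][i] else "unknown"
    if (!role %in% c("dam", "sire", "offspring", "unknown")) role <- "unknown"
    loci <- lapply(locus_cols, function(lc)
      parse_geno(df[[lc]][i], where = sprintf(" (row %s, column %s)", id, lc)))
    names(loci) <- locus_cols
    out[[i]] <- mlg(id, loci, role = role)
  }
  names(out) <- df[[id_col]]
  structure(out, panel = locus_cols)
}

#' Write a multilocus genotype table
#'
#' Inverse of [read_genotype_table()]: one row per individual, cells
#' `"a1/a2"` with `-` for missing calls.
#'
#' @param individuals Named list of [mlg()] objects sharing one panel.
#' @param path Output path.
#' @param sep Field delimiter (default comma).
#' @param role Whether to include the `role` column.
#' @export
write_genotype_table <- function(individuals, path, sep = ",", role = TRUE) {
  p <- check_shared_panel(individuals)
  rows <- vapply(individuals, function(x) {
    cells <- vapply(x$loci, format_geno, "")
    paste(c(x$id, if (role) x$role, cells), collapse = sep)
  }, "")
  header <- paste(c("individual_id", if (role) "role", p), collapse = sep)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Export genotypes in Genepop format
#'
#' Writes a standard Genepop file (one population), coding each allele as a
#' stable 3-digit code assigned by ascending fragment length within each
#' locus; missing calls are coded `000`. The allele-to-code map is written
#' alongside as `<path>.alleles.tsv` so fragment lengths can be recovered.
#'
#' @param individuals Named list of [mlg()] objects sharing one panel.
#' @param path Output path for the Genepop file.
#' @param title Title line for the file.
#' @return Invisibly, the allele map as a data frame (locus, allele, code).
#' @export
write_genepop <- function(individuals, path,
                          title = "parthenotrace genepop export") {
  p <- if (length(individuals)) check_shared_panel(individuals) else
    attr(individuals, "panel")
  if (is.null(p)) stop("cannot determine panel for empty collection")
  maps <- lapply(p, function(lc) {
    al <- sort(unique(unlist(lapply(individuals, function(x)
      geno_alleles(x$loci[[lc]])))))
    if (length(al) > 999L)
      stop("more than 999 distinct alleles at locus ", lc,
           "; Genepop 3-digit coding cannot represent this")
    al
  })
  names(maps) <- p
  code1 <- function(lc, a) {
    if (is.na(a)) return("000")
    sprintf("%03d", match(a, maps[[lc]]))
  }
  body <- vapply(individuals, function(x) {
    codes <- vapply(p, function(lc) {
      g <- x$loci[[lc]]
      paste0(code1(lc, g[1]), code1(lc, g[2]))
    }, "")
    paste0(x$id, " ,  ", paste(codes, collapse = " "))
  }, "")
  writeLines(c(title, p, if (length(body)) c("Pop", body)), path)
  map_df <- do.call(rbind, lapply(p, function(lc) {
    al <- maps[[lc]]
    if (!length(al)) return(NULL)
    data.frame(locus = lc, allele = al,
               code = sprintf("%03d", seq_along(al)))
  }))
  if (is.null(map_df))
    map_df <- data.frame(locus = character(), allele = integer(),
                         code = character())
  utils::write.table(map_df, paste0(path, ".alleles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(map_df)
}

#' Read a panel definition file
#'
#' One locus name per line; blank lines and `#` comments ignored.
#'
#' @param path Path to the panel file.
#' @return Character vector of locus names.
#' @export
read_panel <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (anyDuplicated(ln)) stop("duplicate locus name in panel file")
  ln
}
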