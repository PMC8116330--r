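# Shared fixtures and independent oracles for the test suite.

# Build an mlg from compact cell strings, e.g. list(Cp1 = "289/315").
mk_mlg <- function(id, cells, role = "unknown") {
  loci <- lapply(cells, function(cell) {
    parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
    a <- ifelse(parts %in% c("-", ""), NA, suppressWarnings(as.integer(parts)))
    if (length(a) == 1L) a <- c(a, NA)
    parthenotrace::geno(a[1], a[2])
  })
  parthenotrace::mlg(id, loci, role = role)
}

# A tiny fixed two-locus panel used across unit tests.
toy_panel <- c("locA", "locB")
toy <- function(id, a, b, role = "unknown")
  mk_mlg(id, stats::setNames(list(a, b), toy_panel), role = role)

# ---- independent set-partition minimum (Bell enumeration) ----------------
# Operates on a plain allele matrix (rows = parthenotes, cols = loci, NA =
# failed locus; parthenotes are homozygous so one allele per locus suffices).
# Never calls package search code.

enum_rgs <- function(n) {
  out <- list()
  rec <- function(i, a, m) {
    if (i > n) {
      out[[length(out) + 1L]] <<- a
      return(invisible())
    }
    for (b in seq_len(m + 1L)) {
      a[i] <- b
      rec(i + 1L, a, max(m, b))
    }
  }
  rec(1L, integer(n), 0L)
  out
}

bf_min_partition <- function(allele_mat) {
  n <- nrow(allele_mat)
  if (n == 0L) return(0L)
  best <- n
  for (a in enum_rgs(n)) {
    k <- max(a)
    if (k >= best) next
    ok <- TRUE
    for (b in seq_len(k)) {
      rows <- allele_mat[a == b, , drop = FALSE]
      for (l in seq_len(ncol(rows))) {
        al <- rows[, l]
        if (length(unique(al[!is.na(al)])) > 2L) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) best <- k
  }
  best
}

# Random homozygous-parthenote instance on `n_loci` loci with `n_alleles`
# alleles; each locus fails with prob `miss`. Returns the allele matrix and
# the matching mlg list.
random_parthenote_instance <- function(n, n_loci = 4L, n_alleles = 4L,
                                       miss = 0.1) {
  alleles <- 100L + 2L * seq_len(n_alleles)
  mat <- matrix(sample(alleles, n * n_loci, replace = TRUE), nrow = n)
  mat[matrix(stats::runif(n * n_loci) < miss, nrow = n)] <- NA
  panel <- paste0("L", seq_len(n_loci))
  ms <- lapply(seq_len(n), function(i) {
    loci <- lapply(seq_len(n_loci), function(l) {
      a <- mat[i, l]
      parthenotrace::geno(a, a)
    })
    names(loci) <- panel
    parthenotrace::mlg(paste0("x", i), loci, role = "offspring")
  })
  names(ms) <- paste0("x", seq_len(n))
  list(mat = mat, mlgs = ms)
}

# ---- independent Genepop reader ------------------------------------------
# Minimal parser for the subset the writer emits; decodes via the emitted
# allele map. Independent of the package's writer internals.

read_genepop_oracle <- function(path) {
  lines <- readLines(path)
  pop_at <- which(tolower(trimws(lines)) == "pop")[1]
  loci <- trimws(lines[2:(if (is.na(pop_at)) length(lines) else pop_at - 1L)])
  map <- utils::read.table(paste0(path, ".alleles.tsv"), header = TRUE,
                           sep = "\t", colClasses = "character")
  decode <- function(locus, code) {
    if (code == "000") return(NA_integer_)
    hit <- map$allele[map$locus == locus & map$code == code]
    if (length(hit) != 1L) stop("unmapped code ", code, " at ", locus)
    as.integer(hit)
  }
  if (is.na(pop_at)) return(list())
  body <- lines[(pop_at + 1L):length(lines)]
  out <- lapply(body, function(ln) {
    parts <- strsplit(ln, ",")[[1]]
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    stopifnot(length(codes) == length(loci))
    geno <- lapply(seq_along(loci), function(i) {
      a1 <- decode(loci[i], substr(codes[i], 1, 3))
      a2 <- decode(loci[i], substr(codes[i], 4, 6))
      sort(c(a1, a2), na.last = TRUE)
    })
    names(geno) <- loci
    list(id = id, geno = geno)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

# Exact binomial 95% central interval for a count.
binom_ci_contains <- function(k, n, p) {
  k >= stats::qbinom(0.025, n, p) && k <= stats::qbinom(0.975, n, p)
}

# One habitat-style monitoring season: `n_females` uninseminated females,
# personal laying cycles drawn uniformly in `cycle_range` days, parthenote
# rate `p`. Returns non-wind egg count and the number of developed eggs that
# classify as parthenotes against their own dam.
simulate_habitat_run <- function(seed, n_females = 48L, p = 0.011,
                                 cycle_range = c(60L, 90L)) {
  pop <- parthenotrace::simulate_population(n_females, 0, seed = seed)
  n_eggs <- 0L
  n_parth_called <- 0L
  for (i in seq_len(n_females)) {
    cyc <- parthenotrace:::with_seed(seed * 1000L + i,
      sample(seq(cycle_range[1], cycle_range[2]), 1L))
    model <- parthenotrace::oviposition_model(
      season_length_days = cyc, initial_fertility = 0,
      parthenote_rate = p)
    ev <- parthenotrace::simulate_oviposition(
      paste0("dam_", i), model, insemination_day = NA,
      seed = seed * 2000L + i)
    n_eggs <- n_eggs + sum(ev$fate != "wind")
    n_dev <- sum(ev$parthenote %in% TRUE)
    if (n_dev > 0) {
      dam <- pop[[paste0("dam_", i)]]
      for (j in seq_len(n_dev)) {
        off <- parthenotrace::simulate_parthenote(dam,
                                                  seed = seed * 3000L + i * 40L + j)
        call <- parthenotrace::classify_offspring(off, dam)
        if (call$verdict == "PARTHENOTE") n_parth_called <- n_parth_called + 1L
      }
    }
  }
  list(n_eggs = n_eggs, n_parthenotes = n_parth_called)
}

# session-scoped tempfile (tempdir is cleaned up by R itself)
withr_local_tempfile <- function(ext = ".txt") tempfile(fileext = ext)
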