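# Maternal-genotype reconstruction from parthenote offspring.
#
# A terminal-fusion parthenote is homozygous for one maternal allele at each
# locus, so each offspring pins at most one allele per locus of its dam. A
# group of parthenotes can share a dam iff, locus by locus, the union of
# their known alleles has size <= 2 (a diploid dam has two allele slots).
# The minimum number of dams is the minimum number of blocks in a partition
# of the offspring into such compatible groups -- found by exact depth-first
# search over restricted-growth assignments with iterative deepening.

locus_unions <- function(group) {
  panel <- check_shared_panel(group)
  u <- lapply(panel, function(lc)
    sort(unique(unlist(lapply(group, function(x) geno_alleles(x$loci[[lc]]))))))
  names(u) <- panel
  u
}

#' Can a set of parthenotes share a single dam?
#'
#' @param parthenotes List of [mlg()] objects previously classified
#'   `PARTHENOTE` or `CONSISTENT_UNCONFIRMED`. Missing loci contribute no
#'   alleles.
#' @return `TRUE` iff at every locus the union of known alleles across the
#'   group has size at most 2.
#' @export
group_compatible <- function(parthenotes) {
  if (length(parthenotes) == 0L) return(TRUE)
  all(lengths(locus_unions(parthenotes)) <= 2L)
}

#' Reconstruct a maternal genotype from a compatible parthenote group
#'
#' The dam's allele set at each locus is the union of the group's known
#' alleles there; when fewer than two alleles are pinned the remaining slot
#' is a wildcard (printed `-`).
#'
#' @param group Non-empty list of [mlg()] objects with [group_compatible()]
#'   `TRUE`.
#' @param label Label for the inferred dam.
#' @return An object of class `"maternal_reconstruction"`: list with
#'   `dam_label`, `members` (sorted offspring ids), `alleles` (named list of
#'   integer vectors, length 0--2), and `wildcard` (named logical).
#' @export
reconstruct_dam <- function(group, label = "dam") {
  if (length(group) == 0L) stop("cannot reconstruct a dam from an empty group")
  u <- locus_unions(group)
  if (any(lengths(u) > 2L))
    stop("group is not compatible with a single dam (",
         paste(names(u)[lengths(u) > 2L], collapse = ", "), ")")
  structure(list(
    dam_label = label,
    members = sort(unname(vapply(group, `[[`, "", "id"))),
    alleles = u,
    wildcard = lengths(u) < 2L
  ), class = "maternal_reconstruction")
}

#' Convert a maternal reconstruction to a genotype object
#'
#' Wildcard slots become missing allele calls, so a dam pinned at one allele
#' prints as `"289/-"`.
#'
#' @param rec A [reconstruct_dam()] result.
#' @return An [mlg()] with role `"dam"`.
#' @export
reconstruction_to_mlg <- function(rec) {
  loci <- lapply(rec$alleles, function(a)
    sort_geno(c(a, rep(NA_integer_, 2L - length(a)))))
  mlg(rec$dam_label, loci, role = "dam")
}

#' @export
print.maternal_reconstruction <- function(x, ...) {
  g <- reconstruction_to_mlg(x)
  cat(sprintf("<maternal_reconstruction> %s [%s]\n  %s\n", x$dam_label,
              paste(x$members, collapse = ", "),
              paste(sprintf("%s=%s", names(g$loci),
                            vapply(g$loci, format_geno, "")), collapse = " ")))
  invisible(x)
}

# internal: block state = list(members = integer indices, unions = named list)
block_add <- function(block, idx, geno) {
  unions <- block$unions
  for (lc in names(unions)) {
    al <- geno_alleles(geno$loci[[lc]])
    if (length(al)) {
      u <- unique(c(unions[[lc]], al))
      if (length(u) > 2L) return(NULL)
      unions[[lc]] <- u
    }
  }
  list(members = c(block$members, idx), unions = unions)
}

empty_block <- function(panel) {
  u <- rep(list(integer()), length(panel))
  names(u) <- panel
  list(members = integer(), unions = u)
}

# DFS: place items (in id order) into existing blocks in creation order, or
# open a new block while fewer than `cap` exist. Returns the first complete
# assignment found (the lexicographically smallest restricted-growth
# assignment), or NULL when no partition into <= cap blocks exists.
partition_dfs <- function(items, cap, panel, incompat) {
  n <- length(items)
  recurse <- function(i, blocks) {
    if (i > n) return(blocks)
    for (b in seq_along(blocks)) {
      if (any(incompat[items[[i]]$.idx, blocks[[b]]$members]))
        next
      nb <- block_add(blocks[[b]], items[[i]]$.idx, items[[i]])
      if (is.null(nb)) next
      trial <- blocks
      trial[[b]] <- nb
      res <- recurse(i + 1L, trial)
      if (!is.null(res)) return(res)
    }
    if (length(blocks) < cap) {
      nb <- block_add(empty_block(panel), items[[i]]$.idx, items[[i]])
      res <- recurse(i + 1L, c(blocks, list(nb)))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  recurse(1L, list())
}

#' Minimum number of dams explaining a set of parthenotes
#'
#' Finds the minimum `k` over all partitions of the parthenotes into
#' dam-compatible groups, by exact iterative-deepening depth-first search
#' with pairwise-incompatibility pruning; the lower bound is seeded with a
#' greedily grown pairwise-incompatible subset. Among minimum partitions the
#' deterministic tie-break keeps earlier inputs grouped as early as possible
#' (smallest restricted-growth assignment in input order), so the result is
#' reproducible for a given input ordering. Inputs beyond
#' `exact_limit` individuals fall back to a greedy first-fit merge, with a
#' warning that the result is only an upper bound.
#'
#' @param parthenotes Named list of [mlg()] objects (classified parthenote or
#'   consistent-unconfirmed); missing loci act as wildcards.
#' @param exact_limit Largest input size for which the exact search runs
#'   (default 20).
#' @return List of class `"min_mothers"`: `n_dams`, `reconstructions`
#'   (list of [reconstruct_dam()] results labelled `dam_1`, `dam_2`, ...),
#'   and `exact` (FALSE when the greedy fallback was used).
#' @export
min_mothers <- function(parthenotes, exact_limit = 20L) {
  n <- length(parthenotes)
  if (n == 0L)
    return(structure(list(n_dams = 0L, reconstructions = list(), exact = TRUE),
                     class = "min_mothers"))
  panel <- check_shared_panel(parthenotes)
  items <- parthenotes
  for (i in seq_along(items)) items[[i]]$.idx <- i

  incompat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    ok <- group_compatible(list(items[[i]], items[[j]]))
    incompat[i, j] <- incompat[j, i] <- !ok
  }

  if (n > exact_limit) {
    warning("input larger than exact_limit (", exact_limit,
            "); greedy first-fit merge used -- result is an upper bound")
    blocks <- list()
    for (it in items) {
      placed <- FALSE
      for (b in seq_along(blocks)) {
        nb <- block_add(blocks[[b]], it$.idx, it)
        if (!is.null(nb)) { blocks[[b]] <- nb; placed <- TRUE; break }
      }
      if (!placed) blocks <- c(blocks, list(block_add(empty_block(panel),
                                                      it$.idx, it)))
    }
    sol <- blocks
    exact <- FALSE
  } else {
    # greedy pairwise-incompatible subset => lower bound for k
    picked <- integer()
    for (i in seq_len(n))
      if (length(picked) == 0L || all(incompat[i, picked]))
        picked <- c(picked, i)
    lb <- max(1L, length(picked))
    sol <- NULL
    for (k in lb:n) {
      sol <- partition_dfs(items, k, panel, incompat)
      if (!is.null(sol)) break
    }
    exact <- TRUE
  }

  recs <- lapply(seq_along(sol), function(b)
    reconstruct_dam(items[sol[[b]]$members], label = paste0("dam_", b)))
  structure(list(n_dams = length(sol), reconstructions = recs, exact = exact),
            class = "min_mothers")
}

#' @export
print.min_mothers <- function(x, ...) {
  cat(sprintf("<min_mothers> %d dam(s)%s\n", x$n_dams,
              if (x$exact) "" else " (greedy upper bound)"))
  for (r in x$reconstructions)
    cat(sprintf("  %s: %s\n", r$dam_label, paste(r$members, collapse = ", ")))
  invisible(x)
}

#' Greedy lower bound on the number of dams
#'
#' Size of a greedily grown pairwise-incompatible subset; every partition
#' needs at least this many blocks.
#'
#' @param parthenotes Named list of [mlg()] objects.
#' @return Integer lower bound (0 for empty input).
#' @export
min_mothers_lower_bound <- function(parthenotes) {
  n <- length(parthenotes)
  if (n == 0L) return(0L)
  items <- parthenotes
  picked <- list()
  for (it in items)
    if (all(vapply(picked, function(p)
      !group_compatible(list(p, it)), TRUE)))
      picked <- c(picked, list(it))
  length(picked)
}
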