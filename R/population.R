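#' Population state (plain-R engine)
#'
#' A materialized population is a list of 2N `chromosome` objects plus the
#' absolute generation counter. The plain-R engine keeps the whole population
#' in this form; the C++ engine uses an equivalent internal representation.
#'
#' @param N diploid size.
#' @param L block length.
#' @return a `population` object with 2N empty two-block chromosomes at t = 0.
#' @export
new_population <- function(N, L) {
  chroms <- replicate(2L * N, chromosome(integer(0), integer(0)), simplify = FALSE)
  structure(list(chroms = chroms, N = as.integer(N), L = as.integer(L),
                 t = 0L), class = "population")
}

#' @export
print.population <- function(x, ...) {
  nd <- sum(vapply(x$chroms, n_blocks, 1L) == 3L)
  cat(sprintf("<population> N=%d L=%d t=%d carriers=%d/%d\n",
              x$N, x$L, x$t, nd, 2L * x$N))
  invisible(x)
}

#' Record a sample of individuals
#'
#' Samples `n_sample` individuals (chromosome pairs) without replacement and
#' deep-copies their haplotypes: mutation-position sets per block for
#' `2 * n_sample` chromosomes. Later evolution cannot alter a recording.
#'
#' @param pop a `population`.
#' @param n_sample number of individuals to sample (`<= N`).
#' @return object of class `recorded_sample`: list with `t`, `n_carriers`,
#'   and `haps = list(original =, singlecopy =, duplicated =)`, each a list of
#'   `2 * n_sample` integer vectors; `duplicated` entries are `NULL` for
#'   chromosomes not carrying the duplication.
#' @export
record_sample <- function(pop, n_sample) {
  stopifnot(inherits(pop, "population"))
  if (n_sample > pop$N) stop("n_sample exceeds N")
  ind <- sample.int(pop$N, n_sample)
  slots <- as.integer(rbind(2L * ind - 1L, 2L * ind))
  chroms <- pop$chroms[slots]
  new_recorded_sample(
    t = pop$t,
    original = lapply(chroms, `[[`, 1L),
    singlecopy = lapply(chroms, `[[`, 2L),
    duplicated = lapply(chroms, function(ch) if (n_blocks(ch) == 3L) ch[[3L]] else NULL),
    L = pop$L
  )
}

new_recorded_sample <- function(t, original, singlecopy, duplicated, L) {
  structure(list(
    t = as.integer(t), L = as.integer(L),
    n_carriers = sum(!vapply(duplicated, is.null, TRUE)),
    haps = list(original = original, singlecopy = singlecopy,
                duplicated = duplicated)
  ), class = "recorded_sample")
}

#' @export
print.recorded_sample <- function(x, ...) {
  cat(sprintf("<recorded_sample> t=%d haplotypes=%d carriers=%d L=%d\n",
              x$t, length(x$haps$original), x$n_carriers, x$L))
  invisible(x)
}

#' Erase fixed derived mutations
#'
#' Positions present on all 2N chromosomes in the single-copy block are
#' removed everywhere; positions in the original/duplicated pair are removed
#' only if present on all 2N chromosomes in *both* blocks (hence never during
#' the structured phase, when not every chromosome has the duplicated block).
#' During burn-in, when no duplicated block exists anywhere, the original
#' block is pruned by its own single-block rule. Erasure changes no pairwise
#' difference; erased positions become eligible for new mutations.
#'
#' @param pop a `population`.
#' @return list `(pop, erased)` where `erased` is a list of integer vectors
#'   per block class.
#' @export
prune_fixed <- function(pop) {
  stopifnot(inherits(pop, "population"))
  twoN <- 2L * pop$N
  chroms <- pop$chroms
  nb <- vapply(chroms, n_blocks, 1L)
  fix_sc <- fixed_positions(lapply(chroms, `[[`, 2L), twoN)
  if (all(nb == 2L)) {
    fix_orig <- fixed_positions(lapply(chroms, `[[`, 1L), twoN)
    fix_dup <- integer(0)
  } else if (all(nb == 3L)) {
    fix_orig <- intersect(fixed_positions(lapply(chroms, `[[`, 1L), twoN),
                          fixed_positions(lapply(chroms, `[[`, 3L), twoN))
    fix_dup <- fix_orig
  } else {
    fix_orig <- integer(0); fix_dup <- integer(0)
  }
  if (length(fix_sc) || length(fix_orig)) {
    pop$chroms <- lapply(chroms, function(ch) {
      ch[[1L]] <- ch[[1L]][!(ch[[1L]] %in% fix_orig)]
      ch[[2L]] <- ch[[2L]][!(ch[[2L]] %in% fix_sc)]
      if (n_blocks(ch) == 3L) ch[[3L]] <- ch[[3L]][!(ch[[3L]] %in% fix_dup)]
      ch
    })
  }
  list(pop = pop,
       erased = list(singlecopy = fix_sc, original = fix_orig, duplicated = fix_dup))
}

fixed_positions <- function(hap_list, n_total) {
  tab <- table(unlist(hap_list))
  as.integer(names(tab)[tab == n_total])
}
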