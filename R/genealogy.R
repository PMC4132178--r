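#' Era genealogies
#'
#' An Era is a block of `k` generations whose genealogy is simulated in
#' advance so that only *fertile* chromosomes — those contributing genetic
#' material to the final generation of the Era, either as ancestors or as
#' crossover partners — need to be simulated explicitly. This is valid only
#' under neutrality, where the genealogy is independent of genetic content.
#'
#' Slots are 1-based; the 2N chromosome slots pair into individuals as
#' `(1,2), (3,4), ...`, so the *partner* of slot `x` is `x+1` for odd `x` and
#' `x-1` for even `x`. Generation indices run from 0 (the Era's base
#' generation, already materialized) to `k`.
#'
#' @name era_genealogy
#' @keywords internal
NULL

partner_slot <- function(x) x + ifelse(x %% 2L == 1L, 1L, -1L)

new_era_genealogy <- function(N, k, parent, carrier = NULL) {
  structure(list(
    N = as.integer(N), k = as.integer(k), parent = parent,
    partner_used = NULL, fertile = NULL, carrier = carrier
  ), class = "era_genealogy")
}

#' Assign parents uniformly (neutral Era genealogy)
#'
#' Every slot of generations `1..k` is independently assigned a uniformly
#' chosen parental slot from the previous generation (standard Wright-Fisher
#' sampling with replacement; selfing allowed).
#'
#' @param N diploid size; there are 2N chromosome slots per generation.
#' @param k Era length in generations.
#' @return an `era_genealogy` with the `parent` matrix (`k` rows, 2N columns;
#'   row `j` maps generation-`j` slots to generation-`j-1` slots) filled and
#'   fertility untagged.
#' @seealso [tag_fertile()], [assign_parents_structured()]
#' @export
assign_parents_neutral <- function(N, k) {
  twoN <- 2L * N
  parent <- matrix(sample.int(twoN, k * twoN, replace = TRUE), nrow = k, ncol = twoN)
  new_era_genealogy(N, k, parent)
}

#' Assign parents honoring a duplication-carrier schedule
#'
#' During the structured phase the number of duplication carriers at each
#' generation is dictated by a conditioned fixation trajectory. At every
#' generation exactly `schedule[j]` uniformly chosen slots are carriers;
#' carrier slots draw their parent uniformly among the previous generation's
#' carriers and non-carrier slots among the non-carriers.
#'
#' A generation with `schedule[j] == 0` is fully neutral. The special value
#' `event_gen` marks the generation at which the duplication itself appears:
#' parents there are neutral and a single uniformly chosen slot is marked as
#' the founding carrier (the engine copies its original block at that point).
#'
#' @param N diploid size.
#' @param k Era length.
#' @param schedule integer vector of length `k`: carrier counts for
#'   generations `1..k` (0 where the duplication does not exist yet, 2N after
#'   fixation).
#' @param base_carriers logical vector over the 2N slots of generation 0.
#' @param event_gen generation index (1..k) of the duplication event, or 0.
#' @return an `era_genealogy` with `parent` and `carrier` filled (`carrier`
#'   has `k+1` rows; row 1 is generation 0).
#' @export
assign_parents_structured <- function(N, k, schedule, base_carriers,
                                      event_gen = 0L) {
  twoN <- 2L * N
  stopifnot(length(schedule) == k, length(base_carriers) == twoN)
  if (any(schedule < 0 | schedule > twoN)) stop("schedule counts must lie in [0, 2N]")
  parent <- matrix(0L, nrow = k, ncol = twoN)
  carrier <- matrix(FALSE, nrow = k + 1L, ncol = twoN)
  carrier[1L, ] <- base_carriers
  for (j in seq_len(k)) {
    prev_car <- which(carrier[j, ])
    s <- schedule[j]
    if (s == 0L || j == event_gen) {
      parent[j, ] <- sample.int(twoN, twoN, replace = TRUE)
      if (j == event_gen) {
        if (s != 1L) stop("duplication event generation must have carrier count 1")
        carrier[j + 1L, sample.int(twoN, 1L)] <- TRUE
      }
    } else {
      if (length(prev_car) == 0L)
        stop("schedule demands carriers but none exist upstream")
      slots <- sample.int(twoN, s)
      carrier[j + 1L, slots] <- TRUE
      prev_non <- which(!carrier[j, ])
      if (s < twoN && length(prev_non) == 0L)
        stop("schedule demands non-carriers but none exist upstream")
      parent[j, slots] <- prev_car[sample.int(length(prev_car), s, replace = TRUE)]
      ns <- setdiff(seq_len(twoN), slots)
      if (length(ns) > 0)
        parent[j, ns] <- prev_non[sample.int(length(prev_non), length(ns), replace = TRUE)]
    }
  }
  new_era_genealogy(N, k, parent, carrier)
}

#' Tag fertile chromosomes and fix crossover-partner draws
#'
#' Walks the genealogy backward from generation `k` (all of whose slots are
#' fertile) to generation 0. Each fertile slot's parent is tagged fertile;
#' with probability `r` the parent's *partner* is tagged fertile as well, and
#' that Bernoulli draw is recorded in `partner_used` — it later doubles as
#' the decision that this meiosis performs a crossover, so tagging and
#' crossover execution always agree.
#'
#' @param gen an `era_genealogy` with parents assigned.
#' @param r per-meiosis crossover probability.
#' @param prune if `FALSE`, every slot is tagged fertile (full, unpruned
#'   simulation) and `partner_used` is drawn for all slots.
#' @return the genealogy with `fertile` (`k+1` rows) and `partner_used`
#'   (`k` rows) filled.
#' @export
tag_fertile <- function(gen, r, prune = TRUE) {
  stopifnot(inherits(gen, "era_genealogy"), r >= 0, r <= 1)
  k <- gen$k; twoN <- 2L * gen$N
  fertile <- matrix(!prune, nrow = k + 1L, ncol = twoN)
  partner_used <- matrix(FALSE, nrow = k, ncol = twoN)
  fertile[k + 1L, ] <- TRUE
  if (prune) {
    for (j in rev(seq_len(k))) {
      for (x in which(fertile[j + 1L, ])) {
        p <- gen$parent[j, x]
        fertile[j, p] <- TRUE
        if (r > 0 && runif(1) < r) {
          partner_used[j, x] <- TRUE
          fertile[j, partner_slot(p)] <- TRUE
        }
      }
    }
  } else if (r > 0) {
    partner_used[] <- runif(k * twoN) < r
  }
  gen$fertile <- fertile
  gen$partner_used <- partner_used
  gen
}

#' @export
print.era_genealogy <- function(x, ...) {
  cat(sprintf("<era_genealogy> N=%d k=%d fertile:%s carriers:%s\n", x$N, x$k,
              if (is.null(x$fertile)) "untagged" else "tagged",
              if (is.null(x$carrier)) "none" else "scheduled"))
  invisible(x)
}

#' Dump an Era genealogy as a long-format data frame
#'
#' Debug view: one row per (generation, slot) with parent, fertile, carrier
#' and partner-used flags. Generation 0 rows have no parent.
#'
#' @param gen a tagged `era_genealogy`.
#' @return a data.frame.
#' @export
genealogy_to_df <- function(gen) {
  stopifnot(inherits(gen, "era_genealogy"))
  k <- gen$k; twoN <- 2L * gen$N
  gens <- rep(0:k, each = twoN)
  slot <- rep(seq_len(twoN), k + 1L)
  parent <- c(rep(NA_integer_, twoN), as.integer(t(gen$parent)))
  df <- data.frame(generation = gens, slot = slot, parent = parent)
  if (!is.null(gen$fertile)) df$fertile <- as.logical(t(gen$fertile))
  if (!is.null(gen$carrier)) df$carrier <- as.logical(t(gen$carrier))
  if (!is.null(gen$partner_used))
    df$partner_used <- c(rep(NA, twoN), as.logical(t(gen$partner_used)))
  df
}
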