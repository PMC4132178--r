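#' Run one forward simulation
#'
#' Executes the three phases over Eras: a burn-in of `T1` generations
#' (two-block chromosomes at mutation-drift equilibrium), a structured phase
#' beginning with the duplication event at `t = T1 + 1` and governed by a
#' conditioned neutral fixation trajectory, and a concerted-evolution phase
#' until `t = TT`. A sample of `n_sample` individuals is recorded every `k`
#' generations; fixed derived mutations are erased right after each recording
#' (original/duplicated positions only when fixed in both blocks). Only
#' fertile chromosomes are simulated explicitly (see [tag_fertile()]), which
#' is exact under neutrality.
#'
#' The `"cpp"` engine and the `"r"` engine implement the identical model; the
#' R one exists as a readable reference and cross-validation oracle and is
#' only practical at small N.
#'
#' @param params a [sim_params()] object. If `params$seed` is set, the RNG is
#'   seeded first, making the run fully reproducible.
#' @param engine `"cpp"` (default) or `"r"`.
#' @param prune simulate fertile chromosomes only (default `TRUE`); `FALSE`
#'   materializes all 2N chromosomes every generation (slow; used to validate
#'   the pruning).
#' @param stats_from compute the diversity time series only for recordings
#'   with `t >= stats_from` (default 0 = all).
#' @return object of class `dupsim_run`: list with `params`, `rates`,
#'   `trajectory`, `T2`, `recordings` (list of `recorded_sample`),
#'   `diversity` (data.frame, one row per summarized recording), `counters`,
#'   `final_sample`.
#' @export
#' @examples
#' p <- sim_params(N = 12, L = 500, theta = 0.004, C = 1, R = 10, lam = 20,
#'                 k = 12, T1 = 60, T2max = 240, TT = 360, n_sample = 6,
#'                 seed = 1)
#' res <- run_simulation(p)
#' tail(res$diversity, 2)
run_simulation <- function(params, engine = c("cpp", "r"), prune = TRUE,
                           stats_from = 0) {
  engine <- match.arg(engine)
  validate_params(params)
  rates <- derive_rates(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  raw <- if (engine == "cpp") cpp_engine_run(params, rates, prune)
         else r_engine_run(params, rates, prune)
  recs <- raw$recordings
  div <- do.call(rbind, lapply(recs, function(s)
    if (s$t >= stats_from) diversity_summary(s) else NULL))
  structure(list(
    params = params, rates = rates, engine = engine,
    trajectory = raw$trajectory, T2 = raw$T2,
    recordings = recs, diversity = div, counters = raw$counters,
    final_sample = recs[[length(recs)]]
  ), class = "dupsim_run")
}

#' @export
print.dupsim_run <- function(x, ...) {
  cat(sprintf("<dupsim_run> engine=%s N=%d TT=%d recordings=%d T2=%s\n",
              x$engine, x$params$N, x$params$TT, length(x$recordings),
              if (is.null(x$T2) || x$T2 < 0) "none" else x$T2))
  if (!is.null(x$diversity)) print(tail(x$diversity, 3L))
  invisible(x)
}

cpp_engine_run <- function(params, rates, prune) {
  p <- params
  model <- match(p$crossover_model, c("SCC", "WRC", "HSC")) - 1L
  hot <- if (is.null(p$hotspots)) matrix(numeric(0), ncol = 2) else p$hotspots
  raw <- cpp_run_simulation(
    N = p$N, L = p$L, muL = rates$mu * p$L, r = rates$r,
    g2L = rates$g * 2 * p$L, q = rates$q, model = model, hotspots = hot,
    k = p$k, T1 = p$T1, T2max = p$T2max, TT = p$TT, n_sample = p$n_sample,
    identity_threshold = if (is.null(p$igc_identity_threshold)) -1
                         else p$igc_identity_threshold,
    prune = prune)
  recs <- lapply(raw$recordings, function(r)
    new_recorded_sample(r$t, r$original, r$singlecopy, r$duplicated, p$L))
  list(trajectory = raw$trajectory, T2 = raw$T2, recordings = recs,
       counters = raw$counters)
}

# ---- plain-R reference engine --------------------------------------------

#' Advance a population through one pre-built Era (plain-R engine)
#'
#' For each generation of the Era only fertile slots are materialized: the
#' daughter is a crossover product of its parent and the parent's partner
#' when the meiosis' recorded crossover draw fired, otherwise a copy of the
#' parent; then at most one mutation per block is attempted; then IGC acts on
#' three-block chromosomes. The polymorphism registry is rebuilt from the
#' materialized chromosomes of each new generation, exactly as the C++ engine
#' does with its stamped count arrays.
#'
#' @param pop a `population` (its chromosomes being generation 0 of the Era).
#' @param gen a tagged `era_genealogy` (with `carrier` masks for structured
#'   phases; attach `event_gen`/duplication bookkeeping via
#'   `attr(gen, "event_gen")`).
#' @param rates a [derive_rates()] result.
#' @param model crossover model string.
#' @param hotspots hotspot matrix or NULL.
#' @return list `(pop, counters)`.
#' @export
advance_era <- function(pop, gen, rates, model, hotspots = NULL) {
  stopifnot(inherits(pop, "population"), inherits(gen, "era_genealogy"),
            !is.null(gen$fertile))
  L <- pop$L; twoN <- 2L * pop$N
  event_gen <- attr(gen, "event_gen") %||% 0L
  event_slot <- NA_integer_
  cnt <- c(mutations = 0, mut_skipped = 0, crossovers = 0, igc_events = 0,
           igc_truncated = 0, igc_identity_skipped = 0)
  cur <- pop$chroms
  for (j in seq_len(gen$k)) {
    fer <- gen$fertile[j + 1L, ]
    nxt <- vector("list", twoN)
    for (x in which(fer)) {
      p <- gen$parent[j, x]
      parent <- cur[[p]]
      if (gen$partner_used[j, x]) {
        partner <- cur[[partner_slot(p)]]
        junction <- choose_crossover_junction(model, n_blocks(parent),
                                              n_blocks(partner), hotspots, L)
        d <- recombine(parent, partner, junction, L)
        cnt["crossovers"] <- cnt["crossovers"] + 1
      } else {
        d <- parent
      }
      if (j == event_gen && is.na(event_slot) &&
          !is.null(gen$carrier) && gen$carrier[j + 1L, x]) {
        event_slot <- x
        d[[3L]] <- d[[1L]]
      }
      nxt[[x]] <- d
    }
    live <- which(fer)
    registry <- build_registry(nxt[live])
    for (x in live) {
      d <- nxt[[x]]
      for (b in seq_len(n_blocks(d))) {
        m <- sample_mutation(d, b, registry, rates$mu, L)
        d <- m$chrom; registry <- m$registry
        cnt["mutations"] <- cnt["mutations"] + m$mutated
        cnt["mut_skipped"] <- cnt["mut_skipped"] + m$skipped
      }
      nxt[[x]] <- d
    }
    if (rates$g > 0) {
      for (x in live) {
        d <- nxt[[x]]
        if (n_blocks(d) == 3L) {
          for (ev in sample_igc_initiations(d, rates$g, L, rates$q)) {
            res <- apply_igc(d, ev, NULL, L)
            d <- res$chrom
            cnt["igc_events"] <- cnt["igc_events"] + 1
            cnt["igc_truncated"] <- cnt["igc_truncated"] + ev$truncated
          }
          nxt[[x]] <- d
        }
      }
    }
    cur <- nxt
  }
  pop$chroms <- cur
  pop$t <- pop$t + gen$k
  list(pop = pop, counters = cnt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

r_engine_run <- function(params, rates, prune) {
  p <- params
  twoN <- 2L * p$N
  pop <- new_population(p$N, p$L)
  traj <- NULL; T2 <- -1L
  if (p$T1 < p$TT) {
    traj <- sample_fixation_trajectory(p$N, p$T2max, engine = "r")
    T2 <- traj$T2
    if (p$T1 + 1L + T2 > p$TT)
      stop("phase lengths inconsistent: T1 + 1 + T2 exceeds TT")
  }
  counters <- c(mutations = 0, mut_skipped = 0, crossovers = 0, igc_events = 0,
                igc_truncated = 0, igc_identity_skipped = 0, fixed_erased = 0)
  recs <- list()
  t <- 0L
  while (t < p$TT) {
    k_era <- min(p$k, p$TT - t)
    tp <- (t + seq_len(k_era)) - (p$T1 + 1L)
    want <- vapply(tp, function(z) {
      if (z < 0L) 0L
      else if (T2 >= 0L && z <= T2) traj$counts[z + 1L]
      else twoN
    }, 1L)
    event_gen <- if (any(tp == 0L)) which(tp == 0L) else 0L
    base_carriers <- vapply(pop$chroms, n_blocks, 1L) == 3L
    gen <- if (all(want == 0L)) {
      assign_parents_neutral(p$N, k_era)
    } else {
      assign_parents_structured(p$N, k_era, want, base_carriers, event_gen)
    }
    attr(gen, "event_gen") <- event_gen
    gen <- tag_fertile(gen, rates$r, prune = prune)
    adv <- advance_era(pop, gen, rates, p$crossover_model, p$hotspots)
    pop <- adv$pop
    counters[names(adv$counters)] <- counters[names(adv$counters)] + adv$counters
    t <- pop$t
    recs[[length(recs) + 1L]] <- record_sample(pop, p$n_sample)
    pr <- prune_fixed(pop)
    pop <- pr$pop
    counters["fixed_erased"] <- counters["fixed_erased"] +
      length(pr$erased$singlecopy) * twoN + length(pr$erased$original) * 2L * twoN
  }
  list(trajectory = if (is.null(traj)) integer(0) else traj$counts,
       T2 = T2, recordings = recs, counters = counters)
}

#' Run several replicates of one parameter set
#'
#' Replicate `i` runs with seed `replicate_seed(seed, i)`, so any replicate
#' is reproducible in isolation.
#'
#' @param params a [sim_params()] object (its own `seed`/`replicates` fields
#'   are ignored here).
#' @param replicates replicate count.
#' @param seed master seed.
#' @param ... passed to [run_simulation()].
#' @return list of `dupsim_run` objects.
#' @export
run_replicates <- function(params, replicates, seed, ...) {
  lapply(seq_len(replicates), function(i) {
    params$seed <- replicate_seed(seed, i)
    run_simulation(params, ...)
  })
}

#' Per-replicate seed derivation
#'
#' Deterministic counter scheme: `(seed + i * 1000003) mod (2^31 - 1)`.
#'
#' @param seed master seed (integer).
#' @param i replicate index (1-based).
#' @return integer seed.
#' @export
replicate_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 1000003) %% 2147483647)
}

#' Mean diversity at equilibrium
#'
#' Averages the diversity time series of one or more runs over recordings
#' with `t >= from_t`. `pi_w` is the mean of the original- and
#' duplicated-block values (identical in expectation at equilibrium).
#'
#' @param runs a `dupsim_run` or list of them.
#' @param from_t first generation considered at equilibrium.
#' @return one-row data.frame of means (plus `n_runs`).
#' @export
equilibrium_summary <- function(runs, from_t) {
  if (inherits(runs, "dupsim_run")) runs <- list(runs)
  per_run <- do.call(rbind, lapply(runs, function(r) {
    d <- r$diversity[r$diversity$t >= from_t, , drop = FALSE]
    data.frame(pi_original = mean(d$pi_original),
               pi_singlecopy = mean(d$pi_singlecopy),
               pi_duplicated = mean(d$pi_duplicated),
               pi_w = mean(c(d$pi_original, d$pi_duplicated)),
               pi_b = mean(d$pi_b), pi_s = mean(d$pi_s))
  }))
  out <- as.data.frame(as.list(colMeans(per_run)))
  out$se_pi_w <- stats::sd(per_run$pi_w) / sqrt(nrow(per_run))
  out$n_runs <- nrow(per_run)
  out
}
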