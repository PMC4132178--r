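#' Simulation parameters
#'
#' Construct the canonical parameter set for a simulation run. All rates are
#' population-scaled (per the usual 4N convention): `theta` = 4N*mu per site,
#' `C` = 4N*c per duplicated site, `R` = 4N*r per meiosis. Per-generation rates
#' are always derived from these via [derive_rates()], never set directly, so
#' that a run can be rescaled to a smaller population size while preserving the
#' diffusion-limit equilibria.
#'
#' Coordinates are 0-based, half-open. During the three-block phase the layout
#' in chromosome coordinates is: original block `[0, L)`, single-copy block
#' `[L, 2L)`, duplicated block `[2L, 3L)` (the duplicated block is "pasted" to
#' the right of the single-copy block).
#'
#' @param N diploid population size (individuals).
#' @param L block length in sites. Each chromosome carries 2 or 3 blocks of
#'   `L` sites.
#' @param theta population-scaled mutation rate per site, 4N*mu.
#' @param C population-scaled IGC rate per duplicated site, 4N*c with c = g*lambda.
#' @param R population-scaled crossover rate per meiosis, 4N*r. At most one
#'   crossover occurs per meiosis, irrespective of chromosome length.
#' @param lam mean IGC tract length lambda, in sites.
#' @param crossover_model one of `"SCC"` (junctions within the single-copy
#'   block), `"WRC"` (whole region), `"HSC"` (hotspots only).
#' @param hotspots for HSC only: matrix or list of half-open intervals
#'   `[start, end)` in 3-block chromosome coordinates, each within `[0, 3L)`.
#' @param k Era length in generations (genealogies are pre-simulated in chunks
#'   of `k`; samples are recorded every `k` generations). Default `N`.
#' @param T1 burn-in length in generations (default `30*N`).
#' @param T2max cap on the structured-phase duration (default `20*N`);
#'   conditioned fixation trajectories longer than this are rejected.
#' @param TT total simulated length in generations (default `120*N`).
#' @param n_sample individuals sampled per recording (default 50).
#' @param tract_q_mode `"mean_lambda"` (default): geometric tract-length
#'   parameter q = 1/lambda so realized mean tract length is lambda;
#'   `"literal_eq1"`: q = lambda/L as literally printed alongside the tract
#'   distribution (which makes the mean L/lambda). See the methods vignette.
#' @param igc_identity_threshold optional minimal paralog sequence identity
#'   (fraction in \[0,1\]) below which IGC events are skipped; default `NULL`
#'   (off), i.e. IGC occurs regardless of divergence.
#' @param seed optional RNG seed for [run_simulation()].
#' @param replicates replicate count used by preset runners.
#'
#' @return an object of class `sim_params` (a validated named list).
#' @seealso [derive_rates()], [validate_params()], [run_simulation()]
#' @export
#' @examples
#' p <- sim_params(N = 100, TT = 10 * 100)
#' derive_rates(p)
sim_params <- function(N = 1000, L = 5000, theta = 0.001, C = 0.5, R = 50,
                       lam = 100, crossover_model = c("SCC", "WRC", "HSC"),
                       hotspots = NULL, k = N, T1 = 30 * N, T2max = 20 * N,
                       TT = 120 * N, n_sample = 50,
                       tract_q_mode = c("mean_lambda", "literal_eq1"),
                       igc_identity_threshold = NULL, seed = NULL,
                       replicates = 1L) {
  crossover_model <- match.arg(crossover_model)
  tract_q_mode <- match.arg(tract_q_mode)
  p <- structure(list(
    N = as.integer(N), L = as.integer(L), theta = theta, C = C, R = R,
    lam = lam, crossover_model = crossover_model,
    hotspots = normalize_hotspots(hotspots),
    k = as.integer(k), T1 = as.integer(T1), T2max = as.integer(T2max),
    TT = as.integer(TT), n_sample = as.integer(n_sample),
    tract_q_mode = tract_q_mode,
    igc_identity_threshold = igc_identity_threshold,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    replicates = as.integer(replicates)
  ), class = "sim_params")
  invisible(validate_params(p, warn = FALSE))
  p
}

normalize_hotspots <- function(hotspots) {
  if (is.null(hotspots) || (is.list(hotspots) && length(hotspots) == 0)) return(NULL)
  if (is.list(hotspots)) hotspots <- do.call(rbind, lapply(hotspots, as.numeric))
  hotspots <- matrix(as.numeric(hotspots), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  hotspots
}

#' Validate simulation parameters
#'
#' Hard invariant violations raise an error naming the offending field;
#' soft issues are returned (and emitted) as human-readable warnings. The
#' input is never modified.
#'
#' @param params a [sim_params()] object.
#' @param warn emit `warning()` for each soft issue (default `TRUE`).
#' @return character vector of warning messages (possibly empty), invisibly
#'   when `warn = TRUE`.
#' @export
validate_params <- function(params, warn = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  err <- function(field, msg) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  p <- params
  if (is.na(p$N) || p$N < 2) err("N", "diploid population size must be >= 2")
  if (p$L < 100) err("L", "block length must be >= 100")
  if (p$L %% 100 != 0) err("L", "block length must be divisible by the 100-bp LD window width")
  if (p$theta < 0) err("theta", "must be >= 0")
  if (p$C < 0) err("C", "must be >= 0")
  if (p$R < 0) err("R", "must be >= 0")
  if (p$lam < 1 || p$lam > p$L) err("lam", "mean tract length must satisfy 1 <= lambda <= L")
  if (p$k < 1) err("k", "era length must be >= 1")
  if (p$T1 < 0) err("T1", "burn-in length must be >= 0")
  if (p$T2max < 1) err("T2max", "structured-phase cap must be >= 1")
  if (p$TT < 1) err("TT", "total length must be >= 1")
  if (p$n_sample < 1 || p$n_sample > p$N) err("n_sample", "must satisfy 1 <= n_sample <= N")
  if (p$crossover_model == "HSC") {
    if (is.null(p$hotspots) || nrow(p$hotspots) == 0)
      err("hotspots", "HSC model requires a nonempty hotspot list")
    h <- p$hotspots
    if (any(h[, 1] < 0) || any(h[, 2] > 3 * p$L) || any(h[, 1] >= h[, 2]))
      err("hotspots", "each hotspot must be a half-open interval within [0, 3L)")
  } else if (!is.null(p$hotspots) && nrow(p$hotspots) > 0) {
    err("hotspots", sprintf("hotspots are only meaningful under HSC (model is %s)",
                            p$crossover_model))
  }
  if (!is.null(p$igc_identity_threshold)) {
    if (p$igc_identity_threshold < 0 || p$igc_identity_threshold > 1)
      err("igc_identity_threshold", "must be a fraction in [0, 1]")
  }
  warnings <- character()
  if (p$T1 > 0 && p$T1 < 10 * p$N)
    warnings <- c(warnings, sprintf(
      "T1 = %d < 10N: burn-in may not reach mutation-drift equilibrium", p$T1))
  rr <- derive_rates(p)
  if (rr$g * 2 * p$L > 1)
    warnings <- c(warnings, sprintf(
      "mean IGC initiations per chromosome-generation 2Lg = %.3g > 1", rr$g * 2 * p$L))
  if (p$T1 < p$TT && p$T1 + p$T2max > p$TT)
    warnings <- c(warnings, sprintf(
      "T1 + T2max = %d exceeds TT = %d: a long fixation trajectory would overrun the run",
      p$T1 + p$T2max, p$TT))
  if (warn) for (w in warnings) warning(w, call. = FALSE)
  if (warn) invisible(warnings) else warnings
}

#' Derive per-generation rates from population-scaled parameters
#'
#' Deterministic, side-effect-free conversion of a [sim_params()] object into
#' the per-generation quantities the engine consumes:
#' mu = theta/(4N), r = R/(4N), c = C/(4N), g = c/lambda, and the geometric
#' tract parameter q (mode-dependent: 1/lambda or lambda/L).
#'
#' @param params a [sim_params()] object.
#' @return an object of class `derived_rates` with fields `mu`, `r`, `c`, `g`,
#'   `q`, `Theta_block` (= theta*L).
#' @export
#' @examples
#' derive_rates(sim_params(N = 1000, theta = 0.001, R = 50, C = 0.5, lam = 100))
derive_rates <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  fourN <- 4 * p$N
  r <- p$R / fourN
  if (r > 1) stop("invalid `R`: per-meiosis crossover probability r = R/(4N) = ",
                  r, " exceeds 1", call. = FALSE)
  cc <- p$C / fourN
  q <- switch(p$tract_q_mode,
              mean_lambda = 1 / p$lam,
              literal_eq1 = p$lam / p$L)
  if (q <= 0 || q > 1) stop("invalid tract parameter q = ", q, call. = FALSE)
  structure(list(
    mu = p$theta / fourN,
    r = r,
    c = cc,
    g = cc / p$lam,
    q = q,
    Theta_block = p$theta * p$L
  ), class = "derived_rates")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  N=%d  L=%d  theta=%g  C=%g  R=%g  lambda=%g\n",
              x$N, x$L, x$theta, x$C, x$R, x$lam))
  cat(sprintf("  model=%s%s  k=%d  T1=%d  T2max=%d  TT=%d  n_sample=%d\n",
              x$crossover_model,
              if (is.null(x$hotspots)) "" else sprintf(" (%d hotspot(s))", nrow(x$hotspots)),
              x$k, x$T1, x$T2max, x$TT, x$n_sample))
  cat(sprintf("  tract_q_mode=%s  seed=%s  replicates=%d\n", x$tract_q_mode,
              if (is.null(x$seed)) "NULL" else x$seed, x$replicates))
  invisible(x)
}

#' @export
print.derived_rates <- function(x, ...) {
  cat("<derived_rates>\n")
  cat(sprintf("  mu=%g  r=%g  c=%g  g=%g  q=%g  Theta_block=%g\n",
              x$mu, x$r, x$c, x$g, x$q, x$Theta_block))
  invisible(x)
}
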