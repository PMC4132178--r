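#' Preset experiment configurations
#'
#' Named experiment grids reproducing the published figure layouts at a
#' chosen population scale. Every preset holds the population-scaled
#' parameters (theta, C, R, lambda) fixed and scales N and all durations,
#' which preserves the diffusion-limit equilibria; the trade-off is larger
#' Monte-Carlo noise at small N, compensated by replicates.
#'
#' Available presets:
#' * `fig3` — variation trajectory at C = 0.5, R = 50 (SCC).
#' * `fig5` — SCC crossover-rate grid vs WRC, C = 1 (the WRC curve matches
#'   SCC at R' = (2/3) R).
#' * `fig6` — hotspot-location sweep (left/center/right of the original
#'   block) at R = 10, C = 0.5, bracketed by R = 0 and SCC.
#' * `fig7` — binned pi along the sequence for a centered hotspot, vs SCC and
#'   R = 0 (C = 0.5).
#' * `fig8` — LD with one vs two paralogous hotspots, R = 50, C in {0, 1, 50}.
#' * `table3` — regime grid C in {0.01, 1, 100} x R in {0, 50} (SCC).
#'
#' @return named list of preset definitions (base parameters and sweep).
#' @export
experiment_presets <- function() {
  base <- function(...) list(...)
  hot <- function(s, e) matrix(c(s, e), ncol = 2)
  list(
    fig3 = list(
      base = base(C = 0.5, R = 50, crossover_model = "SCC"),
      sweep = list(list(label = "C0.5_R50")),
      replicates = 30L, output = "timeseries"),
    fig5 = list(
      base = base(C = 1, crossover_model = "SCC"),
      sweep = c(
        lapply(c(0, 10, 25, 100 / 3, 50), function(R)
          list(label = sprintf("SCC_R%.4g", R), R = R, crossover_model = "SCC")),
        lapply(c(25, 50), function(R)
          list(label = sprintf("WRC_R%.4g", R), R = R, crossover_model = "WRC"))),
      replicates = 20L, output = "equilibrium"),
    fig6 = list(
      base = base(C = 0.5, R = 10),
      sweep = list(
        list(label = "R0", R = 0, crossover_model = "SCC"),
        list(label = "hot_left", crossover_model = "HSC", hotspots_frac = c(0, 0.2)),
        list(label = "hot_center", crossover_model = "HSC", hotspots_frac = c(0.4, 0.6)),
        list(label = "hot_right", crossover_model = "HSC", hotspots_frac = c(0.8, 1)),
        list(label = "SCC", crossover_model = "SCC")),
      replicates = 20L, output = "equilibrium"),
    fig7 = list(
      base = base(C = 0.5, R = 10),
      sweep = list(
        list(label = "R0", R = 0, crossover_model = "SCC"),
        list(label = "hot_center", crossover_model = "HSC", hotspots_frac = c(0.4, 0.6)),
        list(label = "SCC", crossover_model = "SCC")),
      replicates = 20L, output = "binned"),
    fig8 = list(
      base = base(R = 50),
      sweep = do.call(c, lapply(c(0, 1, 50), function(C) list(
        list(label = sprintf("one_hotspot_C%g", C), C = C, crossover_model = "HSC",
             hotspots_frac = c(0.4, 0.6)),
        list(label = sprintf("two_hotspots_C%g", C), C = C, crossover_model = "HSC",
             hotspots_frac = c(0.4, 0.6, 2.4, 2.6))))),
      replicates = 10L, output = "ld"),
    table3 = list(
      base = base(crossover_model = "SCC"),
      sweep = do.call(c, lapply(c(0.01, 1, 100), function(C)
        lapply(c(0, 50), function(R)
          list(label = sprintf("C%g_R%g", C, R), C = C, R = R)))),
      replicates = 10L, output = "equilibrium")
  )
}

preset_point_params <- function(preset, point, scale, overrides = NULL) {
  N <- max(4L, as.integer(round(1000 * scale)))
  args <- preset$base
  for (nm in setdiff(names(point), c("label", "hotspots_frac"))) args[[nm]] <- point[[nm]]
  args$N <- N
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  if (!is.null(point$hotspots_frac)) {
    L <- args$L %||% formals(sim_params)$L
    f <- matrix(point$hotspots_frac, ncol = 2, byrow = TRUE)
    args$hotspots <- cbind(round(f[, 1] * L), round(f[, 2] * L))
  }
  do.call(sim_params, args)
}

#' Run a preset experiment
#'
#' Executes the replicates of every sweep point of a named preset and writes
#' deterministic outputs under `out_dir`: per-point equilibrium summary TSV
#' (`summary.tsv`), plus, depending on the preset, a per-generation mean
#' time-series TSV, binned-pi tables, or long-format LD matrices. A
#' `metadata.json` echoes parameters and seeds.
#'
#' @param name preset name (see [experiment_presets()]).
#' @param scale population scale factor relative to N = 1000 (default 0.1,
#'   i.e. N = 100).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; replicate `i` of sweep point `j` uses
#'   `replicate_seed(seed + 7919 * j, i)`.
#' @param replicates overrides the preset's replicate count if not `NULL`.
#' @param overrides named list of [sim_params()] fields forced on every sweep
#'   point (e.g. `list(TT = 600)` for smoke tests).
#' @return (invisibly) the summary data.frame.
#' @export
run_preset <- function(name, scale = 0.1, out_dir, seed = 1L,
                       replicates = NULL, overrides = NULL) {
  presets <- experiment_presets()
  if (!name %in% names(presets))
    stop("unknown preset `", name, "`; available: ",
         paste(names(presets), collapse = ", "))
  preset <- presets[[name]]
  reps <- replicates %||% preset$replicates
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); meta_points <- list()
  for (j in seq_along(preset$sweep)) {
    point <- preset$sweep[[j]]
    params <- preset_point_params(preset, point, scale, overrides)
    eq_from <- params$TT - floor(params$TT / 3)
    runs <- run_replicates(params, reps, seed + 7919L * j,
                           stats_from = if (preset$output == "timeseries") 0 else eq_from)
    eq <- equilibrium_summary(runs, eq_from)
    Theta <- params$theta * params$L
    rows[[j]] <- cbind(data.frame(point = point$label), eq,
                       data.frame(pi_w_over_Theta = eq$pi_w / Theta))
    meta_points[[j]] <- list(label = point$label, N = params$N, C = params$C,
                             R = params$R, model = params$crossover_model,
                             TT = params$TT, replicates = reps,
                             seed_base = seed + 7919L * j)
    if (preset$output == "timeseries") {
      div <- lapply(runs, `[[`, "diversity")
      agg <- div[[1]][, "t", drop = FALSE]
      for (col in c("pi_original", "pi_singlecopy", "pi_duplicated"))
        agg[[col]] <- rowMeans(do.call(cbind, lapply(div, `[[`, col)), na.rm = TRUE)
      write.table(agg, file.path(out_dir, paste0(point$label, "_timeseries.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (preset$output == "binned") {
      bw <- params$L %/% 5L
      bins <- sapply(runs, function(r) {
        s <- r$final_sample
        c(binned_pi(s$haps$original, params$L, bw),
          binned_pi(s$haps$singlecopy, params$L, bw),
          binned_pi(s$haps$duplicated, params$L, bw))
      })
      bdf <- data.frame(
        block = rep(c("original", "singlecopy", "duplicated"), each = 5L),
        bin_start = rep((0:4) * bw, 3L), bin_end = rep((1:5) * bw, 3L),
        pi = rowMeans(bins))
      write.table(bdf, file.path(out_dir, paste0(point$label, "_binned_pi.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (preset$output == "ld") {
      mats <- lapply(runs, function(r) window_ld_matrix(r$final_sample))
      avg <- average_ld_over_runs(mats)
      write_ld_tsv(avg, file.path(out_dir, paste0(point$label, "_ld.tsv")))
    }
  }
  summary_df <- do.call(rbind, rows)
  write.table(summary_df, file.path(out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(preset = name, scale = scale, seed = seed,
                            points = meta_points),
                       file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary_df)
}
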