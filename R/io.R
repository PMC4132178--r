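#' Load a simulation configuration
#'
#' Reads a JSON configuration whose keys are exactly the [sim_params()] field
#' names; missing keys take the documented defaults and unknown keys are
#' rejected. An empty file (or `{}`) yields the full default parameter set.
#' `hotspots` is a list/array of `[start, end)` pairs.
#'
#' @param path path to a JSON file.
#' @return a [sim_params()] object.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- if (nchar(trimws(txt)) == 0) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!is.list(cfg)) stop("config must be a JSON object")
  known <- names(formals(sim_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (expected among: ", paste(known, collapse = ", "), ")")
  for (key in c("N", "L", "k", "T1", "T2max", "TT", "n_sample", "replicates", "seed"))
    if (!is.null(cfg[[key]]) && !is.numeric(cfg[[key]]))
      stop(sprintf("config key `%s` must be numeric", key))
  if (!is.null(cfg$hotspots)) cfg$hotspots <- normalize_hotspots(cfg$hotspots)
  do.call(sim_params, cfg)
}

#' Write a simulation configuration
#'
#' Round-trips through [load_config()] to an identical parameter set.
#'
#' @param params a [sim_params()] object.
#' @param path output path.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  x <- unclass(params)
  x <- x[!vapply(x, is.null, TRUE)]
  if (!is.null(x$hotspots)) x$hotspots <- apply(x$hotspots, 1, as.numeric, simplify = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a recorded sample in an ms-like text dialect
#'
#' One stanza per block: a `//block <name>` line, `segsites: <S>`, a
#' `positions:` line with fractional positions (`pos / L`), then one 0/1 row
#' per haplotype. Columns are the positions segregating *or fixed* among the
#' written haplotypes, in increasing order. Chromosomes without a duplicated
#' block are written as all-missing rows of `.` in that stanza.
#'
#' @param sample a `recorded_sample`.
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [read_ms_like()]
#' @export
write_ms_like <- function(sample, path) {
  stopifnot(inherits(sample, "recorded_sample"))
  con <- file(path, "w")
  on.exit(close(con))
  L <- sample$L
  for (nm in c("original", "singlecopy", "duplicated")) {
    haps <- sample$haps[[nm]]
    pos <- sort(unique(unlist(haps)))
    writeLines(sprintf("//block %s", nm), con)
    writeLines(sprintf("segsites: %d", length(pos)), con)
    if (length(pos) > 0)
      writeLines(paste("positions:", paste(sprintf("%.6f", pos / L), collapse = " ")), con)
    else
      writeLines("positions:", con)
    for (h in haps) {
      if (is.null(h)) writeLines(paste(rep(".", max(length(pos), 1L)), collapse = ""), con)
      else writeLines(paste(as.integer(pos %in% h), collapse = ""), con)
    }
  }
  invisible(path)
}

#' Read an ms-like dump written by [write_ms_like()]
#'
#' Reconstructs integer positions as `round(frac * L)`; pairwise-difference
#' structure is preserved exactly because column identity is.
#'
#' @param path input file.
#' @param L block length used when the file was written.
#' @return a `recorded_sample` (with `t = NA`).
#' @export
read_ms_like <- function(path, L) {
  lines <- readLines(path)
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    stopifnot(startsWith(lines[i], "//block "))
    nm <- sub("^//block ", "", lines[i])
    S <- as.integer(sub("^segsites: ", "", lines[i + 1L]))
    posline <- sub("^positions:\\s*", "", lines[i + 2L])
    pos <- if (nchar(posline) > 0)
      as.integer(round(as.numeric(strsplit(posline, "\\s+")[[1]]) * L)) else integer(0)
    stopifnot(length(pos) == S)
    i <- i + 3L
    haps <- list()
    while (i <= length(lines) && !startsWith(lines[i], "//block ")) {
      row <- strsplit(lines[i], "")[[1]]
      haps[length(haps) + 1L] <-
        list(if (length(row) > 0 && all(row == ".")) NULL else pos[row == "1"])
      i <- i + 1L
    }
    blocks[[nm]] <- haps
  }
  new_recorded_sample(NA_integer_, blocks$original, blocks$singlecopy,
                      blocks$duplicated, L)
}

#' Write a replicate's diversity time series as TSV
#'
#' Columns: generation, pi per block, pi_b, pi_s, S per block.
#'
#' @param run a `dupsim_run`.
#' @param path output path.
#' @export
write_run_tsv <- function(run, path) {
  stopifnot(inherits(run, "dupsim_run"))
  df <- run$diversity
  names(df)[names(df) == "t"] <- "generation"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write run metadata as JSON
#'
#' Parameter echo, seed, trajectory summary and event counters — everything
#' needed to reproduce the run.
#'
#' @param run a `dupsim_run`.
#' @param path output path.
#' @export
write_run_metadata <- function(run, path) {
  stopifnot(inherits(run, "dupsim_run"))
  p <- unclass(run$params)
  p <- p[!vapply(p, is.null, TRUE)]
  if (!is.null(p$hotspots)) p$hotspots <- apply(p$hotspots, 1, as.numeric, simplify = FALSE)
  meta <- list(
    params = p,
    seed = run$params$seed,
    engine = run$engine,
    T2 = run$T2,
    trajectory_length = length(run$trajectory),
    counters = as.list(run$counters)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an LD matrix in long format
#'
#' @param matrix an `ld_matrix`.
#' @param path output path.
#' @param keep_missing include unsupported window pairs.
#' @export
write_ld_tsv <- function(matrix, path, keep_missing = FALSE) {
  write.table(ld_matrix_to_df(matrix, keep_missing), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
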