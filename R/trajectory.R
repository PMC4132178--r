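#' Sample a neutral fixation trajectory
#'
#' Draws an allele-count path of a neutral Wright-Fisher locus started from a
#' single copy among 2N chromosomes, conditioned on eventual fixation. Paths
#' are generated by exact binomial resampling
#' (`count[t+1] ~ Binomial(2N, count[t]/2N)`) and rejection: paths that hit 0
#' or exceed `T2max` generations are discarded and redrawn. The mean accepted
#' duration is close to 4N generations. This schedule of duplication-carrier
#' counts governs the structured phase of a simulation.
#'
#' @param N diploid population size.
#' @param T2max duration cap in generations; `Inf` (or <= 0) disables the cap.
#' @param max_attempts attempt budget before raising an error. The expected
#'   number of attempts per accepted path is about 2N.
#' @param engine `"cpp"` (default, fast) or `"r"` (plain-R reference).
#' @return an object of class `fixation_trajectory`: list with `counts`
#'   (integer vector `s(0..T2)` with `s(0) = 1`, `s(T2) = 2N`) and `T2`.
#' @export
#' @examples
#' tr <- sample_fixation_trajectory(N = 20)
#' tr$counts[1]           # 1
#' tr$counts[tr$T2 + 1]   # 2N = 40
sample_fixation_trajectory <- function(N, T2max = 20 * N, max_attempts = 1e7,
                                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(N >= 2)
  cap <- if (is.infinite(T2max) || T2max <= 0) -1L else as.integer(T2max)
  if (cap != -1L && cap < 1) stop("T2max must be >= 1")
  counts <- if (engine == "cpp") {
    cpp_sample_trajectory(as.integer(N), cap, as.double(max_attempts))
  } else {
    r_sample_trajectory(as.integer(N), cap, max_attempts)
  }
  new_fixation_trajectory(counts, N)
}

new_fixation_trajectory <- function(counts, N) {
  structure(list(counts = as.integer(counts), T2 = length(counts) - 1L,
                 N = as.integer(N)), class = "fixation_trajectory")
}

r_sample_trajectory <- function(N, cap, max_attempts) {
  twoN <- 2L * N
  for (a in seq_len(max_attempts)) {
    x <- 1L
    path <- integer(256L); path[1L] <- 1L; len <- 1L
    repeat {
      x <- rbinom(1L, twoN, x / twoN)
      len <- len + 1L
      if (len > length(path)) path <- c(path, integer(length(path)))
      path[len] <- x
      if (x == twoN) return(path[seq_len(len)])
      if (x == 0L) break
      if (cap > 0L && len - 1L >= cap) break
    }
  }
  stop("no fixation trajectory accepted within attempt budget", call. = FALSE)
}

#' @export
print.fixation_trajectory <- function(x, ...) {
  cat(sprintf("<fixation_trajectory> N=%d T2=%d (%.2f N generations)\n",
              x$N, x$T2, x$T2 / x$N))
  invisible(x)
}

#' Chunk a fixation trajectory into Era-sized carrier schedules
#'
#' Splits the carrier counts `s(0..T2)` into consecutive segments of length
#' `k` (the last one possibly shorter). Concatenating the segments reproduces
#' the trajectory exactly.
#'
#' @param traj a [sample_fixation_trajectory()] result.
#' @param k Era length in generations.
#' @return list of integer vectors (class `carrier_schedule` each).
#' @export
trajectory_to_schedule <- function(traj, k) {
  stopifnot(inherits(traj, "fixation_trajectory"), k >= 1)
  counts <- traj$counts
  idx <- split(seq_along(counts), ceiling(seq_along(counts) / k))
  lapply(unname(idx), function(i) structure(counts[i], class = "carrier_schedule"))
}
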