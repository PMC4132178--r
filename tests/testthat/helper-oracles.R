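# Independent oracles and small fixtures, kept deliberately naive: literal
# loops and set operations, no shared code with the package internals.

# literal mean over all unordered haplotype pairs
bf_pi_pairs <- function(haps) {
  haps <- haps[!vapply(haps, is.null, TRUE)]
  n <- length(haps)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + length(union(haps[[i]], haps[[j]])) -
      length(intersect(haps[[i]], haps[[j]]))
    np <- np + 1
  }
  tot / np
}

# brute-force rejection sampler of conditioned Wright-Fisher fixation paths
bf_trajectory <- function(N) {
  twoN <- 2 * N
  repeat {
    x <- 1; path <- x
    while (x > 0 && x < twoN) {
      x <- rbinom(1, twoN, x / twoN)
      path <- c(path, x)
    }
    if (x == twoN) return(path)
  }
}

# literal two-site LD from 0/1 vectors
bf_ld <- function(a, b) {
  pa <- mean(a); pb <- mean(b); pab <- mean(a & b)
  D <- pab - pa * pb
  dmax <- if (D < 0) min(pa * pb, (1 - pa) * (1 - pb)) else min(pa * (1 - pb), (1 - pa) * pb)
  c(Dprime = if (D == 0) 0 else abs(D) / dmax,
    r2 = D^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

random_chromosome <- function(L, lambda_sites = 8, three_blocks = TRUE) {
  blk <- function() sort(sample.int(L, rpois(1, lambda_sites)) - 1L)
  chromosome(blk(), blk(), if (three_blocks) blk() else NULL, L = L)
}

random_sample_recording <- function(n = 10, L = 500, lambda_sites = 6) {
  chroms <- replicate(n, random_chromosome(L, lambda_sites), simplify = FALSE)
  dupsim:::new_recorded_sample(
    t = 0L,
    original = lapply(chroms, `[[`, 1L),
    singlecopy = lapply(chroms, `[[`, 2L),
    duplicated = lapply(chroms, `[[`, 3L),
    L = L)
}

tiny_params <- function(...) {
  defaults <- list(N = 10, L = 500, theta = 0.01, C = 0.8, R = 10, lam = 20,
                   k = 10, T1 = 100, T2max = 200, TT = 400, n_sample = 10)
  do.call(sim_params, modifyList(defaults, list(...)))
}

record_sample_all <- function(pop) {
  dupsim:::new_recorded_sample(
    pop$t, lapply(pop$chroms, `[[`, 1L), lapply(pop$chroms, `[[`, 2L),
    lapply(pop$chroms, `[[`, 3L), pop$L)
}

expect_sorted_unique <- function(x) {
  expect_true(all(diff(x) > 0) || length(x) <= 1)
}
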