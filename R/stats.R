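#' Pairwise difference between two haplotypes
#'
#' With derived-position sets as the haplotype representation (no back
#' mutation, no indels), the number of pairwise differences is the size of
#' the symmetric difference.
#'
#' @param a,b integer vectors of derived positions.
#' @return integer count.
#' @export
#' @examples
#' pairwise_diff(c(3, 17), c(17, 904))  # 2
pairwise_diff <- function(a, b) {
  length(a) + length(b) - 2L * sum(a %in% b)
}

drop_null <- function(haps) haps[!vapply(haps, is.null, TRUE)]

hap_counts <- function(haps, L) {
  u <- unlist(haps, use.names = FALSE)
  if (is.null(u) || length(u) == 0L) return(integer(0))
  tabulate(u + 1L, nbins = L)
}

#' Average pairwise differences within a block
#'
#' Mean of [pairwise_diff()] over all unordered haplotype pairs, computed via
#' the equivalent derived-count identity
#' `sum_p k_p (n - k_p) / choose(n, 2)`.
#'
#' @param haps list of derived-position vectors (NULL entries are dropped,
#'   e.g. duplicated blocks of non-carriers).
#' @param L block length.
#' @return average pairwise differences (>= 0).
#' @export
#' @examples
#' pi_within(list(integer(0), 5L, c(5L, 7L)), L = 100)  # 4/3
pi_within <- function(haps, L) {
  haps <- drop_null(haps)
  n <- length(haps)
  if (n < 2L) stop("pi_within requires at least 2 haplotypes")
  k <- hap_counts(haps, L)
  sum(as.numeric(k) * (n - k)) / choose(n, 2)
}

#' Variation between paralogs on different chromosomes (pi_b)
#'
#' Mean of `pairwise_diff(original_i, duplicated_j)` over all ordered pairs
#' `i != j` (equivalently the symmetrized unordered mean). Chromosomes
#' without a duplicated block are excluded on the duplicated side.
#'
#' @param sample a `recorded_sample` with at least 2 duplication carriers.
#' @return pi_b.
#' @export
pi_between_paralogs <- function(sample) {
  stopifnot(inherits(sample, "recorded_sample"))
  orig <- sample$haps$original
  dup_idx <- which(!vapply(sample$haps$duplicated, is.null, TRUE))
  if (length(dup_idx) < 2L)
    stop("pi_b requires at least 2 chromosomes carrying the duplication")
  dup <- sample$haps$duplicated[dup_idx]
  ham <- cross_hamming(orig, dup, sample$L)
  same <- cbind(match(dup_idx, seq_along(orig)), seq_along(dup_idx))
  tot <- sum(ham) - sum(ham[same])
  tot / (length(orig) * length(dup) - length(dup_idx))
}

#' Variation between paralogs on the same chromosome (pi_s)
#'
#' Mean over duplication-carrying chromosomes of
#' `pairwise_diff(original_i, duplicated_i)`.
#'
#' @param sample a `recorded_sample` with at least 1 carrier.
#' @return pi_s.
#' @export
pi_same_chromosome <- function(sample) {
  stopifnot(inherits(sample, "recorded_sample"))
  idx <- which(!vapply(sample$haps$duplicated, is.null, TRUE))
  if (length(idx) == 0L) stop("pi_s requires chromosomes carrying the duplication")
  mean(vapply(idx, function(i)
    pairwise_diff(sample$haps$original[[i]], sample$haps$duplicated[[i]]), 1L))
}

# dense |orig_i XOR dup_j| matrix over the union of segregating positions
cross_hamming <- function(hapsA, hapsB, L) {
  pos <- sort(unique(c(unlist(hapsA), unlist(hapsB))))
  A <- vapply(hapsA, function(h) pos %in% h, logical(length(pos)))
  B <- vapply(hapsB, function(h) pos %in% h, logical(length(pos)))
  A <- matrix(as.numeric(A), nrow = length(pos), ncol = length(hapsA))
  B <- matrix(as.numeric(B), nrow = length(pos), ncol = length(hapsB))
  kA <- colSums(A); kB <- colSums(B)
  outer(kA, kB, "+") - 2 * crossprod(A, B)
}

#' Site-frequency spectrum and segregating sites
#'
#' Unfolded spectrum of derived-allele counts `1 .. n-1` among the `n`
#' sampled haplotypes; positions fixed in the sample are neither segregating
#' nor part of the spectrum. The classical identity
#' `pi = sum_i i (n - i) xi_i / choose(n, 2)` ties the output to
#' [pi_within()].
#'
#' @param haps list of derived-position vectors (NULLs dropped).
#' @param L block length.
#' @return list `(sfs, S)`: `sfs` integer vector of length `n - 1`, `S` the
#'   number of segregating sites.
#' @export
sfs_and_S <- function(haps, L) {
  haps <- drop_null(haps)
  n <- length(haps)
  if (n < 2L) stop("sfs_and_S requires at least 2 haplotypes")
  k <- hap_counts(haps, L)
  k <- k[k > 0L & k < n]
  list(sfs = tabulate(k, nbins = n - 1L), S = length(k))
}

#' Binned average pairwise differences along a block
#'
#' Pi restricted to positions within each of the `L / bin_width` bins; bins
#' partition the block, so the bin values sum to the block's pi exactly.
#'
#' @param haps list of derived-position vectors (NULLs dropped).
#' @param L block length; must be divisible by `bin_width`.
#' @param bin_width bin width in sites.
#' @return numeric vector of per-bin pi values.
#' @export
binned_pi <- function(haps, L, bin_width) {
  if (L %% bin_width != 0L) stop("bin_width must divide L")
  haps <- drop_null(haps)
  n <- length(haps)
  if (n < 2L) stop("binned_pi requires at least 2 haplotypes")
  k <- hap_counts(haps, L)
  contrib <- as.numeric(k) * (n - k) / choose(n, 2)
  if (length(contrib) == 0L) return(numeric(L / bin_width))
  bin <- rep(seq_len(L %/% bin_width), each = bin_width)
  as.numeric(tapply(contrib, bin, sum, default = 0))
}

#' Diversity summary of one recording
#'
#' Computes the variation measures of a recorded sample: pi within the
#' original, single-copy, and duplicated blocks; pi_b and pi_s between
#' paralogs (NA before at least 2 carriers exist); segregating sites per
#' block.
#'
#' @param sample a `recorded_sample`.
#' @return one-row data.frame with columns `t`, `n_carriers`, `pi_original`,
#'   `pi_singlecopy`, `pi_duplicated`, `pi_b`, `pi_s`, `S_original`,
#'   `S_singlecopy`, `S_duplicated`.
#' @export
diversity_summary <- function(sample) {
  stopifnot(inherits(sample, "recorded_sample"))
  L <- sample$L
  h <- sample$haps
  n_dup <- sample$n_carriers
  pi_dup <- if (n_dup >= 2L) pi_within(h$duplicated, L) else NA_real_
  S_dup <- if (n_dup >= 2L) sfs_and_S(h$duplicated, L)$S else NA_integer_
  data.frame(
    t = sample$t,
    n_carriers = n_dup,
    pi_original = pi_within(h$original, L),
    pi_singlecopy = pi_within(h$singlecopy, L),
    pi_duplicated = pi_dup,
    pi_b = if (n_dup >= 2L) pi_between_paralogs(sample) else NA_real_,
    pi_s = if (n_dup >= 1L) pi_same_chromosome(sample) else NA_real_,
    S_original = sfs_and_S(h$original, L)$S,
    S_singlecopy = sfs_and_S(h$singlecopy, L)$S,
    S_duplicated = S_dup
  )
}
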