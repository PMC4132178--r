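#' Window grid over the three-block region
#'
#' Half-open windows of `width` bp tiling `[0, 3L)` in chromosome
#' coordinates, tagged by block. `width` must divide `L`.
#'
#' @param L block length.
#' @param width window width in bp (default 100).
#' @return data.frame (class `window_grid`) with columns `window` (1-based
#'   index), `start`, `end`, `block` ("original", "singlecopy", "duplicated").
#' @export
window_grid <- function(L, width = 100L) {
  if (L %% width != 0L) stop("window width must divide L")
  m <- 3L * L %/% width
  start <- (seq_len(m) - 1L) * width
  structure(data.frame(
    window = seq_len(m), start = start, end = start + width,
    block = c("original", "singlecopy", "duplicated")[start %/% L + 1L]
  ), class = c("window_grid", "data.frame"), width = as.integer(width), L = as.integer(L))
}

#' Pairwise linkage disequilibrium between two sites
#'
#' Standard two-locus measures from sample haplotype frequencies:
#' `D = p_ab - p_a p_b`, `r^2 = D^2 / (p_a(1-p_a) p_b(1-p_b))`, and
#' `|D'| = |D| / D_max` with `D_max = min(p_a p_b, (1-p_a)(1-p_b))` for
#' `D < 0` and `min(p_a(1-p_b), (1-p_a)p_b)` otherwise. Both statistics lie
#' in `[0, 1]`. The absolute value of D' is used throughout because derived
#' labels across paralogs carry no consistent sign.
#'
#' @param hapA,hapB logical/0-1 presence vectors of the derived allele at the
#'   two sites across the same haplotypes; both sites must be segregating.
#' @return named numeric vector `c(Dprime =, r2 =)`.
#' @export
#' @examples
#' pairwise_ld(c(1, 1, 0, 0), c(1, 1, 0, 0))  # perfect association: 1, 1
pairwise_ld <- function(hapA, hapB) {
  stopifnot(length(hapA) == length(hapB))
  a <- as.numeric(hapA); b <- as.numeric(hapB)
  pa <- mean(a); pb <- mean(b)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1)
    stop("pairwise_ld requires both sites to be segregating in the sample")
  D <- mean(a * b) - pa * pb
  dmax <- if (D < 0) min(pa * pb, (1 - pa) * (1 - pb)) else min(pa * (1 - pb), (1 - pa) * pb)
  dprime <- if (D == 0) 0 else abs(D) / dmax
  c(Dprime = dprime, r2 = D^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

# 2n x S 0/1 matrix of sample-segregating sites in chromosome coordinates
site_matrix <- function(sample) {
  stopifnot(inherits(sample, "recorded_sample"))
  L <- sample$L
  h <- sample$haps
  if (any(vapply(h$duplicated, is.null, TRUE)))
    stop("LD analysis requires every sampled chromosome to carry the duplication")
  n <- length(h$original)
  coords <- lapply(seq_len(n), function(i)
    c(h$original[[i]], L + h$singlecopy[[i]], 2L * L + h$duplicated[[i]]))
  pos <- sort(unique(unlist(coords)))
  X <- vapply(coords, function(p) pos %in% p, logical(length(pos)))
  X <- t(matrix(as.numeric(X), nrow = length(pos)))   # n x S
  keep <- colSums(X) > 0 & colSums(X) < n
  list(X = X[, keep, drop = FALSE], pos = pos[keep])
}

#' Window-pair LD matrix for one recording
#'
#' For every pair of 100-bp windows (diagonal included), averages `|D'|` and
#' `r^2` from [pairwise_ld()] over all pairs of sample-segregating sites with
#' one site in each window (distinct sites for the diagonal). Averaging per
#' window pair first makes the value independent of how many mutations fall
#' in a particular window. Pairs with no supporting site pair are missing
#' (`NA`), never imputed as 0.
#'
#' @param sample a `recorded_sample` in which every chromosome carries the
#'   duplication (e.g. the final recording at t = TT).
#' @param grid a [window_grid()]; its `L` must match the sample.
#' @return object of class `ld_matrix`: list with symmetric matrices
#'   `dprime`, `r2`, `support` (site-pair counts), `n_runs` (1 where
#'   supported), plus the grid.
#' @export
window_ld_matrix <- function(sample, grid = window_grid(sample$L)) {
  width <- attr(grid, "width")
  if (attr(grid, "L") != sample$L) stop("grid built for a different L")
  m <- nrow(grid)
  sm <- site_matrix(sample)
  X <- sm$X
  S <- ncol(X)
  dp_m <- matrix(NA_real_, m, m); r2_m <- matrix(NA_real_, m, m)
  sup <- matrix(0L, m, m)
  if (S >= 2L) {
    n <- nrow(X)
    p <- colMeans(X)
    P2 <- crossprod(X) / n
    D <- P2 - outer(p, p)
    v <- p * (1 - p)
    r2 <- D^2 / outer(v, v)
    dmax_neg <- pmin(outer(p, p), outer(1 - p, 1 - p))
    dmax_pos <- pmin(outer(p, 1 - p), outer(1 - p, p))
    dmax <- ifelse(D < 0, dmax_neg, dmax_pos)
    dp <- ifelse(D == 0, 0, abs(D) / dmax)
    w <- sm$pos %/% width + 1L
    uw <- sort(unique(w))
    idx <- split(seq_len(S), w)
    for (ai in seq_along(uw)) {
      for (bi in ai:length(uw)) {
        ia <- idx[[ai]]; ib <- idx[[bi]]
        if (uw[ai] == uw[bi]) {
          if (length(ia) < 2L) next
          sub <- upper.tri(matrix(0, length(ia), length(ia)))
          ns <- sum(sub)
          dval <- sum(dp[ia, ia][sub]) / ns
          rval <- sum(r2[ia, ia][sub]) / ns
        } else {
          ns <- length(ia) * length(ib)
          dval <- mean(dp[ia, ib])
          rval <- mean(r2[ia, ib])
        }
        a <- uw[ai]; b <- uw[bi]
        dp_m[a, b] <- dp_m[b, a] <- dval
        r2_m[a, b] <- r2_m[b, a] <- rval
        sup[a, b] <- sup[b, a] <- ns
      }
    }
  }
  structure(list(dprime = dp_m, r2 = r2_m, support = sup,
                 n_runs = matrix(as.integer(!is.na(dp_m)), m, m),
                 grid = grid, width = width, L = sample$L),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d windows of %d bp; %d supported pairs; runs averaged: %d\n",
              nrow(x$dprime), x$width, sum(!is.na(x$dprime[upper.tri(x$dprime, diag = TRUE)])),
              max(x$n_runs)))
  invisible(x)
}

#' Average LD matrices across runs
#'
#' Per-window-pair unweighted mean over the runs in which the pair is
#' supported; pairs missing in some runs are averaged over the remaining
#' ones, and the per-pair run counts are propagated in `n_runs`.
#'
#' @param matrices list of `ld_matrix` objects on identical grids.
#' @return an `ld_matrix`.
#' @export
average_ld_over_runs <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  base <- matrices[[1L]]
  for (mmat in matrices)
    if (!identical(dim(mmat$dprime), dim(base$dprime)) || mmat$width != base$width ||
        mmat$L != base$L)
      stop("LD matrices were computed on different grids")
  m <- nrow(base$dprime)
  acc_d <- matrix(0, m, m); acc_r <- matrix(0, m, m)
  nr <- matrix(0L, m, m); sup <- matrix(0L, m, m)
  for (mmat in matrices) {
    ok <- !is.na(mmat$dprime)
    acc_d[ok] <- acc_d[ok] + mmat$dprime[ok]
    acc_r[ok] <- acc_r[ok] + mmat$r2[ok]
    nr <- nr + mmat$n_runs
    sup <- sup + mmat$support
  }
  dp <- ifelse(nr > 0, acc_d / pmax(nr, 1L), NA_real_)
  r2 <- ifelse(nr > 0, acc_r / pmax(nr, 1L), NA_real_)
  structure(list(dprime = dp, r2 = r2, support = sup, n_runs = nr,
                 grid = base$grid, width = base$width, L = base$L),
            class = "ld_matrix")
}

#' LD between duplicates: the paralogous-window diagonal
#'
#' Extracts the pairs (original window i, duplicated window i) — the
#' diagonal that lights up when recurrent IGC keeps paralogs associated.
#'
#' @param matrix an `ld_matrix` over a 3-block grid.
#' @param stat `"dprime"` or `"r2"`.
#' @return data.frame with `window` (1..L/width), `start`, `value`,
#'   `support`, `n_runs`.
#' @export
between_duplicates_diagonal <- function(matrix, stat = c("dprime", "r2")) {
  stat <- match.arg(stat)
  m_per_block <- matrix$L %/% matrix$width
  i <- seq_len(m_per_block)
  j <- 2L * m_per_block + i
  data.frame(window = i, start = (i - 1L) * matrix$width,
             value = matrix[[stat]][cbind(i, j)],
             support = matrix$support[cbind(i, j)],
             n_runs = matrix$n_runs[cbind(i, j)])
}

#' Long-format export of an LD matrix
#'
#' @param matrix an `ld_matrix`.
#' @param keep_missing include unsupported pairs (default FALSE).
#' @return data.frame with window metadata and `mean_abs_Dprime`, `mean_r2`,
#'   `support_pairs`, `n_runs` for each unordered window pair.
#' @export
ld_matrix_to_df <- function(matrix, keep_missing = FALSE) {
  g <- matrix$grid
  m <- nrow(g)
  ut <- which(upper.tri(matrix$dprime, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(
    window_x_block = g$block[ut[, 1]], window_x_start = g$start[ut[, 1]],
    window_y_block = g$block[ut[, 2]], window_y_start = g$start[ut[, 2]],
    mean_abs_Dprime = matrix$dprime[ut], mean_r2 = matrix$r2[ut],
    support_pairs = matrix$support[ut], n_runs = matrix$n_runs[ut])
  if (!keep_missing) df <- df[!is.na(df$mean_abs_Dprime), , drop = FALSE]
  rownames(df) <- NULL
  df
}
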