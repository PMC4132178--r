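test_that("pairwise_ld matches hand-computed two-site cases", {
  # perfect association: haplotypes 11, 11, 00, 00
  expect_equal(pairwise_ld(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               c(Dprime = 1, r2 = 1))
  # independence at equal frequencies: 11, 10, 01, 00
  expect_equal(pairwise_ld(c(1, 1, 0, 0), c(1, 0, 1, 0)),
               c(Dprime = 0, r2 = 0))
  # a site against itself
  x <- c(1, 0, 1, 1, 0)
  expect_equal(unname(pairwise_ld(x, x)), c(1, 1))
  expect_error(pairwise_ld(c(1, 1), c(1, 0)), "segregating")
  # random cases against the naive oracle; range and r2 = 1 => |D'| = 1
  set.seed(113)
  for (i in 1:50) {
    n <- 20
    a <- rbinom(n, 1, 0.4); b <- rbinom(n, 1, 0.6)
    if (sum(a) %in% c(0, n) || sum(b) %in% c(0, n)) next
    got <- pairwise_ld(a, b)
    expect_equal(got, bf_ld(a, b))
    expect_true(all(got >= 0 & got <= 1))
    if (isTRUE(all.equal(got[["r2"]], 1))) expect_equal(got[["Dprime"]], 1)
  }
})

ld_sample <- function(haps_by_block, L) {
  n <- length(haps_by_block$original)
  dupsim:::new_recorded_sample(0L, haps_by_block$original,
                               haps_by_block$singlecopy,
                               haps_by_block$duplicated, L)
}

test_that("window LD matrices aggregate site pairs correctly", {
  L <- 500
  n <- 6
  empt <- replicate(n, integer(0), simplify = FALSE)
  # a single segregating site supports no pair at all
  one <- empt; one[[1]] <- 10L
  m1 <- window_ld_matrix(ld_sample(list(original = one, singlecopy = empt,
                                        duplicated = empt), L))
  expect_true(all(is.na(m1$dprime)))
  expect_true(all(m1$support == 0))
  # two perfectly associated sites in different windows
  two <- empt; two[[1]] <- c(10L, 150L); two[[2]] <- c(10L, 150L)
  m2 <- window_ld_matrix(ld_sample(list(original = two, singlecopy = empt,
                                        duplicated = empt), L))
  expect_equal(m2$dprime[1, 2], 1)
  expect_equal(m2$r2[1, 2], 1)
  expect_identical(m2$support[1, 2], 1L)
  expect_identical(m2$dprime[2, 1], m2$dprime[1, 2])
  # brute-force recomputation of every supported pair on a random sample
  set.seed(127)
  s <- random_sample_recording(n = 12, L = L, lambda_sites = 10)
  m <- window_ld_matrix(s)
  expect_identical(m$dprime, t(m$dprime))
  h <- s$haps
  coords <- lapply(seq_len(12), function(i)
    c(h$original[[i]], L + h$singlecopy[[i]], 2L * L + h$duplicated[[i]]))
  pos <- sort(unique(unlist(coords)))
  X <- sapply(coords, function(p) as.numeric(pos %in% p))
  keep <- rowSums(X) > 0 & rowSums(X) < 12
  X <- X[keep, , drop = FALSE]; pos <- pos[keep]
  w <- pos %/% 100 + 1
  for (a in unique(w)) for (b in unique(w)) if (a <= b) {
    ia <- which(w == a); ib <- which(w == b)
    vals <- c()
    for (i in ia) for (j in ib) if ((a != b && TRUE) || i < j)
      vals <- rbind(vals, bf_ld(X[i, ], X[j, ]))
    if (is.null(vals)) {
      expect_true(is.na(m$dprime[a, b]))
    } else {
      expect_equal(m$dprime[a, b], mean(vals[, "Dprime"]))
      expect_equal(m$r2[a, b], mean(vals[, "r2"]))
      expect_identical(m$support[a, b], nrow(vals))
    }
  }
  expect_true(all(m$dprime[!is.na(m$dprime)] >= 0 & m$dprime[!is.na(m$dprime)] <= 1))
  expect_true(all(m$r2[!is.na(m$r2)] >= 0 & m$r2[!is.na(m$r2)] <= 1))
})

test_that("cross-run averaging follows the missing-pair policy", {
  L <- 500
  set.seed(131)
  s1 <- random_sample_recording(12, L, 8)
  s2 <- random_sample_recording(12, L, 8)
  m1 <- window_ld_matrix(s1); m2 <- window_ld_matrix(s2)
  expect_equal(average_ld_over_runs(list(m1))$dprime, m1$dprime)
  avg <- average_ld_over_runs(list(m1, m2))
  both <- !is.na(m1$dprime) & !is.na(m2$dprime)
  expect_equal(avg$dprime[both], ((m1$dprime + m2$dprime) / 2)[both])
  only1 <- !is.na(m1$dprime) & is.na(m2$dprime)
  expect_equal(avg$dprime[only1], m1$dprime[only1])
  expect_true(all(avg$n_runs[only1] == 1))
  expect_true(all(avg$n_runs[both] == 2))
  expect_true(all(is.na(avg$dprime[is.na(m1$dprime) & is.na(m2$dprime)])))
  g2 <- window_grid(1000, 100)
  m_other <- window_ld_matrix(random_sample_recording(6, 1000, 5), g2)
  expect_error(average_ld_over_runs(list(m1, m_other)), "grids")
})

test_that("the between-duplicates diagonal picks paralogous windows", {
  g <- window_grid(5000, 100)
  expect_identical(nrow(g), 150L)
  expect_identical(unique(g$block), c("original", "singlecopy", "duplicated"))
  set.seed(137)
  s <- random_sample_recording(10, 5000, 40)
  m <- window_ld_matrix(s)
  d <- between_duplicates_diagonal(m)
  expect_identical(nrow(d), 50L)
  expect_equal(d$value, m$dprime[cbind(1:50, 101:150)])
  # long-format export mirrors the matrix
  df <- ld_matrix_to_df(m)
  expect_true(all(!is.na(df$mean_abs_Dprime)))
  i <- which(df$window_x_start == 0 & df$window_x_block == "original" &
               df$window_y_start == 0 & df$window_y_block == "duplicated")
  if (length(i) == 1) expect_equal(df$mean_abs_Dprime[i], m$dprime[1, 101])
})
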