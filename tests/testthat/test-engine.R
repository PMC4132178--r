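test_that("null dynamics leave the population genetically empty", {
  p <- tiny_params(theta = 0, C = 0, R = 0, seed = 3)
  for (eng in c("cpp", "r")) {
    res <- run_simulation(p, engine = eng)
    fin <- res$final_sample
    expect_true(all(lengths(fin$haps$original) == 0))
    expect_true(all(lengths(fin$haps$singlecopy) == 0))
    expect_identical(fin$n_carriers, 20L)  # duplication still fixes
    expect_identical(res$counters[["mutations"]], 0)
  }
})

test_that("runs are bit-identical under a fixed seed", {
  p <- tiny_params(seed = 11)
  a <- run_simulation(p)
  b <- run_simulation(p)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$counters, b$counters)
  r1 <- run_simulation(p, engine = "r")
  r2 <- run_simulation(p, engine = "r")
  expect_identical(r1$recordings, r2$recordings)
})

test_that("recordings appear every k generations with 2*n_sample haplotypes", {
  p <- tiny_params(seed = 13, n_sample = 7)
  res <- run_simulation(p)
  ts <- vapply(res$recordings, `[[`, 1, "t")
  expect_equal(ts, seq(p$k, p$TT, by = p$k))
  expect_true(all(vapply(res$recordings, function(r) length(r$haps$original), 1L) == 14L))
  expect_identical(res$diversity$t, as.integer(ts))
})

test_that("the duplication appears at t = T1 + 1 and fixes along the trajectory", {
  # k = 1 makes every generation a recording, so phase timing is observable
  p <- suppressWarnings(
    sim_params(N = 8, L = 500, theta = 0.005, C = 1, R = 5, lam = 20,
               k = 1, T1 = 30, T2max = 160, TT = 200, n_sample = 8, seed = 17))
  res <- suppressWarnings(run_simulation(p))
  ncar <- vapply(res$recordings, `[[`, 1L, "n_carriers")
  ts <- vapply(res$recordings, `[[`, 1, "t")
  expect_true(all(ncar[ts <= p$T1] == 0L))
  expect_identical(ncar[ts == p$T1 + 1], 1L)
  # with n_sample = N the recorded carrier counts ARE the trajectory
  idx <- ts > p$T1 & ts <= p$T1 + 1 + res$T2
  expect_identical(ncar[idx], res$trajectory[seq_len(sum(idx))])
  expect_true(all(ncar[ts > p$T1 + 1 + res$T2] == 16L))
  # founder starts as a perfect copy; at most the event generation's own
  # mutations (max one per block) can separate the paralogs
  expect_lte(res$diversity$pi_s[res$diversity$t == p$T1 + 1], 2)
})

test_that("burn-in-only runs never duplicate and stay two-block", {
  p <- tiny_params(T1 = 400, TT = 400, seed = 19)
  res <- run_simulation(p)
  expect_identical(res$T2, -1L)
  expect_identical(length(res$trajectory), 0L)
  expect_true(all(vapply(res$recordings, `[[`, 1L, "n_carriers") == 0L))
})

test_that("phase-length inconsistency is rejected", {
  # T2 >= 1 always, so T1 + 1 + T2 > TT is guaranteed here
  p <- suppressWarnings(tiny_params(T1 = 398, T2max = 350, TT = 400, seed = 2))
  expect_error(suppressWarnings(run_simulation(p, engine = "cpp")), "TT")
  expect_error(suppressWarnings(run_simulation(p, engine = "r")), "TT")
})

test_that("record_sample and prune_fixed behave on constructed populations", {
  set.seed(23)
  pop <- new_population(4, 100)
  pop$chroms <- replicate(8, random_chromosome(100, 5, three_blocks = TRUE),
                          simplify = FALSE)
  expect_error(record_sample(pop, 5), "n_sample")
  s <- record_sample(pop, 4)  # whole population
  expect_identical(length(s$haps$original), 8L)
  expect_setequal(
    vapply(s$haps$original, paste, "", collapse = ","),
    vapply(pop$chroms, function(ch) paste(ch[[1]], collapse = ","), ""))
  # fixed-everywhere in one paralog only: never erased
  pop$chroms <- lapply(pop$chroms, function(ch) {
    ch[[1]] <- sort(unique(c(ch[[1]], 7L)))            # fixed in original only
    ch[[2]] <- sort(unique(c(ch[[2]], 11L)))           # fixed in single-copy
    ch
  })
  pre <- vapply(seq_len(7), function(i)
    pairwise_diff(pop$chroms[[i]][[1]], pop$chroms[[i + 1]][[1]]), 1L)
  out <- prune_fixed(pop)
  expect_identical(out$erased$original, integer(0))
  expect_identical(out$erased$singlecopy, 11L)
  expect_true(all(vapply(out$pop$chroms, function(ch) 7L %in% ch[[1]], TRUE)))
  expect_false(any(vapply(out$pop$chroms, function(ch) 11L %in% ch[[2]], TRUE)))
  # fixed in both paralogs: erased from both, pi unchanged
  pop$chroms <- lapply(pop$chroms, function(ch) {
    ch[[3]] <- sort(unique(c(ch[[3]], 7L))); ch
  })
  pi_b_pre <- pi_between_paralogs(record_sample_all(pop))
  out2 <- prune_fixed(pop)
  expect_identical(out2$erased$original, 7L)
  expect_false(any(vapply(out2$pop$chroms, function(ch) 7L %in% ch[[1]], TRUE)))
  expect_equal(pi_between_paralogs(record_sample_all(out2$pop)), pi_b_pre)
  post <- vapply(seq_len(7), function(i)
    pairwise_diff(out2$pop$chroms[[i]][[1]], out2$pop$chroms[[i + 1]][[1]]), 1L)
  expect_identical(post, pre)
})

test_that("C++ and R engines draw final summaries from the same distribution", {
  p <- sim_params(N = 10, L = 500, theta = 0.01, C = 2, R = 10, lam = 20,
                  k = 10, T1 = 100, T2max = 200, TT = 300, n_sample = 10)
  stat <- function(engine, seeds) t(sapply(seeds, function(s) {
    p$seed <- s
    r <- suppressWarnings(run_simulation(p, engine = engine, stats_from = 200))
    d <- r$diversity
    c(pi_o = mean(d$pi_original), S = mean(d$S_original), pi_s = mean(d$pi_s))
  }))
  set.seed(201)
  A <- stat("cpp", sample.int(1e6, 40))
  B <- stat("r", sample.int(1e6, 40))
  for (col in colnames(A)) {
    ks <- suppressWarnings(stats::ks.test(A[, col], B[, col]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("per-block mutation counts follow the mu*L Bernoulli rate", {
  # theta only, no IGC/crossover: expected mutations = 3 blocks * 2N * muL per
  # generation post-fixation (2 blocks before); use burn-in only for exactness
  p <- tiny_params(theta = 0.02, C = 0, R = 0, T1 = 400, TT = 400, seed = 29)
  res <- run_simulation(p, prune = FALSE)  # all 2N chromosomes materialized
  muL <- derive_rates(p)$mu * p$L
  expected <- 2 * (2 * p$N) * muL * p$TT
  got <- res$counters[["mutations"]]
  expect_lt(abs(got - expected), 4 * sqrt(expected))
})
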