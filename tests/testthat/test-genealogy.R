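test_that("neutral parent assignment is uniform Wright-Fisher sampling", {
  set.seed(41)
  g <- assign_parents_neutral(1, 1)
  expect_true(all(g$parent %in% 1:2))
  # offspring numbers per parent ~ Binomial(2N, 1/2N); chi-square on pooled counts
  N <- 250; k <- 40
  g <- assign_parents_neutral(N, k)
  # offspring numbers per parent within each generation ~ Binomial(2N, 1/2N)
  per_gen <- unlist(lapply(seq_len(k), function(j) tabulate(g$parent[j, ], nbins = 2 * N)))
  obs <- tabulate(per_gen + 1L, nbins = 7)
  pexp <- dbinom(0:5, 2 * N, 1 / (2 * N))
  pexp <- c(pexp, 1 - sum(pexp))
  chi <- suppressWarnings(stats::chisq.test(c(obs[1:6], length(per_gen) - sum(obs[1:6])),
                                            p = pexp))
  expect_gt(chi$p.value, 0.001)
  # determinism under a fixed seed
  set.seed(99); g1 <- assign_parents_neutral(5, 7)
  set.seed(99); g2 <- assign_parents_neutral(5, 7)
  expect_identical(g1, g2)
})

test_that("structured assignment honors the carrier schedule exactly", {
  set.seed(43)
  # founding example: both generation-1 carriers descend from the unique founder
  base <- c(TRUE, rep(FALSE, 19))
  g <- assign_parents_structured(10, 2, c(1L, 2L), base)
  expect_identical(which(g$carrier[1, ]), 1L)
  car1 <- which(g$carrier[2, ])
  expect_length(car1, 1)
  expect_identical(g$parent[1, car1], 1L)
  car2 <- which(g$carrier[3, ])
  expect_length(car2, 2)
  expect_true(all(g$parent[2, car2] == car1))
  # random schedules: per-generation counts match exactly, carrier parents are carriers
  for (i in 1:60) {
    N <- 25; twoN <- 2 * N; k <- 6
    sched <- pmin(cumsum(c(1L, sample(0:8, k - 1, replace = TRUE))), twoN)
    base <- rep(FALSE, twoN); base[sample.int(twoN, 1)] <- TRUE
    g <- assign_parents_structured(N, k, sched, base)
    for (j in seq_len(k)) {
      expect_identical(sum(g$carrier[j + 1, ]), as.integer(sched[j]))
      car <- which(g$carrier[j + 1, ])
      non <- which(!g$carrier[j + 1, ])
      expect_true(all(g$carrier[j, g$parent[j, car]]))
      expect_true(all(!g$carrier[j, g$parent[j, non]]))
    }
  }
  expect_error(assign_parents_structured(5, 1, 3L, rep(FALSE, 10)),
               "upstream")
})

test_that("fixed-carrier schedule reduces to neutral assignment", {
  set.seed(47)
  N <- 30; twoN <- 60
  g <- assign_parents_structured(N, 5, rep(twoN, 5), rep(TRUE, twoN))
  expect_true(all(g$carrier))
  expect_true(all(g$parent >= 1 & g$parent <= twoN))
})

test_that("fertility tagging is closed under ancestry and partnership", {
  set.seed(53)
  # r = 0, k = 1: fertile base set is exactly the set of assigned parents
  g <- tag_fertile(assign_parents_neutral(10, 1), r = 0)
  expect_identical(which(g$fertile[1, ]), sort(unique(as.integer(g$parent[1, ]))))
  expect_true(all(g$fertile[2, ]))
  expect_false(any(g$partner_used))
  # r = 1 forces every fertile slot's parent AND partner fertile
  g1 <- tag_fertile(assign_parents_neutral(10, 4), r = 1)
  for (j in 1:4) {
    fert <- which(g1$fertile[j + 1, ])
    expect_true(all(g1$partner_used[j, fert]))
    pars <- g1$parent[j, fert]
    expect_true(all(g1$fertile[j, pars]))
    expect_true(all(g1$fertile[j, dupsim:::partner_slot(pars)]))
  }
  # closure property at intermediate r
  for (i in 1:20) {
    g <- tag_fertile(assign_parents_neutral(15, 8), r = 0.3)
    for (j in 1:8) {
      fert <- which(g$fertile[j + 1, ])
      expect_true(all(g$fertile[j, g$parent[j, fert]]))
      used <- fert[g$partner_used[j, fert]]
      expect_true(all(g$fertile[j, dupsim:::partner_slot(g$parent[j, used])]))
    }
  }
})

test_that("genealogy debug dump has one row per slot-generation", {
  set.seed(59)
  g <- tag_fertile(assign_parents_neutral(4, 3), 0.2)
  df <- genealogy_to_df(g)
  expect_identical(nrow(df), 4L * 8L)
  expect_true(all(is.na(df$parent[df$generation == 0])))
  expect_true(all(df$fertile[df$generation == 3]))
})
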