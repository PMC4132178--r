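test_that("tract lengths follow the geometric law with support l >= 1", {
  expect_identical(sample_tract_length(1, 10), rep(1L, 10))
  set.seed(61)
  l <- sample_tract_length(0.01, 2e5)
  expect_true(all(l >= 1))
  expect_lt(abs(mean(l == 1) - 0.01), 3 * sqrt(0.01 * 0.99 / 2e5))
  expect_lt(abs(mean(l) - 100), 3 * sd(l) / sqrt(length(l)))
})

test_that("crossover junctions fall in the model's allowed region", {
  L <- 5000
  set.seed(67)
  j_scc <- replicate(3000, choose_crossover_junction("SCC", 3, 3, NULL, L))
  expect_true(all(j_scc >= L & j_scc < 2 * L))
  # uniformity across deciles of the single-copy block
  chi <- suppressWarnings(stats::chisq.test(tabulate((j_scc - L) %/% 500 + 1, 10)))
  expect_gt(chi$p.value, 0.001)
  j_wrc <- replicate(2000, choose_crossover_junction("WRC", 3, 3, NULL, L))
  expect_true(all(j_wrc >= 0 & j_wrc < 3 * L))
  expect_gt(max(j_wrc), 2 * L)  # duplicated block reachable
  # mixed-length meioses use the shared length irrespective of model
  for (m in c("SCC", "WRC", "HSC")) {
    j <- replicate(500, choose_crossover_junction(m, 3, 2, rbind(c(12000, 14000)), L))
    expect_true(all(j >= 0 & j < 2 * L))
  }
  # hotspots confine junctions; union of several intervals is respected
  hot <- rbind(c(1000, 1500), c(9000, 9100))
  j_hsc <- replicate(2000, choose_crossover_junction("HSC", 3, 3, hot, L))
  expect_true(all((j_hsc >= 1000 & j_hsc < 1500) | (j_hsc >= 9000 & j_hsc < 9100)))
  expect_lt(abs(mean(j_hsc < 1500) - 500 / 600), 0.05)
  # two-block meiosis with a hotspot beyond the shared length falls back
  j2 <- replicate(200, choose_crossover_junction("HSC", 2, 2, rbind(c(11000, 12000)), L))
  expect_true(all(j2 >= 0 & j2 < 2 * L))
})

test_that("recombination splices partner and parent around the junction", {
  L <- 5000
  parent <- chromosome(10L, integer(0), integer(0))
  partner <- chromosome(20L, integer(0), integer(0))
  d <- recombine(parent, partner, 15L, L)
  expect_identical(d[[1]], integer(0))  # 10 is <= 15 (parent side excluded), 20 > 15 (partner side excluded)
  # junction at the last coordinate makes the daughter a copy of the partner
  a <- random_chromosome(L); b <- random_chromosome(L)
  expect_identical(unclass(recombine(a, b, 3L * L - 1L, L)), unclass(b))
  # mixed meiosis: 3-block daughter, duplicated block entirely from the parent
  p3 <- chromosome(c(5L, 4000L), c(100L), c(7L, 900L))
  p2 <- chromosome(c(6L), c(200L, 4999L))
  d <- recombine(p3, p2, 7000L, L)
  expect_identical(length(unclass(d)), 3L)
  expect_identical(d[[1]], 6L)             # coords <= 7000 come from the partner
  expect_identical(d[[2]], 200L)           # partner's 9999 and parent's 5100 both excluded
  expect_identical(d[[3]], c(7L, 900L))    # partner has no third block; coords > 7000
  expect_error(recombine(p3, p2, 11000L, L), "shared length")
  # conservation property, also pinning the C++ splice to the R one
  set.seed(71)
  for (i in 1:60) {
    nb <- sample(2:3, 1)
    a <- random_chromosome(L, 15, three_blocks = nb == 3)
    b <- random_chromosome(L, 15, three_blocks = nb == 3)
    j <- sample.int(nb * L, 1) - 1L
    d <- recombine(a, b, j, L)
    for (bl in seq_len(nb)) {
      off <- (bl - 1L) * L
      expect_identical(d[[bl]],
                       c(b[[bl]][off + b[[bl]] <= j], a[[bl]][off + a[[bl]] > j]))
      expect_identical(d[[bl]],
                       dupsim:::cpp_recombine_block(b[[bl]], a[[bl]], off, j))
      expect_sorted_unique(d[[bl]])
    }
  }
})

test_that("mutation respects the joint polymorphism registry", {
  L <- 200
  # exhaustion: every position occupied -> skip, never an error
  chrom <- chromosome(0:(L - 1), integer(0), integer(0))
  reg <- list(singlecopy_poly = integer(0), duplicate_poly = 0:(L - 1))
  set.seed(73)
  res <- replicate(50, sample_mutation(chrom, 1L, reg, mu = 1, L = L)$skipped)
  expect_true(all(res))
  # a variant in the original block blocks the same offset in the duplicated block
  chrom <- chromosome(integer(0), integer(0), integer(0))
  reg <- build_registry(list(chrom))
  set.seed(74)
  out <- sample_mutation(chrom, 1L, reg, mu = 1, L = L)
  p <- out$chrom[[1]]
  expect_true(p %in% out$registry$duplicate_poly)
  hits <- replicate(400, {
    r <- sample_mutation(out$chrom, 3L, out$registry, mu = 1, L = L)
    r$chrom[[3]]
  })
  expect_false(any(unlist(hits) == p))
  # Bernoulli rate: mutation count over many block-generations
  set.seed(79)
  muL <- 0.05
  n <- 4000
  got <- sum(replicate(n, sample_mutation(chrom, 2L, reg, mu = muL / L, L = L)$mutated))
  expect_lt(abs(got - n * muL), 3 * sqrt(n * muL * (1 - muL)))
})

test_that("IGC initiation counts, symmetry and tract clipping are correct", {
  L <- 500
  chrom <- random_chromosome(L)
  expect_identical(sample_igc_initiations(chrom, g = 0, L = L, q = 0.1), list())
  set.seed(83)
  g <- 0.002  # 2Lg = 2
  counts <- replicate(2000, length(sample_igc_initiations(chrom, g, L, q = 0.05)))
  lambda <- 2 * L * g
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 2000))
  ev <- unlist(replicate(400, sample_igc_initiations(chrom, 0.01, L, 0.05),
                         simplify = FALSE), recursive = FALSE)
  frac_orig <- mean(vapply(ev, function(e) e$junction_block == "original", TRUE))
  expect_lt(abs(frac_orig - 0.5), 3 * sqrt(0.25 / length(ev)))
  frac_dir <- mean(vapply(ev, function(e) e$direction == "orig_to_dup", TRUE))
  expect_lt(abs(frac_dir - 0.5), 3 * sqrt(0.25 / length(ev)))
  for (e in ev) {
    expect_gte(e$tract[1], 0); expect_lte(e$tract[2], L - 1)
    expect_lte(e$tract[1], e$junction_pos); expect_gte(e$tract[2], e$junction_pos)
  }
  # worked clip: junction 3, l = 9 -> floor(9/2) = 4 both sides, clipped to [0, 7]
  set.seed(84)
  hit <- list()
  for (i in 1:20000) {  # draw events until one initiates at offset 3 with l = 9
    ev <- sample_igc_initiations(chrom, 0.05, L, q = 0.11)
    hit <- Filter(function(e) e$junction_pos == 3L && e$l == 9L, ev)
    if (length(hit) > 0) break
  }
  expect_gt(length(hit), 0)
  expect_equal(hit[[1]]$tract, c(0, 7))
  expect_true(hit[[1]]$truncated)
})

test_that("IGC application is an exact copy-paste of the donor tract", {
  mk_event <- function(lo, hi, direction = "orig_to_dup")
    structure(list(junction_block = "original",
                   junction_pos = as.integer((lo + hi) %/% 2),
                   l = hi - lo + 1L, direction = direction,
                   tract = c(as.integer(lo), as.integer(hi)), truncated = FALSE),
              class = "igc_event")
  ch <- chromosome(c(10L, 20L), integer(0), 15L)
  out <- apply_igc(ch, mk_event(0, 30))
  expect_identical(out$chrom[[3]], c(10L, 20L))
  expect_identical(out$chrom[[1]], c(10L, 20L))  # donor untouched
  # idempotence and no-op on identical paralogs
  out2 <- apply_igc(out$chrom, mk_event(0, 30))
  expect_identical(out2$chrom, out$chrom)
  # conservation property over random states, both directions, R vs C++
  set.seed(89)
  L <- 300
  for (i in 1:80) {
    ch <- random_chromosome(L, 20)
    lo <- sample.int(L, 1) - 1L; hi <- min(L - 1L, lo + sample.int(60, 1))
    dir <- sample(c("orig_to_dup", "dup_to_orig"), 1)
    res <- apply_igc(ch, mk_event(lo, hi, dir))$chrom
    don <- if (dir == "orig_to_dup") 1L else 3L
    rec <- if (dir == "orig_to_dup") 3L else 1L
    in_tract <- function(x) x[x >= lo & x <= hi]
    out_tract <- function(x) x[x < lo | x > hi]
    expect_identical(res[[don]], ch[[don]])
    expect_identical(in_tract(res[[rec]]), in_tract(res[[don]]))
    expect_identical(out_tract(res[[rec]]), out_tract(ch[[rec]]))
    expect_identical(res[[rec]],
                     dupsim:::cpp_apply_igc_tract(ch[[rec]], ch[[don]], lo, hi))
    expect_sorted_unique(res[[rec]])
  }
  # identity threshold hook skips events between diverged paralogs
  ch <- chromosome(0:49, integer(0), 100:149)  # 100 differences over L=300
  skip <- apply_igc(ch, mk_event(0, 299), identity_threshold = 0.9, L = 300)
  expect_false(skip$applied)
  expect_identical(skip$chrom, ch)
  ok <- apply_igc(ch, mk_event(0, 299), identity_threshold = 0.5, L = 300)
  expect_true(ok$applied)
})
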