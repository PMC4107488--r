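test_that("synthetic library construction is seeded and additive", {
  d <- his_scan_design(1, "Q", "CAW")
  p <- build_synthetic_library(d, 2, seed = 3, unique = TRUE)
  expect_setequal(p$sequence, c("Q", "H"))
  expect_error(build_synthetic_library(d, 3, seed = 1, unique = TRUE),
               "diversity")
  d17 <- pab_library_design()
  p1 <- build_synthetic_library(d17, 500, seed = 9)
  p2 <- build_synthetic_library(d17, 500, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$log_affinity == 0))
  eff <- list(`9` = c(H = 2), `36` = c(H = 1.5))
  p3 <- build_synthetic_library(d17, 500, eff, seed = 9)
  mat <- do.call(rbind, strsplit(p3$sequence, ""))
  expected <- 2 * (mat[, which(d17$position == 9)] == "H") +
    1.5 * (mat[, which(d17$position == 36)] == "H")
  expect_equal(p3$log_affinity, unname(expected))
})

test_that("a strongly advantaged variant takes over the pool", {
  d <- his_scan_design(1, "Q", "CAW")
  pool <- data.frame(sequence = c("Q", "H"), log_affinity = c(0, 10),
                     count = c(500L, 500L))
  class(pool) <- c("variant_pool", class(pool))
  cfg <- panning_config(rounds = 5, pool_size = 1e4,
                        clones_sequenced = rep(50L, 6), seed = 4)
  run <- run_panning(pool, cfg)
  final <- run$pools[[6]]
  expect_gt(final$frequency[final$sequence == "H"], 0.9)
  expect_true(is.na(run$extinct_at))
})

test_that("fitter-variant frequency is non-decreasing in expectation", {
  pool <- data.frame(sequence = c("A", "B"), log_affinity = c(0, 1.5),
                     count = c(500L, 500L))
  class(pool) <- c("variant_pool", class(pool))
  traj <- sapply(1:100, function(s) {
    run <- run_panning(pool, panning_config(
      rounds = 3, pool_size = 5000, clones_sequenced = rep(30L, 4),
      seed = s))
    vapply(run$pools, function(p) {
      f <- p$frequency[p$sequence == "B"]
      if (length(f)) f else 0
    }, numeric(1))
  })
  means <- rowMeans(traj)
  expect_true(all(diff(means) > -0.01))
  expect_gt(means[4], means[1])
})

test_that("without selection, frequencies drift only by sampling noise", {
  d <- pab_library_design()
  pool <- build_synthetic_library(d, 200, seed = 2)
  cfg <- panning_config(rounds = 3, wash_survival = 1,
                        amplification_noise = 0, pool_size = 1e5,
                        capture_capacity = rep(1e5, 3),
                        clones_sequenced = rep(50L, 4), seed = 5)
  run <- run_panning(pool, cfg)
  f0 <- rep(1 / 200, 200)
  f3 <- run$pools[[4]]$frequency
  kl <- sum(f3 * log(f3 / f0[seq_along(f3)]))
  expect_lt(kl, 0.05)
})

test_that("sequencing the whole pool returns the pool itself", {
  d <- his_scan_design(1, "Q", "CAW")
  pool <- build_synthetic_library(d, 50, seed = 1)
  cfg <- panning_config(rounds = 1, pool_size = 100,
                        clones_sequenced = c(100L, 100L), seed = 2)
  run <- run_panning(pool, cfg)
  expect_equal(sort(run$samples[[1]]),
               sort(rep.int(run$pools[[1]]$sequence,
                            run$pools[[1]]$count)))
})

test_that("fixed seeds give byte-identical FASTA output", {
  d <- pab_library_design()
  pool <- build_synthetic_library(d, 1000, pab_effect_model(d), seed = 7)
  cfg <- panning_config(rounds = 2, clones_sequenced = c(20L, 20L, 20L),
                        pool_size = 1e4, seed = 8)
  d1 <- file.path(tempdir(), "fasta_a")
  d2 <- file.path(tempdir(), "fasta_b")
  write_round_fasta(run_panning(pool, cfg), d1)
  write_round_fasta(run_panning(pool, cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  back <- read_round_fasta(file.path(d1, list.files(d1)))
  expect_length(back, 3L)
  expect_length(back[[1]], 20L)
})

test_that("unique-sequence ratios report both rounding conventions", {
  tr <- unique_ratio_trajectory(list(
    paste0("s", 1:50),                          # all distinct
    c(rep("a", 29), paste0("u", 1:29)),          # 30 unique of 58
    c(rep("a", 76), paste0("u", 1:17))           # 18 unique of 93
  ))
  expect_equal(tr$percent, c(100.0, 51.7, 19.4))
  expect_equal(tr$percent_trunc, c(100.0, 51.7, 19.3))
  expect_equal(tr$unique, c(50L, 30L, 18L))
  expect_error(unique_ratio_trajectory(list(character(0))), "empty")
})

test_that("pool extinction is flagged, not an error", {
  pool <- data.frame(sequence = c("A", "B"), log_affinity = c(0, 0),
                     count = c(5L, 5L))
  class(pool) <- c("variant_pool", class(pool))
  cfg <- panning_config(rounds = 3, pool_size = 10, wash_survival = 0,
                        capture_capacity = rep(1L, 3),
                        clones_sequenced = rep(5L, 4), seed = 1)
  run <- run_panning(pool, cfg)
  expect_s3_class(run, "panning_run")
  expect_false(is.na(run$extinct_at))
  expect_lt(length(run$pools), cfg$rounds + 1L)
  pool$count <- c(0L, 0L)
  expect_error(run_panning(pool, cfg), "empty")
})
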