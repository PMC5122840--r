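toy_frame <- function(grs) {
  # frame with a prescribed GRS vector (single pseudo-SNP column; only the
  # grs ordering matters for recruitment)
  structure(list(genotypes = matrix(grs, ncol = 1), grs = grs,
                 frame_size = length(grs)),
            class = "sampling_frame")
}

test_that("frames have consistent shapes, GRS range and HWE composition", {
  set.seed(2)
  p <- draw_panel(20, c(0.2, 0.5), c(0.1, 0.2))
  fr <- build_frame(p, 10)
  expect_equal(fr$frame_size, 10L)
  expect_length(fr$grs, 10)
  expect_equal(fr$grs, compute_grs(fr$genotypes))

  fr2 <- build_frame(p, 10000)
  expect_true(all(fr2$grs >= 0 & fr2$grs <= 40))

  # homozygous-carrier count at the DPP frequency: q^2 N under HWE
  set.seed(3)
  single <- snp_panel(0.44, beta_int = log(0.68))
  fr3 <- build_frame(single, 31000)
  hom <- sum(fr3$genotypes[, 1] == 2)
  expected <- 31000 * 0.44^2
  se <- sqrt(31000 * 0.44^2 * (1 - 0.44^2))
  expect_lt(abs(hom - expected), 4 * se)
})

test_that("conventional recruitment is an unbiased simple random sample", {
  set.seed(4)
  p <- draw_panel(10, c(0.2, 0.5), c(0.1, 0.2))
  fr <- build_frame(p, 2000)

  co <- recruit_conventional(fr, 2000)
  expect_setequal(co$indices, seq_len(2000))

  means <- replicate(500, mean(recruit_conventional(fr, 200)$grs))
  # SRS without replacement: mean of cohort means matches the frame mean
  se <- sd(fr$grs) / sqrt(200) / sqrt(500)
  expect_lt(abs(mean(means) - mean(fr$grs)), 4 * se)

  expect_error(recruit_conventional(fr, 0), class = "gbr_infeasible_design")
  expect_error(recruit_conventional(fr, 2001), class = "gbr_infeasible_design")
})

test_that("GBR recall takes the extremes working inwards, deterministically", {
  fr <- toy_frame(c(1, 2, 3, 4, 5, 6))
  expect_setequal(recruit_gbr(fr, 2)$grs, c(1, 6))
  expect_setequal(recruit_gbr(fr, 4)$grs, c(1, 2, 5, 6))
  # odd n: the extra participant goes to the low tail
  co5 <- recruit_gbr(fr, 5)
  expect_equal(sum(co5$tail == "low"), 3)
  expect_setequal(co5$grs, c(1, 2, 3, 5, 6))
  # exhaustive recall equals the whole frame
  expect_setequal(recruit_gbr(fr, 6)$indices, seq_len(6))
  # deterministic and idempotent
  expect_identical(recruit_gbr(fr, 4), recruit_gbr(fr, 4))
  # ties broken by frame index
  fr_tie <- toy_frame(c(5, 1, 1, 5, 3, 3))
  expect_equal(recruit_gbr(fr_tie, 2)$indices, c(2L, 4L))
  expect_error(recruit_gbr(fr, 7), class = "gbr_infeasible_design")
})

test_that("single-SNP GBR recruits homozygotes before heterozygotes", {
  set.seed(5)
  single <- snp_panel(0.44, beta_int = log(0.68))
  fr <- build_frame(single, 5000)
  n_hom <- min(sum(fr$grs == 0), sum(fr$grs == 2)) * 2
  co <- recruit_gbr(fr, n_hom)
  expect_true(all(co$grs %in% c(0, 2)))
})

test_that("randomization is 1:1 overall and within GBR tails", {
  set.seed(6)
  p <- draw_panel(10, c(0.2, 0.5), c(0.1, 0.2))
  fr <- build_frame(p, 1000)

  co <- randomize_arms(recruit_conventional(fr, 100))
  expect_equal(sum(co$arm == 1), 50)

  co_odd <- randomize_arms(recruit_conventional(fr, 101))
  expect_lte(abs(sum(co_odd$arm == 1) - sum(co_odd$arm == 0)), 1)

  co_gbr <- randomize_arms(recruit_gbr(fr, 400))
  for (s in c("low", "high"))
    expect_equal(sum(co_gbr$arm == 1 & co_gbr$tail == s), 100)
})

test_that("GBR cohorts have at least the GRS variance of conventional ones", {
  set.seed(10)
  p <- draw_panel(20, c(0.2, 0.5), c(0.1, 0.2))
  for (i in 1:100) {
    fr <- build_frame(p, 500)
    v_gbr <- var(recruit_gbr(fr, 100)$grs)
    v_conv <- var(recruit_conventional(fr, 100)$grs)
    expect_gte(v_gbr, v_conv)
  }
})

test_that("larger frames yield a wider gap between the GBR tails", {
  set.seed(20)
  p <- draw_panel(20, c(0.2, 0.5), c(0.1, 0.2))
  gap <- function(frame_size, reps = 30) {
    mean(replicate(reps, {
      co <- recruit_gbr(build_frame(p, frame_size), 200)
      mean(co$grs[co$tail == "high"]) - mean(co$grs[co$tail == "low"])
    }))
  }
  gaps <- c(gap(500), gap(2000), gap(10000))
  expect_true(all(diff(gaps) > 0))
})

test_that("cohort export has the documented columns", {
  set.seed(8)
  p <- draw_panel(5, c(0.2, 0.5), c(0.1, 0.2))
  co <- randomize_arms(recruit_gbr(build_frame(p, 100), 20))
  d <- cohort_table(co)
  expect_named(d, c("id", "grs", "tail", "arm"))
  expect_equal(nrow(d), 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  cohort_table(co, path)
  expect_equal(read.delim(path), d)
})
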