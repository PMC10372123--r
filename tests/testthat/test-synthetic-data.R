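# Span-task design generator, mapping regimes, response simulation, cohort.

test_that("design satisfies the block/trial/set-size invariants", {
  for (cond in CONDITIONS[c(1, 3, 4)]) {
    d <- generate_design(cond, paste0("p_", cond), seed = 11)
    expect_equal(nrow(d), 120)
    expect_equal(unname(table(d$block)), rep(30L, 4), ignore_attr = TRUE)
    expect_equal(d$trial_overall, 30 * (d$block - 1) + d$trial_in_block)
    # opening sequence and per-block balance
    for (b in 1:4) {
      ss <- d$set_size[d$block == b]
      expect_equal(ss[1:5], 2:6)
      expect_equal(unname(table(ss)), rep(6L, 5), ignore_attr = TRUE)
    }
    expect_equal(d$dual_task[1], cond %in% c("constant_search",
                                             "blocked_search"))
  }
})

test_that("rotation sets: 28-degree spacing, disjoint same-shape pairs", {
  for (seed in 1:10) {
    d <- generate_design("constant", "p1", seed)
    rots <- lapply(1:4, function(b)
      sort(unique(unlist(d$stimulus_rotations[d$block == b]))))
    shapes <- sapply(1:4, function(b) d$shape_family[d$block == b][1])
    # shapes alternate in pairs (1,3) vs (2,4)
    expect_equal(shapes[1], shapes[3])
    expect_equal(shapes[2], shapes[4])
    expect_false(shapes[1] == shapes[2])
    for (b in 1:4) {
      r <- rots[[b]]
      expect_lte(length(r), 6)
      # consecutive presented angles of the block's 6-element set are
      # multiples of 28 degrees apart
      expect_true(all(round(diff(r) %% 28, 6) %in% c(0, 28)))
    }
    expect_length(intersect(rots[[1]], rots[[3]]), 0)
    expect_length(intersect(rots[[2]], rots[[4]]), 0)
  }
})

test_that("mapping regimes: constant fixed, blocked per block, random per trial", {
  rot <- 20 + 28 * 0:5
  m1 <- assign_mapping("constant", rot, 1, 1, 99)
  m2 <- assign_mapping("constant", rot, 3, 17, 12345)
  expect_identical(m1, m2)                # one canonical bijection everywhere
  expect_equal(sort(unname(m1)), 1:6)     # bijection
  expect_equal(unname(m1[as.character(sort(rot))]), 1:6)  # ccw order

  b1 <- assign_mapping("blocked", rot, 1, 1, 99)
  b1b <- assign_mapping("blocked", rot, 1, 25, 99)
  expect_identical(b1, b1b)               # fixed within a block
  across <- sapply(2:4, function(b)
    identical(assign_mapping("blocked", rot, b, 1, 99), b1))
  expect_false(all(across))               # new draw per block

  r1 <- assign_mapping("random", rot, 1, 1, 99)
  expect_equal(sort(unname(r1)), 1:6)
  diffs <- sapply(2:30, function(t)
    !identical(assign_mapping("random", rot, 1, t, 99), r1))
  expect_gt(mean(diffs), 0.9)             # fresh bijection per trial
})

test_that("random-mapping identical-pair count matches the combinatorial rate", {
  # chance two independent uniform bijections of 6 items agree is 1/720;
  # over C(120,2) pairs per participant the expected count is ~9.9
  rot <- 20 + 28 * 0:5
  n_pairs <- 0; n_ident <- 0
  for (seed in 1:8) {
    maps <- lapply(1:120, function(i)
      assign_mapping("random", rot, (i - 1) %/% 30 + 1, (i - 1) %% 30 + 1,
                     seed))
    keys <- sapply(maps, paste, collapse = ",")
    tab <- table(keys)
    n_ident <- n_ident + sum(choose(tab, 2))
    n_pairs <- n_pairs + choose(120, 2)
  }
  # binomial 99.9% band around n_pairs/720
  expn <- n_pairs / 720
  expect_gt(n_ident, expn - 3.3 * sqrt(expn))
  expect_lt(n_ident, expn + 3.3 * sqrt(expn))
})

test_that("simulated responses follow the generating psychometric model", {
  # 1e5 items at one set size: empirical accuracy within 3 SE of closed form
  des <- flat_design(120, 5)
  des <- des[rep(1:120, length.out = 25000), ]
  tr <- learning_trajectory(log(4), log(4), log(10), 3)  # flat trajectory
  rec <- simulate_responses(des, tr, "overall_1_120", seed = 21)
  p_true <- weibull_accuracy(5, 4, 3)
  se <- sqrt(p_true * (1 - p_true) / nrow(rec))
  expect_equal(nrow(rec), 25000 * 5)
  expect_lt(abs(mean(rec$correct) - p_true), 3 * se)
  # flat trajectory -> no trend in accuracy over trials
  sl <- glm(correct ~ trial_overall, binomial, data = rec)
  expect_lt(abs(summary(sl)$coefficients[2, "z value"]), 3)
})

test_that("generating threshold at a set size yields 50% accuracy there", {
  des <- flat_design(120, 4)
  des <- des[rep(1:120, 100), ]
  tr <- learning_trajectory(log(4), log(4), log(10), 2.5)
  rec <- simulate_responses(des, tr, "overall_1_120", seed = 5)
  se <- sqrt(0.25 / nrow(rec))
  expect_lt(abs(mean(rec$correct) - 0.5), 3 * se)
})

test_that("chance responder sits at the guessing floor, independent of set size", {
  des <- generate_design("random", "g1", 3)
  recs <- do.call(rbind, lapply(1:30, function(s) chance_responder(des, s)))
  p <- mean(recs$correct)
  se <- sqrt((1 / 6) * (5 / 6) / nrow(recs))
  expect_lt(abs(p - 1 / 6), 4 * se)
  # accuracy unrelated to set size (chi-square independence oracle)
  tab <- table(recs$set_size, recs$correct)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("cohort generation: sizes, determinism, zero-SD degeneracy", {
  cfg <- cohort_config(n = c(constant = 2L, blocked = 2L), seed = 31)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1$records, coh2$records)   # same seed, same bytes
  expect_identical(coh1$truth, coh2$truth)
  expect_equal(nrow(coh1$truth), 4)
  expect_silent(validate_trial_table(coh1$records))
  # zero random-effect SDs collapse a condition onto its fixed effects
  cfg0 <- cohort_config(n = c(constant = 3L), re_sd = c(0, 0, 0), seed = 8)
  t0 <- generate_cohort(cfg0)$truth
  expect_equal(length(unique(t0$log_start)), 1)
  expect_equal(length(unique(t0$log_asym)), 1)
  # default configuration reproduces the five-condition cohort of 151
  cfg_full <- cohort_config()
  expect_equal(sum(cfg_full$n), 151)
  expect_equal(unname(cfg_full$n),
               c(31L, 31L, 30L, 30L, 29L), ignore_attr = TRUE)
})

test_that("within-block generation uses the block schedule", {
  sch <- block_schedule(learning_trajectory(log(3), log(3), log(8), 3),
                        total_delta = c(-2, 0, 0))  # block 1 starts far lower
  des <- flat_design(120, 4)
  des <- des[rep(1:120, 50), ]
  rec <- simulate_responses(des, sch, "within_block_1_30", seed = 9)
  # block 1 start is exp(log3 - 2): far lower accuracy early in block 1
  early <- rec$trial_in_block <= 3
  acc_b1 <- mean(rec$correct[rec$block == 1 & early])
  acc_b4 <- mean(rec$correct[rec$block == 4 & early])
  expect_lt(acc_b1, acc_b4 - 0.05)
})
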