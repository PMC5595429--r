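test_that("cohort simulation is deterministic and matches the design counts", {
  cfg <- sim_config(seed = 13)
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh1, coh2)

  expect_equal(nrow(coh1$groups), 37)
  expect_equal(nrow(coh1$trials), 37 * (180 + 120 + 120))
  counts <- table(coh1$trials$task, coh1$trials$item_class)
  expect_equal(unname(counts["ROC", "target"]), 37 * 120)
  expect_equal(unname(counts["ROC", "distractor"]), 37 * 60)
  expect_equal(unname(counts["PDP", "intact"]), 37 * 40)
  expect_equal(unname(counts["RKG", "target"]), 37 * 60)
  expect_equal(sum(coh1$groups$subgroup == "dMTT"), 7)
  expect_equal(sum(coh1$groups$subgroup == "iMTT"), 5)

  # byte-identical CSV output at a fixed seed
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_trials(coh1$trials, f1)
  write_trials(simulate_cohort(cfg)$trials, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("latent draws respect the configured distributions", {
  cfg <- sim_config()
  # zero spread pins the latents at the group means
  cfg0 <- cfg
  for (g in names(cfg0$groups)) {
    cfg0$groups[[g]]$rho_sd <- 0
    cfg0$groups[[g]]$delta_sd <- 0
    cfg0$groups[[g]]$criteria_shift_sd <- 0
    cfg0$groups[[g]]$yes_criterion_sd <- 0
  }
  set.seed(1)
  lat <- draw_subject("control", cfg0)
  expect_equal(lat$rho, cfg$groups$control$rho_mean)
  expect_equal(lat$delta, cfg$groups$control$delta_mean)
  expect_equal(lat$criteria_roc, cfg$groups$control$criteria)

  # same seed, same draw
  set.seed(7)
  l1 <- draw_subject("patient", cfg)
  set.seed(7)
  l2 <- draw_subject("patient", cfg)
  expect_identical(l1, l2)

  # sample mean of rho near the configured mean
  set.seed(2)
  rhos <- replicate(10000, draw_subject("control", cfg)$rho)
  expect_equal(mean(rhos), cfg$groups$control$rho_mean, tolerance = 0.01)

  expect_error(draw_subject("martian", cfg), "unknown group")
})

test_that("task simulators honor the latent corner cases", {
  cfg <- sim_config()
  set.seed(3)
  roc <- simulate_roc_trials(fixed_latents(rho = 1, delta = 1), cfg)
  expect_true(all(roc$confidence[roc$item_class == "target"] == 6L))

  set.seed(3)
  rkg <- simulate_rkg_trials(fixed_latents(rho = 1, delta = 1), cfg)
  tg <- rkg[rkg$item_class == "target", ]
  expect_true(all(tg$response == "yes" & tg$attribution == "R"))

  set.seed(3)
  rkg0 <- simulate_rkg_trials(fixed_latents(0.4, 1, guess_rate = 0), cfg)
  expect_false(any(rkg0$attribution %in% "G"))

  # recollection vetoes recombined pairs: rho = 1 gives no "yes" there
  set.seed(3)
  pdp <- simulate_pdp_trials(fixed_latents(rho = 1, delta = 1), cfg)
  expect_true(all(pdp$response[pdp$item_class == "intact"] == "yes"))
  expect_true(all(pdp$response[pdp$item_class == "recombined"] == "no"))
})

test_that("estimators recover the generating latents from large simulated samples", {
  lat <- fixed_latents(rho = 0.4, delta = 1.0)
  big <- sim_config()
  big$design <- list(roc = c(targets = 10000L, distractors = 10000L),
                     pdp = c(intact = 10000L, recombined = 10000L,
                             new = 10000L),
                     rkg = c(targets = 10000L, distractors = 10000L))

  set.seed(17)
  roc <- simulate_roc_trials(lat, big)
  old <- tabulate(roc$confidence[roc$item_class == "target"], 6)
  new <- tabulate(roc$confidence[roc$item_class == "distractor"], 6)
  fit <- fit_dpsd(old, new)
  # 3-SD sampling bands at 10,000 items per row
  expect_lt(abs(fit$R - lat$rho), 0.06)
  expect_lt(abs(fit$d_f - lat$delta), 0.12)

  set.seed(18)
  pdp <- simulate_pdp_trials(lat, big)
  yes <- tapply(pdp$response == "yes", pdp$item_class, sum)
  pi <- pdp_indices(yes[["intact"]], yes[["recombined"]], yes[["new"]],
                    10000, 10000, 10000)
  expect_lt(abs(pi$R_pdp - lat$rho), 0.05)
  expect_lt(abs(pi$F_pdp - pnorm(lat$delta - lat$yes_criterion)), 0.05)

  set.seed(19)
  rkg <- simulate_rkg_trials(lat, big)
  rows <- rkg_rows_from_trials(rkg)
  ri <- rkg_indices(rows$old, rows$new)
  expect_lt(abs(ri$R_rkg - lat$rho), 0.05)
  expect_lt(abs(ri$F_rkg - lat$delta), 0.1)
})

test_that("expected indices increase with the generating process strengths", {
  big <- sim_config()
  big$design <- list(roc = c(targets = 20000L, distractors = 20000L),
                     pdp = c(intact = 20000L, recombined = 20000L,
                             new = 20000L),
                     rkg = c(targets = 20000L, distractors = 20000L))
  score_one <- function(rho, delta, seed) {
    set.seed(seed)
    lat <- fixed_latents(rho, delta)
    trials <- rbind(simulate_roc_trials(lat, big),
                    simulate_pdp_trials(lat, big),
                    simulate_rkg_trials(lat, big))
    score_subjects(trials)
  }
  lo <- score_one(0.2, 0.8, 31)
  hi_r <- score_one(0.5, 0.8, 31)
  hi_f <- score_one(0.2, 1.6, 31)
  expect_true(all(hi_r$R_index > lo$R_index))
  expect_true(all(hi_f$F_index > lo$F_index))
})
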