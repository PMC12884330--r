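mk_events <- function(stim, release = "UVR", sync = "synchronous") {
  data.frame(stim_index = stim,
             label_release = rep_len(release, length(stim)),
             label_sync = rep_len(sync, length(stim)))
}

test_that("release probabilities follow the stimulus-based definition", {
  ev <- mk_events(1:100)
  pr <- release_probability(ev, 200)
  expect_equal(pr$pr_overall, 0.5)
  expect_equal(pr$pr_uvr, 0.5)
  expect_equal(pr$pr_mvr, 0)

  empty <- release_probability(mk_events(integer(0)), 200)
  expect_true(all(unlist(empty) == 0))

  expect_error(release_probability(mk_events(201), 200), "stimulus index")

  ## a stimulus with both a synchronous and an asynchronous event
  ## counts once in pr_overall
  both <- mk_events(c(1, 1), sync = c("synchronous", "asynchronous"))
  pr2 <- release_probability(both, 10)
  expect_equal(pr2$pr_overall, 0.1)
  expect_equal(pr2$pr_async, 0.1)
})

test_that("mean + 2 SD rule matches direct arithmetic", {
  amps <- c(rep(1, 9), 3)
  lab <- classify_mvr_per_event(amps)
  expect_equal(attr(lab, "threshold"), mean(amps) + 2 * sd(amps))
  expect_equal(sum(lab == "MVR"), 1L)
  expect_equal(which(lab == "MVR"), 10L)

  allsame <- classify_mvr_per_event(rep(2, 20))
  expect_equal(sum(allsame == "MVR"), 0L)   # threshold = mean, strict >

  expect_warning(single <- classify_mvr_per_event(1.5), "fewer than 2")
  expect_true(attr(single, "degenerate"))
})

test_that("classified MVR fraction tracks ground truth", {
  cfg <- default_cfg(n_synapses = 40, seed = 21)
  ds <- simulate_dataset(cfg)
  ev <- ds$events[ds$events$label_sync == "synchronous", ]
  labs <- unlist(lapply(split(ev$amplitude, ev$synapse_id),
                        classify_mvr_per_event), use.names = FALSE)
  expect_lt(abs(mean(labs == "MVR") - cfg$p_mvr), 0.03)
})

test_that("bi-Gaussian histogram fit recovers a known mixture", {
  set.seed(31)
  x <- c(rnorm(2500, 1, 0.1), rnorm(2500, 2, 0.1))
  fit <- fit_bi_gaussian_histogram(x, bin_width = 0.1)
  expect_true(fit$fit_ok)
  expect_lt(abs(fit$proportion2 - 0.5), 0.05)
  expect_lt(abs(fit$mu2 / fit$mu1 - 2), 0.1)
  expect_false(fit$crosscheck_flag)

  ## tau-like 80/20 mixture
  set.seed(32)
  tau <- c(rnorm(4000, 0.5, 0.05), rnorm(1000, 0.1, 0.02))
  tf <- fit_bi_gaussian_histogram(tau, bin_width = 0.05)
  expect_lt(abs(tf$area1 / (tf$area1 + tf$area2) - 0.2), 0.05)

  expect_error(fit_bi_gaussian_histogram(rnorm(20), 0.1), "at least 50")
})

test_that("single-component data degenerates gracefully", {
  set.seed(33)
  fit <- fit_bi_gaussian_histogram(rnorm(3000, 1, 0.1), bin_width = 0.05)
  minor <- min(fit$proportion2, 1 - fit$proportion2)
  expect_true(!fit$fit_ok || minor < 0.1 || fit$crosscheck_flag ||
                abs(fit$mu1 - fit$mu2) < 0.2)
})

test_that("ultrafast ratio is the small-mean area fraction", {
  mk <- function(a1, a2) structure(
    list(mu1 = 0.1, mu2 = 0.5, sd1 = 0.02, sd2 = 0.05,
         area1 = a1, area2 = a2, proportion2 = a2 / (a1 + a2),
         fit_ok = TRUE), class = "mixture_fit")
  expect_equal(ultrafast_ratio(mk(1, 1)), 0.5)
  expect_equal(ultrafast_ratio(mk(1, 4)), 0.2)
  expect_error(ultrafast_ratio(mk(0, 0)), "zero")
})

test_that("amplitude decomposition recovers a 20% MVR mixture", {
  cfg <- default_cfg(p_mvr = 0.2, q_cv = 0.1)
  set.seed(34)
  kin <- sample_event_kinetics(runif(5000) < cfg$p_mvr, cfg)
  dec <- amplitude_decomposition(kin$amplitude)
  expect_lt(abs(dec$q2 / dec$q1 - 2), 0.2)
  expect_lt(abs(dec$mvr_proportion - 0.2), 0.05)
  ## at 20% MVR the single-pass mean + 2 SD rule saturates (the MVR
  ## events inflate their own threshold) and undercounts relative to
  ## the mixture decomposition
  expect_lt(dec$mvr_proportion_rule, dec$mvr_proportion)
})

test_that("the two MVR estimators agree at the default composition", {
  cfg <- default_cfg()   # p_mvr = 0.1, q_cv = 0.1
  set.seed(39)
  kin <- sample_event_kinetics(runif(5000) < cfg$p_mvr, cfg)
  dec <- amplitude_decomposition(kin$amplitude)
  expect_lt(abs(dec$mvr_proportion - dec$mvr_proportion_rule), 0.05)
  expect_true(dec$methods_agree)
})

test_that("p_mvr = 0 data yields a degenerate MVR component", {
  cfg <- default_cfg(p_mvr = 0)
  set.seed(35)
  kin <- sample_event_kinetics(rep(FALSE, 4000), cfg)
  dec <- amplitude_decomposition(kin$amplitude)
  expect_true(dec$mvr_proportion <= 0.02 || dec$mixture$crosscheck_flag)
})

test_that("synchronicity labels use the post-stimulus window", {
  stims <- 0:9
  expect_equal(classify_synchronicity(2.05, stims), "synchronous")
  expect_equal(classify_synchronicity(2.40, stims), "asynchronous")
  expect_error(classify_synchronicity(-0.5, stims), "before the first")

  cfg <- default_cfg(n_synapses = 10, seed = 36)
  ds <- simulate_dataset(cfg)
  lab <- classify_synchronicity(ds$events$t_s,
                                (seq_len(cfg$n_stimuli) - 1) *
                                  cfg$stim_interval_s)
  expect_gte(mean(lab == ds$events$label_sync), 0.99)
})

test_that("summaries reconcile counts and ignore event order", {
  cfg <- default_cfg(n_synapses = 6, seed = 37)
  ds <- simulate_dataset(cfg)
  s <- summarize_synapses(ds$events, cfg$n_stimuli)
  ## counts reconcile exactly: UVR + MVR + async = total events
  n_uvr <- sum(ds$events$label_release == "UVR" &
                 ds$events$label_sync == "synchronous")
  n_mvr <- sum(ds$events$label_release == "MVR" &
                 ds$events$label_sync == "synchronous")
  n_async <- sum(ds$events$label_sync == "asynchronous")
  expect_equal(n_uvr + n_mvr + n_async, nrow(ds$events))
  expect_equal(sum(s$n_events), nrow(ds$events))
  expect_true(all(s$pr_overall >= 0 & s$pr_overall <= 1))

  set.seed(38)
  shuffled <- ds$events[sample(nrow(ds$events)), ]
  s2 <- summarize_synapses(shuffled, cfg$n_stimuli)
  expect_equal(s, s2)
})
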