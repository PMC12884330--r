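test_that("release-site layouts respect the disc and the separation", {
  cfg1 <- default_cfg(n_sites = 1)
  set.seed(1)
  l1 <- sample_synapse_layout(cfg1)
  expect_equal(nrow(l1$sites), 1L)

  cfg2 <- default_cfg(n_sites = 2, az_radius_nm = 150,
                      site_min_sep_nm = 60)
  for (i in 1:20) {
    l <- sample_synapse_layout(cfg2)
    expect_gte(as.numeric(dist(l$sites)), 60)
    expect_true(all(sqrt(rowSums(l$sites^2)) <= 150 + 1e-9))
  }
})

test_that("infeasible packings raise a configuration error", {
  cfg <- default_cfg(n_sites = 50, az_radius_nm = 60,
                     site_min_sep_nm = 60)
  set.seed(2)
  expect_error(sample_synapse_layout(cfg, max_retries = 200),
               "infeasible")
})

test_that("event schedules follow the stated per-stimulus model", {
  set.seed(3)
  l <- sample_synapse_layout(default_cfg())

  empty <- sample_event_schedule(default_cfg(pr_true = 0, p_async = 0), l)
  expect_equal(nrow(empty), 0L)

  all_rel <- sample_event_schedule(default_cfg(pr_true = 1, p_mvr = 0,
                                               p_async = 0), l)
  expect_equal(nrow(all_rel), 200L)
  expect_true(all(!all_rel$is_mvr))
  expect_true(all(all_rel$synchronous))
  expect_equal(all_rel$stim_index, 1:200)
})

test_that("synchronous event counts match the binomial expectation", {
  ## oracle: E[count] = n_stimuli * pr_true, SE from the binomial
  cfg <- default_cfg(pr_true = 0.3, p_async = 0)
  set.seed(4)
  l <- sample_synapse_layout(cfg)
  n_rep <- 300
  counts <- vapply(seq_len(n_rep), function(i)
    nrow(sample_event_schedule(cfg, l)), 0L)
  se <- sqrt(200 * 0.3 * 0.7 / n_rep)
  expect_lt(abs(mean(counts) - 60), 3 * se)
})

test_that("asynchronous latencies stay in the stated window", {
  cfg <- default_cfg(pr_true = 0, p_async = 1)
  set.seed(5)
  sched <- sample_event_schedule(cfg, sample_synapse_layout(cfg))
  expect_true(all(!sched$synchronous))
  expect_true(all(sched$latency_s >= 0.1 & sched$latency_s <= 0.9))
})

test_that("kinetic sampling honors quantal content and categories", {
  set.seed(6)
  mvr2 <- sample_event_kinetics(rep(TRUE, 5), default_cfg(q_cv = 0))
  expect_equal(mvr2$amplitude, rep(2, 5))

  quantal_only <- default_cfg(p_retrieval = c(0, 1, 0, 0))
  kin <- sample_event_kinetics(rep(FALSE, 500), quantal_only)
  expect_true(all(kin$fraction >= 0.8 & kin$fraction <= 1.2))
  expect_true(all(kin$category == "quantal"))
})

test_that("category frequencies match the multinomial oracle", {
  ## oracle: multinomial SE = sqrt(p (1 - p) / n) per category
  cfg <- default_cfg()
  set.seed(7)
  kin <- sample_event_kinetics(rep(FALSE, 10000), cfg)
  p <- c(partial = 0.35, quantal = 0.38, excessive = 0.24, none = 0.03)
  freq <- prop.table(table(kin$category))[names(p)]
  for (nm in names(p))
    expect_lt(abs(freq[[nm]] - p[[nm]]), 3 * sqrt(p[[nm]] * (1 - p[[nm]]) / 10000))
})

test_that("generated fractions always lie in their category interval", {
  set.seed(8)
  kin <- sample_event_kinetics(runif(2000) < 0.3, default_cfg())
  iv <- list(partial = c(0.3, 0.8), quantal = c(0.8, 1.2),
             excessive = c(1.2, 1.6))
  for (nm in names(iv)) {
    f <- kin$fraction[kin$category == nm]
    expect_true(all(f >= iv[[nm]][1] & f <= iv[[nm]][2]))
  }
  expect_true(all(kin$fraction[kin$category == "none"] == 0))
  expect_true(all(kin$f_model[kin$category == "none"] == 0))
})

test_that("trace synthesis matches the closed-form model", {
  cfg <- default_cfg()
  tr <- noiseless_trace(A = 1, dwell = 0, tau = 0.1, f = 1)
  at <- function(trace, t) trace$values[which.min(abs(trace$t_s - t))]
  expect_equal(at(tr, 0.1), exp(-1), tolerance = 1e-12)

  tr2 <- noiseless_trace(A = 1, dwell = 0, tau = 0.05, f = 1.4)
  expect_equal(at(tr2, 1.0), 1 - 1.4, tolerance = 1e-8)

  tr3 <- noiseless_trace(A = 1, dwell = 0, tau = 0.5, f = 0.5)
  expect_equal(at(tr3, 1.0), 0.5 + 0.5 * exp(-2), tolerance = 1e-12)

  expect_true(all(tr$values[tr$t_s < 0] == 0))
  expect_error(synthesize_trace(1, 0, 0.1, 1, cfg, post_s = 0.6),
               "at least 1 s")
  expect_error(synthesize_trace(0, 0, 0.1, 1, cfg), "amplitude")
  expect_error(synthesize_trace(1, 1.2, 0.1, 1, cfg), "dwell")
})

test_that("simulate_dataset is deterministic and conserves counts", {
  cfg <- default_cfg(n_synapses = 3, seed = 11)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$traces, d2$traces)
  expect_identical(d1$truth, d2$truth)

  d3 <- simulate_dataset(default_cfg(n_synapses = 3, seed = 12))
  expect_false(identical(d1$events, d3$events))

  expect_equal(nrow(d1$events), nrow(d1$truth))
  expect_equal(nrow(d1$events), nrow(d1$traces))
})

test_that("adding synapses does not perturb earlier ones", {
  a <- simulate_dataset(default_cfg(n_synapses = 2, seed = 13))
  b <- simulate_dataset(default_cfg(n_synapses = 4, seed = 13))
  first2 <- b$events[b$events$synapse_id <= 2, ]
  rownames(first2) <- NULL
  expect_identical(a$events, first2)
})

test_that("per-synapse release rates recover pr_true", {
  ## binomial oracle over 60 synapses x 200 stimuli
  cfg <- default_cfg(n_synapses = 60, seed = 14)
  ds <- simulate_dataset(cfg)
  s <- summarize_synapses(ds$events, cfg$n_stimuli)
  se <- sqrt(0.3 * 0.7 / (60 * 200))
  expect_lt(abs(mean(s$pr_overall) - 0.3), 3 * se + 0.01)
})

test_that("condition maps are monotone along the dose ladders", {
  cfg <- default_cfg()
  expect_equal(unclass(apply_condition_map(cfg, "control")),
               unclass(cfg))
  expect_error(apply_condition_map(cfg, "nonsense"), "registered")

  ladder <- c("control", "mbcd_0.1mM", "mbcd_1mM", "mbcd_2.5mM",
              "mbcd_5mM", "mbcd_10mM")
  cfgs <- lapply(ladder, apply_condition_map, config = cfg)
  p_mvr <- vapply(cfgs, `[[`, 0.0, "p_mvr")
  p_uf <- vapply(cfgs, `[[`, 0.0, "p_ultrafast")
  expect_true(all(diff(p_mvr) < 0))
  expect_true(all(diff(p_uf) > 0))

  wsc <- vapply(c("control", "wsc_0.1mgml", "wsc_0.5mgml", "wsc_1mgml"),
                function(cc) apply_condition_map(cfg, cc)$p_mvr, 0.0)
  expect_true(all(diff(wsc) > 0))

  ## >14-fold MVR suppression at the top of the ladder
  expect_gt(cfg$p_mvr / p_mvr[6], 14)

  ## LDL rescue for the transporter block, none for the NPC1 block
  expect_equal(apply_condition_map(cfg, "probucol_valspodar_ldl")$p_mvr,
               cfg$p_mvr)
  expect_equal(apply_condition_map(cfg, "u18666a_ldl")$p_mvr,
               apply_condition_map(cfg, "u18666a")$p_mvr)

  for (cc in list_conditions())
    expect_equal(sum(apply_condition_map(cfg, cc)$p_retrieval), 1,
                 tolerance = 1e-12)
})

test_that("train responses superpose and scale with pr_true", {
  flat <- simulate_train_response(default_cfg(pr_true = 0, n_synapses = 5),
                                  40, 50)
  expect_true(all(flat$dff == 0))

  peaks <- vapply(c(0.1, 0.3, 0.6, 0.9), function(p)
    train_peak_amplitude(simulate_train_response(
      default_cfg(pr_true = p, n_synapses = 20, seed = 15), 40, 50)), 0.0)
  expect_true(all(diff(peaks) > 0))   # common random numbers
})
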