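test_that("trial segmentation implements the protocol windows and exclusions", {
  seg <- segment_trial(45, 100)
  vm <- seg[seg$phase == "vm_analysis", ]
  expect_equal(c(vm$start_idx, vm$end_idx), c(2000, 3000))
  r1 <- seg[seg$phase == "rest1", ]
  expect_equal(c(r1$start_s, r1$end_s), c(0, 15))
  seg1k <- segment_trial(45, 1000)
  expect_equal(seg1k$end_idx[seg1k$phase == "rest1"], 15000)
  r2 <- seg[seg$phase == "rest2_analysis", ]
  expect_equal(c(r2$start_s, r2$end_s), c(40, 45))
  # exclusion arithmetic: analysis windows drop 5 s of VM, 10 s of late rest
  expect_equal(vm$start_s - seg$start_s[seg$phase == "vm_full"], 5)
  expect_equal(r2$start_s - seg$start_s[seg$phase == "rest2_full"], 10)
  expect_error(segment_trial(44, 100), class = "nicp_error_input")
})

test_that("RMSE metric: identity, symmetry, constant offset", {
  x <- waveform(10 + sin(seq(0.01, 20, by = 0.01)), fs = 100, units = "mmHg")
  expect_equal(icp_rmse(x, x), 0)
  y <- waveform(x$value + 1, fs = 100, units = "mmHg")
  expect_equal(icp_rmse(y, x), 1, tolerance = 1e-9)
  expect_equal(icp_rmse(x, y), icp_rmse(y, x))
  z <- waveform(x$value + c(0, 0, 2, 0), fs = 100, units = "mmHg") # 2000 samples
  expect_equal(icp_rmse(z, x), sqrt(mean(c(0, 0, 2, 0)^2)), tolerance = 1e-6)
  far <- waveform(rep(1, 100), fs = 100, t0 = 1e4)
  expect_error(icp_rmse(x, far), class = "nicp_error_input")
})

test_that("phase means average the configured windows", {
  seg <- segment_trial(45, 100)
  const <- waveform(rep(7, 4500), fs = 100, units = "mmHg")
  pm <- phase_means(const, seg)
  expect_equal(unlist(pm), c(rest_mean = 7, vm_mean = 7, rest2_mean = 7))
  tt <- seq(0, 45 - 0.01, by = 0.01)
  stepped <- waveform(ifelse(tt >= 20 & tt < 30, 15, 10), fs = 100, units = "mmHg")
  pm2 <- phase_means(stepped, seg)
  expect_equal(pm2$rest_mean, 10)
  expect_equal(pm2$vm_mean, 15)
})

test_that("SR phase means rise under a venous perturbation, end to end", {
  trial <- synth_vm_trial(synth_config(duration = 45, vm_window = c(15, 30),
                                       vm_pvs_delta = 10, seed = 77))
  seg <- segment_trial(45, 100)
  pm <- phase_means(sr_estimate(trial$abp, trial$cbfv), seg)
  expect_gt(pm$vm_mean, pm$rest_mean)
})

test_that("one-tailed paired t-test matches the closed formula", {
  res <- paired_t_one_tailed(c(1, 2, 3), c(2, 3, 5))
  expect_equal(res$t, 4, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, oracle_paired_t(c(1, 2, 3), c(2, 3, 5))$p, tolerance = 1e-12)
  expect_true(res$significant)
  # symmetric null
  same <- withr::with_seed(1, rnorm(10))
  expect_error(paired_t_one_tailed(same, same), class = "nicp_error_numeric")
  expect_error(paired_t_one_tailed(same, same + 2), class = "nicp_error_numeric")
  expect_error(paired_t_one_tailed(1, 2), class = "nicp_error_input")
  # 100 random small vectors against the independent formula
  withr::with_seed(99, {
    for (i in 1:100) {
      n <- sample(3:12, 1)
      rest <- rnorm(n, 10, 2)
      vm <- rest + rnorm(n, 0.5, 1)
      if (sd(vm - rest) == 0) next
      got <- paired_t_one_tailed(rest, vm)
      ref <- oracle_paired_t(rest, vm)
      expect_equal(got$t, ref$t, tolerance = 1e-10)
      expect_equal(got$p, ref$p, tolerance = 1e-10)
    }
  })
})

test_that("the experiment harness produces the per-method summary and handles failures", {
  trials <- synth_vm_trials(4, seed = 55)
  rep <- run_vm_experiment(trials, methods = c("sr", "pi"))
  expect_s3_class(rep, "vm_experiment")
  td <- tidy(rep)
  expect_equal(nrow(td), 8)
  expect_true(all(c("method", "trial", "rest_mean", "vm_mean") %in% names(td)))
  gl <- glance(rep)
  expect_equal(sort(gl$method), c("pi", "sr"))
  expect_true(all(c("t", "p", "significant") %in% names(gl)))
  expect_match(rep$summary$rest[1], "^\\d+\\.\\d ± \\d+\\.\\d$")
  # a broken trial is dropped with a reason, not fatal
  broken <- trials
  broken[[2]]$cbfv <- waveform(rep(70, 4500), fs = 100, units = "cm/s")
  rep2 <- run_vm_experiment(broken, methods = "pi")
  expect_equal(nrow(rep2$dropped), 1)
  expect_equal(glance(rep2)$n, 3)
  # a single trial cannot be tested: explicit notice
  rep3 <- run_vm_experiment(trials[1], methods = "sr")
  expect_match(glance(rep3)$note, "fewer than 2")
})
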