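test_that("classification nests direction inside movement-relatedness", {
  # strong contra preference, deterministic values
  resp <- neuron_response(r_contra = c(0.50, 0.52, 0.48, 0.51, 0.49, 0.50),
                          r_ipsi = c(0.01, -0.02, 0.02, -0.01, 0.00, 0.01),
                          neuron_id = 1L)
  cl <- classify_neuron(resp)
  expect_true(cl$movement_related)
  expect_equal(cl$direction, "contra")
  expect_lt(cl$p_direction, 0.05)
  # all-zero responses: not movement-related, direction none
  cl0 <- classify_neuron(neuron_response(rep(0, 6), rep(0, 6)))
  expect_false(cl0$movement_related)
  expect_equal(cl0$direction, "none")
  # significance is strict: p exactly equal to alpha does not count
  resp_pos <- neuron_response(c(1, 2, 3, 4, 5, 6), rep(0, 6))
  p_exact <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))$p  # 2/64
  expect_false(classify_neuron(resp_pos, alpha = p_exact)$movement_related)
  expect_true(classify_neuron(resp_pos, alpha = p_exact * 1.01)$movement_related)
  # below the trial minimum the neuron is unusable
  short <- neuron_response(c(1, 2), c(3, 4))
  expect_false(classify_neuron(short)$usable)
})

test_that("an ipsi-preferring neuron is labeled ipsi", {
  resp <- neuron_response(r_contra = c(0.01, -0.02, 0.02, -0.01, 0.00, 0.03),
                          r_ipsi = c(0.60, 0.62, 0.58, 0.61, 0.59, 0.60))
  cl <- classify_neuron(resp)
  expect_true(cl$movement_related)
  expect_equal(cl$direction, "ipsi")
})

test_that("difference in dff increase is the difference of condition means", {
  resp <- neuron_response(c(0.2, 0.4), c(0.0, 0.2))
  expect_equal(diff_dff_increase(resp), 0.2)
  same <- neuron_response(c(1, 2, 3), c(1, 2, 3))
  expect_equal(diff_dff_increase(same), 0)
  # swapping the conditions negates the value
  swapped <- neuron_response(c(0.0, 0.2), c(0.2, 0.4))
  expect_equal(diff_dff_increase(swapped), -0.2)
  expect_error(diff_dff_increase(neuron_response(numeric(), c(1))), "empty")
})

test_that("selectivity index boundaries and out-of-range behavior", {
  expect_equal(selectivity_index(0.4, 0), 1.0)
  expect_equal(selectivity_index(0, 0.4), -1.0)
  # a negative condition mean can push the index beyond 1
  expect_equal(selectivity_index(0.5, -0.1), 1.5)
  expect_true(is.na(selectivity_index(0.2, -0.2)))
  expect_equal(selectivity_index(0.3, 0.1, denominator_override = 0.8),
               0.25)
})

test_that("paired selectivity shares the larger denominator", {
  before <- neuron_response(rep(0.4, 6), rep(0.2, 6), neuron_id = 5L)
  after <- neuron_response(rep(0.1, 6), rep(0.1, 6), neuron_id = 5L)
  ps <- paired_selectivity(before, after)
  expect_equal(ps$shared_denominator, 0.6)
  expect_equal(ps$si_before, 1 / 3)
  expect_equal(ps$si_after, 0)
  expect_equal(ps$delta_si, -1 / 3)
  # identical sessions: delta SI is zero
  ps0 <- paired_selectivity(before, before)
  expect_equal(ps0$delta_si, 0)
  # relabeling contra/ipsi in both sessions negates both indices
  before_sw <- neuron_response(rep(0.2, 6), rep(0.4, 6))
  after_sw <- neuron_response(rep(0.1, 6), rep(0.1, 6))
  ps_sw <- paired_selectivity(before_sw, after_sw)
  expect_equal(ps_sw$si_before, -ps$si_before)
  expect_equal(ps_sw$delta_si, -ps$delta_si)
})

test_that("population skew test reports median and signed-rank p", {
  res <- population_skew_test(seq(0.1, 2, length.out = 20))
  expect_lt(res$p, 0.05)
  expect_gt(res$median, 0)
  # values symmetric about zero by construction: exact p = 1
  x <- c(1.3, 0.4, 2.2, 0.9)
  expect_equal(population_skew_test(c(x, -x))$p, 1)
  expect_equal(population_skew_test(0)$p, 1)
})

test_that("population classification recovers simulated tuning", {
  sched <- make_grid_schedule(40)
  specs <- neuron_spec(rep(c("contra", "ipsi", "untuned"), each = 15),
                       response_amplitude = 0.5, noise_sd = 0.5 / 3)
  fl <- simulate_calcium(sched, specs, seed = 60)
  cls <- classify_population(trial_activity(fl, sched))
  expect_equal(nrow(cls), 45)
  expect_true(all(cls$usable))
  # tuned neurons at this SNR and trial count are nearly always recovered
  expect_gt(mean(cls$direction[specs$tuning == "contra"] == "contra"), 0.85)
  expect_gt(mean(cls$direction[specs$tuning == "ipsi"] == "ipsi"), 0.85)
  # responsive untuned neurons are movement-related but rarely selective
  untuned <- cls[specs$tuning == "untuned", ]
  expect_true(all(untuned$movement_related))
  expect_lt(mean(untuned$direction != "none"), 0.3)
})
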