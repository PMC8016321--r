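# End-to-end synthetic runs shared by the system-level tests: the 10-subject,
# 30-trials/day cohort with the 1200-600-10 network. Memoized per seed.

e2e_spec <- function(seed) {
  synthetic_spec(n_subjects = 10, trials_per_day = 30, seed = seed)
}

e2e_run <- function(seed) {
  fixture(paste0("e2e_run_", seed), {
    data <- generate_gait_data(e2e_spec(seed))
    patterns <- stride_patterns(data)
    day1 <- dplyr::filter(patterns, day == 1)
    day2 <- dplyr::filter(patterns, day == 2)
    net <- fit_gait_net(day1, max_epochs = 400, seed = seed)
    report <- participant_accuracy(predict(net, day2))
    list(
      data = data, day1 = day1, day2 = day2, net = net, report = report
    )
  })
}

e2e_relevance <- function(seed) {
  fixture(paste0("e2e_rel_", seed), {
    run <- e2e_run(seed)
    maps <- suppressMessages(collect_relevance(run$net, run$day2))
    aggregate_relevance(maps)
  })
}
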