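test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(duration_s = 5), "sim_config")
  expect_error(sim_config(duration_s = 0), class = "zfecg_config")
  expect_error(sim_config(fs = 50), class = "zfecg_config")
  expect_error(sim_config(sd_pp_s = 0.6, mean_pp_s = 0.52), class = "zfecg_config")
  expect_error(sim_config(sd_pp_s = 0), class = "zfecg_config")
  expect_error(sim_config(sa_pause_min_s = 0.4), class = "zfecg_config")
  expect_error(sim_config(sa_pause_max_s = 1.0), class = "zfecg_config")
  expect_error(sim_config(p_consecutive = 1), class = "zfecg_config")
  expect_error(sim_config(qrs_suppression = 1.5), class = "zfecg_config")
  expect_error(sim_config(p_amp_mV = -0.1), class = "zfecg_config")
})

test_that("beat schedules are deterministic in config and seed", {
  cfg <- class_ii_config(duration_s = 20, seed = 42)
  s1 <- generate_beat_schedule(cfg)
  s2 <- generate_beat_schedule(cfg)
  expect_identical(s1, s2)
  s3 <- generate_beat_schedule(class_ii_config(duration_s = 20, seed = 43))
  expect_false(identical(s1$p_times_s, s3$p_times_s))
})

test_that("without injection the schedule is a plain truncated-normal rhythm", {
  cfg <- sim_config(duration_s = 60, sa_rate_per_min = 0, seed = 1)
  sched <- generate_beat_schedule(cfg)
  iv <- diff(sched$p_times_s)
  expect_length(sched$injected_pause_indices, 0)
  expect_true(all(iv <= cfg$mean_pp_s + 5 * cfg$sd_pp_s))
  expect_true(all(iv >= 0.5 * cfg$mean_pp_s))
  # ~115 beats in one minute at a 0.52 s mean interval
  expect_gt(length(sched$p_times_s), 105)
  expect_lt(length(sched$p_times_s), 125)
})

test_that("beat counts match duration / mean interval (Monte Carlo, 200 reps)", {
  counts <- vapply(1:200, function(s) {
    length(generate_beat_schedule(sim_config(duration_s = 60, seed = s))$p_times_s)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 60 / 0.52), 3 * stats::sd(counts))
})

test_that("injected episode rate matches the Poisson model (Monte Carlo)", {
  rates <- vapply(1:1000, function(s) {
    sched <- generate_beat_schedule(
      sim_config(duration_s = 60, sa_rate_per_min = 1.6,
                 sa_pause_max_s = 2.5, seed = s)
    )
    length(sched$injected_pause_indices)
  }, numeric(1))
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 1.6), 3 * se)
})

test_that("injected pauses exceed the pause minimum; base intervals stay short", {
  cfg <- sim_config(duration_s = 60, mean_pp_s = 0.5, sd_pp_s = 0.05,
                    sa_rate_per_min = 2, p_consecutive = 0.3, seed = 7)
  sched <- generate_beat_schedule(cfg)
  iv <- diff(sched$p_times_s)
  inj <- sched$injected_pause_indices
  expect_gt(length(inj), 0)
  expect_true(all(iv[inj] > cfg$sa_pause_min_s))
  expect_true(all(iv[-inj] < 1.0))
})

test_that("schedules with too much expected pause time are rejected", {
  expect_error(
    generate_beat_schedule(sim_config(duration_s = 60, sa_rate_per_min = 30)),
    class = "zfecg_config"
  )
})

test_that("a noiseless beat renders its R peak at the configured amplitude", {
  cfg <- noiseless(duration_s = 2)
  tr <- render_trace(manual_schedule(0.3, cfg))
  fs <- attr(tr, "fs")
  r_center <- 0.3 + cfg$pr_interval_s + cfg$qrs_duration_s / 2
  peak_i <- which.max(tr$voltage_mV)
  expect_lte(abs(peak_i - (round(r_center * fs) + 1L)), 1L)
  expect_equal(max(tr$voltage_mV), cfg$r_amp_mV, tolerance = 0.01)
})

test_that("QRS suppression scales the R-to-P peak ratio as configured", {
  ratio_at <- function(supp) {
    cfg <- noiseless(duration_s = 2, qrs_suppression = supp)
    tr <- render_trace(manual_schedule(0.5, cfg))
    fs <- attr(tr, "fs")
    r_center <- 0.5 + cfg$pr_interval_s + cfg$qrs_duration_s / 2
    tr$voltage_mV[round(r_center * fs) + 1L] / tr$voltage_mV[round(0.5 * fs) + 1L]
  }
  expect_equal(ratio_at(1), 0.248 / 0.045, tolerance = 0.1)
  expect_equal(ratio_at(0.1), 0.1 * 0.248 / 0.045, tolerance = 0.1)
})

test_that("with all wave amplitudes zero the trace RMS equals the noise SD", {
  cfg <- sim_config(duration_s = 20, p_amp_mV = 0, r_amp_mV = 0, t_amp_mV = 0,
                    wander_amp_mV = 0, noise_sd_mV = 0.005, seed = 3)
  tr <- render_trace(generate_beat_schedule(cfg))
  expect_gt(nrow(tr), 1e4)
  expect_equal(stats::sd(tr$voltage_mV), 0.005, tolerance = 0.05)
})

test_that("overlapping beats are rejected at render time", {
  cfg <- noiseless(duration_s = 2)
  short <- cfg$pr_interval_s + cfg$qrs_duration_s - 0.01
  expect_error(render_trace(manual_schedule(c(0.3, 0.3 + short), cfg)),
               class = "zfecg_overlap")
})

test_that("the default cohort has the study's group structure", {
  cohort <- simulate_cohort(default_cohort_manifest(duration_s = 6), seed = 1)
  expect_equal(nrow(cohort), 28)
  expect_equal(as.vector(table(cohort$group)[c("WT", "ClassI", "ClassII")]),
               c(14L, 9L, 5L))
  expect_false(anyDuplicated(cohort$subject_id) > 0)
  # every trace spans duration * fs samples
  expect_true(all(vapply(cohort$trace, nrow, numeric(1)) == 6 * 1000))
})

test_that("cohort simulation is reproducible down to the written bytes", {
  m <- tibble::tibble(
    group = c("WT", "ClassII"), n = c(1L, 1L),
    config = list(wt_config(duration_s = 5), class_ii_config(duration_s = 5))
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(m, seed = 9, out_dir = d1)
  simulate_cohort(m, seed = 9, out_dir = d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("duplicate group labels are rejected", {
  m <- tibble::tibble(group = c("WT", "WT"), n = c(1L, 1L),
                      config = list(wt_config(duration_s = 5),
                                    wt_config(duration_s = 5)))
  expect_error(simulate_cohort(m, seed = 1), class = "zfecg_input")
})

test_that("traces and truth round-trip through CSV/JSON files", {
  rec <- simulate_ecg(wt_config(duration_s = 5, seed = 11))
  d <- withr::local_tempdir()
  tr_path <- file.path(d, "fish.csv")
  write_trace(rec$trace, tr_path)
  back <- read_trace(tr_path)
  expect_equal(back$voltage_mV, rec$trace$voltage_mV)
  expect_equal(attr(back, "fs"), attr(rec$trace, "fs"))
  th_path <- file.path(d, "fish_truth.json")
  write_truth(rec$truth, th_path)
  back_t <- read_truth(th_path)
  expect_equal(back_t$p_times_s, rec$truth$p_times_s)
  expect_equal(back_t$class_label, rec$truth$class_label)
})

test_that("genotype fragment lengths follow the allele model", {
  allele <- allele_model(152, 11)
  expect_equal(genotype_fragments("-/-", allele), 141L)
  expect_equal(genotype_fragments("+/-", allele), c(152L, 141L))
  expect_equal(genotype_fragments("+/+", allele), 152L)
  expect_equal(genotype_fragments("-/-", allele_model(152, 0)), 152L)
  expect_true(allele_model(152, 11)$is_frameshift)
  expect_false(allele_model(152, 9)$is_frameshift)
  expect_error(allele_model(152, 200), class = "zfecg_input")
})
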