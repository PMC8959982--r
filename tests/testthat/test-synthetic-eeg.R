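test_that("cohort generation is balanced, labelled, and seeded-deterministic", {
  spec <- tiny_spec(n_per_group = 2, duration = 8)
  coh <- generate_cohort(spec)
  expect_length(coh, 4L)
  groups <- vapply(coh, function(r) r$group, "")
  expect_equal(sort(unique(groups)), c("HC", "SCZ"))
  expect_equal(as.numeric(table(groups)), c(2, 2))
  ids <- vapply(coh, function(r) r$subject_id, "")
  expect_equal(anyDuplicated(ids), 0L)
  for (r in coh) {
    expect_equal(nrow(r$data), length(r$channel_labels))
    expect_true(all(is.finite(r$data)))
    expect_equal(ncol(r$data), round(spec$fs * spec$duration))
  }
  coh2 <- generate_cohort(spec)
  for (i in seq_along(coh))
    expect_identical(coh[[i]]$data, coh2[[i]]$data)
  # per-subject substreams: regenerating one subject matches the cohort copy
  one <- generate_subject(spec, "SCZ", 2)
  expect_identical(one$data, coh[[which(ids == "SCZ_02")]]$data)
})

test_that("unknown group labels are rejected with the valid labels named", {
  spec <- tiny_spec(n_per_group = 2, duration = 8)
  expect_error(generate_subject(spec, "AD", 1), "HC")
  expect_error(generate_subject(spec, "AD", 1), "SCZ")
  expect_error(generate_subject(spec, "SCZ", 99), "subject_index")
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(cohort_spec(fs = 50), "fs")
  expect_error(cohort_spec(duration = 0), "duration")
  bad <- default_coupling()
  bad$HC$alpha[1, 2] <- 1.5; bad$HC$alpha[2, 1] <- 1.5
  expect_error(cohort_spec(coupling = bad), "\\[0,1\\]")
  asym <- default_coupling()
  asym$HC$alpha[1, 2] <- 0.2  # break symmetry
  expect_error(cohort_spec(coupling = asym), "symmetric")
})

test_that("perfect pair coupling forces identical band phase (PLV = 1)", {
  ch <- default_channels()
  spec <- tiny_spec(
    n_per_group = 2, duration = 12, noise_sd = 0,
    band_power = single_band_power("alpha"),
    coupling = single_pair_coupling(ch, "alpha", 1, 2, 1))
  rec <- generate_subject(spec, "HC", 1)
  seg <- split_segments(rec, 1)[[1]]
  cm <- connectivity_matrix(seg, "alpha")
  expect_equal(cm$values[1, 2], 1, tolerance = 1e-9)
})

test_that("strong default coupling survives the full pipeline (PLV >= 0.95)", {
  ch <- default_channels()
  spec <- tiny_spec(
    n_per_group = 2, duration = 24,
    coupling = single_pair_coupling(ch, "alpha", 7, 8, 1))
  rec <- generate_subject(spec, "HC", 1)
  seg <- split_segments(preprocess(rec, duration_s(rec)), 4)[[2]]
  cm <- connectivity_matrix(seg, "alpha")
  expect_gte(cm$values["O1", "O2"], 0.95)
})

test_that("uncoupled channels are indistinguishable from the independent null", {
  ch <- default_channels()
  spec <- tiny_spec(n_per_group = 2, duration = 12, noise_sd = 0,
                    band_power = single_band_power("alpha"),
                    coupling = single_pair_coupling(ch, "alpha", 1, 2, 0))
  # null oracle: PLV between the same channel of *different* subjects,
  # independent by construction, over many seeds
  null_vals <- unlist(lapply(1:40, function(s) {
    sp <- tiny_spec(n_per_group = 2, duration = 12, noise_sd = 0, seed = s,
                    band_power = single_band_power("alpha"),
                    coupling = single_pair_coupling(ch, "alpha", 1, 2, 0))
    a <- generate_subject(sp, "HC", 1)
    b <- generate_subject(sp, "HC", 2)
    pa <- instantaneous_phase(split_segments(a, 1)[[1]], "alpha")
    pb <- instantaneous_phase(split_segments(b, 1)[[1]], "alpha")
    idx <- (spec$fs + 1):(ncol(pa) - spec$fs)
    plv(pa[1, idx], pb[1, idx])
  }))
  # within-subject uncoupled pair falls inside the null distribution's range
  rec <- generate_subject(spec, "HC", 1)
  ph <- instantaneous_phase(split_segments(rec, 1)[[1]], "alpha")
  idx <- (spec$fs + 1):(ncol(ph) - spec$fs)
  v <- plv(ph[1, idx], ph[2, idx])
  expect_lt(v, max(null_vals) + 2 * stats::sd(null_vals))
  expect_lt(mean(null_vals), 0.35)  # the null itself is far from locking
})

test_that("expected PLV is monotone in the coupling weight", {
  ch <- default_channels()
  weights <- c(0.2, 0.5, 0.8, 0.95)
  mean_plv <- vapply(weights, function(w) {
    vals <- vapply(1:12, function(s) {
      sp <- tiny_spec(n_per_group = 2, duration = 12, seed = 100 + s,
                      coupling = single_pair_coupling(ch, "alpha", 1, 2, w))
      rec <- generate_subject(sp, "HC", 1)
      cm <- connectivity_matrix(split_segments(rec, 1)[[1]], "alpha")
      cm$values[1, 2]
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(mean_plv) > 0))
})

test_that("planted spectral contrast yields lower alpha power in the patient group", {
  spec <- tiny_spec(n_per_group = 6, duration = 16, seed = 9)
  coh <- generate_cohort(spec)
  alpha_pw <- vapply(coh, function(r)
    band_power(welch_psd(r), "alpha"), 0)
  groups <- vapply(coh, function(r) r$group, "")
  # sign test: every SCZ-vs-HC subject-mean ordering strongly favours HC
  expect_lt(mean(alpha_pw[groups == "SCZ"]), mean(alpha_pw[groups == "HC"]))
  expect_gt(mean(alpha_pw[groups == "HC"]) / mean(alpha_pw[groups == "SCZ"]), 1.5)
})

test_that("EDF round trip preserves rate, labels, ids and samples to quantization", {
  spec <- tiny_spec(n_per_group = 2, duration = 4)
  rec <- generate_subject(spec, "SCZ", 1)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, rec$fs)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_identical(back$subject_id, rec$subject_id)
  expect_identical(back$group, rec$group)
  qstep <- max(apply(rec$data, 1, function(v) diff(range(v)))) / 65534
  expect_lte(max(abs(back$data - rec$data)), qstep)
})

test_that("EDF channel subsetting keeps configured labels and flags missing ones", {
  spec <- tiny_spec(n_per_group = 2, duration = 4)
  rec <- generate_subject(spec, "HC", 1)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  sub <- read_edf(path, channels = c("C3", "C4"))
  expect_identical(sub$channel_labels, c("C3", "C4"))
  expect_error(read_edf(path, channels = c("FP1", "ZZ9")), "ZZ9")
})

test_that("malformed EDF headers are rejected with the offending field named", {
  path <- withr::local_tempfile(fileext = ".edf")
  writeBin(charToRaw(strrep("x", 300)), path)
  expect_error(read_edf(path), "number of data records|not numeric")
  writeBin(charToRaw("short"), path)
  expect_error(read_edf(path), "shorter than 256")
})
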