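# Cohort filters, one-hot encoding, hourly binning, normalization,
# aggregation and splitting, each against a brute-force recomputation.

test_that("filter_cohort applies the eligibility predicates and is idempotent", {
  co <- handmade_cohort()
  # a1: eligible; a2: age 17 (and only an out-of-window observation);
  # a3: LOS 0.5 days
  kept <- filter_cohort(co)
  expect_identical(kept$static$admission_id, "a1")
  expect_identical(filter_cohort(kept)$static, kept$static)
  # order preservation on a generated cohort
  co2 <- small_cohort(n = 50, seed = 2)
  f <- filter_cohort(co2)
  expect_identical(f$static$admission_id,
                   co2$static$admission_id[co2$static$admission_id %in%
                                             f$static$admission_id])
})

test_that("age buckets follow the five half-open adult groups", {
  expect_identical(age_bucket(c(18, 24, 25, 30, 44, 45, 64, 65, 88, 89, 90, 101)),
                   c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 5L))
  expect_error(age_bucket(17), "adult")
})

test_that("static one-hot encoding has exactly one 1 per known-field block", {
  co <- small_cohort(n = 60, seed = 4)
  layout <- static_layout(co$static)
  X <- encode_static(co$static, layout)
  expect_identical(ncol(X), nrow(layout))
  # 6 fields, all known at training time -> every row sums to 6
  expect_true(all(rowSums(X) == 6))
  for (f in unique(layout$field)) {
    block <- X[, layout$field == f, drop = FALSE]
    expect_true(all(rowSums(block) == 1), info = f)
  }
  # age 30 lands in the second bucket
  i <- which(co$static$age >= 25 & co$static$age < 45)[1]
  expect_identical(unname(X[i, "age_group=[25,45)"]), 1)
})

test_that("unseen categorical levels encode as an all-zero block", {
  co <- small_cohort(n = 30, seed = 4)
  layout <- static_layout(co$static)
  new <- co$static[1, , drop = FALSE]
  new$insurance <- "UNSEEN_PLAN"
  X <- encode_static(new, layout)
  expect_identical(sum(X[, layout$field == "insurance"]), 0)
  expect_identical(sum(X), 5)
})

test_that("hourly binning means match brute-force re-aggregation and drop
           out-of-window observations", {
  co <- handmade_cohort()
  tt <- bin_temporal(co)
  # heart-rate readings 80 and 90 in hour 3 average to 85
  expect_identical(tt$values["a1", 4, "heart_rate"], 85)
  expect_identical(tt$mask["a1", 4, "heart_rate"], 1L)
  # observation at offset 25 h is absent
  expect_identical(sum(tt$mask["a2", , ]), 0L)
  # random cohort against a brute-force oracle
  co2 <- small_cohort(n = 25, seed = 9, missing_rate = 0.8)
  tt2 <- bin_temporal(co2)
  ob <- co2$observations
  for (id in co2$static$admission_id[1:10]) {
    for (v in sample(co2$variables$variable, 5)) {
      sub <- ob[ob$admission_id == id & ob$variable == v, ]
      for (h in 1:24) {
        vals <- sub$value[floor(sub$hour_offset) == h - 1]
        if (length(vals)) {
          expect_equal(tt2$values[id, h, v], mean(vals), tolerance = 1e-12)
          expect_identical(tt2$mask[id, h, v], 1L)
        } else {
          expect_identical(tt2$values[id, h, v], 0)
          expect_identical(tt2$mask[id, h, v], 0L)
        }
      }
    }
  }
  # undeclared variables are rejected
  bad <- co
  bad$observations$variable[1] <- "mystery"
  expect_error(bin_temporal(bad), "undeclared")
})

test_that("min-max normalization maps endpoints, clips, imputes zero and
           zeroes degenerate ranges", {
  co <- small_cohort(n = 40, seed = 5)
  sp <- split_data(co, 1)
  tt <- bin_temporal(co)
  st <- fit_normalization(tt, sp$train)
  nm <- apply_normalization(tt, st)
  expect_true(all(nm$values >= 0 & nm$values <= 1))
  expect_true(all(nm$values[nm$mask == 0L] == 0))
  # training endpoints map to 0 and 1
  v <- 1
  tr_cells <- tt$values[sp$train, , v][tt$mask[sp$train, , v] == 1L]
  expect_equal(st$min[v], min(tr_cells))
  i_min <- which(tt$values[, , v] == st$min[v] & tt$mask[, , v] == 1L)[1]
  expect_identical(nm$values[, , v][i_min], 0)
  i_max <- which(tt$values[, , v] == st$max[v] & tt$mask[, , v] == 1L)[1]
  expect_identical(nm$values[, , v][i_max], 1)
  # degenerate range maps observed values to 0
  st2 <- st; st2$min[2] <- st2$max[2]
  nm2 <- apply_normalization(tt, st2)
  expect_true(all(nm2$values[, , 2] == 0))
})

test_that("normalization stats never see validation/test observations", {
  co <- small_cohort(n = 40, seed = 6)
  sp <- split_data(co, 3)
  st1 <- fit_normalization(bin_temporal(co), sp$train)
  # perturb every held-out observation massively
  co2 <- co
  held <- co2$observations$admission_id %in% c(sp$validation, sp$test)
  co2$observations$value[held] <- co2$observations$value[held] * 100 + 1000
  st2 <- fit_normalization(bin_temporal(co2), sp$train)
  expect_identical(st1, st2)
})

test_that("baseline aggregations match an independent recomputation", {
  co <- small_cohort(n = 30, seed = 8, missing_rate = 0.85)
  tt <- bin_temporal(co)
  agg <- aggregate_for_baselines(tt)
  expect_identical(dim(agg), c(30L, 5L * 26L))
  for (i in sample(30, 8)) {
    for (v in sample(26, 6)) {
      cells <- tt$values[i, , v][tt$mask[i, , v] == 1L]
      got <- agg[i, (v - 1) * 5 + 1:5]
      if (length(cells) == 0) {
        expect_identical(unname(got), rep(0, 5))
      } else {
        sd_pop <- sqrt(mean((cells - mean(cells))^2))
        expect_equal(unname(got),
                     c(mean(cells), min(cells), max(cells), sd_pop,
                       length(cells)),
                     tolerance = 1e-12)
      }
    }
  }
  # {1,2,3} -> mean 2, min 1, max 3, count 3
  one <- ehrfusion:::new_ehr_cohort(
    data.frame(admission_id = "x", age = 50L, gender = "F",
               marital_status = "SINGLE", ethnicity = "WHITE",
               insurance = "PRIVATE", admission_type = "EMERGENCY",
               length_of_stay = 2, mortality = 0L, readmission = 0L,
               long_los = 0L, stringsAsFactors = FALSE),
    data.frame(admission_id = "x", variable = "heart_rate",
               hour_offset = c(0.5, 1.5, 2.5), value = c(1, 2, 3),
               stringsAsFactors = FALSE),
    handmade_cohort()$notes[0, ],
    ehrfusion:::default_variable_panel())
  a <- aggregate_for_baselines(bin_temporal(one))
  expect_equal(unname(a[1, 1:5]), c(2, 1, 3, sqrt(2 / 3), 3))
})

test_that("split_data partitions 70/10/20, deterministically per seed", {
  co <- small_cohort(n = 100, seed = 1)
  sp <- split_data(co, 42)
  expect_identical(lengths(sp), c(train = 70L, validation = 10L, test = 20L))
  all_ids <- sort(unlist(sp, use.names = FALSE))
  expect_identical(all_ids, sort(co$static$admission_id))
  expect_identical(split_data(co, 42), sp)
  sp2 <- split_data(co, 43)
  expect_false(identical(sp, sp2))
  expect_error(split_data(co$static$admission_id[1:5], 1), "at least 10")
  # non-multiple n: sizes floor(0.7n), floor(0.1n), remainder
  sp3 <- split_data(small_cohort(n = 57, seed = 1), 7)
  expect_identical(lengths(sp3), c(train = 39L, validation = 5L, test = 13L))
})
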