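test_that("blood generation is a pure function of seed and spec", {
  a <- gen_blood(5)
  b <- gen_blood(5)
  expect_identical(as.data.frame(a$samples), as.data.frame(b$samples))
  expect_identical(attr(a$samples, "fp"), attr(b$samples, "fp"))
  c <- gen_blood(6)
  expect_false(identical(as.data.frame(a$samples), as.data.frame(c$samples)))
})

test_that("free plasma fraction stays in the 1.4-2.7% range", {
  fps <- sapply(1:25, function(s) attr(gen_blood(s)$samples, "fp"))
  expect_true(all(fps >= 0.014 & fps <= 0.027))
})

test_that("sampling layout covers automated and manual schedules", {
  b <- gen_blood(9)
  s <- b$samples
  auto <- s[s$source == "automated", ]
  man <- s[s$source == "manual", ]
  expect_equal(range(auto$time_min), c(0, 15))
  expect_equal(median(diff(auto$time_min)), 1 / 60)
  expect_equal(man$time_min, manual_sample_times())
  expect_true(all(!is.na(man$parent_fraction)))
})

test_that("plasma parent area stays below whole-blood area when pob*pf <= 1", {
  b <- gen_blood(4, blood_spec(pob = 0.9))
  tg <- seq(0, 90, by = 0.01)
  a_cp <- sum(b$truth$cp_fn(tg)) * 0.01
  a_wb <- sum(b$truth$cwb_fn(tg)) * 0.01
  expect_lte(a_cp, a_wb)
})

test_that("phantom truth encodes the expected WMH-vs-NAWM pattern", {
  spec <- cohort_spec(pet_grid = c(16, 16, 8))
  for (s in 1:5) {
    sub <- gen_dynamic_pet(s * 11, spec, group = "svd_asymptomatic",
                           make_voxels = FALSE)
    tw <- sub$truth[sub$truth$roi == "WMH", ]
    tn <- sub$truth[sub$truth$roi == "NAWM", ]
    expect_lt(tw$VT, tn$VT)
    expect_lt(tw$Vb, tn$Vb)
    expect_lt(tw$K1, tn$K1)
    expect_gt(tw$Kb, tn$Kb)
  }
})

test_that("noiseless phantoms reproduce the forward model exactly", {
  spec <- cohort_spec(noise_level = 0, pet_grid = c(12, 12, 6))
  sub <- gen_dynamic_pet(3, spec, group = "svd_asymptomatic")
  mask <- sub$labels == roi_labels()[["WMH"]]
  tac <- extract_tac(sub$pet, mask, sub$schedule)
  expect_equal(tac$values, unname(sub$region_tacs$WMH), tolerance = 1e-12)
})

test_that("seeds change voxel noise but not the truth structure", {
  spec <- cohort_spec(pet_grid = c(12, 12, 6))
  a <- gen_dynamic_pet(1, spec)
  b <- gen_dynamic_pet(1, spec)
  expect_identical(a$pet, b$pet)
  expect_identical(a$truth, b$truth)
  d <- gen_dynamic_pet(2, spec)
  expect_false(identical(a$pet, d$pet))
  expect_identical(a$labels, d$labels)  # geometry is spec-determined
})

test_that("symptomatic subjects carry an infarct label", {
  spec <- cohort_spec(pet_grid = c(20, 20, 10))
  sym <- gen_dynamic_pet(2, spec, group = "svd_symptomatic",
                         make_voxels = FALSE)
  asym <- gen_dynamic_pet(2, spec, group = "svd_asymptomatic",
                          make_voxels = FALSE)
  expect_true(any(sym$labels == roi_labels()[["infarct"]]))
  expect_false(any(asym$labels == roi_labels()[["infarct"]]))
  expect_true("infarct" %in% sym$truth$roi)
})

test_that("stained images hit their target positive fractions", {
  im <- gen_ihc_image(55, target_iba1_pct = 25, target_tspo_pct = 0,
                      size = 128)
  expect_gte(im$truth[["iba1_pct"]], 23.5)
  expect_lte(im$truth[["iba1_pct"]], 26.5)
  expect_equal(im$truth[["tspo_pct"]], 0)
  # no DAB ellipses at target 0: deconvolved DAB stays below threshold
  expect_equal(quantify_stain(im$tspo)$percent_area, 0)
  expect_error(gen_ihc_image(1, 150, 0), "\\[0, 100\\]")
})

test_that("SVD-like staining has a lower TSPO:Iba1 ratio than control-like", {
  svd <- gen_ihc_image(7, target_iba1_pct = 8, target_tspo_pct = 1, size = 96)
  hc <- gen_ihc_image(8, target_iba1_pct = 2.5, target_tspo_pct = 1.5,
                      size = 96)
  r_svd <- svd$truth[["tspo_pct"]] / svd$truth[["iba1_pct"]]
  r_hc <- hc$truth[["tspo_pct"]] / hc$truth[["iba1_pct"]]
  expect_lt(r_svd, r_hc)
})

test_that("cohort bundles match the study group sizes and are deterministic", {
  spec <- cohort_spec(pet_grid = c(10, 10, 6))
  coh <- gen_cohort(77, spec, include = "pet", make_voxels = FALSE)
  expect_equal(length(coh$subjects), 32)
  expect_equal(sum(coh$truth$group == "control") / 2, 21)  # 2 ROIs each
  groups <- sapply(coh$subjects, `[[`, "group")
  expect_equal(sum(groups == "svd_asymptomatic"), 6)
  expect_equal(sum(groups == "svd_symptomatic"), 5)
  coh2 <- gen_cohort(77, spec, include = "pet", make_voxels = FALSE)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$truth, coh2$truth)
})

test_that("cohort CBF truths concentrate around the specified means", {
  spec <- cohort_spec(pet_grid = c(8, 8, 4))
  coh <- gen_cohort(101, spec, include = "pet", make_voxels = FALSE)
  svd <- coh$subjects[sapply(coh$subjects, `[[`, "group") != "control"]
  wmh <- sapply(svd, function(s) s$cbf_truth[["WMH"]])
  nawm <- sapply(svd, function(s) s$cbf_truth[["NAWM"]])
  expect_lt(abs(mean(wmh) - 31.4), 2 * 3.8 / sqrt(11) * 1.5)
  expect_lt(abs(mean(nawm) - 43.0), 2 * 4.5 / sqrt(11) * 1.5)
})

test_that("written cohorts produce the declared files and manifest", {
  dir <- tempfile("cohort_")
  spec <- cohort_spec(n_svd_asymptomatic = 1, n_svd_symptomatic = 1,
                      n_controls = 1, pet_grid = c(10, 10, 6))
  coh <- gen_cohort(3, spec, dir = dir, ihc_size = 48)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_true(file.exists(file.path(dir, "frames.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_true(file.exists(file.path(dir, "P01", "blood.csv")))
  expect_true(file.exists(file.path(dir, "P01", "pet.nii.gz")))
  expect_true(file.exists(file.path(dir, "ihc", "SVD1_pallidus_iba1.png")))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$seed, 3)
  # blood CSV round-trips into the reader
  bs <- read_blood_samples(file.path(dir, "P01", "blood.csv"))
  expect_s3_class(bs, "blood_samples")
  unlink(dir, recursive = TRUE)
})
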