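test_that("match scoring reproduces hand counts on the reference profiles", {
  p <- hoxb8_profiles()
  self <- match_score(p[["#1_HoxB8FL"]], p[["#1_HoxB8FL"]])
  expect_equal(self$score, 1)
  expect_identical(self$verdict, "match")
  # #1 vs #3 share 5 of 9+9 single-allele loci
  r13 <- match_score(p[["#1_HoxB8FL"]], p[["#3_HoxB8FL"]])
  expect_equal(r13$n_shared, 5)
  expect_equal(r13$score, 10 / 18)
  expect_identical(r13$verdict, "related")
  # #1 vs #2 share nothing
  r12 <- match_score(p[["#1_HoxB8FL"]], p[["#2_HoxB8FL"]])
  expect_equal(r12$n_shared, 0)
  expect_equal(r12$score, 0)
  expect_identical(r12$verdict, "mismatch")
  expect_error(match_score(p[["#1_HoxB8FL"]], str_profile("e", list())),
               "no called loci")
})

test_that("Tanabe is symmetric, Masters is not, and both match the counting oracle", {
  refs <- reference_profiles()
  nm <- names(refs)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    ij <- match_score(refs[[i]], refs[[j]])
    ji <- match_score(refs[[j]], refs[[i]])
    expect_equal(ij$score, ji$score, label = paste(nm[i], nm[j]))
    # counting oracle: explicit per-locus multiset intersection
    common <- intersect(called_loci(refs[[i]]), called_loci(refs[[j]]))
    ns <- sum(vapply(common, function(loc)
      brute_force_shared(refs[[i]]$calls[[loc]], refs[[j]]$calls[[loc]]),
      integer(1)))
    expect_equal(ij$n_shared, ns, label = paste(nm[i], nm[j]))
  }
  # Masters divides by one side only: #2 vs #3 share 4 of 10 vs 9 alleles
  p <- hoxb8_profiles()
  mq <- match_score(p[["#2_HoxB8FL"]], p[["#3_HoxB8FL"]],
                    algorithm = "masters_query")
  mr <- match_score(p[["#2_HoxB8FL"]], p[["#3_HoxB8FL"]],
                    algorithm = "masters_ref")
  expect_equal(mq$score, 4 / 10)
  expect_equal(mr$score, 4 / 9)
})

test_that("no pair of distinct reference lines reaches the match threshold", {
  refs <- reference_profiles()
  nm <- names(refs)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    expect_lt(match_score(refs[[i]], refs[[j]])$score, 0.8)
  }
  for (i in seq_along(nm))
    expect_equal(match_score(refs[[i]], refs[[i]])$score, 1)
})

test_that("database authentication ranks the true line first", {
  refs <- reference_profiles()
  res <- authenticate_against_db(refs[["#2_HoxB8FL"]], refs)
  expect_identical(res$best$reference, "#2_HoxB8FL")
  expect_identical(res$verdict, "match")
  scores <- vapply(res$results, `[[`, numeric(1), "score")
  expect_false(is.unsorted(rev(scores)))
  # PDAC lines match none of the others
  pd <- mpdac_profiles()
  res06 <- authenticate_against_db(pd[["mPDAC06"]], pd[c("mPDAC09", "mPDAC95")])
  expect_false(res06$verdict == "match")
  expect_error(authenticate_against_db(refs[[1]], list()), "empty")
  # a single-locus query is still ranked
  q <- str_profile("onelocus", list(`18-3` = 16L))
  res1 <- authenticate_against_db(q, refs)
  expect_identical(res1$best$reference, "#1_HoxB8FL")
})

test_that("passage stability compares replicate profiles locus by locus", {
  panel <- fix_panel()
  model <- fix_model()
  p1 <- hoxb8_profiles()[["#1_HoxB8FL"]]
  # P5 / P15 / post-cryo emulated as independently seeded noisy runs
  reps <- lapply(c(500, 600, 700), function(s)
    roundtrip_profile(p1, panel, model, seed = s))
  rep_report <- check_passage_stability(reps)
  expect_true(rep_report$stable)
  expect_length(rep_report$discordant_loci, 0)
  # one allele shifted by one repeat -> unstable, locus listed
  drift <- reps[[1]]
  drift$calls[["15-3"]] <- drift$calls[["15-3"]] + 1L
  bad <- check_passage_stability(list(reps[[2]], drift))
  expect_false(bad$stable)
  expect_identical(bad$discordant_loci, "15-3")
  expect_error(check_passage_stability(reps[1]), "at least two")
})

test_that("interspecies detection flags mixtures but not pure samples", {
  panel <- fix_panel()
  model <- fix_model()
  cal <- fix_calibration(panel, model, seed = 1)
  p1 <- hoxb8_profiles()[["#1_HoxB8FL"]]
  mm <- mm1s_profile()
  mix <- size_peaks(simulate_mixture(panel, 2, p1, mm, 0.5, model, 11), cal)
  rep_mix <- detect_interspecies(mix, panel, 2)
  expect_true(rep_mix$interspecies_flag)
  pure_m <- size_peaks(simulate_sample_trace(panel, 2, p1, model, 12), cal)
  expect_false(detect_interspecies(pure_m, panel, 2)$interspecies_flag)
  expect_identical(detect_interspecies(pure_m, panel, 2)$species, "mouse")
  pure_h <- size_peaks(simulate_sample_trace(panel, 2, mm, model, 13), cal)
  rep_h <- detect_interspecies(pure_h, panel, 2)
  expect_false(rep_h$interspecies_flag)
  expect_identical(rep_h$species, "human")
  # profile input works the same way
  prof <- roundtrip_profile(p1, panel, model, seed = 800)
  expect_false(detect_interspecies(prof, panel)$interspecies_flag)
})

test_that("intraspecies detection finds murine-murine mixtures", {
  panel <- fix_panel()
  model <- fix_model()
  lad <- simulate_ladder_trace(panel, model, seed = 1)
  p <- hoxb8_profiles()
  p1 <- p[["#1_HoxB8FL"]]; p3 <- p[["#3_HoxB8FL"]]
  mix_profile <- function(f, seed) {
    wells <- lapply(1:4, function(s)
      simulate_mixture(panel, s, p1, p3, f, model, seed + s))
    profile_from_traces(lad, wells, panel, sprintf("mix %.1f", f))
  }
  mix <- mix_profile(0.5, 40)
  got <- detect_intraspecies(mix, reference = p1)
  expect_true(got$intraspecies_flag)
  expect_setequal(got$supporting_loci, c("9-2", "12-1", "5-5", "X-1"))
  # clean profiles never flag
  clean <- roundtrip_profile(p1, panel, model, seed = 900)
  expect_false(detect_intraspecies(clean, reference = p1)$intraspecies_flag)
  expect_false(detect_intraspecies(clean)$intraspecies_flag)
  # threshold above panel size can never fire
  expect_false(detect_intraspecies(mix, min_extra_loci = 10,
                                   reference = p1)$intraspecies_flag)
  # detection is monotone in the mixing fraction
  flags <- vapply(c(0.2, 0.3, 0.5), function(f)
    detect_intraspecies(mix_profile(f, 40),
                        reference = p1)$intraspecies_flag, logical(1))
  expect_false(is.unsorted(flags))
})

test_that("three or more alleles at a locus flag contamination without a reference", {
  pd <- mpdac_profiles()
  panel <- fix_panel()
  model <- fix_model()
  lad <- simulate_ladder_trace(panel, model, seed = 1)
  wells <- lapply(1:4, function(s)
    simulate_mixture(panel, s, pd[["mPDAC06"]], pd[["mPDAC09"]], 0.5, model,
                     50 + s))
  mix <- profile_from_traces(lad, wells, panel, "pdac mix")
  got <- detect_intraspecies(mix)
  expect_true(got$intraspecies_flag)
  expect_gte(length(got$supporting_loci), 2)
})
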