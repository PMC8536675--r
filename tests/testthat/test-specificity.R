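mk_assess <- function(pam_status = "canonical", seed = 0L, distal = 0L,
                      gaps = 0L, identical = NULL, species = "spX") {
  tibble::tibble(
    guide_id = "g1", species = species, pam_status = pam_status,
    pam_obs = "TTTA", seed_mismatches = as.integer(seed),
    distal_mismatches = as.integer(distal), gap_positions = as.integer(gaps),
    spacer_identical = identical %||%
      (seed == 0L && distal == 0L && gaps == 0L))
}

test_that("signal prediction follows the rule order", {
  strict <- activity_rules("strict")
  # identical spacer, canonical PAM: the target-species situation
  expect_equal(predict_signal(mk_assess(), strict)$call, "positive")
  # gap-disrupted PAM is a hard negative whatever the spacer
  p <- predict_signal(mk_assess("absent", gaps = 2L, identical = TRUE), strict)
  expect_equal(p$call, "negative")
  expect_match(p$rationale, "pam_absent")
  # variant PAM with an identical spacer stays positive (identity override)
  p <- predict_signal(mk_assess("variant", identical = TRUE), strict)
  expect_equal(p$call, "positive")
  expect_match(p$rationale, "identity_override")
  # with the override disabled the variant penalty decides; push it past
  # the threshold to see the flip
  no_ovr <- activity_rules("strict", identity_override = FALSE,
                           pam_variant_penalty = 3)
  expect_equal(predict_signal(mk_assess("variant", identical = TRUE),
                              no_ovr)$call, "negative")
  with_ovr <- activity_rules("strict", pam_variant_penalty = 3)
  expect_equal(predict_signal(mk_assess("variant", identical = TRUE),
                              with_ovr)$call, "positive")
  # one seed mismatch: negative under strict (3 >= 3), positive under
  # permissive (2 < 4)
  expect_equal(predict_signal(mk_assess(seed = 1L), strict)$call, "negative")
  expect_equal(predict_signal(mk_assess(seed = 1L),
                              activity_rules("permissive"))$call, "positive")
  # scores are linear in the penalties
  p <- predict_signal(mk_assess("variant", seed = 1L, distal = 3L), strict)
  expect_equal(p$score, 3 * 1 + 1 * 3 + 2)
})

test_that("extra seed mismatches never rescue a negative call", {
  strict <- activity_rules("strict")
  set.seed(37)
  for (i in 1:30) {
    seed <- sample(0:4, 1); distal <- sample(0:6, 1)
    status <- sample(c("canonical", "variant"), 1)
    a <- mk_assess(status, seed, distal, identical = FALSE)
    b <- mk_assess(status, seed + 1L, distal, identical = FALSE)
    pa <- predict_signal(a, strict); pb <- predict_signal(b, strict)
    expect_gte(pb$score, pa$score)
    if (pa$call == "negative") expect_equal(pb$call, "negative")
  }
})

test_that("discrimination score is the off-target negative fraction", {
  expect_equal(discrimination_score(rep("negative", 3), "positive"), 1)
  expect_equal(discrimination_score(rep("positive", 3), "positive"), 0)
  expect_equal(discrimination_score(c("negative", "negative", "positive"),
                                    "positive"), 2 / 3)
  expect_equal(discrimination_score(rep("negative", 3), "negative"), -Inf)
  expect_error(discrimination_score(character(0), "positive"), "no off-target")
})

test_that("ranking puts a planted perfect discriminator first", {
  gen <- generate_panel(panel_spec(
    seed = 41L, n_species = 4L, background_divergence = 0,
    offtarget_edits = list(
      species2 = tibble::tibble(zone = c("pam", "seed"), offset = c(4L, 1L), new = NA),
      species3 = tibble::tibble(zone = c("pam", "seed"), offset = c(4L, 3L), new = NA),
      species4 = tibble::tibble(zone = c("pam", "seed"), offset = c(4L, 2L), new = NA))))
  ranked <- rank_candidates(gen$msa)
  expect_equal(ranked$pam_start[1], 150L)
  expect_equal(ranked$strand[1], "+")
  expect_equal(ranked$discrimination[1], 1)
  # a conserved (background-free) site elsewhere ranks below: every other
  # candidate has all off-targets identical, hence positive
  expect_true(all(ranked$discrimination[-1] == 0))
})

test_that("tied candidates keep input order and ranks are a permutation", {
  base <- paste0(strrep("G", 5), "TTTA", random_dna(30), "TTTC", random_dna(30))
  msa <- as_barcode_msa(tibble::tibble(
    id = c("t", "o"), species = c("s1", "s2"),
    aligned = rep(base, 2)), target_species = "s1")
  cands <- enumerate_candidates(msa)
  ranked <- rank_candidates(msa, cands)
  expect_equal(sort(ranked$rank), seq_len(nrow(cands)))
  same <- ranked[ranked$discrimination == 0 &
                   ranked$off_penalty_total == 0 &
                   ranked$n_off_canonical_pam == ranked$n_off_canonical_pam[1], ]
  expect_equal(same$win_start, sort(same$win_start))
})

test_that("the top-ranked candidate maximises a re-scored criterion", {
  for (seed in c(51L, 52L, 53L, 54L, 55L)) {
    gen <- generate_panel(recovery_spec(seed))
    ranked <- rank_candidates(gen$msa)
    # independent re-scoring from the per-species predictions
    preds <- predict_signal(
      assess_candidates(gen$msa, enumerate_candidates(gen$msa)),
      activity_rules("strict"))
    frac <- tapply(preds$call == "negative", preds$guide_id, mean)
    expect_equal(ranked$discrimination[1], max(frac))
    expect_equal(unname(frac[ranked$guide_id[1]]), max(frac))
  }
})

test_that("design wrapper ties the stages together", {
  fx <- fixture("gRNA-A")
  d <- design_guides(fx$msa)
  expect_s3_class(d, "cas12a_design")
  expect_equal(d$ranking$guide_id[1], "gp150")
  td <- tidy(d)
  expect_true(all(c("guide_id", "species", "call", "score") %in% names(td)))
  g <- glance(d)
  expect_equal(g$top_guide, "gp150")
  expect_equal(g$top_discrimination, 1)
  pl <- autoplot(d)
  expect_s3_class(pl, "ggplot")
})
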