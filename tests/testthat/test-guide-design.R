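test_that("PAM scanning honours pattern semantics and spacer room", {
  hits <- scan_pams(paste0("TTTA", strrep("C", 25)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 0L)
  expect_equal(hits$pam, "TTTA")

  # V excludes T, so a poly-T sequence has no sites on either strand
  expect_equal(nrow(scan_pams(strrep("T", 60))), 0L)

  expect_warning(short <- scan_pams("TTTACCC"), "shorter")
  expect_equal(nrow(short), 0L)

  # TTTN accepts the poly-T windows that TTTV rejects
  expect_gt(nrow(scan_pams(strrep("T", 60), design_params(pam = "TTTN"))), 0L)
})

test_that("PAM scanning equals the sliding-window oracle", {
  set.seed(3)
  p <- design_params(spacer_len = 21L)
  for (i in 1:40) {
    s <- random_dna(60)
    got <- as.data.frame(scan_pams(s, p))
    want <- oracle_scan_pams(s, "TTTV", 21)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = s)
  }
})

test_that("candidate enumeration finds planted sites on either strand", {
  gen <- generate_panel(panel_spec(seed = 17L, n_species = 4L,
                                   background_divergence = 0))
  cands <- enumerate_candidates(gen$msa)
  planted <- cands[cands$strand == "+" & cands$pam_start == 150L, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$pam_seq, "TTTA")
  expect_equal(nchar(planted$spacer_seq), 21L)
  tgt <- gen$panel$seq[1]
  expect_equal(planted$spacer_seq, substr(tgt, 155, 175))
  # gap-free target row: columns coincide with positions
  expect_equal(planted$spacer_cols[[1]], 154:174)

  gen_m <- generate_panel(panel_spec(seed = 18L, n_species = 4L,
                                     guide_strand = "-",
                                     background_divergence = 0))
  cands_m <- enumerate_candidates(gen_m$msa)
  planted_m <- cands_m[cands_m$strand == "-" & cands_m$pam_start == 150L, ]
  expect_equal(nrow(planted_m), 1L)
  tgt <- gen_m$panel$seq[1]
  expect_equal(planted_m$pam_seq, revcomp(substr(tgt, 151, 154)))
  expect_equal(planted_m$spacer_seq, revcomp(substr(tgt, 130, 150)))
})

test_that("designing on the reverse-complemented panel mirrors strands", {
  gen <- generate_panel(panel_spec(seed = 19L, n_species = 4L,
                                   background_divergence = 0.02))
  fwd <- enumerate_candidates(gen$msa)
  L <- nchar(gen$panel$seq[1])
  rc <- gen$msa
  rc$aligned <- revcomp(rc$aligned)
  rev <- enumerate_candidates(rc)
  expect_equal(nrow(rev), nrow(fwd))
  key <- function(df, flip) {
    strand <- if (flip) ifelse(df$strand == "+", "-", "+") else df$strand
    start <- if (flip) L - df$pam_start - 4L else df$pam_start
    df <- tibble::tibble(strand = strand, start = start,
                         pam = df$pam_seq, spacer = df$spacer_seq)
    df[order(df$start, df$strand), ]
  }
  expect_equal(key(rev, TRUE), key(fwd, FALSE))
})

test_that("a gap in the target row's window excludes the candidate", {
  msa <- as_barcode_msa(tibble::tibble(
    id = c("t", "o"), species = c("s1", "s2"),
    aligned = c(paste0("TT-TA", strrep("C", 25)),
                paste0("TTGTA", strrep("C", 25)))),
    target_species = "s1")
  # degapped target has TTTA at 0 but the window spans a gap column
  expect_equal(nrow(enumerate_candidates(msa)), 0L)
})

test_that("disagreeing duplicate target rows disqualify candidates", {
  base <- paste0("TTTA", strrep("C", 25))
  mut <- paste0("TTTA", strrep("C", 10), "G", strrep("C", 14))
  msa_ok <- as_barcode_msa(tibble::tibble(
    id = c("t1", "t2", "o"), species = c("s1", "s1", "s2"),
    aligned = c(base, base, mut)), target_species = "s1")
  expect_equal(nrow(enumerate_candidates(msa_ok)), 1L)
  msa_bad <- as_barcode_msa(tibble::tibble(
    id = c("t1", "t2", "o"), species = c("s1", "s1", "s2"),
    aligned = c(base, mut, base)), target_species = "s1")
  expect_equal(nrow(enumerate_candidates(msa_bad)), 0L)
})

test_that("assessment classifies PAM status and splits seed/distal mismatches", {
  gen <- generate_panel(panel_spec(
    seed = 23L, n_species = 5L, background_divergence = 0,
    offtarget_edits = list(
      species2 = tibble::tibble(zone = "seed", offset = 2L, new = NA),
      species3 = tibble::tibble(zone = c("pam", "distal"), offset = c(4L, 7L),
                                new = NA),
      species4 = tibble::tibble(zone = "pam", offset = 2L, new = "-"))))
  cands <- enumerate_candidates(gen$msa)
  planted <- cands[cands$pam_start == 150L & cands$strand == "+", ]
  a <- assess_candidates(gen$msa, planted)
  a <- a[order(a$species), ]
  expect_equal(a$species, paste0("species", 2:5))
  expect_equal(a$pam_status, c("canonical", "variant", "absent", "canonical"))
  expect_equal(a$seed_mismatches, c(1L, 0L, 0L, 0L))
  expect_equal(a$distal_mismatches, c(0L, 1L, 0L, 0L))
  expect_equal(a$spacer_identical, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(a$gap_positions, c(0L, 0L, 1L, 0L))
})

test_that("identical off-target gives the identity assessment", {
  msa <- as_barcode_msa(tibble::tibble(
    id = c("t", "o"), species = c("s1", "s2"),
    aligned = rep(paste0("TTTA", random_dna(30)), 2)), target_species = "s1")
  a <- assess_candidates(msa, enumerate_candidates(msa)[1, ])
  expect_equal(a$pam_status[1], "canonical")
  expect_equal(a$seed_mismatches[1] + a$distal_mismatches[1], 0L)
  expect_true(a$spacer_identical[1])
})

test_that("seed plus distal mismatches equal the full mismatch count", {
  set.seed(29)
  for (i in 1:10) {
    gen <- generate_panel(panel_spec(seed = 100L + i, n_species = 4L,
                                     background_divergence = 0.05))
    cands <- enumerate_candidates(gen$msa)
    a <- assess_candidates(gen$msa, cands)
    for (r in seq_len(nrow(a))) {
      cand <- cands[cands$guide_id == a$guide_id[r], ]
      sp_row <- gen$msa$aligned[gen$msa$species == a$species[r]]
      obs <- chars_of(sp_row)[cand$spacer_cols[[1]] + 1L]
      if (cand$strand == "-") obs <- chars_of(oracle_revcomp(
        paste(rev(obs), collapse = "")))
      mm <- sum(!mapply(oracle_match, obs, chars_of(cand$spacer_seq)))
      expect_equal(a$seed_mismatches[r] + a$distal_mismatches[r], mm)
    }
  }
})

test_that("IVT construct assembles promoter, scaffold and spacer", {
  spacer <- random_dna(21)
  con <- build_construct(spacer)
  defs <- construct_defaults()
  expect_equal(nchar(con$crRNA), nchar(defs$scaffold) + 21L)
  expect_false(grepl("T", con$crRNA, fixed = TRUE))
  expect_equal(con$top, paste0(defs$t7, defs$scaffold, spacer))
  expect_equal(con$bottom, revcomp(con$top))
  # the 3' end of the template recovers the spacer
  expect_equal(substr(con$top, nchar(con$top) - 20L, nchar(con$top)), spacer)
  expect_error(build_construct(spacer, scaffold = ""), "scaffold")
})
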