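# the blinded-panel composition: 7 target samples among 20
blinded_manifest <- function() {
  counts <- c(P_amarus = 7L, P_urinaria = 2L, P_debilis = 2L, P_virgatus = 1L,
              P_airy_shawii = 2L, P_acidus = 1L, P_emblica = 2L,
              P_reticulatus = 2L, Phyllanthus_sp = 1L)
  species <- rep(names(counts), counts)
  panel_manifest(tibble::tibble(sample_id = sprintf("S%02d", seq_along(species)),
                                true_species = species),
                 target_species = "P_amarus")
}

assay_calls <- function(m) {
  stats::setNames(ifelse(m$true_species %in% c("P_amarus", "P_reticulatus"),
                         "positive", "negative"), m$sample_id)
}

test_that("reported panel calls give accuracy 90.00 and precision 77.78", {
  m <- blinded_manifest()
  cm <- confusion_matrix(m, assay_calls(m))
  expect_equal(tidy(cm)$n, c(7L, 2L, 11L, 0L))
  expect_equal(cm$accuracy_pct, 90.00)
  expect_equal(cm$precision_pct, 77.78)
  expect_equal(cm$recall_pct, 100.00)
})

test_that("degenerate call patterns are reported correctly", {
  m <- blinded_manifest()
  all_neg <- stats::setNames(rep("negative", nrow(m)), m$sample_id)
  cm <- confusion_matrix(m, all_neg)
  expect_equal(cm$recall_pct, 0)
  expect_true(is.na(cm$precision_pct))  # n/a, not 0.00

  all_right <- stats::setNames(ifelse(m$true_species == "P_amarus",
                                      "positive", "negative"), m$sample_id)
  expect_equal(confusion_matrix(m, all_right)$accuracy_pct, 100.00)
})

test_that("metrics match closed-form recomputation for random calls", {
  m <- blinded_manifest()
  set.seed(79)
  for (i in 1:20) {
    calls <- stats::setNames(sample(c("positive", "negative"), nrow(m), TRUE),
                             m$sample_id)
    cm <- confusion_matrix(m, calls)
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, nrow(m))
    expect_equal(cm$accuracy_pct,
                 floor(100 * 100 * (cm$tp + cm$tn) / nrow(m) + 0.5) / 100)
    if (cm$tp + cm$fp > 0) {
      expect_equal(cm$precision_pct,
                   floor(100 * 100 * cm$tp / (cm$tp + cm$fp) + 0.5) / 100)
    } else {
      expect_true(is.na(cm$precision_pct))
    }
    # relabelling sample ids leaves the metrics unchanged
    m2 <- m
    m2$sample_id <- paste0("X", m$sample_id)
    cm2 <- confusion_matrix(panel_manifest(m2, "P_amarus"),
                            stats::setNames(unname(calls), m2$sample_id))
    expect_equal(glance(cm2), glance(cm))
  }
})

test_that("call bookkeeping errors are caught by name", {
  m <- blinded_manifest()
  calls <- assay_calls(m)
  expect_error(confusion_matrix(m, calls[-1]), "S01")
  expect_error(confusion_matrix(m, c(calls, bogus = "positive")), "bogus")
  calls[1] <- "maybe"
  expect_error(confusion_matrix(m, calls), "positive")
})

test_that("in-silico panel evaluation reproduces the 7/2/11/0 matrix", {
  fx <- fixture("accuracy-panel")
  ev <- evaluate_panel(fx$samples, fx$manifest, fx$reference,
                       guide_id = fx$guide_id)
  cm <- ev$confusion
  expect_equal(cm$tp, 7L); expect_equal(cm$fp, 2L)
  expect_equal(cm$tn, 11L); expect_equal(cm$fn, 0L)
  expect_equal(cm$accuracy_pct, 90.00)
  expect_equal(cm$precision_pct, 77.78)
  expect_equal(cm$recall_pct, 100.00)
  # the two false positives are the variant-PAM/identical-spacer samples
  fp <- ev$predictions[ev$predictions$call == "positive" &
                         ev$predictions$true_species != "P_amarus", ]
  expect_equal(unique(fp$true_species), "P_reticulatus")
  expect_true(all(grepl("identity_override", fp$rationale)))

  # shuffling sample order leaves the matrix unchanged
  set.seed(83)
  idx <- sample(nrow(fx$samples))
  m2 <- panel_manifest(fx$manifest[idx, ], "P_amarus")
  ev2 <- evaluate_panel(fx$samples[idx, ], m2, fx$reference,
                        guide_id = fx$guide_id)
  expect_equal(glance(ev2$confusion), glance(cm))
})

test_that("a target-only panel with a perfect guide gives full recall", {
  gen <- generate_panel(panel_spec(seed = 89L, n_species = 2L,
                                   background_divergence = 0))
  samples <- tibble::tibble(id = c("t1", "t2", "t3"),
                            seq = rep(gen$panel$seq[1], 3))
  m <- panel_manifest(tibble::tibble(sample_id = samples$id,
                                     true_species = "species1"), "species1")
  ev <- evaluate_panel(samples, m, gen$panel$seq[1], guide_id = "gp150")
  expect_equal(ev$confusion$fp + ev$confusion$tn, 0L)
  expect_equal(ev$confusion$recall_pct, 100.00)
})

test_that("missing sample sequences are a named contract error", {
  fx <- fixture("accuracy-panel")
  expect_error(evaluate_panel(fx$samples[-1, ], fx$manifest, fx$reference),
               "S01")
})
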