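#' Named synthetic fixtures reproducing described assay configurations
#'
#' Three ready-made synthetic panels encode the qualitative configurations
#' of a Phyllanthus trnL authentication assay. They are generated, not
#' biological, sequences: the mismatch/PAM layout is faithful to the
#' described assay outcomes, but the nucleotide sequences themselves are
#' random and must not be used as reference data for real species.
#'
#' * `"gRNA-A"` — a well-discriminating guide: the target (P. amarus
#'   stand-in) carries the only canonical PAM; one off-target species has a
#'   variant PAM plus a mismatch at seed position 1, another a variant PAM
#'   plus three distal mismatches, and the last has a gap-disrupted
#'   (absent) PAM. Under `strict` rules only the target is called
#'   positive.
#' * `"gRNA-B"` — a conserved site: canonical PAM in all four species; the
#'   off-targets differ only by a single A>G-style variant at seed
#'   position 2. Under `permissive` rules all four species are positive.
#' * `"accuracy-panel"` — a 20-sample blinded panel (7 target, 13
#'   non-target across eight other species) in which two P. reticulatus
#'   stand-in samples carry a variant PAM with a spacer identical to the
#'   target, so they are called positive by the identity override:
#'   TP 7, FP 2, TN 11, FN 0 under `strict` rules.
#'
#' @param name `"gRNA-A"`, `"gRNA-B"` or `"accuracy-panel"`.
#' @return List of class `cas12a_fixture`. For the guide fixtures:
#'   `panel`, `msa`, `guide` (planted site), `expected_calls` (per species
#'   and rule preset), `params`. For the accuracy panel: `samples`
#'   (aligned), `manifest`, `reference`, `guide_id`, `expected`
#'   (confusion counts and metrics), `params`.
#' @export
fixture <- function(name = c("gRNA-A", "gRNA-B", "accuracy-panel")) {
  name <- match.arg(name)
  switch(name,
         "gRNA-A" = .fixture_grna_a(),
         "gRNA-B" = .fixture_grna_b(),
         "accuracy-panel" = .fixture_accuracy())
}

.rename_species <- function(gen, new_names) {
  map <- stats::setNames(new_names, paste0("species", seq_along(new_names)))
  relabel <- function(x) unname(map[x])
  gen$panel$id <- relabel(gen$panel$id)
  gen$panel$species <- relabel(gen$panel$species)
  attr(gen$panel, "target_species") <- relabel(attr(gen$panel, "target_species"))
  gen$msa$id <- relabel(gen$msa$id)
  gen$msa$species <- relabel(gen$msa$species)
  attr(gen$msa, "target_species") <- relabel(attr(gen$msa, "target_species"))
  gen$truth$expected$species <- relabel(gen$truth$expected$species)
  gen
}

.fixture_grna_a <- function() {
  params <- design_params()
  spec <- panel_spec(
    seed = 101L, n_species = 4L, locus_len = 400L,
    guide_pos = 150L, guide_strand = "+",
    offtarget_edits = list(
      species2 = tibble::tibble(zone = c("pam", "seed"), offset = c(4L, 1L),
                                new = NA_character_),
      species3 = tibble::tibble(zone = c("pam", "distal", "distal", "distal"),
                                offset = c(4L, 8L, 12L, 16L),
                                new = NA_character_),
      species4 = tibble::tibble(zone = c("pam", "pam"), offset = c(2L, 3L),
                                new = c("-", "-"))),
    background_divergence = 0, params = params)
  gen <- .rename_species(generate_panel(spec),
                         c("P_amarus", "P_debilis", "P_urinaria", "P_virgatus"))
  expected_calls <- tibble::tibble(
    species = c("P_amarus", "P_debilis", "P_urinaria", "P_virgatus"),
    strict = c("positive", "negative", "negative", "negative"),
    permissive = c("positive", "negative", "negative", "negative"))
  structure(list(name = "gRNA-A", panel = gen$panel, msa = gen$msa,
                 guide = gen$truth$guide, expected_assess = gen$truth$expected,
                 expected_calls = expected_calls, params = params),
            class = "cas12a_fixture")
}

.fixture_grna_b <- function() {
  params <- design_params()
  seed2 <- tibble::tibble(zone = "seed", offset = 2L, new = NA_character_)
  spec <- panel_spec(
    seed = 202L, n_species = 4L, locus_len = 400L,
    guide_pos = 220L, guide_strand = "+",
    offtarget_edits = list(species2 = seed2, species3 = seed2, species4 = seed2),
    background_divergence = 0, params = params)
  gen <- .rename_species(generate_panel(spec),
                         c("P_amarus", "P_urinaria", "P_debilis", "P_virgatus"))
  expected_calls <- tibble::tibble(
    species = c("P_amarus", "P_urinaria", "P_debilis", "P_virgatus"),
    strict = c("positive", "negative", "negative", "negative"),
    permissive = rep("positive", 4))
  structure(list(name = "gRNA-B", panel = gen$panel, msa = gen$msa,
                 guide = gen$truth$guide, expected_assess = gen$truth$expected,
                 expected_calls = expected_calls, params = params),
            class = "cas12a_fixture")
}

.fixture_accuracy <- function() {
  params <- design_params()
  species <- c("P_amarus", "P_urinaria", "P_debilis", "P_virgatus",
               "P_airy_shawii", "P_acidus", "P_emblica", "P_reticulatus",
               "Phyllanthus_sp")
  spec <- panel_spec(
    seed = 303L, n_species = 9L, locus_len = 400L,
    guide_pos = 150L, guide_strand = "+",
    offtarget_edits = list(
      species2 = tibble::tibble(zone = c("pam", "distal", "distal", "distal"),
                                offset = c(4L, 8L, 12L, 16L), new = NA_character_),
      species3 = tibble::tibble(zone = c("pam", "seed"), offset = c(4L, 1L),
                                new = NA_character_),
      species4 = tibble::tibble(zone = c("pam", "pam"), offset = c(2L, 3L),
                                new = c("-", "-")),
      species5 = tibble::tibble(zone = c("seed", "seed"), offset = c(3L, 4L),
                                new = NA_character_),
      species6 = tibble::tibble(zone = "seed", offset = 1L, new = NA_character_),
      species7 = tibble::tibble(zone = c("seed", "distal"), offset = c(5L, 9L),
                                new = NA_character_),
      species8 = tibble::tibble(zone = "pam", offset = 4L, new = NA_character_),
      species9 = tibble::tibble(zone = c("pam", "seed"), offset = c(4L, 2L),
                                new = NA_character_)),
    background_divergence = 0.02, params = params)
  gen <- .rename_species(generate_panel(spec), species)
  counts <- c(P_amarus = 7L, P_urinaria = 2L, P_debilis = 2L, P_virgatus = 1L,
              P_airy_shawii = 2L, P_acidus = 1L, P_emblica = 2L,
              P_reticulatus = 2L, Phyllanthus_sp = 1L)
  true_species <- rep(names(counts), counts)
  sample_id <- sprintf("S%02d", seq_along(true_species))
  aligned_of <- stats::setNames(gen$msa$aligned, gen$msa$species)
  samples <- tibble::tibble(id = sample_id, seq = unname(aligned_of[true_species]))
  manifest <- panel_manifest(
    tibble::tibble(sample_id = sample_id, true_species = true_species),
    target_species = "P_amarus")
  structure(list(
    name = "accuracy-panel",
    samples = samples,
    manifest = manifest,
    reference = unname(aligned_of["P_amarus"]),
    guide_id = sprintf("gp%03d", 150L),
    expected = list(tp = 7L, fp = 2L, tn = 11L, fn = 0L,
                    accuracy_pct = 90.00, precision_pct = 77.78,
                    recall_pct = 100.00),
    params = params),
    class = "cas12a_fixture")
}
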