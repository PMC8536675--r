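#' Run the full design-predict-(amplicon)-evaluate pipeline
#'
#' One call from a panel to ranked guides and, when a manifest is given, a
#' confusion-matrix evaluation; all tables are also written under
#' `out_dir` when supplied. Outputs are deterministic: the same inputs and
#' configuration produce byte-identical files (the provenance block
#' records the package version, a configuration hash and input checksums,
#' never a timestamp).
#'
#' @param panel A [barcode_panel()], a `barcode_msa`, a fixture name
#'   (`"fixture:gRNA-A"`, `"fixture:gRNA-B"`), or a FASTA path.
#' @param target Target species (defaults to the panel's).
#' @param params A [design_params()] object.
#' @param rules An [activity_rules()] object.
#' @param primers Optional [primer_set()]: per-record amplicon check of
#'   the top guide.
#' @param aln An [aln_params()] object.
#' @param out_dir Optional output directory (created if needed).
#' @return List with `design` (a `cas12a_design`), `amplicons` (tibble or
#'   `NULL`) and `files` (paths written).
#' @export
run_pipeline <- function(panel, target = NULL, params = design_params(),
                         rules = activity_rules("strict"), primers = NULL,
                         aln = aln_params(), out_dir = NULL) {
  if (is.character(panel) && length(panel) == 1L) {
    panel <- if (startsWith(panel, "fixture:")) {
      fx <- fixture(sub("^fixture:", "", panel))
      if (!is.null(fx$msa)) fx$msa else stop("fixture '", fx$name,
                                             "' is an evaluation panel; use evaluate_panel()")
    } else {
      recs <- read_barcode_fasta(panel)
      if (is.null(target)) stop("--target required for FASTA input")
      barcode_panel(recs, target)
    }
  }
  des <- design_guides(panel, target = target, params = params, rules = rules,
                       aln = aln)
  amplicons <- NULL
  if (!is.null(primers) && nrow(des$ranking)) {
    top <- des$candidates[des$candidates$guide_id == des$ranking$guide_id[1], ]
    amplicons <- dplyr::bind_rows(lapply(seq_len(nrow(des$msa)), function(i) {
      seq_i <- gsub("-", "", des$msa$aligned[i], fixed = TRUE)
      hits <- predict_amplicon(seq_i, primers, guide = top)
      if (nrow(hits)) dplyr::mutate(hits, id = des$msa$id[i], .before = 1)
      else hits
    }))
  }
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- .write_pipeline_outputs(des, amplicons, params, rules, out_dir)
  }
  list(design = des, amplicons = amplicons, files = files)
}

.flatten_cols <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(x) paste(x, collapse = ","),
                         character(1))
    }
  }
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(.flatten_cols(as.data.frame(df)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

.write_pipeline_outputs <- function(des, amplicons, params, rules, out_dir) {
  p <- function(f) file.path(out_dir, f)
  files <- c(
    .write_tsv(des$candidates, p("candidates.tsv")),
    .write_tsv(des$predictions, p("predictions.tsv")),
    .write_tsv(des$ranking, p("ranking.tsv")))
  if (nrow(des$candidates)) {
    cons <- lapply(seq_len(nrow(des$candidates)), function(i) {
      build_construct(des$candidates[i, ])
    })
    recs <- tibble::tibble(
      id = paste0(des$candidates$guide_id, "_construct_top"),
      species = des$target_species,
      seq = vapply(cons, `[[`, character(1), "top"))
    files <- c(files, write_barcode_fasta(recs, p("constructs.fasta")))
  }
  if (!is.null(amplicons)) files <- c(files, .write_tsv(amplicons, p("amplicons.tsv")))
  cfg <- list(target = des$target_species,
              params = unclass(params), rules = unclass(rules))
  cfg_path <- p("config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  prov <- list(
    package = "crisprbarcode",
    version = as.character(utils::packageVersion("crisprbarcode")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    input_rows = nrow(des$msa),
    input_md5 = unname(tools::md5sum(.write_tsv(
      des$msa, p("alignment.tsv")))))
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE, digits = NA)
  c(files, cfg_path, p("alignment.tsv"), p("provenance.json"))
}
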