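# Independent oracles and small generators used across the suite.
# All of these are deliberately naive re-derivations (set arithmetic on
# IUPAC codes, exhaustive recursion, position-by-position sliding windows)
# so they share no code with the package internals they check.

IUPAC_SETS <- lapply(Biostrings::IUPAC_CODE_MAP, function(s)
  strsplit(s, "", fixed = TRUE)[[1]])

chars_of <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# set-intersection match of two IUPAC characters; gaps never match
oracle_match <- function(x, y) {
  if (x == "-" || y == "-") return(FALSE)
  length(intersect(IUPAC_SETS[[x]], IUPAC_SETS[[y]])) > 0
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N", `-` = "-")
  paste(rev(unname(comp[chars_of(s)])), collapse = "")
}

# exhaustive recursive global-alignment score (memoised on suffix pair)
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ac <- chars_of(a); bc <- chars_of(b)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i > length(ac) && j > length(bc)) 0
    else if (i > length(ac)) (length(bc) - j + 1) * gap
    else if (j > length(bc)) (length(ac) - i + 1) * gap
    else max(
      rec(i + 1, j + 1) + if (oracle_match(ac[i], bc[j])) match else mismatch,
      rec(i + 1, j) + gap,
      rec(i, j + 1) + gap)
    memo[[key]] <- res
    res
  }
  rec(1, 1)
}

# position-by-position PAM scan on both strands, plus-strand coordinates
oracle_scan_pams <- function(seq, pam = "TTTV", spacer_len = 21,
                             both = TRUE) {
  sc <- chars_of(seq); pc <- chars_of(pam)
  L <- length(sc); pl <- length(pc)
  hits <- list()
  for (i in 0:(L - pl)) {
    win <- sc[(i + 1):(i + pl)]
    if (all(mapply(oracle_match, win, pc)) && i + pl + spacer_len <= L) {
      hits[[length(hits) + 1]] <- data.frame(strand = "+", start = i,
                                             pam = paste(win, collapse = ""))
    }
    if (both) {
      # a minus-strand PAM occupying the same plus-strand window
      rc <- chars_of(oracle_revcomp(paste(win, collapse = "")))
      if (all(mapply(oracle_match, rc, pc)) && i - spacer_len >= 0) {
        hits[[length(hits) + 1]] <- data.frame(strand = "-", start = i,
                                               pam = paste(rc, collapse = ""))
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(strand = character(), start = integer(),
                      pam = character()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), ]
}

# sliding-window primer search with mismatch counting
oracle_locate <- function(seq, probe, max_mm) {
  sc <- chars_of(seq); pc <- chars_of(probe)
  L <- length(sc); pl <- length(pc)
  if (pl > L) {
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer()))
  }
  rows <- list()
  for (i in 0:(L - pl)) {
    mm <- sum(!mapply(oracle_match, sc[(i + 1):(i + pl)], pc))
    if (mm <= max_mm) {
      rows[[length(rows) + 1]] <- data.frame(start = i, end = i + pl,
                                             mismatches = mm)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer()))
  }
  do.call(rbind, rows)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_iupac <- function(n, gaps = FALSE) {
  pool <- names(Biostrings::IUPAC_CODE_MAP)
  if (gaps) pool <- c(pool, "-")
  paste(sample(pool, n, TRUE), collapse = "")
}

# a panel spec whose planted window fully discriminates the target and
# strictly dominates any other window: every off-target gets a variant PAM
# plus three seed mismatches (penalty 2 + 3*3 = 11 under strict rules),
# more than any overlapping window can collect from the same edits (at
# most 3 seed hits = 9)
recovery_spec <- function(seed) {
  set.seed(seed)
  strand <- sample(c("+", "-"), 1)
  gp <- sample(60:330, 1)
  n_sp <- sample(4:6, 1)
  edits <- lapply(seq_len(n_sp - 1), function(i) {
    tibble::tibble(zone = c("pam", "seed", "seed", "seed"),
                   offset = c(4L, sample(1:5, 3)),
                   new = NA_character_)
  })
  names(edits) <- paste0("species", 2:n_sp)
  panel_spec(seed = seed, n_species = n_sp, locus_len = 400L,
             guide_pos = gp, guide_strand = strand,
             offtarget_edits = edits, background_divergence = 0.02)
}
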