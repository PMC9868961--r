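#' Classify one alignment column of a guide/site pair
#'
#' Assigns each aligned column to exactly one pair class, comparing the
#' guide (in DNA alphabet, U already transliterated to T) against the
#' protospacer strand of the site:
#'
#' * `MATCH` — identical bases;
#' * `RNA_BULGE` — gap in the site row (an unpaired extra guide base);
#' * `DNA_BULGE` — gap in the guide row (an unpaired extra site base);
#' * `RR` — both purines (A/G), `YY` — both pyrimidines (C/T),
#'   `TV` — purine against pyrimidine (a transversion).
#'
#' A wobble flag is additionally raised on top of the RR/YY class when the
#' pairing with the target strand is the tolerated non-Watson-Crick rG:dT or
#' rU:dG pair, i.e. guide G over site A, or guide T over site C, in
#' protospacer-strand coordinates.
#'
#' @param guide_base Single character: A/C/G/T or `"-"`.
#' @param site_base Single character: A/C/G/T or `"-"`.
#' @return A list with `class` (one of MATCH, RR, YY, TV, RNA_BULGE,
#'   DNA_BULGE) and logical `wobble`.
#' @examples
#' classify_pair("G", "A")  # purine-purine mismatch, wobble-flagged
#' classify_pair("A", "C")  # transversion
#' @export
classify_pair <- function(guide_base, site_base) {
  if (guide_base == "-" && site_base == "-") {
    abort("an alignment column cannot contain two gaps")
  }
  if (site_base == "-") return(list(class = "RNA_BULGE", wobble = FALSE))
  if (guide_base == "-") return(list(class = "DNA_BULGE", wobble = FALSE))
  if (!guide_base %in% .BASES || !site_base %in% .BASES) {
    abort(sprintf("invalid bases in alignment column: '%s'/'%s'",
                  guide_base, site_base))
  }
  if (guide_base == site_base) return(list(class = "MATCH", wobble = FALSE))
  wob <- (guide_base == "G" && site_base == "A") ||
    (guide_base == "T" && site_base == "C")
  gp <- guide_base %in% .PURINES
  sp <- site_base %in% .PURINES
  cls <- if (gp && sp) "RR" else if (!gp && !sp) "YY" else "TV"
  list(class = cls, wobble = wob)
}

#' Align a guide RNA to a candidate protospacer
#'
#' Global (Needleman-Wunsch) alignment of the guide against the candidate
#' protospacer under a match/mismatch/linear-gap scoring triple, with
#' deterministic traceback (diagonal preferred over a gap in the site,
#' preferred over a gap in the guide, so ties always resolve to the same
#' alignment). Gaps model the bulges tolerated by the Cas9 R-loop: a gap in
#' the site row is an RNA bulge (unpaired guide base), a gap in the guide
#' row is a DNA bulge.
#'
#' @param guide Guide sequence (A/C/G/T; U transliterated to T on ingest).
#' @param protospacer Candidate protospacer sequence (A/C/G/T).
#' @param scoring Named numeric vector or list with `match`, `mismatch`,
#'   `gap` (defaults +1/-1/-2).
#' @return An object of class `guide_alignment`: list with `aligned_guide`,
#'   `aligned_site`, per-column `columns` (tibble of `guide_base`,
#'   `site_base`, `class`, `wobble`, `guide_pos`), `score`, and `counts`
#'   (mismatches, mismatches_17_20, rna_bulges, dna_bulges, wobble_total,
#'   tv_total, rr_total, yy_total).
#' @examples
#' aln <- align_guide_to_site("ACGTA", "ACTA")
#' aln$counts$rna_bulges
#' @export
align_guide_to_site <- function(guide, protospacer,
                                scoring = c(match = 1, mismatch = -1,
                                            gap = -2)) {
  scoring <- as.list(scoring)
  if (!all(c("match", "mismatch", "gap") %in% names(scoring))) {
    abort("scoring must provide match, mismatch and gap values")
  }
  guide <- toupper(gsub("U", "T", guide, fixed = TRUE))
  protospacer <- toupper(protospacer)
  if (!nzchar(guide) || !nzchar(protospacer)) {
    abort("guide and protospacer must be non-empty")
  }
  if (!.is_acgt(guide)) abort("guide contains non-ACGT bases")
  if (!.is_acgt(protospacer)) abort("protospacer contains non-ACGT bases")

  a <- .chars(guide)
  b <- .chars(protospacer)
  n <- length(a)
  m <- length(b)
  sm <- scoring$match
  sx <- scoring$mismatch
  sg <- scoring$gap

  # DP matrix; move[i+1, j+1] records the argmax with the fixed preference
  # diag (1) > up/gap-in-site (2) > left/gap-in-guide (3)
  S <- matrix(0, n + 1L, m + 1L)
  M <- matrix(0L, n + 1L, m + 1L)
  S[, 1L] <- sg * (0:n)
  S[1L, ] <- sg * (0:m)
  M[2:(n + 1L), 1L] <- 2L
  M[1L, 2:(m + 1L)] <- 3L
  for (i in seq_len(n)) {
    sub_i <- ifelse(a[i] == b, sm, sx)
    for (j in seq_len(m)) {
      diag <- S[i, j] + sub_i[j]
      up <- S[i, j + 1L] + sg
      left <- S[i + 1L, j] + sg
      best <- max(diag, up, left)
      S[i + 1L, j + 1L] <- best
      M[i + 1L, j + 1L] <- if (diag == best) 1L else if (up == best) 2L else 3L
    }
  }
  # traceback
  ag <- character()
  as_ <- character()
  i <- n
  j <- m
  while (i > 0L || j > 0L) {
    mv <- M[i + 1L, j + 1L]
    if (mv == 1L) {
      ag <- c(a[i], ag); as_ <- c(b[j], as_); i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      ag <- c(a[i], ag); as_ <- c("-", as_); i <- i - 1L
    } else {
      ag <- c("-", ag); as_ <- c(b[j], as_); j <- j - 1L
    }
  }
  cls <- map(seq_along(ag), function(k) classify_pair(ag[k], as_[k]))
  columns <- tibble(
    guide_base = ag,
    site_base = as_,
    class = map_chr(cls, "class"),
    wobble = purrr::map_lgl(cls, "wobble"),
    guide_pos = cumsum(ag != "-") * (ag != "-")
  )
  columns$guide_pos[columns$guide_pos == 0L] <- NA_integer_
  mism <- columns$class %in% c("RR", "YY", "TV")
  counts <- tibble(
    mismatches = sum(mism),
    mismatches_17_20 = .seed_window_count(columns, n),
    rna_bulges = sum(columns$class == "RNA_BULGE"),
    dna_bulges = sum(columns$class == "DNA_BULGE"),
    wobble_total = sum(columns$wobble),
    tv_total = sum(columns$class == "TV"),
    rr_total = sum(columns$class == "RR"),
    yy_total = sum(columns$class == "YY")
  )
  structure(list(
    aligned_guide = paste(ag, collapse = ""),
    aligned_site = paste(as_, collapse = ""),
    columns = columns,
    score = S[n + 1L, m + 1L],
    counts = counts,
    guide_length = n,
    scoring = scoring
  ), class = "guide_alignment")
}

# mismatches in the 4 PAM-proximal guide positions (17-20 for a 20-mer)
.seed_window_count <- function(columns, guide_len) {
  lo <- max(1L, guide_len - 3L)
  positional_mismatches_impl(columns, lo, guide_len)
}

positional_mismatches_impl <- function(columns, lo, hi) {
  mism <- columns$class %in% c("RR", "YY", "TV")
  pos <- columns$guide_pos
  sum(mism & !is.na(pos) & pos >= lo & pos <= hi)
}

#' Count mismatches within a guide-position window
#'
#' Guide positions are numbered 1 at the PAM-distal (5') end up to the
#' guide length at the PAM-proximal end, so the window 17-20 of a 20-nt
#' guide is the seed region next to the PAM. For guides shorter than 20 nt
#' pass the corresponding PAM-proximal window (see
#' [align_guide_to_site()], whose `mismatches_17_20` count already uses the
#' 4 PAM-proximal positions whatever the guide length).
#'
#' @param alignment A `guide_alignment`.
#' @param window Integer vector of length 2: first and last guide position
#'   (inclusive).
#' @return Integer count of mismatch columns in the window.
#' @export
positional_mismatches <- function(alignment, window) {
  stopifnot(inherits(alignment, "guide_alignment"))
  lo <- as.integer(window[1])
  hi <- as.integer(window[2])
  if (lo < 1L || hi > alignment$guide_length || lo > hi) {
    abort(sprintf("window [%d, %d] outside guide positions 1..%d",
                  lo, hi, alignment$guide_length))
  }
  positional_mismatches_impl(alignment$columns, lo, hi)
}

#' @export
print.guide_alignment <- function(x, ...) {
  bar <- ifelse(x$columns$class == "MATCH", "|",
                ifelse(x$columns$class %in% c("RNA_BULGE", "DNA_BULGE"),
                       " ", ifelse(x$columns$wobble, ":", ".")))
  cat("guide  ", x$aligned_guide, "\n",
      "       ", paste(bar, collapse = ""), "\n",
      "site   ", x$aligned_site, "\n", sep = "")
  cat(sprintf("score %g; %d mismatch(es), %d RNA / %d DNA bulge(s)\n",
              x$score, x$counts$mismatches, x$counts$rna_bulges,
              x$counts$dna_bulges))
  invisible(x)
}

#' Alignment-derived feature block for one guide/site pair
#'
#' The nine alignment features of the registry, as a one-row tibble:
#' pairwise alignment score, wobble total, RNA bulges, mismatches in the
#' PAM-proximal 17-20 window, total mismatches, DNA bulges, and the
#' transversion / purine-purine / pyrimidine-pyrimidine mismatch totals.
#'
#' @param alignment A `guide_alignment`.
#' @return A one-row tibble with 9 numeric columns.
#' @export
alignment_features <- function(alignment) {
  stopifnot(inherits(alignment, "guide_alignment"))
  bind_cols(tibble(alignment_score = alignment$score),
            alignment$counts[, c("wobble_total", "rna_bulges",
                                 "mismatches_17_20", "mismatches",
                                 "dna_bulges", "tv_total", "rr_total",
                                 "yy_total")])
}
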