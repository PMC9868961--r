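#' PAM-site features of a candidate cleavage site
#'
#' Reads the 3-nt PAM immediately 3' of the protospacer and the nearby
#' downstream bases from the genomic context. The PAM type is decided
#' solely by PAM positions 2-3: `GG` gives `NGG` (canonical), `AG` gives
#' `NAG` (tolerated), anything else `OTHER`. Downstream positions 1, 2 and
#' 5 are the bases that many 3' of the PAM end; when the context is too
#' short they are returned as `NA` and flagged missing rather than imputed.
#'
#' @param context Genomic context string (A/C/G/T/N).
#' @param protospacer_end_offset 0-based half-open end of the protospacer
#'   within `context` (i.e. the offset of the first PAM base).
#' @return A one-row tibble: `pam`, `pam_type`, `pam_n`, `downstream_nt_1`,
#'   `downstream_nt_2`, `downstream_nt_5` (NA when out of range).
#' @examples
#' pam_features("AAAATGGTTCCCG", 4L)  # PAM TGG -> NGG, N = T
#' @export
pam_features <- function(context, protospacer_end_offset) {
  end <- as.integer(protospacer_end_offset)
  if (nchar(context) < end + 3L) {
    abort("context too short to contain a 3-nt PAM at the stated offset")
  }
  pam <- substr(context, end + 1L, end + 3L)
  p23 <- substr(pam, 2L, 3L)
  pam_type <- if (p23 == "GG") "NGG" else if (p23 == "AG") "NAG" else "OTHER"
  down <- function(k) {
    pos <- end + 3L + k
    if (nchar(context) >= pos) {
      b <- substr(context, pos, pos)
      if (b %in% .BASES) b else NA_character_
    } else NA_character_
  }
  tibble(pam = pam, pam_type = pam_type,
         pam_n = substr(pam, 1L, 1L),
         downstream_nt_1 = down(1L),
         downstream_nt_2 = down(2L),
         downstream_nt_5 = down(5L))
}

#' GC content of a sequence
#'
#' Proportion of G+C among unambiguous bases; `N` is excluded from both
#' numerator and denominator.
#'
#' @param seq Nucleotide string (A/C/G/T/N).
#' @return Proportion in \[0, 1\].
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) abort("empty sequence")
  ch <- .chars(toupper(seq))
  if (!all(ch %in% c(.BASES, "N"))) abort("sequence may contain only ACGTN")
  ch <- ch[ch != "N"]
  if (!length(ch)) abort("sequence is all N: GC content undefined")
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Nearest-neighbor duplex-formation enthalpy of a DNA sequence
#'
#' Sums the nearest-neighbor enthalpy increments (delta-H, kcal/mol) over
#' every adjacent dinucleotide stack of the sequence. The default parameter
#' set is the SantaLucia (1998) unified DNA/DNA table shipped with the
#' package; any 16-entry table can be supplied instead. `N` breaks the
#' window: stacks touching an `N` are skipped with a warning, so the value
#' is the sum over the N-free segments.
#'
#' @param seq Nucleotide string, length >= 2 for a non-zero value.
#' @param table Named numeric vector of 16 dinucleotide enthalpies, as
#'   returned by [nn_enthalpy_table()].
#' @return Enthalpy in kcal/mol (negative for stabilizing stacks). A
#'   single-base sequence returns 0 with a warning.
#' @examples
#' nn_enthalpy("AA")     # the AA/TT stack: -7.9
#' nn_enthalpy("GATTACA")
#' @export
nn_enthalpy <- function(seq, table = nn_enthalpy_table()) {
  seq <- toupper(seq)
  ch <- .chars(seq)
  if (!all(ch %in% c(.BASES, "N"))) {
    abort("sequence may contain only ACGTN")
  }
  if (length(ch) < 2L) {
    warn("sequence shorter than 2 nt has no dinucleotide stacks; enthalpy 0")
    return(0)
  }
  if (any(ch == "N")) {
    warn("sequence contains N; stacks touching N are skipped")
  }
  di <- paste0(ch[-length(ch)], ch[-1L])
  di <- di[!grepl("N", di, fixed = TRUE)]
  if (!length(di)) return(0)
  unknown <- setdiff(unique(di), names(table))
  if (length(unknown)) {
    abort(paste0("dinucleotide(s) missing from the parameter table: ",
                 paste(unknown, collapse = ", ")))
  }
  sum(table[di])
}

#' Nearest-neighbor enthalpy parameter table
#'
#' Loads a 16-entry dinucleotide delta-H table (kcal/mol) from a
#' tab-delimited file with columns `dinucleotide` and `dH_kcal_mol`. The
#' default is the SantaLucia (1998) unified DNA/DNA parameter set shipped
#' under `extdata`.
#'
#' @param path Path to the parameter file; default the shipped table.
#' @return Named numeric vector of length 16.
#' @export
nn_enthalpy_table <- function(path = system.file(
  "extdata", "santalucia1998_unified_dH.tsv", package = "crisprcleavr")) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  setNames(tab$dH_kcal_mol, tab$dinucleotide)
}

#' Positional nucleotide features of a protospacer
#'
#' The identity of the bases at guide positions 2, 4 and 20 and the
#' dinucleotide at positions 4-5, numbered 1 at the PAM-distal (5') end.
#' For guides shorter than 20 nt the "position 20" feature falls back to
#' the PAM-proximal (last) base.
#'
#' @param protospacer Protospacer (or guide) string, length >= 5.
#' @return A one-row tibble: `nt_position_2`, `nt_position_4`,
#'   `nt_positions_4_5`, `nt_position_20`.
#' @export
positional_nucleotides <- function(protospacer) {
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) < 5L) {
    abort("protospacer must be at least 5 nt for positional features")
  }
  if (!.is_acgt(protospacer)) abort("protospacer contains non-ACGT bases")
  last <- min(nchar(protospacer), 20L)
  tibble(nt_position_2 = substr(protospacer, 2L, 2L),
         nt_position_4 = substr(protospacer, 4L, 4L),
         nt_positions_4_5 = substr(protospacer, 4L, 5L),
         nt_position_20 = substr(protospacer, last, last))
}

#' The 30-feature registry
#'
#' The machine-readable manifest of the feature set: name, block
#' (`alignment`, `content`, `pam`), type (`numeric`, `binary`,
#' `categorical`), encoding and categorical levels. Categorical features
#' are one-hot expanded in the feature matrix; [feature_registry_columns()]
#' gives the expanded column order, which is stable across runs and equals
#' the feature-matrix header.
#'
#' @return A 30-row tibble: `feature`, `block`, `type`, `encoding`,
#'   `levels` (list-column).
#' @export
feature_registry <- function() {
  nt <- list(.BASES)
  dint <- list(as.vector(outer(.BASES, .BASES, paste0)))
  tribble_args <- list(
    # alignment block
    list("alignment_score", "alignment", "numeric", "identity", list(NULL)),
    list("wobble_total", "alignment", "numeric", "identity", list(NULL)),
    list("rna_bulges", "alignment", "numeric", "identity", list(NULL)),
    list("mismatches_17_20", "alignment", "numeric", "identity", list(NULL)),
    list("mismatches", "alignment", "numeric", "identity", list(NULL)),
    list("dna_bulges", "alignment", "numeric", "identity", list(NULL)),
    list("tv_total", "alignment", "numeric", "identity", list(NULL)),
    list("rr_total", "alignment", "numeric", "identity", list(NULL)),
    list("yy_total", "alignment", "numeric", "identity", list(NULL)),
    # nucleotide-content block
    list("nt_position_20", "content", "categorical", "onehot", nt),
    list("mgw_pam", "content", "numeric", "identity", list(NULL)),
    list("dna_enthalpy_223", "content", "numeric", "identity", list(NULL)),
    list("nt_position_2", "content", "categorical", "onehot", nt),
    list("dhs_signal", "content", "numeric", "identity", list(NULL)),
    list("guanine_occupancy", "content", "numeric", "identity", list(NULL)),
    list("distance_from_nucleosome", "content", "numeric", "identity",
         list(NULL)),
    list("nt_positions_4_5", "content", "categorical", "onehot", dint),
    list("transcription_region", "content", "binary", "identity",
         list(NULL)),
    list("coding_region", "content", "binary", "identity", list(NULL)),
    list("gc_content_extended", "content", "numeric", "identity",
         list(NULL)),
    list("nt_position_4", "content", "categorical", "onehot", nt),
    # PAM block
    list("pam_type", "pam", "categorical", "onehot",
         list(c("NGG", "NAG", "OTHER"))),
    list("in_exon_non_ngg", "pam", "binary", "identity", list(NULL)),
    list("downstream_nt_1", "pam", "categorical", "onehot_missing", nt),
    list("downstream_nt_5", "pam", "categorical", "onehot_missing", nt),
    list("downstream_nt_2", "pam", "categorical", "onehot_missing", nt),
    list("in_exon_ngg", "pam", "binary", "identity", list(NULL)),
    list("ngg_strand_expression", "pam", "numeric", "identity", list(NULL)),
    list("non_ngg_strand_expression", "pam", "numeric", "identity",
         list(NULL)),
    list("pam_n", "pam", "categorical", "onehot", nt)
  )
  tibble(
    feature = map_chr(tribble_args, 1L),
    block = map_chr(tribble_args, 2L),
    type = map_chr(tribble_args, 3L),
    encoding = map_chr(tribble_args, 4L),
    levels = map(tribble_args, function(x) x[[5]][[1]])
  )
}

#' Expanded feature-matrix column order
#'
#' One-hot categorical features expand to one indicator column per level
#' (`<feature>.<level>`); features whose encoding allows missingness get an
#' additional `<feature>.missing` flag. The order follows the registry.
#'
#' @return Character vector of expanded column names.
#' @export
feature_registry_columns <- function() {
  reg <- feature_registry()
  unlist(pmap(reg, function(feature, block, type, encoding, levels) {
    if (encoding == "identity") return(feature)
    cols <- paste0(feature, ".", levels)
    if (encoding == "onehot_missing") cols <- c(cols, paste0(feature,
                                                             ".missing"))
    cols
  }), use.names = FALSE)
}

# one-hot encode a single categorical value; NA -> all zeros (+ flag)
.onehot <- function(value, feature, levels, missing_flag = FALSE) {
  v <- as.numeric(!is.na(value) & levels == value)
  out <- setNames(as.list(v), paste0(feature, ".", levels))
  if (missing_flag) out[[paste0(feature, ".missing")]] <-
      as.numeric(is.na(value))
  out
}

# the extended window: up to `width` nt of context centered on the
# protospacer span [start, end) (0-based half-open)
.extended_window <- function(context, start, end, width = 223L) {
  len <- nchar(context)
  span <- end - start
  extra <- max(0L, width - span)
  up <- extra %/% 2L
  lo <- max(0L, start - up)
  hi <- min(len, lo + width)
  lo <- max(0L, hi - width)
  substr(context, lo + 1L, hi)
}

#' Assemble the full feature vector for one guide/site pair
#'
#' Combines the nine alignment features, the nucleotide-content block
#' (positional bases, GC content and nearest-neighbor enthalpy over the
#' 223-nt extended window centered on the protospacer, plus the annotation
#' signals), and the PAM block into the registry-ordered, one-hot expanded
#' feature row. Featurization is a pure, deterministic function of its
#' inputs.
#'
#' @param guide One row of a guides table (`guide_id`, `sequence`).
#' @param site One row of a sites table.
#' @param alignment Optional precomputed `guide_alignment`; computed from
#'   `guide$sequence` and `site$protospacer` when `NULL`.
#' @param annotations An annotation bundle for the site, as returned by an
#'   annotation provider; default neutral values.
#' @param scoring Alignment scoring triple, used when `alignment` is `NULL`.
#' @param window_width Width of the extended window (default 223 nt).
#' @param max_bulges Maximum total bulges tolerated per alignment before
#'   featurization refuses the pair (default 2; larger indel structures are
#'   outside the CRISPR off-target regime).
#' @return A one-row tibble with `site_id`, `label`, then the expanded
#'   feature columns in registry order.
#' @export
build_feature_vector <- function(guide, site, alignment = NULL,
                                 annotations = annotation_neutral(),
                                 scoring = c(match = 1, mismatch = -1,
                                             gap = -2),
                                 window_width = 223L, max_bulges = 2L) {
  if (guide$guide_id != site$guide_id) {
    abort(sprintf("guide/site linkage mismatch: guide '%s' vs site '%s'",
                  guide$guide_id, site$guide_id))
  }
  if (is.null(alignment)) {
    alignment <- align_guide_to_site(guide$sequence, site$protospacer,
                                     scoring)
  }
  n_bulges <- alignment$counts$rna_bulges + alignment$counts$dna_bulges
  if (n_bulges > max_bulges) {
    abort(sprintf(
      "site %s: %d bulges exceed the maximum of %d tolerated at featurization",
      site$site_id, n_bulges, max_bulges))
  }
  proto_end <- site$context_offset + nchar(site$protospacer)
  pam <- pam_features(site$context, proto_end)
  posn <- positional_nucleotides(site$protospacer)
  ext <- .extended_window(site$context, site$context_offset,
                          proto_end + 3L, window_width)
  gc_ext <- gc_content(ext)
  dh <- suppressWarnings(nn_enthalpy(ext))

  vals <- c(
    as.list(alignment_features(alignment)),
    .onehot(posn$nt_position_20, "nt_position_20", .BASES),
    list(mgw_pam = annotations$mgw_pam,
         dna_enthalpy_223 = dh),
    .onehot(posn$nt_position_2, "nt_position_2", .BASES),
    list(dhs_signal = annotations$dhs_signal,
         guanine_occupancy = annotations$guanine_occupancy,
         distance_from_nucleosome = annotations$distance_from_nucleosome),
    .onehot(posn$nt_positions_4_5, "nt_positions_4_5",
            as.vector(outer(.BASES, .BASES, paste0))),
    list(transcription_region = annotations$transcription_region,
         coding_region = annotations$coding_region,
         gc_content_extended = gc_ext),
    .onehot(posn$nt_position_4, "nt_position_4", .BASES),
    .onehot(pam$pam_type, "pam_type", c("NGG", "NAG", "OTHER")),
    list(in_exon_non_ngg = annotations$in_exon_non_ngg),
    .onehot(pam$downstream_nt_1, "downstream_nt_1", .BASES,
            missing_flag = TRUE),
    .onehot(pam$downstream_nt_5, "downstream_nt_5", .BASES,
            missing_flag = TRUE),
    .onehot(pam$downstream_nt_2, "downstream_nt_2", .BASES,
            missing_flag = TRUE),
    list(in_exon_ngg = annotations$in_exon_ngg,
         ngg_strand_expression = annotations$ngg_strand_expression,
         non_ngg_strand_expression = annotations$non_ngg_strand_expression),
    .onehot(pam$pam_n, "pam_n", .BASES)
  )
  row <- as_tibble(vals)[, feature_registry_columns()]
  bind_cols(tibble(site_id = site$site_id, label = site$label), row)
}

#' Featurize every site of a dataset
#'
#' Runs [build_feature_vector()] across all sites of a dataset, aligning
#' each protospacer to its guide, and returns the feature matrix as a
#' tibble (one row per site, columns in registry order).
#'
#' @param ds A `guide_dataset`.
#' @param annotations An annotation provider function
#'   (`function(site) -> bundle`), default the neutral provider; see
#'   [annotation_provider_neutral()].
#' @param scoring,window_width,max_bulges Passed to
#'   [build_feature_vector()].
#' @return A tibble: `site_id`, `label`, then the expanded feature columns.
#' @export
featurize_dataset <- function(ds, annotations = annotation_provider_neutral(),
                              scoring = c(match = 1, mismatch = -1,
                                          gap = -2),
                              window_width = 223L, max_bulges = 2L) {
  validate_guide_dataset(ds)
  gmap <- split(ds$guides, ds$guides$guide_id)
  rows <- map(seq_len(nrow(ds$sites)), function(i) {
    site <- ds$sites[i, ]
    build_feature_vector(gmap[[site$guide_id]], site,
                         annotations = annotations(site),
                         scoring = scoring, window_width = window_width,
                         max_bulges = max_bulges)
  })
  list_rbind(rows)
}
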