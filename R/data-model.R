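#' Construct a labeled guide/target-site dataset
#'
#' Bundles a table of single-guide RNAs (sgRNAs) and a table of candidate
#' genomic cleavage sites into a validated dataset object, the central
#' container of the package. Every site references a guide, carries the
#' protospacer it presents to Cas9, the 3-nt PAM immediately 3' of it, a
#' stretch of flanking genomic context, and a binary label (1 = on-target,
#' 0 = off-target).
#'
#' Coordinates are 0-based half-open internally: `context_offset` is the
#' position of the first protospacer base within `context`, so
#' `substr(context, context_offset + 1, context_offset + nchar(protospacer))`
#' recovers the protospacer. Minus-strand sites are stored already
#' reverse-complemented into protospacer orientation; `strand` is metadata.
#'
#' @param guides A data frame with columns `guide_id`, `sequence` (17-20 nt,
#'   A/C/G/T; U is transliterated to T) and optionally `crop`.
#' @param sites A data frame with columns `site_id`, `guide_id`,
#'   `protospacer`, `pam` (3 nt), `context`, `context_offset`, `label`
#'   (0/1) and optionally `strand` (+/-) and `source`.
#' @return An object of class `guide_dataset`: a list with tibbles `guides`
#'   and `sites`.
#' @examples
#' g <- tibble::tibble(guide_id = "g1", sequence = "GATTACAGATTACAGATTAC",
#'                     crop = "rice")
#' s <- tibble::tibble(site_id = "s1", guide_id = "g1",
#'                     protospacer = g$sequence, pam = "TGG",
#'                     context = paste0("AAAA", g$sequence, "TGG", "AAAA"),
#'                     context_offset = 4L, label = 1L, strand = "+",
#'                     source = "example")
#' ds <- guide_dataset(g, s)
#' class_counts(ds)
#' @export
guide_dataset <- function(guides, sites) {
  guides <- as_tibble(guides)
  sites <- as_tibble(sites)
  if (!"crop" %in% names(guides)) guides$crop <- NA_character_
  if (!"strand" %in% names(sites)) sites$strand <- "+"
  if (!"source" %in% names(sites)) sites$source <- NA_character_
  guides$sequence <- toupper(gsub("U", "T", guides$sequence, fixed = TRUE))
  for (col in c("protospacer", "pam", "context")) {
    sites[[col]] <- toupper(sites[[col]])
  }
  sites$label <- as.integer(sites$label)
  sites$context_offset <- as.integer(sites$context_offset)
  ds <- structure(list(guides = guides, sites = sites),
                  class = "guide_dataset")
  validate_guide_dataset(ds)
  ds
}

#' Validate a guide/site dataset against its invariants
#'
#' Checks every structural invariant of the container: guide lengths and
#' alphabet, unique guide ids, resolvable foreign keys, 3-nt PAMs, binary
#' labels, and that protospacer+PAM is a contiguous substring of the context
#' at the recorded offset. Ambiguous bases (N) are permitted only in the
#' context flanks, never in protospacer or PAM. Violations are reported with
#' row-level diagnostics.
#'
#' @param ds A `guide_dataset`.
#' @return `ds`, invisibly, if valid; otherwise an error naming the offending
#'   rows.
#' @export
validate_guide_dataset <- function(ds) {
  g <- ds$guides
  s <- ds$sites
  req_g <- c("guide_id", "sequence")
  req_s <- c("site_id", "guide_id", "protospacer", "pam", "context",
             "context_offset", "label")
  if (!all(req_g %in% names(g))) {
    abort(paste0("guides table is missing column(s): ",
                 paste(setdiff(req_g, names(g)), collapse = ", ")),
          class = "crisprcleavr_format_error")
  }
  if (!all(req_s %in% names(s))) {
    abort(paste0("sites table is missing column(s): ",
                 paste(setdiff(req_s, names(s)), collapse = ", ")),
          class = "crisprcleavr_format_error")
  }
  problems <- character()
  bad_len <- which(nchar(g$sequence) < 17 | nchar(g$sequence) > 20)
  if (length(bad_len)) {
    problems <- c(problems, paste0(
      "guide row ", bad_len, " (", g$guide_id[bad_len],
      "): length ", nchar(g$sequence)[bad_len], " outside [17, 20]"))
  }
  bad_alpha <- which(!.is_acgt(g$sequence))
  if (length(bad_alpha)) {
    problems <- c(problems, paste0(
      "guide row ", bad_alpha, " (", g$guide_id[bad_alpha],
      "): non-ACGT base in sequence"))
  }
  if (anyDuplicated(g$guide_id)) {
    dup <- unique(g$guide_id[duplicated(g$guide_id)])
    problems <- c(problems, paste0("duplicated guide_id: ",
                                   paste(dup, collapse = ", ")))
  }
  orphan <- which(!s$guide_id %in% g$guide_id)
  if (length(orphan)) {
    problems <- c(problems, paste0(
      "site row ", orphan, " (", s$site_id[orphan],
      "): unknown guide_id '", s$guide_id[orphan], "'"))
  }
  bad_label <- which(!s$label %in% c(0L, 1L))
  if (length(bad_label)) {
    problems <- c(problems, paste0(
      "site row ", bad_label, " (", s$site_id[bad_label],
      "): label must be 0 or 1, got ", s$label[bad_label]))
  }
  bad_pam <- which(nchar(s$pam) != 3L | !.is_acgt(s$pam))
  if (length(bad_pam)) {
    problems <- c(problems, paste0(
      "site row ", bad_pam, " (", s$site_id[bad_pam],
      "): PAM must be 3 ACGT bases, got '", s$pam[bad_pam], "'"))
  }
  bad_proto <- which(!.is_acgt(s$protospacer))
  if (length(bad_proto)) {
    problems <- c(problems, paste0(
      "site row ", bad_proto, " (", s$site_id[bad_proto],
      "): non-ACGT base in protospacer"))
  }
  bad_ctx <- which(!.is_acgtn(s$context))
  if (length(bad_ctx)) {
    problems <- c(problems, paste0(
      "site row ", bad_ctx, " (", s$site_id[bad_ctx],
      "): context may contain only A/C/G/T/N"))
  }
  emb <- substr(s$context, s$context_offset + 1L,
                s$context_offset + nchar(s$protospacer) + 3L)
  bad_emb <- which(emb != paste0(s$protospacer, s$pam))
  bad_emb <- setdiff(bad_emb, union(bad_pam, union(bad_proto, bad_ctx)))
  if (length(bad_emb)) {
    problems <- c(problems, paste0(
      "site row ", bad_emb, " (", s$site_id[bad_emb],
      "): protospacer+PAM is not found in context at offset ",
      s$context_offset[bad_emb]))
  }
  if (length(problems)) {
    abort(c("invalid guide_dataset:", problems),
          class = "crisprcleavr_validation_error")
  }
  invisible(ds)
}

#' @export
print.guide_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf(
    "<guide_dataset> %d guides, %d sites (%d on-target, %d off-target)\n",
    nrow(x$guides), nrow(x$sites), cc$n_on, cc$n_off))
  if ("split" %in% names(x$sites)) {
    tab <- table(x$sites$split)
    cat("  split:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Class counts of a labeled dataset
#'
#' @param ds A `guide_dataset`.
#' @return A one-row tibble with `n_sites`, `n_on` (label 1) and `n_off`
#'   (label 0).
#' @export
class_counts <- function(ds) {
  tibble(n_sites = nrow(ds$sites),
         n_on = sum(ds$sites$label == 1L),
         n_off = sum(ds$sites$label == 0L))
}

#' Read a labeled dataset from a guide FASTA and a site table
#'
#' The guide FASTA holds one record per guide; the record id is the
#' `guide_id` and the description (after the first space) is taken as the
#' crop tag when present. The site table is a CSV/TSV with the documented
#' header (`site_id`, `guide_id`, `protospacer`, `pam`, `context`,
#' `context_offset`, `label`, optionally `strand`, `source`). Rows failing
#' the dataset invariants are rejected with row-level diagnostics.
#'
#' @param guide_fasta Path to the guide FASTA file.
#' @param site_table Path to the delimited site table (delimiter inferred
#'   from the extension: `.tsv` reads tab, anything else comma).
#' @return A validated `guide_dataset`.
#' @export
read_dataset <- function(guide_fasta, site_table) {
  if (!file.exists(guide_fasta)) {
    abort(paste0("guide FASTA not found: ", guide_fasta),
          class = "crisprcleavr_format_error")
  }
  if (!file.exists(site_table)) {
    abort(paste0("site table not found: ", site_table),
          class = "crisprcleavr_format_error")
  }
  seqs <- Biostrings::readDNAStringSet(guide_fasta)
  nm <- names(seqs)
  guide_id <- sub("\\s.*$", "", nm)
  crop <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), NA_character_)
  guides <- tibble(guide_id = guide_id,
                   sequence = unname(as.character(seqs)),
                   crop = crop)
  delim <- if (grepl("\\.tsv$", site_table, ignore.case = TRUE)) "\t" else ","
  sites <- readr::read_delim(site_table, delim = delim,
                             col_types = readr::cols(.default = "c"),
                             progress = FALSE, show_col_types = FALSE)
  req <- c("site_id", "guide_id", "protospacer", "pam", "context",
           "context_offset", "label")
  missing_cols <- setdiff(req, names(sites))
  if (length(missing_cols)) {
    abort(paste0("site table ", site_table, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "crisprcleavr_format_error")
  }
  sites$context_offset <- as.integer(sites$context_offset)
  suppressWarnings(lab <- as.integer(sites$label))
  if (anyNA(lab)) {
    bad <- which(is.na(lab))
    abort(paste0("site table row ", bad, " (", sites$site_id[bad],
                 "): non-integer label '", sites$label[bad], "'"),
          class = "crisprcleavr_validation_error")
  }
  sites$label <- lab
  guide_dataset(guides, sites)
}

#' Write a labeled dataset to a guide FASTA and a site CSV
#'
#' Inverse of [read_dataset()]: the pair of files round-trips to an
#' identical dataset.
#'
#' @param ds A `guide_dataset`.
#' @param guide_fasta Output path for the guide FASTA.
#' @param site_table Output path for the site CSV.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_dataset <- function(ds, guide_fasta, site_table) {
  validate_guide_dataset(ds)
  seqs <- Biostrings::DNAStringSet(ds$guides$sequence)
  names(seqs) <- ifelse(is.na(ds$guides$crop), ds$guides$guide_id,
                        paste(ds$guides$guide_id, ds$guides$crop))
  Biostrings::writeXStringSet(seqs, guide_fasta)
  cols <- c("site_id", "guide_id", "protospacer", "pam", "context",
            "context_offset", "label", "strand", "source")
  readr::write_csv(ds$sites[, intersect(cols, names(ds$sites))], site_table,
                   progress = FALSE)
  invisible(c(guide_fasta, site_table))
}

#' Split a dataset into training and test portions
#'
#' Random split by site record. The training portion has exactly
#' `floor(train_fraction * N)` sites; with the default 0.7 fraction a
#' 379-site dataset splits into 265 training and 114 test records. The
#' assignment is a deterministic function of `seed`.
#'
#' @param ds A `guide_dataset`.
#' @param train_fraction Proportion of sites assigned to training
#'   (0 < f < 1; default 0.7).
#' @param seed Integer seed controlling the random assignment.
#' @param group_by_guide If `TRUE`, whole guides (with all their sites) are
#'   assigned to one side, accumulating guides until the training target is
#'   reached. Off by default: the reference protocol splits individual site
#'   records by chance.
#' @return `ds` with a `split` column (`"train"`/`"test"`) added to
#'   `ds$sites`.
#' @export
split_dataset <- function(ds, train_fraction = 0.7, seed = 1L,
                          group_by_guide = FALSE) {
  n <- nrow(ds$sites)
  if (n == 0L) abort("cannot split an empty dataset")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  n_train <- floor(train_fraction * n)
  if (n_train == 0L || n_train == n) {
    abort(sprintf("degenerate split: %d of %d sites in training", n_train, n))
  }
  split <- rep("test", n)
  if (group_by_guide) {
    gids <- .with_seed(seed, sample(unique(ds$sites$guide_id)))
    taken <- 0L
    for (gid in gids) {
      if (taken >= n_train) break
      idx <- which(ds$sites$guide_id == gid)
      split[idx] <- "train"
      taken <- taken + length(idx)
    }
  } else {
    idx <- .with_seed(seed, sample.int(n, n_train))
    split[idx] <- "train"
  }
  ds$sites$split <- split
  ds
}

#' Build k disjoint cross-validation folds
#'
#' Partitions ids into `k` folds whose sizes differ by at most one,
#' deterministically under `seed`.
#'
#' @param ids Character or integer vector of record ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A tibble with columns `id` and `fold` (1..k).
#' @export
make_cv_folds <- function(ids, k = 5L, seed = 1L) {
  n <- length(ids)
  if (k < 2L) abort("k must be at least 2")
  if (k > n) abort(sprintf("k = %d exceeds the number of ids (%d)", k, n))
  perm <- .with_seed(seed, sample.int(n))
  # fold sizes: n %% k folds get one extra record
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold <- rep(seq_len(k), times = sizes)
  tibble(id = ids[perm], fold = fold) |> arrange(.data$id)
}

#' Write a computed feature matrix to CSV
#'
#' Emits the per-site feature matrix with its registry-ordered header, the
#' site id, and the label column. Numeric values are written at full
#' precision so the file round-trips losslessly.
#'
#' @param features A tibble as produced by [featurize_dataset()]: `site_id`,
#'   `label`, then the expanded feature columns.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(features, path) {
  if (is.null(features) || nrow(features) == 0L) {
    abort("no features to write: featurize the dataset first")
  }
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return A tibble with `site_id`, `label` and numeric feature columns.
#' @export
read_feature_matrix <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    site_id = "c", label = "i", .default = "d"),
    progress = FALSE, show_col_types = FALSE)
}

# evaluate an expression under a temporary RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
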