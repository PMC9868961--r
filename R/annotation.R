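#' Neutral genomic-annotation bundle
#'
#' The genomic-context features of the registry (chromatin accessibility,
#' nucleosome distance, strandwise expression, exon/transcription/coding
#' flags, guanine occupancy, minor groove width at the PAM pentamer) require
#' genome-browser tracks that exist for few plant genomes and cannot be
#' fetched by this package. They therefore enter through a provider
#' interface; the neutral bundle is the documented default for every field:
#' 0 for signals and flags, including the minor groove width, for which no
#' redistributable pentamer reference table is available. With neutral
#' defaults these features are constant and carry no class signal, which is
#' exactly the honest behaviour on data without annotations.
#'
#' @return A one-row tibble with the ten annotation fields.
#' @export
annotation_neutral <- function() {
  tibble(dhs_signal = 0, distance_from_nucleosome = 0,
         guanine_occupancy = 0, mgw_pam = 0,
         in_exon_ngg = 0, in_exon_non_ngg = 0,
         transcription_region = 0, coding_region = 0,
         ngg_strand_expression = 0, non_ngg_strand_expression = 0)
}

#' Annotation provider returning neutral values for every site
#'
#' An annotation provider is a function taking one site row and returning
#' an annotation bundle (see [annotation_neutral()]). This provider ignores
#' the site and returns the neutral bundle, so the pipeline runs without
#' any external annotation source.
#'
#' @return A provider function `function(site) -> tibble`.
#' @export
annotation_provider_neutral <- function() {
  function(site) annotation_neutral()
}

#' File-backed annotation provider
#'
#' Reads a tab-delimited annotation track table with one row per site
#' (column `site_id` plus any subset of the annotation fields) and serves
#' the matching row per site, defaulting the remaining fields to the
#' neutral values. Binary fields must be 0/1; all numerics must be finite.
#'
#' @param path Path to the tab-delimited table.
#' @return A provider function `function(site) -> tibble`.
#' @export
annotation_provider_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"site_id" %in% names(tab)) {
    abort("annotation table must have a site_id column")
  }
  fields <- names(annotation_neutral())
  extra <- setdiff(names(tab), c("site_id", fields))
  if (length(extra)) {
    abort(paste0("unknown annotation column(s): ",
                 paste(extra, collapse = ", ")))
  }
  for (f in intersect(fields, names(tab))) {
    if (!all(is.finite(tab[[f]]))) {
      abort(paste0("non-finite values in annotation column ", f))
    }
  }
  for (f in c("in_exon_ngg", "in_exon_non_ngg", "transcription_region",
              "coding_region")) {
    if (f %in% names(tab) && !all(tab[[f]] %in% c(0, 1))) {
      abort(paste0("annotation column ", f, " must be binary 0/1"))
    }
  }
  function(site) {
    out <- annotation_neutral()
    hit <- tab[tab$site_id == site$site_id, , drop = FALSE]
    if (nrow(hit) >= 1L) {
      for (f in intersect(fields, names(hit))) out[[f]] <- hit[[f]][1L]
    }
    out
  }
}
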