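#' Substrate class of a CAZyme family
#'
#' @param family CAZyme family label(s), e.g. `"GH48"`.
#' @param map An `activity_map`; families absent from the map are `OTHER`.
#' @return Character vector of substrate classes (`CELLULOSE`,
#'   `HEMICELLULOSE`, `OLIGOSACCHARIDE`, `OTHER`).
#' @export
#' @examples
#' classify_gh_activity(c("GH7", "GH10", "GH9999"))
classify_gh_activity <- function(family, map = default_activity_map()) {
  cls <- unname(unclass(map)[family])
  cls[is.na(cls)] <- "OTHER"
  cls
}

# highest-priority substrate class among GH domains of one protein
# (CELLULOSE > HEMICELLULOSE > OLIGOSACCHARIDE > OTHER); a protein counts
# once per organism tally, under its best class.
.CLASS_PRIORITY <- c(CELLULOSE = 1L, HEMICELLULOSE = 2L, OLIGOSACCHARIDE = 3L,
                     OTHER = 4L)

.best_gh_class <- function(arch, map) {
  gh <- arch$domains$label[is_gh_label(arch$domains$label)]
  if (!length(gh)) return(NA_character_)
  cls <- classify_gh_activity(gh, map)
  cls[which.min(.CLASS_PRIORITY[cls])]
}

#' Classify a dockerin-fusion protein
#'
#' Assigns exactly one fusion category per dockerin-containing protein, by
#' precedence: a cohesin makes it `DOC_COHESIN` (an adaptor/primary
#' scaffoldin); else a GH with cellulose or hemicellulose activity makes it
#' `DOC_GH_LCB`; else any GH/PL/CE domain makes it `DOC_CAZYME`; else a
#' carbohydrate-binding module makes it `DOC_CBM`; else `DOC_OTHER`.
#'
#' @param arch A `protein_arch` containing at least one dockerin.
#' @param map An `activity_map`.
#' @return Single fusion-category string.
#' @export
classify_dockerin_fusion <- function(arch, map = default_activity_map()) {
  if (count_dockerins(arch) == 0L) {
    stop("protein ", arch$protein_id, " has no dockerin domain")
  }
  labels <- arch$domains$label
  if (any(labels %in% .COHESIN_LABELS)) return("DOC_COHESIN")
  gh_class <- .best_gh_class(arch, map)
  if (!is.na(gh_class) && gh_class %in% c("CELLULOSE", "HEMICELLULOSE")) {
    return("DOC_GH_LCB")
  }
  if (any(is_cazyme_label(labels))) return("DOC_CAZYME")
  if (any(labels %in% .CBM_LABELS)) return("DOC_CBM")
  "DOC_OTHER"
}

#' Tabulate the per-organism enzyme profile
#'
#' Counts proteins (not domains): a protein with a dockerin and a GH of class
#' `CELLULOSE`/`HEMICELLULOSE`/`OLIGOSACCHARIDE` increments the matching
#' `DocGH-*` counter (one count per protein, under its highest-priority
#' class); the same GH content without a dockerin increments `FreeGH-*`.
#' `DocGH-LCB = DocGH-Cell + DocGH-Hemi`, and likewise for `FreeGH-LCB`.
#' Dockerin fusions are broken down via [classify_dockerin_fusion()].
#' Additional accessory features: non-dockerin GH-LCB proteins carrying a
#' cellulose-binding CBM (`CBM(cell)-GH-LCB`), CBM3-SLH fusion proteins, and
#' RsgI-type anti-sigma factor genes.
#'
#' @param archs List of `protein_arch` objects from one organism.
#' @param map An `activity_map`.
#' @param organism_id Organism identifier.
#' @return Object of class `enzyme_profile` (a named list of counts).
#' @export
tabulate_enzyme_profile <- function(archs, map = default_activity_map(),
                                    organism_id = "organism") {
  stopifnot(is.character(organism_id), length(organism_id) == 1L)
  z <- function() 0L
  p <- list(organism_id = organism_id,
            docgh_cell = z(), docgh_hemi = z(), docgh_oligo = z(),
            freegh_cell = z(), freegh_hemi = z(), freegh_oligo = z(),
            doc_cbm = z(), doc_cazyme = z(), doc_cohesin = z(), doc_other = z(),
            free_cazyme = z(), cbm_cell_gh_lcb = z(), cbm3_slh = z(),
            rsgi = z(), dockerin_proteins = z())
  for (arch in archs) {
    labels <- arch$domains$label
    has_doc <- count_dockerins(arch) > 0L
    gh_class <- .best_gh_class(arch, map)
    if (any(labels == "RSGI")) p$rsgi <- p$rsgi + 1L
    if (any(labels == "CBM3") && any(labels == "SLH") &&
        count_cohesins(arch) == 0L) {
      p$cbm3_slh <- p$cbm3_slh + 1L
    }
    if (has_doc) {
      p$dockerin_proteins <- p$dockerin_proteins + 1L
      fusion <- classify_dockerin_fusion(arch, map)
      if (fusion == "DOC_GH_LCB") {
        if (gh_class == "CELLULOSE") p$docgh_cell <- p$docgh_cell + 1L
        else p$docgh_hemi <- p$docgh_hemi + 1L
      } else if (fusion == "DOC_COHESIN") {
        p$doc_cohesin <- p$doc_cohesin + 1L
      } else if (fusion == "DOC_CAZYME") {
        p$doc_cazyme <- p$doc_cazyme + 1L
        if (identical(gh_class, "OLIGOSACCHARIDE")) {
          p$docgh_oligo <- p$docgh_oligo + 1L
        }
      } else if (fusion == "DOC_CBM") {
        p$doc_cbm <- p$doc_cbm + 1L
      } else {
        p$doc_other <- p$doc_other + 1L
      }
    } else {
      if (!is.na(gh_class) && gh_class == "CELLULOSE") {
        p$freegh_cell <- p$freegh_cell + 1L
      } else if (!is.na(gh_class) && gh_class == "HEMICELLULOSE") {
        p$freegh_hemi <- p$freegh_hemi + 1L
      } else if (!is.na(gh_class) && gh_class == "OLIGOSACCHARIDE") {
        p$freegh_oligo <- p$freegh_oligo + 1L
      } else if (any(is_cazyme_label(labels))) {
        p$free_cazyme <- p$free_cazyme + 1L
      }
      if (!is.na(gh_class) && gh_class %in% c("CELLULOSE", "HEMICELLULOSE") &&
          any(labels %in% .CBM_LABELS)) {
        p$cbm_cell_gh_lcb <- p$cbm_cell_gh_lcb + 1L
      }
    }
  }
  p$docgh_lcb <- p$docgh_cell + p$docgh_hemi
  p$freegh_lcb <- p$freegh_cell + p$freegh_hemi
  structure(p, class = "enzyme_profile")
}

#' @export
print.enzyme_profile <- function(x, ...) {
  cat(sprintf(paste0("<enzyme_profile> %s: DocGH-LCB %d (Cell %d / Hemi %d), ",
                     "DocGH-Oligo %d, FreeGH-LCB %d, dockerin proteins %d\n"),
              x$organism_id, x$docgh_lcb, x$docgh_cell, x$docgh_hemi,
              x$docgh_oligo, x$freegh_lcb, x$dockerin_proteins))
  invisible(x)
}

#' One-row data.frame view of an enzyme profile
#'
#' @param profile An `enzyme_profile`.
#' @return `data.frame` with Table-style column names.
#' @export
enzyme_profile_row <- function(profile) {
  data.frame(organism_id = profile$organism_id,
             docgh_cell = profile$docgh_cell, docgh_hemi = profile$docgh_hemi,
             docgh_oligo = profile$docgh_oligo, docgh_lcb = profile$docgh_lcb,
             freegh_cell = profile$freegh_cell, freegh_hemi = profile$freegh_hemi,
             freegh_oligo = profile$freegh_oligo, freegh_lcb = profile$freegh_lcb,
             doc_cbm = profile$doc_cbm, doc_cazyme = profile$doc_cazyme,
             doc_cohesin = profile$doc_cohesin, doc_other = profile$doc_other,
             free_cazyme = profile$free_cazyme,
             cbm_cell_gh_lcb = profile$cbm_cell_gh_lcb,
             cbm3_slh = profile$cbm3_slh, rsgi = profile$rsgi,
             dockerin_proteins = profile$dockerin_proteins,
             stringsAsFactors = FALSE)
}
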