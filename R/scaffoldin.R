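#' The eight scaffoldin categories
#'
#' @return Character vector of the eight category labels (excluding
#'   `NOT_SCAFFOLDIN`, the outcome for proteins without cohesins).
#' @export
scaffoldin_categories <- function() {
  c("SIMPLE_PRIMARY", "SINGLE_COHESIN", "COMPLEX_PRIMARY", "SLH_ANCHORING",
    "NONSLH_ANCHORING", "MONOVALENT_ADAPTOR", "POLYVALENT_ADAPTOR", "CELL_FREE")
}

# does the architecture carry a cell-wall motif other than SLH?
# A TM helix counts only when it lies in the C-terminal 10% of the protein.
.has_nonslh_cw_motif <- function(arch) {
  d <- arch$domains
  plain <- any(d$label %in% c("LPXTG", "LYSM", "CU_AMINE_OXIDASE"))
  tm <- d$label == "TM_HELIX_CTERM" & d$start > 0.9 * arch$length
  plain || any(tm)
}

#' Classify a cohesin-containing protein into a scaffoldin category
#'
#' Deterministic decision tree over the canonical domain content, applied in
#' this fixed order:
#' \enumerate{
#'   \item no cohesin domain: `NOT_SCAFFOLDIN`;
#'   \item any SLH domain: `SLH_ANCHORING`;
#'   \item any other cell-wall motif (LPxTG sorting signal, LysM,
#'     C-terminal TM helix within the last 10% of the protein, or Cu-amine
#'     oxidase-like domain): `NONSLH_ANCHORING`;
#'   \item at least one dockerin: one cohesin gives `MONOVALENT_ADAPTOR`;
#'     two or more cohesins give `COMPLEX_PRIMARY` if an internal CBM3 is
#'     present, else `POLYVALENT_ADAPTOR`;
#'   \item no dockerin: one cohesin gives `SINGLE_COHESIN`; two or more give
#'     `SIMPLE_PRIMARY` with an N-terminal CBM3, else `CELL_FREE`.
#' }
#' Cell-wall attachment outranks dockerin content because the anchoring
#' categories are defined by the wall motif irrespective of other domains.
#' A multi-cohesin, dockerin-free, CBM-free protein defaults to `CELL_FREE`
#' and is annotated as a possible CBM-less simple primary, since operon
#' context (which would resolve the ambiguity) is not modelled.
#'
#' @param arch A `protein_arch` from [build_architectures()].
#' @return Single category string (one of [scaffoldin_categories()] or
#'   `"NOT_SCAFFOLDIN"`).
#' @seealso [classify_scaffoldins()] for the audited per-protein table.
#' @export
#' @examples
#' # nine Coh1 modules, internal CBM3, C-terminal Doc2 -> complex primary
#' arch <- generate_scaffoldin_architecture("COMPLEX_PRIMARY", seed = 1)
#' classify_scaffoldin(arch)
classify_scaffoldin <- function(arch) {
  .classify_scaffoldin_full(arch)$category
}

.classify_scaffoldin_full <- function(arch) {
  stopifnot(inherits(arch, "protein_arch"))
  d <- arch$domains
  n_coh <- count_cohesins(arch)
  n_doc <- count_dockerins(arch)
  internal_cbm3 <- any(d$label == "CBM3" & d$is_internal)
  nterm_cbm3 <- any(d$label == "CBM3" & d$is_n_terminal)
  note <- NA_character_
  if (n_coh == 0L) {
    category <- "NOT_SCAFFOLDIN"
    evidence <- "no cohesin domain"
  } else if (any(d$label == "SLH")) {
    category <- "SLH_ANCHORING"
    evidence <- "cohesin + SLH domain"
  } else if (.has_nonslh_cw_motif(arch)) {
    category <- "NONSLH_ANCHORING"
    evidence <- "cohesin + non-SLH cell-wall motif"
  } else if (n_doc >= 1L) {
    if (n_coh == 1L) {
      category <- "MONOVALENT_ADAPTOR"
      evidence <- "dockerin + single cohesin"
    } else if (internal_cbm3) {
      category <- "COMPLEX_PRIMARY"
      evidence <- "dockerin + multiple cohesins + internal CBM3"
    } else {
      category <- "POLYVALENT_ADAPTOR"
      evidence <- "dockerin + multiple cohesins, no internal CBM3"
    }
  } else {
    if (n_coh == 1L) {
      category <- "SINGLE_COHESIN"
      evidence <- "single cohesin, no dockerin or wall motif"
    } else if (nterm_cbm3) {
      category <- "SIMPLE_PRIMARY"
      evidence <- "multiple cohesins + N-terminal CBM3, no dockerin"
    } else {
      category <- "CELL_FREE"
      evidence <- "multiple cohesins, no dockerin, no N-terminal CBM3"
      if (!any(d$label %in% .CBM_LABELS)) {
        note <- "possible CBM-less simple primary"
      }
    }
  }
  coh_types <- d$label[d$label %in% .COHESIN_LABELS]
  list(category = category, n_cohesin = n_coh, n_dockerin = n_doc,
       cohesin_types = paste(coh_types, collapse = ","),
       evidence = evidence, note = note)
}

#' Per-protein scaffoldin classification table
#'
#' Runs [classify_scaffoldin()] on every architecture and returns the audit
#' table: which branch of the decision tree fired and on what evidence.
#'
#' @param archs List of `protein_arch` objects.
#' @return `data.frame` with columns `protein_id`, `category`, `n_cohesin`,
#'   `n_dockerin`, `cohesin_types`, `evidence`, `note`.
#' @export
classify_scaffoldins <- function(archs) {
  if (length(archs) == 0L) {
    return(data.frame(protein_id = character(0), category = character(0),
                      n_cohesin = integer(0), n_dockerin = integer(0),
                      cohesin_types = character(0), evidence = character(0),
                      note = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(archs, function(a) {
    r <- .classify_scaffoldin_full(a)
    data.frame(protein_id = a$protein_id, category = r$category,
               n_cohesin = r$n_cohesin, n_dockerin = r$n_dockerin,
               cohesin_types = r$cohesin_types, evidence = r$evidence,
               note = r$note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally scaffoldin categories for one organism
#'
#' @param archs List of `protein_arch` objects, all from one organism.
#' @param organism_id Organism identifier recorded in the tally.
#' @return Object of class `scaffoldin_tally`: per-category counts over the
#'   cohesin-containing proteins (`NOT_SCAFFOLDIN` proteins are excluded from
#'   scaffoldin counts), the total cohesin domain count, and the maximum
#'   cohesin count on any single protein.
#' @export
tally_scaffoldins <- function(archs, organism_id) {
  stopifnot(is.character(organism_id), length(organism_id) == 1L)
  cls <- classify_scaffoldins(archs)
  counts <- stats::setNames(integer(length(scaffoldin_categories())),
                            scaffoldin_categories())
  tab <- table(cls$category[cls$category != "NOT_SCAFFOLDIN"])
  counts[names(tab)] <- as.integer(tab)
  n_coh <- vapply(archs, count_cohesins, integer(1))
  structure(list(organism_id = organism_id, counts = counts,
                 n_scaffoldins = sum(counts),
                 total_cohesins = sum(n_coh),
                 max_cohesins = if (length(n_coh)) max(n_coh) else 0L),
            class = "scaffoldin_tally")
}

#' @export
print.scaffoldin_tally <- function(x, ...) {
  cat(sprintf("<scaffoldin_tally> %s: %d scaffoldins, %d cohesins (max %d/protein)\n",
              x$organism_id, x$n_scaffoldins, x$total_cohesins, x$max_cohesins))
  nz <- x$counts[x$counts > 0]
  if (length(nz)) {
    cat(paste(sprintf("  %-18s %d", names(nz), nz), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write per-protein classifications and per-organism tallies
#'
#' @param cls Classification table from [classify_scaffoldins()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scaffoldin_table <- function(cls, path) {
  utils::write.table(cls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaffoldin_table
#' @param tally A `scaffoldin_tally`.
#' @export
write_scaffoldin_tally <- function(tally, path) {
  jsonlite::write_json(
    list(organism_id = tally$organism_id, counts = as.list(tally$counts),
         n_scaffoldins = tally$n_scaffoldins,
         total_cohesins = tally$total_cohesins,
         max_cohesins = tally$max_cohesins),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
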