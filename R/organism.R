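#' Genome-level prescan filter
#'
#' A genome passes when it encodes at least one multi-cohesin scaffoldin
#' (a protein with two or more cohesin domains) and at least one
#' dockerin-fused GH (DocGH-Cell, -Hemi or -Oligo). Failing genomes are
#' non-producers and are not typed further.
#'
#' @param tally A `scaffoldin_tally`.
#' @param profile An `enzyme_profile` for the same organism.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failed criteria, empty on pass).
#' @export
prescan_filter <- function(tally, profile) {
  .check_same_organism(tally, profile)
  reasons <- character(0)
  if (tally$max_cohesins < 2L) {
    reasons <- c(reasons, "no multi-cohesin scaffoldin (>= 2 cohesin domains)")
  }
  n_docgh <- profile$docgh_cell + profile$docgh_hemi + profile$docgh_oligo
  if (n_docgh < 1L) {
    reasons <- c(reasons, "no dockerin-fused GH protein")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

.check_same_organism <- function(tally, profile) {
  if (!identical(tally$organism_id, profile$organism_id)) {
    stop("tally (", tally$organism_id, ") and profile (", profile$organism_id,
         ") refer to different organisms")
  }
}

#' Type an organism's cellulosome-producing capacity
#'
#' Prescan-failing organisms are `NON_PRODUCER`. Among producers, an
#' organism is `COMPLEX` when it has at least one anchoring scaffoldin (SLH
#' or non-SLH) *and* at least one dockerin-bearing multi-cohesin scaffoldin
#' (complex primary or polyvalent adaptor) that could tether to it;
#' otherwise `SIMPLE` when it has a simple primary scaffoldin or any
#' scaffoldin with at least `threshold_conventional` cohesins; otherwise
#' `SCAFFOLDIN_CONTAINING` (its largest scaffoldin carries only two cohesins
#' and lacks the anchoring/primary configuration of conventional
#' cellulosomes). Cohesin-dockerin type pairing is audited separately
#' ([cohesin_dockerin_complementarity()]) and never used for typing, since
#' type usage is reversed in some species.
#'
#' @param tally A `scaffoldin_tally`.
#' @param profile An `enzyme_profile` for the same organism.
#' @param threshold_conventional Minimum cohesin count on a single scaffoldin
#'   for "conventional" capacity in the absence of a primary scaffoldin.
#' @param high_min,low_max DocGH-LCB band bounds, passed to
#'   [docgh_lcb_level()].
#' @return Object of class `organism_type` with `organism_id`,
#'   `producer_class`, `docgh_lcb_level` (`NA` for non-producers) and an
#'   `evidence` log of rule firings.
#' @export
type_organism <- function(tally, profile, threshold_conventional = 3L,
                          high_min = 22L, low_max = 10L) {
  .check_same_organism(tally, profile)
  prescan <- prescan_filter(tally, profile)
  evidence <- character(0)
  if (!prescan$pass) {
    return(structure(list(organism_id = tally$organism_id,
                          producer_class = "NON_PRODUCER",
                          docgh_lcb_level = NA_character_,
                          evidence = paste("prescan fail:", prescan$reasons)),
                     class = "organism_type"))
  }
  counts <- tally$counts
  has_anchor <- counts[["SLH_ANCHORING"]] + counts[["NONSLH_ANCHORING"]] >= 1L
  has_tetherable <- counts[["COMPLEX_PRIMARY"]] + counts[["POLYVALENT_ADAPTOR"]] >= 1L
  if (has_anchor && has_tetherable) {
    producer_class <- "COMPLEX"
    evidence <- c(evidence, sprintf(
      "anchoring scaffoldin (SLH %d, nonSLH %d) + dockerin-bearing multi-cohesin scaffoldin (complex primary %d, polyvalent adaptor %d)",
      counts[["SLH_ANCHORING"]], counts[["NONSLH_ANCHORING"]],
      counts[["COMPLEX_PRIMARY"]], counts[["POLYVALENT_ADAPTOR"]]))
  } else if (counts[["SIMPLE_PRIMARY"]] >= 1L ||
             tally$max_cohesins >= threshold_conventional) {
    producer_class <- "SIMPLE"
    evidence <- c(evidence, if (counts[["SIMPLE_PRIMARY"]] >= 1L) {
      sprintf("simple primary scaffoldin present (%d)", counts[["SIMPLE_PRIMARY"]])
    } else {
      sprintf("scaffoldin with %d cohesins (>= %d)", tally$max_cohesins,
              threshold_conventional)
    })
  } else {
    producer_class <- "SCAFFOLDIN_CONTAINING"
    evidence <- c(evidence, sprintf(
      "largest scaffoldin has only %d cohesins; no primary or anchoring+adaptor pair",
      tally$max_cohesins))
  }
  level <- docgh_lcb_level(profile, high_min = high_min, low_max = low_max)
  structure(list(organism_id = tally$organism_id,
                 producer_class = producer_class,
                 docgh_lcb_level = level, evidence = evidence),
            class = "organism_type")
}

#' @export
print.organism_type <- function(x, ...) {
  cat(sprintf("<organism_type> %s: %s (DocGH-LCB level %s)\n", x$organism_id,
              x$producer_class, x$docgh_lcb_level))
  cat(paste(" -", x$evidence, collapse = "\n"), "\n")
  invisible(x)
}

#' DocGH-LCB level of a producer
#'
#' `HIGH` for 22 or more DocGH-LCB genes, `LOW` for 10 or fewer, and
#' `INTERMEDIATE` for the unobserved 11-21 band (no organism in the
#' reference screen fell there, so the band is labelled rather than silently
#' assigned to either side).
#'
#' @param profile An `enzyme_profile`.
#' @param high_min,low_max Band bounds (inclusive).
#' @return `"HIGH"`, `"LOW"` or `"INTERMEDIATE"`.
#' @export
docgh_lcb_level <- function(profile, high_min = 22L, low_max = 10L) {
  n <- profile$docgh_lcb
  if (is.na(n) || n < 0L) stop("negative or missing DocGH-LCB count")
  if (n >= high_min) "HIGH" else if (n <= low_max) "LOW" else "INTERMEDIATE"
}

#' Cohesin-dockerin type complementarity audit
#'
#' Counts typed cohesin and dockerin domains (Coh1/2/3, Doc1/2/3) across an
#' organism's proteins and flags orphans: a cohesin type present with zero
#' complementary dockerins anywhere in the genome, or vice versa (e.g. Coh2
#' modules in a genome lacking any Doc2-containing protein).
#'
#' @param archs List of `protein_arch` objects for one organism.
#' @return Object of class `complementarity_report` with `coh` and `doc`
#'   counts (named vectors over types 1-3) and logical `orphan_coh`,
#'   `orphan_doc` flags per type.
#' @export
cohesin_dockerin_complementarity <- function(archs) {
  labels <- unlist(lapply(archs, function(a) a$domains$label), use.names = FALSE)
  coh <- vapply(1:3, function(i) sum(labels == paste0("COH", i)), integer(1))
  doc <- vapply(1:3, function(i) sum(labels == paste0("DOC", i)), integer(1))
  names(coh) <- paste0("COH", 1:3)
  names(doc) <- paste0("DOC", 1:3)
  structure(list(coh = coh, doc = doc,
                 orphan_coh = coh > 0L & doc == 0L,
                 orphan_doc = doc > 0L & coh == 0L),
            class = "complementarity_report")
}

#' @export
print.complementarity_report <- function(x, ...) {
  for (i in 1:3) {
    cat(sprintf("  Coh%d: %d  Doc%d: %d%s\n", i, x$coh[i], i, x$doc[i],
                if (x$orphan_coh[i]) "  [orphan cohesin type]"
                else if (x$orphan_doc[i]) "  [orphan dockerin type]" else ""))
  }
  invisible(x)
}

#' OLS regression of DocGH-LCB counts on total dockerin-protein counts
#'
#' Ordinary least squares with the DocGH-LCB gene count as response and the
#' total dockerin-fusion protein count as predictor, across organisms. The
#' reported R-squared is the squared Pearson correlation and is therefore
#' symmetric in the two axes.
#'
#' @param profiles List of `enzyme_profile` objects (>= 3 organisms).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
dockerin_vs_docghlcb_regression <- function(profiles) {
  if (length(profiles) < 3L) stop("need profiles for at least 3 organisms")
  x <- vapply(profiles, function(p) p$dockerin_proteins, numeric(1))
  y <- vapply(profiles, function(p) p$docgh_lcb, numeric(1))
  if (stats::var(x) == 0) stop("zero variance in dockerin-protein counts; fit undefined")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = unname(stats::cor(x, y)^2),
       n = length(x))
}
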