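#' Canonical domain labels
#'
#' The controlled vocabulary every member-database accession is mapped into.
#' Typed cohesins and dockerins (`COH1`/`COH2`/`COH3`, `DOC1`/`DOC2`/`DOC3`)
#' carry the class-specific binding information; `COH_GENERIC`/`DOC_GENERIC`
#' cover profile hits without a type call. CAZyme families keep their family
#' number (`GH5`, `PL1`, `CE4`, ...). `COH_LIKE_FOLD` marks hits to the
#' cohesin-like jelly-roll CATH superfamily that are *not* counted as
#' sequence-detected cohesins but nominate a protein for structure-based
#' rescue (see [rescue_cohesins()]). Everything unrecognised is `OTHER`.
#'
#' @return Character vector of the fixed (non-CAZyme) canonical labels.
#' @export
canonical_labels <- function() {
  c("COH1", "COH2", "COH3", "COH_GENERIC",
    "DOC1", "DOC2", "DOC3", "DOC_GENERIC",
    "CBM3", "CBM_CELLULOSE_OTHER", "SLH", "LPXTG", "LYSM",
    "TM_HELIX_CTERM", "CU_AMINE_OXIDASE", "X2", "FN3",
    "SIGNAL_PEPTIDE", "RSGI", "COH_LIKE_FOLD", "OTHER")
}

.COHESIN_LABELS  <- c("COH1", "COH2", "COH3", "COH_GENERIC")
.DOCKERIN_LABELS <- c("DOC1", "DOC2", "DOC3", "DOC_GENERIC")
.CBM_LABELS      <- c("CBM3", "CBM_CELLULOSE_OTHER")
.CW_MOTIFS       <- c("LPXTG", "LYSM", "TM_HELIX_CTERM", "CU_AMINE_OXIDASE")

#' Is a canonical label a CAZyme family label?
#'
#' @param label Character vector of canonical labels.
#' @return Logical vector, `TRUE` for `GH<n>`, `PL<n>` or `CE<n>` labels.
#' @export
is_cazyme_label <- function(label) grepl("^(GH|PL|CE)[0-9]+$", label)

is_gh_label <- function(label) grepl("^GH[0-9]+$", label)

#' Default domain lexicon
#'
#' Maps member-database accessions (CDD, Pfam, SUPERFAMILY, Gene3D,
#' Phobius-style callers) to canonical cellulosome domain labels. The typed
#' cohesin/dockerin CDD profiles and the generic Pfam cohesin profile follow
#' the identifiers used throughout the cellulosome literature (Coh1 cd08548,
#' Coh2 cd08547, Coh3 cd08759, Coh PF00963; dockerins cd14256, cd14254,
#' cd14255). cd14255 is mapped to `DOC3`; note that it has also been referred
#' to as a Coh3 profile, so remap it via a custom lexicon if your annotation
#' source treats it that way. GH-family assignments for the Pfam glycoside
#' hydrolase profiles reflect the Pfam family descriptions; all entries are
#' overridable with [read_lexicon()].
#'
#' @return Named character vector (`accession -> canonical label`) of class
#'   `domain_lexicon`.
#' @seealso [read_lexicon()], [canonicalize_hits()]
#' @export
#' @examples
#' lex <- default_lexicon()
#' lex[["cd08548"]]  # "COH1"
default_lexicon <- function() {
  lex <- c(
    # cohesins
    cd08548 = "COH1", cd08547 = "COH2", cd08759 = "COH3", PF00963 = "COH_GENERIC",
    # dockerins (cd14255: listed with the dockerin profiles; see note above)
    cd14256 = "DOC1", cd14254 = "DOC2", cd14255 = "DOC3", PF00404 = "DOC_GENERIC",
    # carbohydrate-binding modules
    PF00942 = "CBM3", SSF49384 = "CBM_CELLULOSE_OTHER",
    # cell-wall attachment
    PF00395 = "SLH", PF00746 = "LPXTG", PF01476 = "LYSM",
    TRANSMEMBRANE = "TM_HELIX_CTERM", PF01179 = "CU_AMINE_OXIDASE",
    # accessory scaffoldin modules
    PF03442 = "X2", PF00041 = "FN3", SIGNAL_PEPTIDE = "SIGNAL_PEPTIDE",
    # biomass-sensing anti-sigma factor (placeholder key; extend per your source)
    RSGI_PROFILE = "RSGI",
    # cohesin-like jelly-roll fold: rescue candidate, not a cohesin call
    `G3DSA:2.60.40.680` = "COH_LIKE_FOLD",
    # glycoside hydrolase Pfam profiles
    PF00150 = "GH5",  PF00759 = "GH9",  PF02011 = "GH48", PF01270 = "GH11",
    PF02015 = "GH45", PF01670 = "GH12", PF12891 = "GH44", PF03537 = "GH26",
    PF00331 = "GH10", PF04616 = "GH43", PF00232 = "GH1",  PF00933 = "GH3",
    PF01341 = "GH6",  PF00840 = "GH7"
  )
  class(lex) <- c("domain_lexicon", class(lex))
  lex
}

#' Read a domain lexicon from a TSV or YAML config
#'
#' TSV files need columns `accession` and `label` (extra columns and `#`
#' comment lines are ignored); YAML files are flat `accession: label` maps.
#' Entries extend/override [default_lexicon()] unless `base = NULL`.
#'
#' @param path Path to the config file.
#' @param base Lexicon to extend, or `NULL` to start empty.
#' @return A `domain_lexicon` named character vector.
#' @export
read_lexicon <- function(path, base = default_lexicon()) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    acc <- names(raw)
    lab <- vapply(raw, as.character, character(1))
  } else {
    tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("accession", "label") %in% names(tab))) {
      stop("lexicon file must have columns 'accession' and 'label': ", path)
    }
    acc <- as.character(tab$accession)
    lab <- as.character(tab$label)
  }
  if (anyDuplicated(acc)) {
    stop("lexicon maps an accession more than once: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  lex <- if (is.null(base)) stats::setNames(character(0), character(0)) else unclass(base)
  lex[acc] <- lab
  bad <- !(lex %in% canonical_labels()) & !is_cazyme_label(lex)
  if (any(bad)) {
    stop("unknown canonical label(s) in lexicon: ",
         paste(unique(lex[bad]), collapse = ", "))
  }
  class(lex) <- c("domain_lexicon", class(lex))
  lex
}

#' Look up canonical labels for accessions
#'
#' @param accession Character vector of member-database accessions.
#' @param lexicon A `domain_lexicon`; unknown accessions map to `"OTHER"`.
#' @return Character vector of canonical labels.
#' @export
lexicon_label <- function(accession, lexicon = default_lexicon()) {
  lab <- unname(unclass(lexicon)[accession])
  lab[is.na(lab)] <- "OTHER"
  lab
}

#' Default CAZyme family-to-substrate activity map
#'
#' Maps `GH<n>` (and a few `PL`/`CE`) family labels to the substrate class
#' driving DocGH/FreeGH profiling: `CELLULOSE`, `HEMICELLULOSE`,
#' `OLIGOSACCHARIDE` or `OTHER`. Families named in the cellulosome literature
#' (endoglucanases GH7/GH12, exoglucanases GH5/GH9, cellulosomal staples
#' GH5/GH10/GH11/GH43/GH48) anchor the table; the remainder follows CAZy
#' family descriptions compiled by the package authors. Unlisted families
#' resolve to `OTHER`. Override with [read_activity_map()].
#'
#' @return Named character vector (`family -> substrate class`) of class
#'   `activity_map`.
#' @export
#' @examples
#' classify_gh_activity("GH48")  # "CELLULOSE"
default_activity_map <- function() {
  map <- c(
    # cellulases: endo/exo-glucanases and processive cellulases
    GH5 = "CELLULOSE", GH6 = "CELLULOSE", GH7 = "CELLULOSE", GH8 = "CELLULOSE",
    GH9 = "CELLULOSE", GH12 = "CELLULOSE", GH44 = "CELLULOSE",
    GH45 = "CELLULOSE", GH48 = "CELLULOSE", GH124 = "CELLULOSE",
    # hemicellulases: xylanases, mannanases, arabinofuranosidases, ...
    GH10 = "HEMICELLULOSE", GH11 = "HEMICELLULOSE", GH26 = "HEMICELLULOSE",
    GH30 = "HEMICELLULOSE", GH43 = "HEMICELLULOSE", GH51 = "HEMICELLULOSE",
    GH53 = "HEMICELLULOSE", GH54 = "HEMICELLULOSE", GH62 = "HEMICELLULOSE",
    GH67 = "HEMICELLULOSE", GH74 = "HEMICELLULOSE", GH115 = "HEMICELLULOSE",
    # oligosaccharide-active: beta-glucosidases/galactosidases etc.
    GH1 = "OLIGOSACCHARIDE", GH2 = "OLIGOSACCHARIDE", GH3 = "OLIGOSACCHARIDE",
    GH20 = "OLIGOSACCHARIDE", GH29 = "OLIGOSACCHARIDE", GH31 = "OLIGOSACCHARIDE",
    GH35 = "OLIGOSACCHARIDE", GH36 = "OLIGOSACCHARIDE", GH38 = "OLIGOSACCHARIDE",
    GH39 = "OLIGOSACCHARIDE", GH42 = "OLIGOSACCHARIDE", GH94 = "OLIGOSACCHARIDE"
  )
  class(map) <- c("activity_map", class(map))
  map
}

#' Read a CAZyme activity map from TSV or YAML
#'
#' TSV needs columns `family` and `class`; YAML is a flat `family: class`
#' map. Classes must be one of `CELLULOSE`, `HEMICELLULOSE`,
#' `OLIGOSACCHARIDE`, `OTHER`.
#'
#' @param path Path to the config file.
#' @param base Map to extend, or `NULL` to start empty.
#' @return An `activity_map` named character vector.
#' @export
read_activity_map <- function(path, base = default_activity_map()) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    fam <- names(raw)
    cls <- vapply(raw, as.character, character(1))
  } else {
    tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("family", "class") %in% names(tab))) {
      stop("activity map file must have columns 'family' and 'class': ", path)
    }
    fam <- as.character(tab$family)
    cls <- toupper(as.character(tab$class))
  }
  ok <- cls %in% c("CELLULOSE", "HEMICELLULOSE", "OLIGOSACCHARIDE", "OTHER")
  if (!all(ok)) stop("unknown substrate class(es): ", paste(unique(cls[!ok]), collapse = ", "))
  map <- if (is.null(base)) stats::setNames(character(0), character(0)) else unclass(base)
  map[fam] <- cls
  class(map) <- c("activity_map", class(map))
  map
}
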