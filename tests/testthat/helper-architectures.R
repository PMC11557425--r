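# deterministic architecture builder for tests: fixed per-label lengths and
# 10-residue linkers, so positions (and hence terminal flags) are predictable
.test_len <- c(COH1 = 140, COH2 = 140, COH3 = 140, COH_GENERIC = 140,
               DOC1 = 60, DOC2 = 60, DOC3 = 60, DOC_GENERIC = 60,
               CBM3 = 160, CBM_CELLULOSE_OTHER = 100, SLH = 50, LPXTG = 30,
               LYSM = 45, TM_HELIX_CTERM = 21, CU_AMINE_OXIDASE = 350,
               X2 = 90, FN3 = 90, SIGNAL_PEPTIDE = 25, RSGI = 100,
               COH_LIKE_FOLD = 140, OTHER = 150)

.label_len <- function(label) {
  if (label %in% names(.test_len)) .test_len[[label]] else 350 # CAZymes
}

# build a protein_arch from an ordered label vector; a trailing
# TM_HELIX_CTERM is placed flush with the C-terminus
mk_arch <- function(labels, protein_id = "prot", tail_pad = 10L) {
  pos <- 1L
  rows <- lapply(labels, function(lab) {
    start <- pos + 10L
    end <- start + .label_len(lab) - 1L
    pos <<- end
    data.frame(label = lab, start = start, end = end, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  total <- pos + if (labels[length(labels)] == "TM_HELIX_CTERM") 2L else tail_pad
  calls <- cbind(protein_id = protein_id, d)
  build_architectures(calls, stats::setNames(total, protein_id))[[protein_id]]
}

# a small multi-organism fixture: architectures for one organism drawn from
# an explicit category composition, via the seeded generator
mk_organism <- function(id, scaffoldins, seed, ...) {
  generate_organism(organism_composition(id, scaffoldins = scaffoldins,
                                         seed = seed, ...))
}

pcell_composition <- function(seed = 1L, docgh_lcb = 70L) {
  # the most complex known producer: 33 scaffoldins across seven categories
  # (1 complex + 2 simple-type primaries, 10 monovalent and 3 polyvalent
  # adaptors, 8 SLH- and 3 nonSLH-anchoring, 3 cell-free, 3 single-cohesin)
  organism_composition(
    "P_cellulosolvens_syn",
    scaffoldins = c(COMPLEX_PRIMARY = 1L, SIMPLE_PRIMARY = 2L,
                    MONOVALENT_ADAPTOR = 10L, POLYVALENT_ADAPTOR = 3L,
                    SLH_ANCHORING = 8L, NONSLH_ANCHORING = 3L,
                    CELL_FREE = 3L, SINGLE_COHESIN = 3L),
    docgh_lcb = docgh_lcb, seed = seed)
}

amesophilus_archs <- function() {
  ext <- system.file("extdata", package = "cellulosomics")
  hits <- parse_interproscan_tsv(
    file.path(ext, "synthetic_amesophilus_interproscan.tsv"))
  lens <- utils::read.delim(file.path(ext, "synthetic_amesophilus_lengths.tsv"))
  build_architectures(canonicalize_hits(hits),
                      stats::setNames(lens$length, lens$protein_id))
}
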