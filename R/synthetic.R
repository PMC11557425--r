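# Generated domain-length ranges (residues). Plausible module sizes for
# scaffoldin components; configurable via options(cellulosomics.lengths=...).
# No claim of biological realism beyond order of magnitude.
.DOMAIN_LEN <- list(
  COH = c(120L, 160L), DOC = c(55L, 70L), CBM3 = c(150L, 170L),
  CBM_CELLULOSE_OTHER = c(90L, 110L), SLH = c(45L, 60L), X2 = c(80L, 100L),
  FN3 = c(85L, 95L), LPXTG = c(28L, 35L), LYSM = c(40L, 48L),
  TM_HELIX_CTERM = c(18L, 24L), CU_AMINE_OXIDASE = c(250L, 450L),
  GH = c(280L, 450L), CAZYME = c(200L, 350L), OTHER = c(120L, 300L),
  RSGI = c(80L, 120L), SIGNAL_PEPTIDE = c(20L, 30L), LINKER = c(5L, 30L)
)

.rand_len <- function(kind) {
  r <- .DOMAIN_LEN[[kind]]
  if (is.null(r)) r <- .DOMAIN_LEN$OTHER
  sample(r[1]:r[2], 1L)
}

.linker_len <- function() sample(.DOMAIN_LEN$LINKER[1]:.DOMAIN_LEN$LINKER[2], 1L)

# lay out domain labels sequentially with random linkers; returns a
# protein_arch with position flags computed by the standard rules
.layout_architecture <- function(protein_id, labels, kinds = NULL,
                                 trailing_linker = TRUE) {
  if (is.null(kinds)) {
    kinds <- ifelse(labels %in% c("COH1", "COH2", "COH3", "COH_GENERIC"), "COH",
             ifelse(labels %in% c("DOC1", "DOC2", "DOC3", "DOC_GENERIC"), "DOC",
             ifelse(is_gh_label(labels), "GH",
             ifelse(is_cazyme_label(labels), "CAZYME", labels))))
  }
  pos <- 1L
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    start <- pos + .linker_len()
    len <- .rand_len(kinds[i])
    rows[[i]] <- data.frame(label = labels[i], start = start,
                            end = start + len - 1L, stringsAsFactors = FALSE)
    pos <- start + len - 1L
  }
  d <- do.call(rbind, rows)
  total <- pos + (if (trailing_linker) .linker_len() else 2L)
  d <- .flag_domains(d, total)
  protein_arch(protein_id, total, d)
}

#' Generate a synthetic scaffoldin architecture of a given category
#'
#' Emits a `protein_arch` whose domain content satisfies exactly the
#' requested category's defining predicate and no higher-precedence branch
#' of the decision tree (a generated `CELL_FREE` never carries an SLH
#' domain or a dockerin, a `MONOVALENT_ADAPTOR` never a wall motif, and so
#' on), so classification round-trips exactly. Cohesin counts are sampled
#' within category-legal ranges (>= 2 for multi-cohesin categories, 1
#' otherwise) unless pinned with `n_cohesins`.
#'
#' @param category One of [scaffoldin_categories()] (`NOT_SCAFFOLDIN` is
#'   rejected: there is nothing to generate).
#' @param n_cohesins Optional cohesin count override (must be category-legal).
#' @param coh_type Cohesin type label used for the typed cohesins.
#' @param doc_type Dockerin type label for dockerin-bearing categories.
#' @param protein_id Identifier for the emitted protein.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A `protein_arch`.
#' @export
#' @examples
#' arch <- generate_scaffoldin_architecture("SIMPLE_PRIMARY", seed = 7)
#' classify_scaffoldin(arch)  # "SIMPLE_PRIMARY"
generate_scaffoldin_architecture <- function(category, n_cohesins = NULL,
                                             coh_type = NULL, doc_type = NULL,
                                             protein_id = paste0("syn_", tolower(category)),
                                             seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_scaffoldin_architecture(
      category, n_cohesins = n_cohesins, coh_type = coh_type,
      doc_type = doc_type, protein_id = protein_id)))
  }
  if (identical(category, "NOT_SCAFFOLDIN")) {
    stop("cannot generate a NOT_SCAFFOLDIN protein: request a category")
  }
  stopifnot(category %in% scaffoldin_categories())
  pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  n_coh <- function(lo, hi) {
    if (!is.null(n_cohesins)) {
      stopifnot(n_cohesins >= lo, n_cohesins <= hi)
      as.integer(n_cohesins)
    } else {
      sample(lo:hi, 1L)
    }
  }
  labels <- switch(
    category,
    SLH_ANCHORING = {
      ct <- if (is.null(coh_type)) pick(c("COH2", "COH2", "COH1")) else coh_type
      c(rep("SLH", sample(1:3, 1L)), rep(ct, n_coh(1L, 3L)))
    },
    NONSLH_ANCHORING = {
      ct <- if (is.null(coh_type)) pick(c("COH1", "COH2")) else coh_type
      motif <- pick(c("LPXTG", "LYSM", "CU_AMINE_OXIDASE", "TM_HELIX_CTERM"))
      if (motif == "TM_HELIX_CTERM") {
        # TM helix counts only in the C-terminal 10%: pad the N-terminus
        # and emit it flush with the C-terminus (see layout call below)
        c(rep(ct, n_coh(1L, 2L)), "OTHER", motif)
      } else if (motif == "LPXTG") {
        c(rep(ct, n_coh(1L, 2L)), motif)
      } else {
        c(motif, rep(ct, n_coh(1L, 2L)))
      }
    },
    MONOVALENT_ADAPTOR = {
      ct <- if (is.null(coh_type)) pick(c("COH1", "COH2", "COH3")) else coh_type
      dt <- if (is.null(doc_type)) pick(c("DOC1", "DOC2", "DOC3")) else doc_type
      n_coh(1L, 1L)
      if (stats::runif(1) < 0.5) c(dt, ct) else c(ct, dt)
    },
    COMPLEX_PRIMARY = {
      ct <- if (is.null(coh_type)) "COH1" else coh_type
      dt <- if (is.null(doc_type)) "DOC2" else doc_type
      k <- n_coh(2L, 9L)
      # >= 1 cohesin on each side, and enough N-terminal cohesin mass that
      # the CBM3 starts beyond the 15% N-terminal band (stays internal)
      lo <- min(k - 1L, max(1L, as.integer(ceiling(0.23 * k + 0.4))))
      before <- if (lo == k - 1L) lo else sample(lo:(k - 1L), 1L)
      c(rep(ct, before), "CBM3", rep(ct, k - before), dt)
    },
    POLYVALENT_ADAPTOR = {
      ct <- if (is.null(coh_type)) pick(c("COH1", "COH2", "COH3")) else coh_type
      dt <- if (is.null(doc_type)) pick(c("DOC1", "DOC2", "DOC3")) else doc_type
      k <- n_coh(2L, 4L)
      if (stats::runif(1) < 0.5) c(dt, rep(ct, k)) else c(rep(ct, k), dt)
    },
    SINGLE_COHESIN = {
      ct <- if (is.null(coh_type)) pick(c("COH1", "COH2")) else coh_type
      n_coh(1L, 1L)
      ct
    },
    SIMPLE_PRIMARY = {
      ct <- if (is.null(coh_type)) pick(c("COH1", "COH1", "COH2")) else coh_type
      k <- n_coh(2L, 9L)
      body <- unlist(lapply(seq_len(k), function(i) {
        if (stats::runif(1) < 0.4) c("X2", ct) else ct
      }))
      c("CBM3", body)
    },
    CELL_FREE = {
      ct <- if (is.null(coh_type)) pick(c("COH1", "COH2")) else coh_type
      k <- n_coh(2L, 6L)
      unlist(lapply(seq_len(k), function(i) {
        if (stats::runif(1) < 0.25) c(ct, "X2") else ct
      }))
    }
  )
  # a C-terminal TM helix must stay within the last 10% of the protein
  .layout_architecture(protein_id, labels,
                       trailing_linker = labels[length(labels)] != "TM_HELIX_CTERM")
}

#' Synthetic organism composition
#'
#' The recipe [generate_organism()] realizes: how many scaffoldins of each
#' category, how many dockerin-fused GH proteins per substrate class, how
#' many free enzymes, and the accessory dockerin-fusion complement. The seed
#' fixes all sampling.
#'
#' @param organism_id Organism identifier.
#' @param scaffoldins Named integer vector over [scaffoldin_categories()]
#'   (missing categories default to 0).
#' @param docgh_lcb,docgh_oligo Dockerin-fused GH counts (LCB-active
#'   cellulases/hemicellulases; oligosaccharide-active).
#' @param freegh_lcb,free_cazyme Non-dockerin enzyme counts.
#' @param doc_cbm,doc_cazyme,doc_other Accessory dockerin-fusion counts.
#' @param rsgi,cbm3_slh Accessory feature counts.
#' @param seed Random seed (integer).
#' @return Object of class `organism_composition`.
#' @export
organism_composition <- function(organism_id, scaffoldins = c(),
                                 docgh_lcb = 0L, docgh_oligo = 0L,
                                 freegh_lcb = 0L, free_cazyme = 0L,
                                 doc_cbm = 0L, doc_cazyme = 0L, doc_other = 0L,
                                 rsgi = 0L, cbm3_slh = 0L, seed = 1L) {
  sc <- stats::setNames(integer(length(scaffoldin_categories())),
                        scaffoldin_categories())
  if (length(scaffoldins)) {
    stopifnot(!is.null(names(scaffoldins)),
              all(names(scaffoldins) %in% scaffoldin_categories()))
    sc[names(scaffoldins)] <- as.integer(scaffoldins)
  }
  counts <- c(docgh_lcb = docgh_lcb, docgh_oligo = docgh_oligo,
              freegh_lcb = freegh_lcb, free_cazyme = free_cazyme,
              doc_cbm = doc_cbm, doc_cazyme = doc_cazyme,
              doc_other = doc_other, rsgi = rsgi, cbm3_slh = cbm3_slh)
  stopifnot(all(sc >= 0L), all(counts >= 0L))
  structure(c(list(organism_id = organism_id, scaffoldins = sc, seed = seed),
              as.list(counts)),
            class = "organism_composition")
}

.GH_LCB_FAMILIES <- c("GH5", "GH9", "GH48", "GH44", "GH45", "GH12",
                      "GH10", "GH11", "GH43", "GH26")
.GH_OLIGO_FAMILIES <- c("GH1", "GH2", "GH3")

# placeholder residues: repetitive, non-biological; no stage reads identity
.placeholder_seq <- function(len) {
  pat <- "ACDEFGHIKLMNPQRSTVWY"
  substr(strrep(pat, len %/% nchar(pat) + 1L), 1L, len)
}

#' Generate a synthetic organism
#'
#' Realizes an [organism_composition()]: one protein per requested
#' scaffoldin (via [generate_scaffoldin_architecture()]) plus the requested
#' enzyme and dockerin-fusion complement, with placeholder amino-acid
#' sequences whose lengths match the architectures. Deterministic under the
#' composition's seed: the same composition generates byte-identical output.
#' Round-trip guarantees: [tally_scaffoldins()] on the generated
#' architectures recovers the scaffoldin composition exactly, and
#' [tabulate_enzyme_profile()] reports exactly the requested `docgh_lcb`.
#'
#' @param comp An `organism_composition`.
#' @return Object of class `synthetic_organism`: `organism_id`,
#'   `architectures` (named list of `protein_arch`), `sequences` (named
#'   character vector of placeholder sequences), `composition`.
#' @export
generate_organism <- function(comp) {
  stopifnot(inherits(comp, "organism_composition"))
  withr::with_seed(comp$seed, {
    archs <- list()
    k <- 0L
    add <- function(arch) {
      archs[[arch$protein_id]] <<- arch
    }
    for (cat in scaffoldin_categories()) {
      n <- comp$scaffoldins[[cat]]
      for (i in seq_len(n)) {
        k <- k + 1L
        add(generate_scaffoldin_architecture(
          cat, protein_id = sprintf("%s|P%03d_%s", comp$organism_id, k,
                                    tolower(cat))))
      }
    }
    emit <- function(n, labeller, tag) {
      for (i in seq_len(n)) {
        k <<- k + 1L
        add(.layout_architecture(
          sprintf("%s|P%03d_%s", comp$organism_id, k, tag), labeller()))
      }
    }
    emit(comp$docgh_lcb, function() c("DOC1", sample(.GH_LCB_FAMILIES, 1L)),
         "docgh_lcb")
    emit(comp$docgh_oligo, function() c("DOC1", sample(.GH_OLIGO_FAMILIES, 1L)),
         "docgh_oligo")
    emit(comp$freegh_lcb, function() sample(.GH_LCB_FAMILIES, 1L), "freegh_lcb")
    emit(comp$free_cazyme, function() sample(c("PL1", "CE4", "PL9"), 1L),
         "free_cazyme")
    emit(comp$doc_cbm, function() c("DOC1", "CBM3"), "doc_cbm")
    emit(comp$doc_cazyme, function() c("DOC1", sample(c("PL1", "CE4"), 1L)),
         "doc_cazyme")
    emit(comp$doc_other, function() c("DOC1", "OTHER"), "doc_other")
    emit(comp$rsgi, function() "RSGI", "rsgi")
    emit(comp$cbm3_slh, function() c("CBM3", "SLH"), "cbm3_slh")
    seqs <- vapply(archs, function(a) .placeholder_seq(a$length), character(1))
    structure(list(organism_id = comp$organism_id, architectures = archs,
                   sequences = seqs, composition = comp),
              class = "synthetic_organism")
  })
}

#' @export
print.synthetic_organism <- function(x, ...) {
  cat(sprintf("<synthetic_organism> %s: %d proteins (%d scaffoldins requested)\n",
              x$organism_id, length(x$architectures),
              sum(x$composition$scaffoldins)))
  invisible(x)
}

#' Write a synthetic organism to disk
#'
#' Emits the architecture-table TSV (annotation interchange dialect), a
#' protein FASTA of the placeholder sequences, and the composition as YAML.
#' The placeholder sequences are repetitive and non-biological: running real
#' sequence annotators on them will not reproduce the architectures.
#'
#' @param org A `synthetic_organism`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_organism <- function(org, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_architecture_table(org$architectures,
                           file.path(dir, "architectures.tsv"))
  seqinr::write.fasta(as.list(org$sequences), names = names(org$sequences),
                      file.out = file.path(dir, "proteins.fasta"))
  comp <- org$composition
  yaml::write_yaml(list(organism_id = comp$organism_id,
                        scaffoldins = as.list(comp$scaffoldins),
                        docgh_lcb = comp$docgh_lcb,
                        docgh_oligo = comp$docgh_oligo,
                        freegh_lcb = comp$freegh_lcb,
                        free_cazyme = comp$free_cazyme,
                        doc_cbm = comp$doc_cbm, doc_cazyme = comp$doc_cazyme,
                        doc_other = comp$doc_other, rsgi = comp$rsgi,
                        cbm3_slh = comp$cbm3_slh, seed = comp$seed),
                   file.path(dir, "composition.yaml"))
  invisible(dir)
}

#' Truncate an architecture at a contig break
#'
#' Models a sequencing truncation: the protein ends at `cut`, domains lying
#' entirely beyond the cut are removed, and a domain straddling the cut is
#' removed too (a partial domain is not detectable by profile search).
#' Position flags are recomputed for the shortened protein and the
#' truncation flag is set. The cohesin count never increases.
#'
#' @param arch A `protein_arch`.
#' @param cut Residue index of the break (`1 <= cut < length`).
#' @return The truncated `protein_arch`.
#' @export
apply_truncation <- function(arch, cut) {
  cut <- as.integer(cut)
  if (cut < 1L || cut >= arch$length) {
    stop("cut must lie within [1, length): ", cut, " vs length ", arch$length)
  }
  d <- arch$domains[arch$domains$end <= cut, c("label", "start", "end"),
                    drop = FALSE]
  d <- .flag_domains(d, cut)
  protein_arch(arch$protein_id, cut, d, truncated = TRUE)
}

#' Decoy structure specification and generation
#'
#' Perturbs a reference fold with isotropic Gaussian coordinate noise and
#' optional random residue deletions, synthesizing uniform confidence values
#' (pLDDT 90) for the retained residues. Seed-deterministic.
#'
#' @param base Reference name present in `refs`.
#' @param sigma Coordinate noise standard deviation (Angstrom, >= 0).
#' @param delete_frac Fraction of residues deleted (in `[0, 0.5]`).
#' @param seed Random seed.
#' @param refs A `reference_set`.
#' @return A `ca_structure`.
#' @export
generate_decoy_structure <- function(base, sigma = 0, delete_frac = 0,
                                     seed = 1L,
                                     refs = synthetic_reference_set()) {
  if (!base %in% names(refs$structures)) {
    stop("unknown reference: ", base, " (have: ",
         paste(names(refs$structures), collapse = ", "), ")")
  }
  stopifnot(sigma >= 0, delete_frac >= 0, delete_frac <= 0.5)
  xyz <- refs$structures[[base]]
  withr::with_seed(seed, {
    n <- nrow(xyz)
    keep <- sort(sample(n, n - floor(delete_frac * n)))
    pert <- xyz[keep, , drop = FALSE] +
      matrix(stats::rnorm(length(keep) * 3, sd = sigma), ncol = 3)
    ca_structure(sprintf("decoy_%s_s%g", base, sigma), pert,
                 plddt = rep(90, length(keep)))
  })
}

#' Generate a non-cohesin negative structure
#'
#' Extended chains and three-helix bundles with lengths matched to the
#' references, guaranteeing a negative class for match-threshold tests.
#'
#' @param kind `"extended"` or `"three_helix"`.
#' @param length Residue count.
#' @param seed Random seed (jitters coordinates slightly so repeated
#'   negatives are distinct).
#' @return A `ca_structure`.
#' @export
generate_negative_structure <- function(kind = c("extended", "three_helix"),
                                        length = 140L, seed = 1L) {
  kind <- match.arg(kind)
  withr::with_seed(seed, {
    n <- as.integer(length)
    if (kind == "extended") {
      # beta-strand-like zigzag, ~3.4 A rise per residue
      xyz <- cbind(3.4 * seq_len(n), rep(c(0.9, -0.9), length.out = n), 0)
    } else {
      per <- ceiling(n / 3)
      helix <- function(m, x0, flip) {
        t <- seq_len(m)
        z <- 1.5 * t
        if (flip) z <- rev(z)
        cbind(x0 + 2.3 * cos(t * 100 * pi / 180),
              2.3 * sin(t * 100 * pi / 180), z)
      }
      xyz <- rbind(helix(per, 0, FALSE), helix(per, 10, TRUE),
                   helix(n - 2L * per, 20, FALSE))
    }
    xyz <- xyz + matrix(stats::rnorm(3 * n, sd = 0.05), ncol = 3)
    ca_structure(paste0("negative_", kind), xyz)
  })
}

#' Simulate a cohort of cellulosome-producing organisms
#'
#' Generates a population with the class structure of the published screen:
#' complex producers with high DocGH-LCB gene counts, simple producers with
#' high or low counts, and marginal scaffoldin-containing organisms. Count
#' ranges follow the screen's reported bands (high 22-70, low 1-10 DocGH-LCB
#' genes; non-GH dockerin-fusion load roughly 0.8-2.2x the DocGH-LCB count
#' for high producers) — see the methods vignette for the full recipe and
#' its limits.
#'
#' @param seed Cohort seed; per-organism seeds are derived from it.
#' @param n_complex_high,n_simple_high,n_simple_low,n_scaffoldin Class sizes.
#' @return List of `synthetic_organism` objects.
#' @export
simulate_cohort <- function(seed = 1L, n_complex_high = 10L,
                            n_simple_high = 8L, n_simple_low = 15L,
                            n_scaffoldin = 4L) {
  withr::with_seed(seed, {
    org_seeds <- sample.int(2^30, n_complex_high + n_simple_high +
                              n_simple_low + n_scaffoldin)
    comps <- list()
    i <- 0L
    split3 <- function(total) {
      if (total == 0L) return(c(0L, 0L, 0L))
      as.integer(stats::rmultinom(1, total, prob = c(0.35, 0.3, 0.35)))
    }
    for (j in seq_len(n_complex_high)) {
      i <- i + 1L
      lcb <- sample(22:70, 1L)
      extras <- split3(round(lcb * stats::runif(1, 0.8, 2.2)))
      comps[[i]] <- organism_composition(
        sprintf("complex_high_%02d", j),
        scaffoldins = c(COMPLEX_PRIMARY = sample(1:2, 1L),
                        SLH_ANCHORING = sample(2:8, 1L),
                        NONSLH_ANCHORING = sample(0:3, 1L),
                        MONOVALENT_ADAPTOR = sample(1:10, 1L),
                        POLYVALENT_ADAPTOR = sample(1:3, 1L),
                        CELL_FREE = sample(0:3, 1L),
                        SINGLE_COHESIN = sample(0:3, 1L)),
        docgh_lcb = lcb, docgh_oligo = sample(0:8, 1L),
        freegh_lcb = sample(2:15, 1L), free_cazyme = sample(5:30, 1L),
        doc_cbm = extras[1], doc_cazyme = extras[2], doc_other = extras[3],
        rsgi = sample(7:14, 1L), cbm3_slh = sample(0:6, 1L),
        seed = org_seeds[i])
    }
    for (j in seq_len(n_simple_high)) {
      i <- i + 1L
      lcb <- sample(22:45, 1L)
      extras <- split3(round(lcb * stats::runif(1, 0.3, 1.2)))
      comps[[i]] <- organism_composition(
        sprintf("simple_high_%02d", j),
        scaffoldins = c(SIMPLE_PRIMARY = sample(1:4, 1L),
                        SINGLE_COHESIN = sample(0:2, 1L),
                        CELL_FREE = sample(0:1, 1L)),
        docgh_lcb = lcb, docgh_oligo = sample(0:5, 1L),
        freegh_lcb = sample(1:10, 1L), free_cazyme = sample(3:20, 1L),
        doc_cbm = extras[1], doc_cazyme = extras[2], doc_other = extras[3],
        seed = org_seeds[i])
    }
    for (j in seq_len(n_simple_low)) {
      i <- i + 1L
      extras <- split3(sample(0:6, 1L))
      comps[[i]] <- organism_composition(
        sprintf("simple_low_%02d", j),
        scaffoldins = c(SIMPLE_PRIMARY = 1L,
                        SINGLE_COHESIN = sample(0:2, 1L)),
        docgh_lcb = sample(1:10, 1L), docgh_oligo = sample(0:3, 1L),
        freegh_lcb = sample(0:5, 1L), free_cazyme = sample(5:40, 1L),
        doc_cbm = extras[1], doc_cazyme = extras[2], doc_other = extras[3],
        seed = org_seeds[i])
    }
    for (j in seq_len(n_scaffoldin)) {
      i <- i + 1L
      comps[[i]] <- organism_composition(
        sprintf("scaffoldin_cont_%02d", j),
        scaffoldins = c(POLYVALENT_ADAPTOR = 1L,
                        MONOVALENT_ADAPTOR = sample(0:5, 1L),
                        SINGLE_COHESIN = sample(0:3, 1L)),
        docgh_lcb = 1L, doc_other = sample(0:12, 1L),
        free_cazyme = sample(5:40, 1L),
        seed = org_seeds[i])
    }
    # pin the polyvalent adaptors of marginal organisms at 2 cohesins
    orgs <- lapply(comps, function(comp) {
      org <- generate_organism(comp)
      if (startsWith(comp$organism_id, "scaffoldin_cont")) {
        org <- .pin_polyvalent_two_cohesins(org)
      }
      org
    })
    names(orgs) <- vapply(orgs, `[[`, character(1), "organism_id")
    orgs
  })
}

# regenerate polyvalent adaptors with exactly two cohesins so the largest
# scaffoldin of a marginal organism stays below the conventional threshold
.pin_polyvalent_two_cohesins <- function(org) {
  for (pid in names(org$architectures)) {
    if (grepl("polyvalent_adaptor$", pid)) {
      org$architectures[[pid]] <- generate_scaffoldin_architecture(
        "POLYVALENT_ADAPTOR", n_cohesins = 2L, protein_id = pid,
        seed = org$composition$seed + nchar(pid))
      org$sequences[[pid]] <- .placeholder_seq(org$architectures[[pid]]$length)
    }
  }
  org
}
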