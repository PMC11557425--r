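#' Parse an InterProScan-style domain annotation table
#'
#' Reads the tab-separated dialect with at least the columns protein id,
#' accession, start, end (1-based inclusive coordinates). Both a minimal
#' 4/5-column layout (`protein_id  accession  start  end [score]`, with or
#' without a header) and the full 11+-column InterProScan layout (protein in
#' column 1, member database in 4, accession in 5, start/stop in 7/8, score
#' in 9) are accepted; the layout is chosen by column count.
#'
#' @param path Path to the TSV file.
#' @param lexicon `domain_lexicon` used downstream; kept as an attribute so
#'   callers can pass the hits straight to [canonicalize_hits()].
#' @return A `data.frame` of domain hits (class `domain_hits`) with columns
#'   `protein_id`, `source_db`, `accession`, `start`, `end`, `score`, sorted
#'   by protein id then start. An empty file yields a zero-row frame.
#' @export
#' @examples
#' tsv <- system.file("extdata", "synthetic_amesophilus_interproscan.tsv",
#'                    package = "cellulosomics")
#' hits <- parse_interproscan_tsv(tsv)
#' head(hits)
parse_interproscan_tsv <- function(path, lexicon = default_lexicon()) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  empty <- data.frame(protein_id = character(0), source_db = character(0),
                      accession = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(.as_domain_hits(empty, lexicon))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  # header detection: minimal layout may lead with column names
  if (ncol1 <= 6 && identical(trimws(fields[[1]][1]), "protein_id")) {
    fields <- fields[-1]
    lines <- lines[-1]
    if (length(fields) == 0L) return(.as_domain_hits(empty, lexicon))
  }
  parse_row <- function(f, i) {
    f <- trimws(f)
    if (length(f) >= 11) {
      out <- list(protein_id = f[1], source_db = f[4], accession = f[5],
                  start = f[7], end = f[8], score = f[9])
    } else if (length(f) >= 4) {
      out <- list(protein_id = f[1], source_db = NA_character_, accession = f[2],
                  start = f[3], end = f[4],
                  score = if (length(f) >= 5) f[5] else NA_character_)
    } else {
      stop("line ", i, ": expected >= 4 tab-separated fields, got ", length(f))
    }
    s <- suppressWarnings(as.integer(out$start))
    e <- suppressWarnings(as.integer(out$end))
    if (is.na(s) || is.na(e)) {
      stop("line ", i, ": malformed coordinates '", out$start, "'-'", out$end, "'")
    }
    if (s < 1L || e < s) stop("line ", i, ": invalid interval ", s, "-", e)
    if (!nzchar(out$accession)) stop("line ", i, ": empty accession")
    sc <- suppressWarnings(as.numeric(out$score))
    data.frame(protein_id = out$protein_id, source_db = out$source_db,
               accession = out$accession, start = s, end = e, score = sc,
               stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, Map(parse_row, fields, seq_along(fields)))
  hits <- hits[order(hits$protein_id, hits$start, hits$end, hits$accession), ,
               drop = FALSE]
  rownames(hits) <- NULL
  .as_domain_hits(hits, lexicon)
}

.as_domain_hits <- function(df, lexicon) {
  attr(df, "lexicon") <- lexicon
  class(df) <- c("domain_hits", class(df))
  df
}

#' Canonicalize domain hits
#'
#' Relabels each hit to its canonical label via the lexicon (unknown
#' accessions become `OTHER`), then merges overlapping hits on the same
#' protein that share a canonical label into a single call spanning the union
#' interval. Overlapping hits with *different* labels are both kept, except
#' that a generic cohesin/dockerin call overlapped by a typed call of the
#' same superfamily is absorbed into the typed call (typed profiles beat the
#' generic profile; raw profile hits are not what gets counted).
#'
#' @param hits `domain_hits` from [parse_interproscan_tsv()] or a compatible
#'   data.frame with `protein_id`, `accession`, `start`, `end`.
#' @param lexicon `domain_lexicon`.
#' @return A `data.frame` of canonical calls: `protein_id`, `label`, `start`,
#'   `end`, sorted by protein then start. Merging is idempotent.
#' @export
canonicalize_hits <- function(hits, lexicon = default_lexicon()) {
  stopifnot(all(c("protein_id", "accession", "start", "end") %in% names(hits)))
  calls <- data.frame(protein_id = hits$protein_id,
                      label = lexicon_label(hits$accession, lexicon),
                      start = as.integer(hits$start), end = as.integer(hits$end),
                      stringsAsFactors = FALSE)
  merged <- lapply(split(calls, calls$protein_id), .canonicalize_protein)
  out <- do.call(rbind, merged)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), label = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$protein_id, out$start, out$end, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.overlaps <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

.canonicalize_protein <- function(calls) {
  # drop generic cohesin/dockerin hits overlapped by a typed hit of the same kind
  for (grp in list(c(typed = "COH", generic = "COH_GENERIC"),
                   c(typed = "DOC", generic = "DOC_GENERIC"))) {
    typed <- calls[calls$label %in% paste0(grp[["typed"]], 1:3), , drop = FALSE]
    gen_i <- which(calls$label == grp[["generic"]])
    if (nrow(typed) && length(gen_i)) {
      absorbed <- vapply(gen_i, function(i) {
        any(.overlaps(calls$start[i], calls$end[i], typed$start, typed$end))
      }, logical(1))
      if (any(absorbed)) calls <- calls[-gen_i[absorbed], , drop = FALSE]
    }
  }
  # merge overlapping same-label calls into union intervals
  parts <- split(calls, calls$label)
  merged <- lapply(parts, function(p) {
    p <- p[order(p$start, p$end), , drop = FALSE]
    keep <- p[1, , drop = FALSE]
    if (nrow(p) > 1) {
      for (i in 2:nrow(p)) {
        j <- nrow(keep)
        if (p$start[i] <= keep$end[j]) {
          keep$end[j] <- max(keep$end[j], p$end[i])
        } else {
          keep <- rbind(keep, p[i, , drop = FALSE])
        }
      }
    }
    keep
  })
  do.call(rbind, merged)
}

#' Construct a protein architecture
#'
#' Low-level constructor; most callers go through [build_architectures()],
#' which also derives the terminal/internal flags.
#'
#' @param protein_id Protein identifier.
#' @param length Residue count.
#' @param domains `data.frame` with `label`, `start`, `end` (1-based
#'   inclusive) and, if already computed, the flag columns.
#' @param truncated `TRUE` when the protein ends at a contig break.
#' @return Object of class `protein_arch`.
#' @export
protein_arch <- function(protein_id, length, domains, truncated = FALSE) {
  stopifnot(is.character(protein_id), length >= 1)
  domains <- domains[order(domains$start, domains$end), , drop = FALSE]
  rownames(domains) <- NULL
  if (nrow(domains) && any(domains$start < 1 | domains$end > length |
                           domains$start > domains$end)) {
    stop("domain coordinates exceed protein bounds for ", protein_id)
  }
  structure(list(protein_id = protein_id, length = as.integer(length),
                 domains = domains, truncated = isTRUE(truncated)),
            class = "protein_arch")
}

#' @export
print.protein_arch <- function(x, ...) {
  cat(sprintf("<protein_arch> %s (%d aa%s): %s\n", x$protein_id, x$length,
              if (x$truncated) ", truncated" else "", domain_string(x)))
  invisible(x)
}

#' Ordered domain string of an architecture
#'
#' @param arch A `protein_arch`.
#' @param sep Separator between domain labels.
#' @return Single string, e.g. `"SIGNAL_PEPTIDE|CBM3|X2|COH1|COH1|DOC2"`.
#' @export
domain_string <- function(arch, sep = "|") paste(arch$domains$label, collapse = sep)

#' Count domains of given canonical labels in an architecture
#'
#' @param arch A `protein_arch`.
#' @param labels Character vector of canonical labels.
#' @return Integer count.
#' @export
count_domains <- function(arch, labels) sum(arch$domains$label %in% labels)

#' Count cohesin / dockerin domains
#'
#' Cohesins are `COH1`+`COH2`+`COH3`+`COH_GENERIC` calls after merging;
#' dockerins analogously.
#'
#' @param arch A `protein_arch`.
#' @return Integer count.
#' @export
count_cohesins <- function(arch) count_domains(arch, .COHESIN_LABELS)

#' @rdname count_cohesins
#' @export
count_dockerins <- function(arch) count_domains(arch, .DOCKERIN_LABELS)

# terminal/internal flags for a sorted domain table of one protein
.flag_domains <- function(domains, length,
                          n_term_frac = 0.15, c_term_margin = 60L) {
  n <- nrow(domains)
  if (n == 0L) {
    domains$is_n_terminal <- logical(0)
    domains$is_c_terminal <- logical(0)
    domains$is_internal <- logical(0)
    return(domains)
  }
  non_sp <- which(domains$label != "SIGNAL_PEPTIDE")
  first_non_sp <- if (length(non_sp)) non_sp[1] else NA_integer_
  idx <- seq_len(n)
  domains$is_n_terminal <- (idx == first_non_sp & !is.na(first_non_sp)) |
    domains$start <= n_term_frac * length
  domains$is_c_terminal <- idx == n | domains$end >= length - c_term_margin + 1L
  domains$is_internal <- !domains$is_n_terminal & !domains$is_c_terminal
  domains
}

#' Build per-protein architectures from canonical calls
#'
#' Sorts calls by start and derives position flags: a domain is N-terminal if
#' it is the first non-signal-peptide domain or starts within the first
#' `n_term_frac` of the sequence; C-terminal if it is the last domain or ends
#' within `c_term_margin` residues of the C-terminus; internal otherwise (a
#' lone domain is both N- and C-terminal). Truncation flags are supplied
#' externally, e.g. for proteins at contig ends.
#'
#' @param calls Canonical call `data.frame` from [canonicalize_hits()].
#' @param lengths Named integer vector, `protein_id -> residue count`. Every
#'   protein appearing in `calls` must be present.
#' @param truncations Character vector of protein ids flagged as truncated.
#' @param n_term_frac,c_term_margin Positional thresholds (fraction of the
#'   sequence / residues from the C-terminus).
#' @return Named list of `protein_arch` objects, one per protein in
#'   `lengths` (proteins without calls get empty architectures).
#' @export
build_architectures <- function(calls, lengths, truncations = character(0),
                                n_term_frac = 0.15, c_term_margin = 60L) {
  stopifnot(!is.null(names(lengths)))
  missing_len <- setdiff(unique(calls$protein_id), names(lengths))
  if (length(missing_len)) {
    stop("no length known for protein(s): ", paste(missing_len, collapse = ", "))
  }
  by_protein <- split(calls, calls$protein_id)
  archs <- lapply(names(lengths), function(pid) {
    len <- as.integer(lengths[[pid]])
    d <- by_protein[[pid]]
    if (is.null(d)) {
      d <- data.frame(label = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
    } else {
      if (any(d$end > len)) {
        stop("call coordinates exceed protein length for ", pid)
      }
      d <- d[order(d$start, d$end), c("label", "start", "end"), drop = FALSE]
    }
    rownames(d) <- NULL
    d <- .flag_domains(d, len, n_term_frac, c_term_margin)
    protein_arch(pid, len, d, truncated = pid %in% truncations)
  })
  names(archs) <- names(lengths)
  archs
}

#' Write / read the normalized architecture table
#'
#' The architecture-table TSV is the package's interchange dialect: one row
#' per protein with the ordered domain string, per-domain coordinates
#' (`label:start-end` separated by `;`) and the truncation flag. A round trip
#' through [write_architecture_table()] and [read_architecture_table()]
#' reproduces identical architectures.
#'
#' @param archs List of `protein_arch` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_architecture_table <- function(archs, path) {
  rows <- vapply(archs, function(a) {
    coords <- paste(sprintf("%s:%d-%d", a$domains$label, a$domains$start,
                            a$domains$end), collapse = ";")
    paste(a$protein_id, a$length, domain_string(a), coords,
          as.integer(a$truncated), sep = "\t")
  }, character(1))
  writeLines(c("protein_id\tlength\tdomain_string\tdomain_coords\ttruncated", rows),
             path)
  invisible(path)
}

#' @rdname write_architecture_table
#' @param n_term_frac,c_term_margin Flag thresholds, as in
#'   [build_architectures()].
#' @export
read_architecture_table <- function(path, n_term_frac = 0.15,
                                    c_term_margin = 60L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "character",
                                          "character", "integer"))
  archs <- lapply(seq_len(nrow(tab)), function(i) {
    coords <- tab$domain_coords[i]
    if (nzchar(coords)) {
      parts <- strsplit(strsplit(coords, ";", fixed = TRUE)[[1]], "[:-]")
      d <- data.frame(
        label = vapply(parts, function(p) paste(p[seq_len(length(p) - 2)],
                                                collapse = ":"), character(1)),
        start = vapply(parts, function(p) as.integer(p[length(p) - 1]), integer(1)),
        end = vapply(parts, function(p) as.integer(p[length(p)]), integer(1)),
        stringsAsFactors = FALSE)
    } else {
      d <- data.frame(label = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
    }
    d <- .flag_domains(d[order(d$start, d$end), , drop = FALSE], tab$length[i],
                       n_term_frac, c_term_margin)
    protein_arch(tab$protein_id[i], tab$length[i], d,
                 truncated = tab$truncated[i] == 1L)
  })
  names(archs) <- tab$protein_id
  archs
}
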