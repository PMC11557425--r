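#' Run configuration
#'
#' Bundles the paths and thresholds of a pipeline run so outputs can be
#' reproduced. The serialized config (and its hash) is written into every
#' output directory by [write_run_config()].
#'
#' @param input Input path (architecture table or annotation TSV).
#' @param lexicon,activity_map,references Optional config-file paths
#'   (`NULL` = packaged defaults).
#' @param out Output directory.
#' @param seed Integer seed for any stochastic step.
#' @param tm_threshold TM-score match threshold.
#' @param l_norm TM-score normalization length.
#' @param high_min,low_max DocGH-LCB level bounds.
#' @param threshold_conventional Minimum cohesins for conventional capacity.
#' @param log_level `"info"` or `"debug"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, lexicon = NULL, activity_map = NULL,
                       references = NULL, out = ".", seed = 1L,
                       tm_threshold = 0.50, l_norm = 140L, high_min = 22L,
                       low_max = 10L, threshold_conventional = 3L,
                       log_level = "info") {
  stopifnot(tm_threshold > 0, tm_threshold < 1, l_norm >= 16,
            high_min > low_max, threshold_conventional >= 2,
            log_level %in% c("info", "debug"))
  structure(list(input = input, lexicon = lexicon,
                 activity_map = activity_map, references = references,
                 out = out, seed = as.integer(seed),
                 tm_threshold = tm_threshold, l_norm = as.integer(l_norm),
                 high_min = as.integer(high_min), low_max = as.integer(low_max),
                 threshold_conventional = as.integer(threshold_conventional),
                 log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param dir Directory the config is serialized into.
#' @return The config hash (MD5 of the serialized YAML), invisibly for
#'   [write_run_config()].
#' @export
write_run_config <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(unclass(config), path)
  hash <- unname(tools::md5sum(path))
  writeLines(hash, file.path(dir, "run_config.md5"))
  invisible(hash)
}

#' Render the per-organism summary table
#'
#' One row per organism: producer class, DocGH-LCB level, scaffoldin
#' category counts, cohesin totals, enzyme counts, RsgI count and (when
#' complementarity reports are supplied) the orphan cohesin/dockerin types.
#' Rows are sorted by producer class (complex, simple,
#' scaffoldin-containing, non-producer) and then organism id, so reruns on
#' identical inputs are byte-identical.
#'
#' @param typings List of `organism_type` objects.
#' @param tallies List of `scaffoldin_tally` objects.
#' @param profiles List of `enzyme_profile` objects.
#' @param complementarity Optional list of `complementarity_report`s, named
#'   by organism id.
#' @return `data.frame`, one row per organism.
#' @export
render_summary <- function(typings, tallies, profiles, complementarity = NULL) {
  ids <- function(xs) sort(vapply(xs, `[[`, character(1), "organism_id"))
  if (!identical(ids(typings), ids(tallies)) ||
      !identical(ids(typings), ids(profiles))) {
    stop("typings, tallies and profiles cover different organism sets")
  }
  by_id <- function(xs) {
    stats::setNames(xs, vapply(xs, `[[`, character(1), "organism_id"))
  }
  typings <- by_id(typings); tallies <- by_id(tallies); profiles <- by_id(profiles)
  rows <- lapply(names(typings), function(id) {
    ty <- typings[[id]]; ta <- tallies[[id]]; pr <- profiles[[id]]
    row <- data.frame(organism_id = id, producer_class = ty$producer_class,
                      docgh_lcb_level = ty$docgh_lcb_level,
                      stringsAsFactors = FALSE)
    counts <- as.data.frame(as.list(ta$counts))
    names(counts) <- tolower(names(ta$counts))
    row <- cbind(row, counts,
                 data.frame(total_cohesins = ta$total_cohesins,
                            max_cohesins = ta$max_cohesins))
    row <- cbind(row, enzyme_profile_row(pr)[, -1])
    if (!is.null(complementarity)) {
      cr <- complementarity[[id]]
      orphans <- if (is.null(cr)) NA_character_ else {
        o <- c(names(cr$orphan_coh)[cr$orphan_coh],
               names(cr$orphan_doc)[cr$orphan_doc])
        if (length(o)) paste(o, collapse = ",") else ""
      }
      row$orphan_types <- orphans
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(organism_id = character(0)))
  ord <- order(factor(out$producer_class,
                      levels = c("COMPLEX", "SIMPLE", "SCAFFOLDIN_CONTAINING",
                                 "NON_PRODUCER")),
               out$organism_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end typing of one organism's architectures
#'
#' Convenience wrapper chaining [tally_scaffoldins()],
#' [tabulate_enzyme_profile()], [type_organism()] and
#' [cohesin_dockerin_complementarity()].
#'
#' @param archs Named list of `protein_arch` objects for one organism.
#' @param organism_id Organism identifier.
#' @param map An `activity_map`.
#' @param ... Threshold arguments forwarded to [type_organism()].
#' @return List with `tally`, `profile`, `typing`, `complementarity`.
#' @export
profile_organism <- function(archs, organism_id, map = default_activity_map(),
                             ...) {
  tally <- tally_scaffoldins(archs, organism_id)
  profile <- tabulate_enzyme_profile(archs, map, organism_id)
  list(tally = tally, profile = profile,
       typing = type_organism(tally, profile, ...),
       complementarity = cohesin_dockerin_complementarity(archs))
}
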