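# Run manifests and tabular reports. Every CLI run writes a JSON manifest
# (inputs, checksums, seeds, replicate counts, package version, timestamp)
# sufficient to reproduce its outputs.

#' Build a run manifest
#'
#' @param inputs named character vector of input file paths (checksummed).
#' @param seed base seed of the run.
#' @param n_replicates replicate count.
#' @param years,burn_in simulation horizon.
#' @param traits traits covered by the run.
#' @param extra optional named list merged into the manifest.
#' @return named list of class `run_manifest`.
#' @export
run_manifest <- function(inputs, seed, n_replicates, years, burn_in,
                         traits = character(0), extra = list()) {
  m <- c(list(
    package = "herdEV",
    version = as.character(packageVersion("herdEV")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(unname(inputs))),
    seed = seed,
    n_replicates = n_replicates,
    years = years,
    burn_in = burn_in,
    traits = traits
  ), extra)
  class(m) <- "run_manifest"
  m
}

#' Write a manifest as JSON
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' One-row EV report from an estimate
#' @param est an `ev_estimate`.
#' @param breed breed label for the report row.
#' @return one-row data.frame mirroring the EV summary columns.
#' @export
ev_report_row <- function(est, breed) {
  data.frame(breed = breed, trait = est$trait, unit = est$unit,
             ev = est$ev, se = est$se,
             ci95_lower = est$ci95[["lower"]], ci95_upper = est$ci95[["upper"]],
             per_case_cost = est$per_case_cost, n_rows = est$n_rows)
}

#' Assemble the traits-by-breeds EV summary matrix
#'
#' @param rows data.frame of [ev_report_row()] rows (possibly several
#'   breeds).
#' @return data.frame with one row per trait (in the canonical trait order)
#'   and one `ev_<breed>` column per breed, plus a units column; traits
#'   absent from `rows` carry `NA` and are listed in the
#'   `"missing_traits"` attribute.
#' @export
ev_summary_table <- function(rows) {
  stopifnot(nrow(rows) > 0)
  breeds <- unique(rows$breed)
  out <- data.frame(trait = TRAITS,
                    unit = vapply(TRAITS, trait_unit, character(1)))
  for (b in breeds) {
    sub <- rows[rows$breed == b, ]
    out[[paste0("ev_", b)]] <- sub$ev[match(TRAITS, sub$trait)]
  }
  missing <- TRAITS[!TRAITS %in% rows$trait]
  attr(out, "missing_traits") <- missing
  out
}
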