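#' Estimated complete genome size from assembly length and completeness
#'
#' length / (completeness / 100), rounded to the nearest base pair. The
#' estimate is always at least the assembly length and is monotone
#' decreasing in completeness at fixed length.
#'
#' @param length_bp assembly length in bp (> 0); vectorized.
#' @param completeness_percent completeness in (0, 100], e.g. a CheckM
#'   estimate.
#' @return estimated complete size in bp (integer-valued numeric).
#' @examples
#' estimated_complete_size(1935310, 96.17)   # ~2.01 Mbp
#' @export
estimated_complete_size <- function(length_bp, completeness_percent) {
  if (any(length_bp <= 0)) stop("assembly length must be > 0")
  if (any(completeness_percent <= 0) || any(completeness_percent > 100)) {
    stop("completeness must lie in (0, 100]")
  }
  round(length_bp / (completeness_percent / 100))
}

#' Read a genome cohort table
#'
#' TSV with columns `name`, `assembly_length`, `completeness`,
#' `contamination`, `gc`, `coding_density` and optionally `subclade`.
#' Completeness and contamination are consumed from upstream tool output
#' (CheckM-style), never computed here.
#'
#' @param path file path.
#' @return validated data frame of class `ecophys_genomes`.
#' @export
read_genome_table <- function(path) {
  genome_records(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Validate a genome cohort table
#'
#' @param records data frame with the columns listed in
#'   [read_genome_table()].
#' @return the table, classed `ecophys_genomes`, with an
#'   `estimated_size` column added.
#' @export
genome_records <- function(records) {
  needed <- c("name", "assembly_length", "completeness", "gc", "coding_density")
  if (!all(needed %in% names(records))) {
    stop("genome table needs columns: ", paste(needed, collapse = ", "))
  }
  if (!nrow(records)) stop("empty genome table")
  records$estimated_size <- estimated_complete_size(records$assembly_length,
                                                    records$completeness)
  structure(records, class = c("ecophys_genomes", "data.frame"))
}

#' Cohort medians and ranges for genome characteristics
#'
#' Medians (usual order statistic, mean of the central pair for even n) and
#' (min, max) ranges of estimated complete genome size, GC content and
#' coding density. Sizes are kept in bp internally; rounding to Mbp happens
#' only at print time (2 decimals).
#'
#' @param records an `ecophys_genomes` table (see [genome_records()]).
#' @return data frame of class `ecophys_cohort` with columns `metric`,
#'   `median`, `min`, `max` (size rows in bp).
#' @export
cohort_summary <- function(records) {
  stopifnot(nrow(records) > 0)
  if (!"estimated_size" %in% names(records)) records <- genome_records(records)
  one <- function(metric, v) {
    data.frame(metric = metric, median = stats::median(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }
  out <- rbind(one("estimated_size_bp", records$estimated_size),
               one("gc_percent", records$gc),
               one("coding_density_percent", records$coding_density))
  structure(out, class = c("ecophys_cohort", "data.frame"))
}

#' @export
print.ecophys_cohort <- function(x, ...) {
  shown <- as.data.frame(x)
  sz <- shown$metric == "estimated_size_bp"
  shown[sz, c("median", "min", "max")] <-
    round(shown[sz, c("median", "min", "max")] / 1e6, 2)
  shown$metric[sz] <- "estimated_size_mbp"
  print(shown, row.names = FALSE)
  invisible(x)
}
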