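#' Read and write the package's tab-separated formats
#'
#' Plain TSV with a header row, UTF-8, `.` decimal. Sites:
#' `site_id, name, latitude_deg`. Weather: `site_id, date, tmean_c`.
#' Phenotypes: `genotype_id, env_id, rep, heading_days`. Genotypes: lines
#' by markers, first column `line_id`, remaining headers are marker ids.
#' Map: `marker_id, chrom, pos_cM`. Designs travel as JSON
#' (`{"env_ids": [...], "K": n}`).
#'
#' @param path File path.
#' @name optimet_io
NULL

#' @rdname optimet_io
#' @export
read_sites_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  sites_table(d$site_id, d$latitude_deg, d$name)
}

#' @rdname optimet_io
#' @param x Object to write (tibble of the matching shape).
#' @export
write_weather_tsv <- function(x, path) {
  readr::write_tsv(x[, c("site_id", "date", "tmean_c")], path)
}

#' @rdname optimet_io
#' @export
read_weather_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(site_id = "c", date = "D",
                                               tmean_c = "d"))
  if (any(d$tmean_c < -40 | d$tmean_c > 55)) {
    stop_invalid("temperatures outside the plausible [-40, 55] degC window")
  }
  d
}

#' @rdname optimet_io
#' @export
read_phenotypes_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(genotype_id = "c", env_id = "c",
                                          rep = "i", heading_days = "d"))
}

#' @rdname optimet_io
#' @export
write_phenotypes_tsv <- function(x, path) {
  readr::write_tsv(x[, c("genotype_id", "env_id", "rep", "heading_days")],
                   path)
}

#' @rdname optimet_io
#' @export
read_genotypes_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  X <- as.matrix(d[, -1])
  storage.mode(X) <- "integer"
  rownames(X) <- d[[1]]
  X
}

#' @rdname optimet_io
#' @export
read_map_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(marker_id = "c", chrom = "i",
                                          pos_cM = "d"))
}

#' @rdname optimet_io
#' @param design `met_design` object.
#' @param env_ids Candidate environment ids the design indexes into.
#' @export
write_design_json <- function(design, env_ids, path) {
  jsonlite::write_json(list(env_ids = env_ids[design$indices], K = design$K),
                       path, auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname optimet_io
#' @export
read_design_json <- function(path, env_ids) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  idx <- match(d$env_ids, env_ids)
  if (anyNA(idx)) {
    stop_invalid("design references unknown environments: ",
                 paste(d$env_ids[is.na(idx)], collapse = ", "))
  }
  met_design(idx, d$K)
}
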