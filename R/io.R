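#' Write a lattice window to delimited text
#'
#' One line of JSON metadata (prefixed `#`) followed by the 0/1 state
#' matrix, one lattice row per line, space-delimited.
#'
#' @param lattice a [lattice_window()].
#' @param path output file path.
#' @param extra optional named list merged into the JSON header.
#' @return `path`, invisibly.
#' @export
write_lattice <- function(lattice, path, extra = list()) {
  stopifnot(inherits(lattice, "lattice_window"))
  header <- c(list(n_rows = lattice$n_rows, n_cols = lattice$n_cols,
                   parity = lattice$parity, phi = lattice$phi), extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(header, auto_unbox = TRUE,
                                          digits = NA, null = "null")), con)
  write.table(lattice$states, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a lattice window written by [write_lattice()]
#'
#' @param path input file path.
#' @return A [lattice_window()]; the JSON header is attached as attribute
#'   `header`.
#' @export
read_lattice <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) stop("missing JSON header line")
  header <- jsonlite::fromJSON(sub("^#", "", first))
  states <- as.matrix(read.table(path, skip = 1L))
  dimnames(states) <- NULL
  lat <- lattice_window(states,
                        phi = if (is.null(header$phi)) NA_real_ else header$phi)
  attr(lat, "header") <- header
  lat
}

#' Write lineage records as delimited text
#'
#' @param records data.frame with columns `mother`, `daughter`, `time`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(records, path) {
  write.table(records[, c("mother", "daughter", "time")], path,
              row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Write a correlation profile as two-column delimited text
#'
#' @param profile a [correlation_profile()].
#' @param path output file path.
#' @param extra optional named list merged into the JSON header.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, extra = list()) {
  stopifnot(inherits(profile, "correlation_profile"))
  header <- c(list(axis = attr(profile, "axis"), xi = attr(profile, "xi"),
                   n = nrow(profile)), extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(header, auto_unbox = TRUE,
                                          digits = NA)), con)
  write.table(profile[, c("lag", "value")], con,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run manifest for a set of output files
#'
#' Records the configuration snapshot, master seed, package version and a
#' checksum per output file, so that identical `(config, seed)` reruns can
#' be verified byte for byte.
#'
#' @param files character vector of output paths.
#' @param config list (or `growth_config`) echoed into the manifest.
#' @param seed master seed used for the run.
#' @param path manifest output path (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(files, config, seed, path) {
  manifest <- list(
    package = "corrperc",
    version = as.character(packageVersion("corrperc")),
    seed = seed,
    config = unclass(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Grow an ensemble and write it to disk
#'
#' Writes one lattice file and one lineage table per run, plus a manifest.
#' All randomness flows from `seed`, so identical `(config, seed)` calls
#' produce byte-identical outputs.
#'
#' @param config a [growth_config()].
#' @param n_lattices ensemble size.
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @return Invisibly, the manifest path.
#' @export
write_ensemble <- function(config, n_lattices, out_dir, seed = 1L) {
  stopifnot(inherits(config, "growth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  files <- character(0)
  for (i in seq_len(n_lattices)) {
    g <- grow_lattice(config)
    lat_path <- file.path(out_dir, sprintf("lattice_%04d.txt", i))
    lin_path <- file.path(out_dir, sprintf("lineage_%04d.tsv", i))
    write_lattice(g$window, lat_path,
                  extra = list(index = i, seed = seed))
    write_lineage(g$lineage, lin_path)
    files <- c(files, lat_path, lin_path)
  }
  man <- file.path(out_dir, "manifest.json")
  write_manifest(files, config, seed, man)
  invisible(man)
}
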