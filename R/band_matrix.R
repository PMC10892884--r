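#' Construct a band-presence matrix
#'
#' A `band_matrix` holds the binary data matrix produced by scoring dominant
#' markers (ISSR, RAPD, AFLP) as 1 (band present) or 0 (band absent), together
#' with the population (geographic group) each isolate belongs to. Missing
#' scores are `NA`, never 0: an unscorable lane carries no information about
#' the band.
#'
#' @param values integer/numeric matrix, isolates in rows, loci in columns;
#'   entries 0, 1 or `NA`. Row and column names are used as isolate and locus
#'   IDs when `isolate_ids`/`locus_ids` are not given.
#' @param populations character vector, one population label per isolate.
#' @param isolate_ids,locus_ids optional character vectors of unique labels.
#' @return object of class `band_matrix` with components `values` (matrix with
#'   dimnames), `populations` (named character vector).
#' @export
band_matrix <- function(values, populations, isolate_ids = rownames(values),
                        locus_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(isolate_ids)) isolate_ids <- paste0("iso", seq_len(nrow(values)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(values)))
  isolate_ids <- as.character(isolate_ids)
  locus_ids <- as.character(locus_ids)
  if (nrow(values) < 2L || ncol(values) < 1L)
    stop("band matrix needs at least 2 isolates and 1 locus", call. = FALSE)
  if (anyDuplicated(isolate_ids))
    stop("duplicate isolate IDs: ",
         paste(unique(isolate_ids[duplicated(isolate_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(locus_ids))
    stop("duplicate locus IDs: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(populations) != nrow(values))
    stop("need one population label per isolate", call. = FALSE)
  if (anyNA(populations))
    stop("every isolate must have a population label", call. = FALSE)
  bad <- !(values %in% c(0, 1) | is.na(values))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(values)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid cell value %s at isolate '%s', locus '%s' (must be 0, 1 or NA)",
                 format(values[idx[1L], idx[2L]]),
                 isolate_ids[idx[1L]], locus_ids[idx[2L]]), call. = FALSE)
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(isolate_ids, locus_ids)
  structure(list(values = values,
                 populations = stats::setNames(as.character(populations),
                                               isolate_ids)),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d isolates x %d loci, %d populations, %d missing cells\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$populations)), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.band_matrix <- function(x) dim(x$values)

#' Read a band-presence matrix from delimited text
#'
#' Expected layout: header row, first column isolate ID, second column
#' population label, remaining columns one locus each with cells 0, 1 or NA.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`; default guessed from the file extension.
#' @return a [band_matrix].
#' @export
read_band_matrix <- function(path, dialect = c("guess", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "guess")
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (ncol(df) < 3L)
    stop("band matrix file needs isolate, population and >=1 locus column: ", path,
         call. = FALSE)
  loci <- as.matrix(df[, -(1:2), drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(loci), nrow = nrow(loci),
                                 dimnames = dimnames(loci)))
  bad <- which(!is.na(loci) & (is.na(num) | !(num %in% c(0, 1))), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid cell '%s' at isolate '%s', locus '%s' in %s",
                 loci[bad[1L, 1L], bad[1L, 2L]], df[[1L]][bad[1L, 1L]],
                 colnames(loci)[bad[1L, 2L]], path), call. = FALSE)
  band_matrix(num, populations = df[[2L]], isolate_ids = df[[1L]],
              locus_ids = colnames(loci))
}

#' Write a band-presence matrix to delimited text
#'
#' Round-trips exactly through [read_band_matrix()]: `NA` cells are written as
#' the literal string `NA`.
#'
#' @param m a [band_matrix].
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(m, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(isolate = rownames(m$values),
                   population = unname(m$populations),
                   m$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Partition isolates into analyzable populations
#'
#' Groups isolates by population label and flags groups smaller than `min_n`
#' as singletons: with a single isolate the within-group diversity of a clonal
#' collection is not estimable, so such groups are excluded from
#' per-population statistics while remaining in pooled analyses.
#'
#' @param m a [band_matrix].
#' @param min_n minimum isolates for a group to be analyzable (default 2).
#' @return object of class `population_partition`: data.frame with columns
#'   `population`, `n`, `analyzable`, plus attribute `indices` (named list of
#'   row indices into the matrix).
#' @export
partition_populations <- function(m, min_n = 2L) {
  stopifnot(inherits(m, "band_matrix"), min_n >= 1L)
  pops <- unique(unname(m$populations))
  idx <- lapply(pops, function(p) which(unname(m$populations) == p))
  names(idx) <- pops
  out <- data.frame(population = pops,
                    n = lengths(idx),
                    analyzable = lengths(idx) >= min_n,
                    stringsAsFactors = FALSE)
  attr(out, "indices") <- idx
  class(out) <- c("population_partition", class(out))
  out
}
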