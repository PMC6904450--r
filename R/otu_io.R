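#' OTU read-count tables
#'
#' An `otu_table` is an integer matrix of read counts with one row per OTU
#' and one column per sample, carrying unique OTU and sample identifiers as
#' dimnames. It is the raw input of every downstream analysis.
#'
#' @param counts Integer matrix (OTU x sample) of non-negative read counts.
#' @param otu_ids Character vector of unique OTU identifiers (defaults to
#'   `rownames(counts)`).
#' @param sample_ids Character vector of unique sample identifiers (defaults
#'   to `colnames(counts)`).
#' @return An `otu_table` object.
#' @export
otu_table <- function(counts, otu_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(otu_ids) || is.null(sample_ids)) {
    stop_parse("otu_table requires OTU and sample identifiers")
  }
  otu_ids <- as.character(otu_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(otu_ids)) {
    stop_parse(paste0("duplicate OTU id: ", otu_ids[duplicated(otu_ids)][1]))
  }
  if (anyDuplicated(sample_ids)) {
    stop_parse(paste0("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1]))
  }
  if (length(otu_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
    stop_parse("identifier lengths do not match the count matrix")
  }
  if (any(!is.finite(counts))) stop_parse("non-finite read count")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop_parse(sprintf("negative read count at OTU '%s', sample '%s'",
                       otu_ids[bad[1]], sample_ids[bad[2]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop_parse(sprintf("non-integer read count at OTU '%s', sample '%s'",
                       otu_ids[bad[1]], sample_ids[bad[2]]))
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max
  if (all(rowSums(counts) == 0)) stop_parse("no OTU with a positive total count")
  dimnames(counts) <- list(otu_ids, sample_ids)
  structure(counts, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples, %s reads\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Read an OTU table from TSV
#'
#' Expects a header row of sample identifiers, with the first column (named
#' `id_col`, by default `OTU_ID`) holding OTU identifiers. Gzip-compressed
#' files are handled transparently.
#'
#' @param path Path to the TSV (optionally .gz).
#' @param id_col Name of the identifier column. If the file's first column
#'   has a different name it is used regardless, with a warning only when
#'   `id_col` was set explicitly.
#' @param sep Field separator, default tab.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, id_col = "OTU_ID", sep = "\t") {
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  dt <- tryCatch({
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "rt")
      on.exit(close(con), add = TRUE)
      data.table::fread(text = readLines(con), sep = sep, header = TRUE,
                        data.table = TRUE, colClasses = list(character = 1))
    } else {
      data.table::fread(path, sep = sep, header = TRUE, data.table = TRUE,
                        colClasses = list(character = 1))
    }
  }, error = function(e) stop_parse(paste0("malformed table: ", conditionMessage(e))))
  if (ncol(dt) < 2) stop_parse("need an identifier column plus at least one sample")
  first <- names(dt)[1]
  if (!missing(id_col) && !identical(first, id_col)) {
    warning(sprintf("first column is named '%s', not '%s'; using it as the OTU id column",
                    first, id_col))
  }
  ids <- dt[[1]]
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(dt[, -1], is.numeric, logical(1)))[1]
    stop_parse(sprintf("non-numeric counts in sample column '%s'", names(dt)[bad + 1]))
  }
  nonint <- which(rowSums(mat != round(mat) | mat < 0 | !is.finite(mat)) > 0)
  if (length(nonint)) {
    stop_parse(sprintf("invalid count on line %d (OTU '%s')",
                       nonint[1] + 1L, ids[nonint[1]]))
  }
  otu_table(mat, otu_ids = ids, sample_ids = colnames(mat))
}

#' Write an OTU table as TSV
#'
#' Emits the same dialect [read_otu_table()] consumes, so read-write-read is
#' an identity on counts and identifiers.
#'
#' @param table An [otu_table].
#' @param path Output path; a `.gz` suffix triggers compression.
#' @param id_col Header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, id_col = "OTU_ID") {
  stopifnot(inherits(table, "otu_table"))
  dt <- data.table::data.table(id = rownames(table))
  data.table::setnames(dt, "id", id_col)
  dt <- cbind(dt, data.table::as.data.table(unclass(table)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Aggregate sample counts into an abundance vector
#'
#' Sums reads per OTU over a subset of samples and drops OTUs whose total in
#' that subset is zero, yielding the abundance vector x (reads per OTU) that
#' all distribution fitting operates on.
#'
#' @param table An [otu_table].
#' @param samples Character vector of sample ids to aggregate (default: all).
#' @return An `abundance_vector`: a data.frame with columns `otu_id` and `x`,
#'   plus attributes `N` (total reads) and `S` (observed richness).
#' @export
aggregate_counts <- function(table, samples = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(samples)) samples <- colnames(table)
  if (length(samples) == 0) stop_domain("empty sample subset")
  unknown <- setdiff(samples, colnames(table))
  if (length(unknown)) {
    stop_lookup(paste0("unknown sample id: ", unknown[1]))
  }
  x <- rowSums(table[, samples, drop = FALSE])
  keep <- x > 0
  abundance_vector(x[keep], otu_ids = rownames(table)[keep])
}

#' Construct an abundance vector
#'
#' @param x Positive integer reads per OTU.
#' @param otu_ids OTU identifiers (defaults to `names(x)` or generated ids).
#' @return An `abundance_vector` data.frame with attributes `N` and `S`.
#' @export
abundance_vector <- function(x, otu_ids = NULL) {
  if (length(x) == 0) stop_domain("empty abundance vector")
  if (any(x < 1) || any(x != round(x))) {
    stop_domain("abundances must be positive integers (reads per OTU)")
  }
  if (is.null(otu_ids)) {
    otu_ids <- names(x)
    if (is.null(otu_ids)) otu_ids <- sprintf("otu_%06d", seq_along(x))
  }
  if (anyDuplicated(otu_ids)) stop_domain("duplicate OTU ids in abundance vector")
  out <- data.frame(otu_id = as.character(otu_ids), x = as.numeric(x),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "N") <- sum(out$x)
  attr(out, "S") <- nrow(out)
  class(out) <- c("abundance_vector", "data.frame")
  out
}

#' @rdname abundance_vector
#' @param v An `abundance_vector`.
#' @export
total_reads <- function(v) attr(v, "N")

#' @rdname abundance_vector
#' @export
richness <- function(v) attr(v, "S")

#' Read/write an abundance vector as two-column TSV
#'
#' @param v An `abundance_vector`.
#' @param path File path.
#' @return The abundance vector (read) or `path` invisibly (write).
#' @export
write_abundance_vector <- function(v, path) {
  stopifnot(inherits(v, "abundance_vector"))
  data.table::fwrite(as.data.frame(v), path, sep = "\t")
  invisible(path)
}

#' @rdname write_abundance_vector
#' @export
read_abundance_vector <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  abundance_vector(dt[[2]], otu_ids = dt[[1]])
}

#' Rank-abundance representation
#'
#' Sorts abundances in descending order; ties are broken lexicographically
#' by OTU id so curves are reproducible across runs. The normalized rank
#' r/S in (0, 1] equals the empirical complementary cumulative distribution
#' evaluated at each abundance, which is why the rank-abundance exponent
#' equals the CCD exponent alpha.
#'
#' @param v An `abundance_vector`.
#' @return A data.frame with columns `rank`, `otu_id`, `x`, `rank_norm`.
#' @export
rank_abundance <- function(v) {
  stopifnot(inherits(v, "abundance_vector"))
  if (nrow(v) < 1) stop_domain("empty abundance vector")
  ord <- order(-v$x, v$otu_id)
  data.frame(
    rank = seq_len(nrow(v)),
    otu_id = v$otu_id[ord],
    x = v$x[ord],
    rank_norm = seq_len(nrow(v)) / nrow(v),
    stringsAsFactors = FALSE
  )
}
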