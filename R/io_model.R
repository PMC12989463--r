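## Input model: taxon-by-sample valve counts, per-sample environment, and
## the bound analysis set used by the downstream modules.

#' Validate a count matrix
#'
#' Checks that a taxon-by-sample table of valve counts is a non-negative
#' integer matrix with unique taxon and sample identifiers.
#'
#' @param counts numeric matrix, taxa as rows, samples as columns, with
#'   dimnames.
#' @return the matrix, invisibly, with storage mode integer.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) < 1L || ncol(counts) < 1L)
    stop("counts must be a matrix with at least 1 taxon and 1 sample")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-integer or negative count at taxon '",
         rownames(counts)[bad[1L, 1L]], "', sample '",
         colnames(counts)[bad[1L, 2L]], "'")
  storage.mode(counts) <- "integer"
  invisible(counts)
}

detect_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a taxon-by-sample valve count table
#'
#' Reads a delimited text file with an id header row and id first column.
#' Orientation is normalized to taxa-as-rows.
#'
#' @param path file path (.csv comma-delimited, .tsv tab-delimited; override
#'   with `delim`).
#' @param taxa_as_rows logical; set `FALSE` when the file stores samples as
#'   rows, in which case the table is transposed on read.
#' @param delim optional field delimiter overriding extension detection.
#' @return validated integer matrix, taxa as rows.
#' @export
read_count_matrix <- function(path, taxa_as_rows = TRUE, delim = NULL) {
  d <- utils::read.table(path, sep = detect_delim(path, delim), header = TRUE,
                         row.names = 1L, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d)
  if (!is.numeric(m)) stop("count table contains non-numeric cells")
  if (!taxa_as_rows) m <- t(m)
  validate_count_matrix(m)
  m
}

#' Write a count matrix to CSV
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @export
write_count_matrix <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = TRUE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects one row per sample with a `sample` id column; recognised columns
#' are `mat_p` (total phosphorus of the periphyton mat, ug P per g dry
#' mass), `region`, `latitude`, `longitude`, `year`, and any extras are kept.
#' Missing mat P may be an empty cell or `NA`.
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @return data frame with unique `sample` ids.
#' @export
read_sample_table <- function(path, delim = NULL) {
  d <- utils::read.table(path, sep = detect_delim(path, delim), header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  validate_sample_table(d)
  d
}

#' @rdname read_sample_table
#' @param samples sample metadata data frame.
#' @export
validate_sample_table <- function(samples) {
  if (!"sample" %in% names(samples)) stop("sample table needs a 'sample' column")
  if (anyDuplicated(samples$sample))
    stop("duplicate sample ids: ",
         paste(unique(samples$sample[duplicated(samples$sample)]), collapse = ", "))
  if ("mat_p" %in% names(samples)) {
    bad <- !is.na(samples$mat_p) & samples$mat_p <= 0
    if (any(bad))
      stop("mat_p must be positive where present; offending samples: ",
           paste(samples$sample[bad], collapse = ", "))
  }
  for (cc in intersect(c("latitude", "longitude"), names(samples))) {
    bad <- !is.na(samples[[cc]]) & !is.finite(samples[[cc]])
    if (any(bad)) stop("non-finite ", cc, " for samples: ",
                       paste(samples$sample[bad], collapse = ", "))
  }
  invisible(samples)
}

#' Bind counts and sample metadata into a validated analysis set
#'
#' Restricts the metadata to the samples present in the count matrix, in
#' count-matrix order, and flags samples lacking mat P (those are excluded
#' from gradient-dependent operations downstream).
#'
#' @param counts validated count matrix (taxa x samples).
#' @param samples sample metadata data frame with a `sample` column.
#' @return object of class `analysis_set`: list with elements `counts`,
#'   `samples` (co-ordered) and `has_mat_p` (logical per sample).
#' @export
bind_analysis_set <- function(counts, samples) {
  validate_count_matrix(counts)
  validate_sample_table(samples)
  missing <- setdiff(colnames(counts), samples$sample)
  if (length(missing) > 0L)
    stop("count samples absent from metadata: ", paste(missing, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  has_p <- if ("mat_p" %in% names(samples)) !is.na(samples$mat_p)
           else rep(FALSE, nrow(samples))
  n_missing <- sum(!has_p)
  if (n_missing > 0L)
    message(n_missing, " sample(s) lack mat_p and are excluded from ",
            "gradient-dependent operations")
  structure(list(counts = counts, samples = samples, has_mat_p = has_p),
            class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  cat("analysis_set:", nrow(x$counts), "taxa x", ncol(x$counts), "samples;",
      sum(x$has_mat_p), "with mat P\n")
  invisible(x)
}

#' Randomly select one sample per site
#'
#' Draws, reproducibly for a fixed seed, exactly one sample from each site,
#' e.g. to remove repeat-visit pseudo-replication before calibration.
#'
#' @param sample_ids character vector of sample ids.
#' @param site_ids character vector, same length, mapping each sample to its
#'   site.
#' @param seed integer seed.
#' @return character vector of selected sample ids, one per site.
#' @export
select_one_per_site <- function(sample_ids, site_ids, seed) {
  stopifnot(length(sample_ids) == length(site_ids))
  with_seed(derive_seed(seed, "one_per_site"), {
    sel <- vapply(split(as.character(sample_ids), site_ids), function(s) {
      if (length(s) == 1L) s else sample(s, 1L)
    }, character(1))
    unname(sel)
  })
}
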