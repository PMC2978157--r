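#' Read a genes-by-samples expression table
#'
#' Parses a tab-delimited expression table whose header row holds sample
#' identifiers and whose first column holds gene identifiers. Expression is
#' taken as provided (log scale assumed by downstream correlation tests).
#' Rows sharing a gene identifier (e.g. multiple probes mapped to one gene)
#' are collapsed with `collapse`.
#'
#' @param path Path to a TSV file.
#' @param collapse How duplicate gene rows are combined: `"mean"` (default),
#'   `"max"` (per-sample maximum), or `"first"`.
#' @return A numeric matrix (genes x samples) with gene identifiers as row
#'   names and sample identifiers as column names.
#' @export
read_expression_table <- function(path, collapse = c("mean", "max", "first")) {
  collapse <- match.arg(collapse)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    abort(paste0("duplicate sample ids in header: ",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  if (nrow(raw) == 0L) abort("no data rows")
  genes <- raw[[1]]
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' for gene '%s' in column '%s'",
                    col[bad[1]], genes[bad[1]], samples[j]))
    }
    vals[, j] <- num
  }
  all_missing <- rowSums(is.finite(vals)) == 0L
  if (any(all_missing)) {
    warn(sprintf("dropped %d all-missing row(s)", sum(all_missing)))
    vals <- vals[!all_missing, , drop = FALSE]
    genes <- genes[!all_missing]
  }
  if (nrow(vals) == 0L) abort("no data rows")
  first_seen <- unique(genes)
  if (anyDuplicated(genes)) {
    vals <- switch(collapse,
      mean = rowsum(vals, genes, na.rm = TRUE) /
        rowsum((!is.na(vals)) + 0, genes),
      max = {
        grp <- split(seq_along(genes), genes)
        t(vapply(grp, function(i) {
          apply(vals[i, , drop = FALSE], 2, function(x)
            if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
        }, numeric(ncol(vals))))
      },
      first = {
        keep <- !duplicated(genes)
        rownames(vals) <- genes
        vals[keep, , drop = FALSE]
      })
    if (collapse == "mean") vals[!is.finite(vals)] <- NA_real_
  } else {
    rownames(vals) <- genes
  }
  vals[first_seen, , drop = FALSE]
}

#' Construct a two-condition sample design
#'
#' @param sample Character vector of sample identifiers.
#' @param condition Character vector of condition labels (exactly two distinct
#'   labels, each with at least 3 samples -- the Pearson-correlation floor).
#' @param positive The condition treated as positive (e.g. the disease state);
#'   defaults to the first label in order of appearance.
#' @return A `sample_design` tibble with columns `sample` and `condition` and
#'   a `positive` attribute.
#' @export
sample_design <- function(sample, condition, positive = NULL) {
  d <- tibble(sample = as.character(sample),
              condition = as.character(condition)) |> dplyr::distinct()
  if (anyDuplicated(d$sample)) {
    dup <- unique(d$sample[duplicated(d$sample)])
    abort(paste0("sample(s) listed with conflicting condition labels: ",
                 paste(dup, collapse = ", ")))
  }
  labs <- unique(d$condition)
  if (length(labs) != 2L) {
    abort(sprintf("design must have exactly two condition labels, found %d",
                  length(labs)))
  }
  cnt <- table(d$condition)
  if (any(cnt < 3L)) abort("minimum 3 samples per condition")
  positive <- positive %||% labs[1]
  if (!positive %in% labs) abort("`positive` is not one of the condition labels")
  structure(d, positive = positive,
            class = c("sample_design", class(d)))
}

#' Read a sample-to-condition design table
#'
#' @param path Two-column TSV (sample id, condition label); a header row is
#'   detected when the first field is `sample` or `sample_id`.
#' @inheritParams sample_design
#' @return A [sample_design()] tibble.
#' @export
read_sample_design <- function(path, positive = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty design file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) abort(sprintf("design line %d does not have 2 fields", bad[1]))
  if (tolower(fields[[1]][1]) %in% c("sample", "sample_id")) fields <- fields[-1]
  m <- do.call(rbind, fields)
  sample_design(m[, 1], m[, 2], positive = positive)
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("Two-condition sample design (%d samples; positive = '%s')\n",
              nrow(x), design_positive(x)))
  print(table(x$condition))
  invisible(x)
}

#' Positive-condition label of a design
#' @param design A [sample_design()].
#' @return The positive condition label.
#' @export
design_positive <- function(design) attr(design, "positive")

#' Samples belonging to one condition
#' @inheritParams design_positive
#' @param condition A condition label of the design.
#' @return Character vector of sample ids.
#' @export
design_samples <- function(design, condition) {
  stopifnot(condition %in% design$condition)
  design$sample[design$condition == condition]
}

design_conditions <- function(design) {
  pos <- design_positive(design)
  c(pos, setdiff(unique(design$condition), pos))
}
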