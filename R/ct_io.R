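#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("ASD", "TS", "TS+ASD", "NC")

DEFAULT_SENTINELS <- c("Undetermined", "NA", "")

#' Construct a Ct matrix object
#'
#' A `ct_matrix` holds raw cycle-threshold (Ct) values for miRNAs (rows) by
#' samples (columns) together with a per-well flag mask. A flagged well is a
#' failed/undetermined amplification; its Ct is never consumed as a number by
#' any downstream computation ([ct_values()] masks it to `NA`).
#'
#' @param ct numeric matrix, miRNAs x samples, with unique dimnames.
#' @param flag logical matrix of identical dimensions; `TRUE` marks a flagged
#'   well. Defaults to all-`FALSE`.
#' @param panel optional panel label (e.g. `"A"`/`"B"`).
#' @return An object of class `ct_matrix`.
#' @export
ct_matrix <- function(ct, flag = NULL, panel = NA_character_) {
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  if (is.null(flag)) flag <- matrix(FALSE, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  flag <- as.matrix(flag)
  stopifnot(is.logical(flag))
  if (!identical(dim(ct), dim(flag)))
    stop("`ct` and `flag` must have identical dimensions")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have row (miRNA) and column (sample) names")
  .check_unique(rownames(ct), "miRNA id")
  .check_unique(colnames(ct), "sample id")
  dimnames(flag) <- dimnames(ct)
  flag[is.na(ct)] <- TRUE
  structure(list(ct = ct, flag = flag, panel = panel), class = "ct_matrix")
}

.check_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup))
    stop(sprintf("duplicate %s: %s", what, paste(dup, collapse = ", ")))
  invisible(x)
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d miRNAs x %d samples (panel %s), %d flagged wells\n",
              nrow(x$ct), ncol(x$ct), x$panel, sum(x$flag)))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' Numeric Ct values with flagged wells masked to NA
#'
#' The only sanctioned way to read Ct values out of a [ct_matrix()]: flagged
#' wells come back as `NA` so they can never be consumed as numbers.
#'
#' @param x a `ct_matrix`.
#' @return numeric matrix with `NA` at every flagged well.
#' @export
ct_values <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  out <- x$ct
  out[x$flag] <- NA_real_
  out
}

.detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a Ct matrix from a delimited text file
#'
#' Expects a header row of sample ids, a first column of miRNA ids, and
#' numeric cells; sentinel tokens (by default `"Undetermined"`, `"NA"`, empty)
#' mark flagged wells. The file encoding of flags varies across instrument
#' exports, hence the configurable sentinel vocabulary.
#'
#' @param path file path (.tsv or .csv; delimiter auto-detected from the
#'   extension, overridable via `sep`).
#' @param sentinels character vector of tokens denoting a flagged well.
#' @param panel optional panel label stored on the result.
#' @param sep field delimiter override.
#' @return A [ct_matrix()].
#' @export
read_ct_matrix <- function(path, sentinels = DEFAULT_SENTINELS,
                           panel = NA_character_, sep = NULL) {
  stopifnot(file.exists(path))
  sep <- .detect_sep(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  ids <- raw[[1L]]
  .check_unique(ids, "miRNA id")
  .check_unique(colnames(raw)[-1L], "sample id")
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(cells) <- ids
  flag <- matrix(cells %in% sentinels, nrow(cells), dimnames = dimnames(cells))
  ct <- suppressWarnings(matrix(as.numeric(cells), nrow(cells),
                                dimnames = dimnames(cells)))
  bad <- which(is.na(ct) & !flag, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric, non-sentinel cell at row '%s', column '%s': '%s'",
                 rownames(cells)[bad[1, 1]], colnames(cells)[bad[1, 2]],
                 cells[bad[1, 1], bad[1, 2]]))
  ct[flag] <- NA_real_
  ct_matrix(ct, flag, panel = panel)
}

#' Write a Ct matrix to a delimited text file
#'
#' Flagged wells are serialized as the first sentinel token so that
#' [read_ct_matrix()] round-trips the flag mask.
#'
#' @param x a [ct_matrix()].
#' @param path output path.
#' @param sentinel token written for flagged wells.
#' @param sep field delimiter override.
#' @export
write_ct_matrix <- function(x, path, sentinel = "Undetermined", sep = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  sep <- .detect_sep(path, sep)
  cells <- matrix(format(x$ct, trim = TRUE, digits = 15), nrow(x$ct),
                  dimnames = dimnames(x$ct))
  cells[x$flag] <- sentinel
  df <- data.frame(miRNA = rownames(cells), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort metadata table
#'
#' One row per sample with columns `sample`, `group`, `IQ`, `YGTSS`,
#' `ADOS_A`..`ADOS_D` (Communication, Social interaction, Imagination,
#' Repetitive and restricted behaviors). Extra columns are preserved.
#' Group labels are validated against the four-level vocabulary
#' ASD / TS / TS+ASD / NC.
#'
#' @param path file path (.tsv or .csv).
#' @param case_fold fold group labels to the canonical case before
#'   validation (default `FALSE`: `"asd"` is an error).
#' @param sep field delimiter override.
#' @return A `data.frame` of class `cohort_table`, `group` a factor with
#'   levels ASD, TS, TS+ASD, NC.
#' @export
read_cohort <- function(path, case_fold = FALSE, sep = NULL) {
  stopifnot(file.exists(path))
  sep <- .detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "\"")
  as_cohort_table(df, case_fold = case_fold)
}

#' Validate a data frame as a cohort table
#'
#' @param df data.frame with at least `sample` and `group` columns.
#' @param case_fold see [read_cohort()].
#' @return the validated `cohort_table`.
#' @export
as_cohort_table <- function(df, case_fold = FALSE) {
  need <- c("sample", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing cohort columns: ", paste(miss, collapse = ", "))
  df$sample <- as.character(df$sample)
  .check_unique(df$sample, "sample id")
  grp <- as.character(df$group)
  if (case_fold) {
    idx <- match(toupper(grp), toupper(GROUP_LEVELS))
    grp <- GROUP_LEVELS[idx]
  }
  unknown <- setdiff(unique(grp), GROUP_LEVELS)
  if (length(unknown) || anyNA(grp))
    stop("unknown group label(s): ",
         paste(unique(c(unknown, if (anyNA(grp)) "<NA>")), collapse = ", "))
  df$group <- factor(grp, levels = GROUP_LEVELS)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table
#' @param cohort a cohort table.
#' @param path output path.
#' @param sep field delimiter override.
#' @export
write_cohort <- function(cohort, path, sep = NULL) {
  sep <- .detect_sep(path, sep)
  utils::write.table(cohort, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: tab-separated `term`, `description`, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (term -> genes), with a
#'   `description` attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- vapply(parts, `[`, character(1), 1L)
  .check_unique(terms, "gene-set term")
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- terms
  attr(sets, "description") <- stats::setNames(
    vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1)),
    terms)
  sets
}

#' Read an undirected interaction network from an edge list
#'
#' Accepts a two-column TSV (`from`, `to`; a header line is detected and
#' skipped) or a SIF file (`from  relation  to`). Self-loops are dropped with
#' a warning and duplicate/reciprocal edges are collapsed.
#'
#' @param path file path.
#' @return an undirected, simplified `igraph` graph.
#' @export
read_edge_list <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  ncols <- lengths(parts)
  edges <- t(vapply(parts, function(p) {
    if (length(p) >= 3) c(p[1], p[3]) else c(p[1], p[2])
  }, character(2)))
  if (nrow(edges) && tolower(edges[1, 1]) %in% c("from", "source", "node1"))
    edges <- edges[-1L, , drop = FALSE]
  edges_from_pairs(edges)
}

#' Build an undirected graph from a two-column character matrix
#' @param edges 2-column character matrix of endpoints.
#' @return simplified undirected `igraph` graph.
#' @export
edges_from_pairs <- function(edges) {
  edges <- as.matrix(edges)
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}
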