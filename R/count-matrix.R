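#' Construct a tag/gene count matrix
#'
#' The shared count container of the package: an integer (or, after
#' [tpm_normalize()], real-valued) matrix of tags or genes by libraries,
#' optionally carrying a two-group assignment of libraries (e.g. normal vs
#' cancer) used by the permutation scorer.
#'
#' @param counts numeric matrix with unique rownames (tag or gene ids) and
#'   unique colnames (library ids); all entries finite and non-negative.
#' @param unit `"raw"` for raw tag counts, `"tpm"` for tags-per-million
#'   normalized values (every column must then sum to 1e6).
#' @param groups optional named character vector mapping every library id to a
#'   group label.
#' @return an object of class `"count_matrix"`: a list with elements
#'   `counts`, `unit` and `groups`.
#' @seealso [read_count_matrix()], [tpm_normalize()], [collapse_tags()]
#' @export
count_matrix <- function(counts, unit = c("raw", "tpm"), groups = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have row and column names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate row ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate library ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  if (any(!is.finite(counts)))
    stop("counts must all be finite", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row '%s', library '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  if (!is.null(groups)) {
    groups <- check_groups(groups, colnames(counts))
  }
  if (unit == "tpm") {
    cs <- colSums(counts)
    if (any(abs(cs - 1e6) > 1e-9 * 1e6))
      stop("unit = 'tpm' requires every column to sum to 1,000,000",
           call. = FALSE)
  }
  structure(list(counts = counts, unit = unit, groups = groups),
            class = "count_matrix")
}

check_groups <- function(groups, lib_ids) {
  if (is.factor(groups)) groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(names(groups)))
    stop("`groups` must be named by library id", call. = FALSE)
  missing_libs <- setdiff(lib_ids, names(groups))
  if (length(missing_libs))
    stop("libraries without a group label: ",
         paste(missing_libs, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(groups), lib_ids)
  if (length(extra))
    stop("group file names libraries absent from the matrix: ",
         paste(extra, collapse = ", "), call. = FALSE)
  groups[lib_ids]
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d rows x %d libraries [unit: %s]\n",
              nrow(x$counts), ncol(x$counts), x$unit))
  if (!is.null(x$groups)) {
    tb <- table(x$groups)
    cat("groups:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a tag/gene count matrix from a TSV file
#'
#' Strict tab-separated dialect: first row is a header of library ids, first
#' column holds tag/gene ids, every remaining cell must parse as an explicit
#' non-negative number (`"."` or empty cells are rejected). Lines starting
#' with `#` are treated as comments.
#'
#' @param path path to the count TSV.
#' @param groups_path optional 2-column headerless TSV (library id, group
#'   label) covering every library in the matrix.
#' @return a [count_matrix()] with `unit = "raw"`; row and column order
#'   preserved from the file.
#' @export
read_count_matrix <- function(path, groups_path = NULL) {
  raw <- read_tsv_table(path)
  m <- parse_numeric_table(raw, path)
  groups <- if (!is.null(groups_path)) read_group_file(groups_path)
  count_matrix(m, unit = "raw", groups = groups)
}

read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", row.names = NULL)
  if (ncol(df) < 2) stop("expected at least one data column in ", path,
                         call. = FALSE)
  df
}

parse_numeric_table <- function(df, path) {
  ids <- df[[1]]
  libs <- colnames(df)[-1]
  m <- matrix(NA_real_, nrow(df), length(libs),
              dimnames = list(ids, libs))
  for (j in seq_along(libs)) {
    cell <- df[[j + 1]]
    bad <- cell == "" | cell == "." | is.na(suppressWarnings(as.numeric(cell)))
    if (any(bad))
      stop(sprintf("%s: cell '%s' at row '%s', library '%s' is not a number",
                   path, cell[which(bad)[1]], ids[which(bad)[1]], libs[j]),
           call. = FALSE)
    m[, j] <- as.numeric(cell)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: negative count at row '%s', library '%s'",
                 path, ids[bad[1]], libs[bad[2]]), call. = FALSE)
  }
  m
}

read_group_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", colClasses = "character")
  if (ncol(df) != 2)
    stop("group file must have exactly two columns (library id, group label): ",
         path, call. = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_matrix()]; integer matrices round-trip
#' bit-identically. Optional `#`-prefixed comment lines (e.g. provenance
#' headers) are written before the header row and skipped on re-read.
#'
#' @param m a [count_matrix()].
#' @param path output path.
#' @param comments character vector of comment lines (without the leading
#'   `#`).
#' @export
write_count_matrix <- function(m, path, comments = character()) {
  stopifnot(inherits(m, "count_matrix"))
  write_tsv_matrix(m$counts, path, id_col = "id", comments = comments)
  invisible(path)
}

write_tsv_matrix <- function(mat, path, id_col = "id",
                             comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c(id_col, colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1, function(r) paste(format(r, trim = TRUE,
                                                 scientific = FALSE,
                                                 digits = 15),
                                          collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Normalize raw tag counts to tags per million
#'
#' Each library (column) is scaled so its total equals 1,000,000, putting
#' libraries of different sequencing depth on a common footing.
#'
#' @param m a raw-unit [count_matrix()].
#' @return a [count_matrix()] with `unit = "tpm"`; groups are preserved.
#' @export
tpm_normalize <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$unit != "raw")
    stop("tpm_normalize() expects raw counts", call. = FALSE)
  totals <- colSums(m$counts)
  if (any(totals == 0))
    stop("library with zero total tags cannot be normalized: ",
         paste(colnames(m$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  tpm <- sweep(m$counts, 2, 1e6 / totals, `*`)
  count_matrix(tpm, unit = "tpm", groups = m$groups)
}

#' Read a tag-to-gene map
#'
#' 2-column headerless TSV (tag, gene symbol). Each tag must map to exactly
#' one gene; ambiguous maps are rejected rather than resolved by guesswork.
#'
#' @param path path to the map TSV.
#' @return named character vector: `map[tag] == gene`.
#' @export
read_tag_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", colClasses = "character")
  if (ncol(df) != 2)
    stop("tag map must have exactly two columns (tag, gene)", call. = FALSE)
  tag_map(stats::setNames(df[[2]], df[[1]]))
}

tag_map <- function(map) {
  if (!length(map)) stop("empty tag-to-gene map", call. = FALSE)
  if (is.null(names(map))) stop("tag map must be named by tag", call. = FALSE)
  if (anyDuplicated(names(map)))
    stop("ambiguous tag map: tags mapping to multiple genes: ",
         paste(unique(names(map)[duplicated(names(map))]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(map))) stop("empty gene symbol in tag map", call. = FALSE)
  map
}

#' Collapse tags to genes by cumulative raw count
#'
#' Multiple tags frequently map to one gene (transcript variants); their raw
#' counts are summed per library so downstream analysis sees one cumulative
#' count per gene. Collapse operates on raw counts, before any normalization.
#' Tags absent from the map are dropped and reported via the
#' `"dropped_tags"` attribute of the result.
#'
#' @param m a raw-unit [count_matrix()] whose rows are tags.
#' @param map named character vector (tag -> gene), e.g. from
#'   [read_tag_map()].
#' @return a [count_matrix()] whose rows are gene symbols, with attribute
#'   `dropped_tags` listing unmapped tag ids.
#' @export
collapse_tags <- function(m, map) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$unit != "raw")
    stop("collapse_tags() must run on raw counts, before normalization",
         call. = FALSE)
  map <- tag_map(map)
  tags <- rownames(m$counts)
  mapped <- tags[tags %in% names(map)]
  if (!length(mapped))
    stop("tag map covers none of the tags in the matrix", call. = FALSE)
  dropped <- setdiff(tags, mapped)
  genes <- map[mapped]
  agg <- rowsum(m$counts[mapped, , drop = FALSE], group = genes,
                reorder = FALSE)
  out <- count_matrix(agg, unit = "raw", groups = m$groups)
  attr(out, "dropped_tags") <- dropped
  if (length(dropped))
    message(length(dropped), " unmapped tag(s) dropped during collapse")
  out
}
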