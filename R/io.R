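#' Construct an expression matrix
#'
#' Container for a genes x samples expression matrix of one cohort. Values are
#' RSEM-like non-negative abundances (\code{scale = "raw"}) or log2-transformed
#' values (\code{scale = "log2"}).
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param cohort_id single string labelling the cohort.
#' @param scale either \code{"raw"} or \code{"log2"}.
#' @return An object of class \code{"ExpressionMatrix"} with fields
#'   \code{values}, \code{cohort_id}, \code{scale}.
#' @export
expression_matrix <- function(values, cohort_id = "cohort", scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  .check_ids(rownames(values), "gene")
  .check_ids(colnames(values), "sample")
  if (anyNA(values))
    stop("expression matrix must not contain missing values")
  if (scale == "raw" && any(values < 0))
    stop("raw-scale expression values must be non-negative")
  structure(list(values = values, cohort_id = cohort_id, scale = scale),
            class = "ExpressionMatrix")
}

#' Construct a methylation beta matrix
#'
#' Container for a probes x samples matrix of beta values in [0,1]; missing
#' entries (NA) are allowed.
#'
#' @param betas numeric matrix, probes in rows, samples in columns.
#' @param cohort_id single string labelling the cohort.
#' @return An object of class \code{"MethylationMatrix"} with fields
#'   \code{betas}, \code{cohort_id}.
#' @export
methylation_matrix <- function(betas, cohort_id = "cohort") {
  betas <- as.matrix(betas)
  .check_ids(rownames(betas), "probe")
  .check_ids(colnames(betas), "sample")
  rng <- range(betas, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0,1]; found range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  structure(list(betas = betas, cohort_id = cohort_id),
            class = "MethylationMatrix")
}

.check_ids <- function(ids, what) {
  if (is.null(ids)) stop(what, " ids (dimnames) are required")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicated ", what, " id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples (%s scale)\n",
              x$cohort_id, nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix [%s]: %d probes x %d samples, %d missing\n",
              x$cohort_id, nrow(x$betas), ncol(x$betas), sum(is.na(x$betas))))
  invisible(x)
}

#' Read an expression or methylation matrix from TSV
#'
#' Expects a tab-separated file with the first column holding row ids and the
#' header holding sample ids; the string \code{"NA"} denotes a missing value.
#' Missing values are only legal for methylation.
#'
#' @param path file path.
#' @param kind \code{"expression"} or \code{"methylation"}.
#' @param cohort_id cohort label to attach.
#' @param scale expression scale flag (ignored for methylation).
#' @return \code{ExpressionMatrix} or \code{MethylationMatrix}.
#' @export
read_matrix <- function(path, kind = c("expression", "methylation"),
                        cohort_id = "cohort", scale = "raw") {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = "NA", stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (kind == "expression") expression_matrix(m, cohort_id, scale)
  else methylation_matrix(m, cohort_id)
}

#' Write a matrix container (or plain matrix) as TSV
#'
#' Round-trips through \code{read_matrix} losslessly at full double precision
#' (>= 15 significant digits). Missing cells are written as \code{"NA"}.
#'
#' @param x \code{ExpressionMatrix}, \code{MethylationMatrix} or matrix.
#' @param path output file path.
#' @param id_col name of the first (row-id) column in the header.
#' @export
write_matrix <- function(x, path, id_col = "id") {
  m <- if (inherits(x, "ExpressionMatrix")) x$values
       else if (inherits(x, "MethylationMatrix")) x$betas
       else as.matrix(x)
  df <- data.frame(id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  names(df)[-1L] <- colnames(m)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a probe annotation table
#'
#' BED-like TSV with columns \code{probe_id}, \code{chromosome},
#' \code{position} (1-based), \code{region_class} (one of \code{cgi},
#' \code{shore_shelf}, \code{opensea}), \code{promoter_gene} (gene symbol or
#' NA) and \code{promoter_cgi} (TRUE/FALSE).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_probe_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           na.strings = "NA", stringsAsFactors = FALSE)
  ann$promoter_cgi <- as.logical(ann$promoter_cgi)
  validate_probe_annotation(ann)
}

#' Validate a probe annotation data.frame
#'
#' @param ann data.frame with the columns listed in
#'   \code{\link{read_probe_annotation}}.
#' @return the validated annotation (invisibly usable).
#' @export
validate_probe_annotation <- function(ann) {
  need <- c("probe_id", "chromosome", "position", "region_class",
            "promoter_gene", "promoter_cgi")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  .check_ids(ann$probe_id, "probe")
  if (any(ann$position < 1)) stop("probe positions must be >= 1")
  ok_class <- c("cgi", "shore_shelf", "opensea")
  bad <- setdiff(unique(ann$region_class), ok_class)
  if (length(bad)) stop("unknown region_class value(s): ", paste(bad, collapse = ", "))
  if (any(ann$promoter_cgi & ann$region_class != "cgi"))
    stop("promoter_cgi = TRUE requires region_class = 'cgi'")
  ann
}

#' Read a sample sheet
#'
#' TSV with columns \code{sample_id}, \code{status} (\code{normal} or
#' \code{cancer}), \code{cohort_id} and optional \code{group}.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, na.strings = "NA",
                             stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet data.frame
#' @param sheet data.frame with sample_id, status, cohort_id columns.
#' @return the validated sheet.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "status", "cohort_id")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  .check_ids(sheet$sample_id, "sample")
  bad <- setdiff(unique(sheet$status), c("normal", "cancer"))
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  if (!"group" %in% names(sheet)) sheet$group <- NA_character_
  sheet
}

#' Read an epigenetic-enzyme gene list
#'
#' One symbol per line; defaults to the list bundled with the package (the
#' chromatin/DNA-methylation writer, reader, eraser and editor genes named in
#' the main analyses this package implements).
#'
#' @param path file path; if \code{NULL} the bundled list is used.
#' @return character vector of unique gene symbols.
#' @export
read_ee_genes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ee_genes.txt", package = "methylZ")
  sym <- readLines(path)
  sym <- trimws(sym)
  sym <- sym[nzchar(sym) & !startsWith(sym, "#")]
  if (anyDuplicated(sym))
    stop("duplicated gene symbol(s) in EE list: ",
         paste(unique(sym[duplicated(sym)]), collapse = ", "))
  sym
}

#' Align expression, methylation and sample sheet of one cohort
#'
#' Restricts all three inputs to the samples present in every one of them,
#' preserving the sample order of the expression matrix. The matching-sample
#' requirement mirrors analyses that correlate expression with methylation
#' indices over matched tumor samples only.
#'
#' @param expr \code{ExpressionMatrix}.
#' @param meth \code{MethylationMatrix}.
#' @param sheet sample sheet data.frame.
#' @return list with the subset \code{expr}, \code{meth}, \code{sheet} and a
#'   \code{dropped} count vector (samples lost from each input).
#' @export
align_cohort <- function(expr, meth, sheet) {
  sheet <- validate_sample_sheet(sheet)
  se <- colnames(expr$values)
  sm <- colnames(meth$betas)
  ss <- sheet$sample_id
  keep <- se[se %in% sm & se %in% ss]  # expression order preserved
  if (!length(keep)) stop("no samples shared by expression, methylation and sample sheet")
  out_sheet <- sheet[match(keep, sheet$sample_id), , drop = FALSE]
  rownames(out_sheet) <- NULL
  list(
    expr = expression_matrix(expr$values[, keep, drop = FALSE], expr$cohort_id, expr$scale),
    meth = methylation_matrix(meth$betas[, keep, drop = FALSE], meth$cohort_id),
    sheet = out_sheet,
    dropped = c(expression = length(se) - length(keep),
                methylation = length(sm) - length(keep),
                sheet = length(ss) - length(keep))
  )
}
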